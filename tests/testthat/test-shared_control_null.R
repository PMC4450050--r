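test_that("rho_shared handles the limiting designs", {
  expect_equal(rho_shared(study_pair_design(500, 600, 100, 200, 0)), 0)
  # fully shared controls, equal sizes: rho = N/(N+N0) = 1/2
  expect_equal(rho_shared(study_pair_design(2000, 2000, 0, 0, 2000)), 0.5)
  expect_error(rho_shared(list(n_cases_i = -1, n_cases_j = 1,
                               n_controls_unique_i = 0,
                               n_controls_unique_j = 0,
                               n_controls_shared = 1)), "negative")
})

test_that("the asymptotic rho matches the genotype-level Monte-Carlo oracle", {
  d <- study_pair_design(6087, 6088, 0, 0, 15171)
  zz <- simulate_genotype_studies(2000, design = d, seed = 21)
  expect_lt(abs(cor(zz$z_i, zz$z_j) - d$rho), 0.02)
  expect_equal(d$rho, 0.2864, tolerance = 1e-3)
})

test_that("tail_prob reduces to known values and matches Monte-Carlo", {
  expect_equal(tail_prob(0, 0, 0.3, 2), 1)
  # independence: product of two-sided tails
  expect_equal(tail_prob(1.959964, 1.959964, 0, 0), 0.0025, tolerance = 1e-6)
  # Monte-Carlo at rho=0.5, sigma2=8
  set.seed(31)
  n <- 2e6
  x <- rnorm(n); y <- 0.5 * x + sqrt(8.75) * rnorm(n)  # cov [[1,.5],[.5,9]]
  emp <- mean(abs(x) > 2 & abs(y) > 2)
  se <- sqrt(emp * (1 - emp) / n)
  expect_lt(abs(tail_prob(2, 2, 0.5, 8) - emp), 3 * se)
  expect_error(tail_prob(1, 1, 1, 0), "rho")
})

test_that("cumulative expected quantile collapses to p_i under independence", {
  spec <- make_spec(0, 0.9, 3)
  p <- c(1e-6, 0.01, 0.5, 1)
  expect_identical(expected_quantile_cum(p, 0.05, spec), p)
  spec2 <- make_spec(0.5, 0.9, 3)
  expect_identical(expected_quantile_cum(p, 1, spec2), p)
})

test_that("cumulative expected quantile matches simulated conditional frequencies", {
  spec <- make_spec(0.5, 0.9, 3)
  sim <- simulate_pair(sim_config(n_snps = 2e5, pi0_i = 1, pi0_j = 0.9,
                                  sigma_j = 3, rho = 0.5, seed = 8))
  sel <- sim$p_j <= 0.05
  emp <- mean(sim$p_i[sel] <= 0.01)
  th <- expected_quantile_cum(0.01, 0.05, spec)
  se <- sqrt(th * (1 - th) / sum(sel))
  expect_lt(abs(th - emp), 4 * se)
})

test_that("expected quantile is monotone in p_i, exceeds p_i under sharing", {
  spec <- make_spec(0.5, 0.9, 3)
  p_i <- 10^seq(-8, 0, length.out = 30)
  for (p_j in c(1e-4, 0.01, 0.05)) {
    eq <- expected_quantile_cum(p_i, p_j, spec)
    expect_true(all(diff(eq) >= -1e-12))
    expect_equal(eq[30], 1)
    expect_true(all(eq >= p_i - 1e-12))  # "falsely low" raw p values
  }
})

test_that("assuming every conditional SNP null overestimates the quantile", {
  # red-dots effect: the pi0 = 1 expected quantile exceeds the true
  # conditional frequency at small p_j
  sim <- simulate_pair(sim_config(n_snps = 2e5, pi0_i = 1, pi0_j = 0.9,
                                  sigma_j = 3, rho = 0.5, seed = 12))
  spec_allnull <- make_spec(0.5, 1, 3)
  sel <- sim$p_j <= 0.01
  for (p_i in c(0.005, 0.02, 0.1)) {
    emp <- mean(sim$p_i[sel] <= p_i)
    expect_gt(expected_quantile_cum(p_i, 0.01, spec_allnull), emp)
  }
})

test_that("formula matches empirical conditional frequencies over random models", {
  set.seed(19)
  for (rep in 1:5) {
    rho <- runif(1, 0, 0.7)
    pi0 <- runif(1, 0.7, 1)
    sigma <- runif(1, 1, 4)
    spec <- make_spec(rho, pi0, sigma)
    sim <- simulate_pair(sim_config(n_snps = 1e5, pi0_i = 1, pi0_j = pi0,
                                    sigma_j = sigma, rho = rho,
                                    seed = 5000 + rep))
    p_j <- 0.05; p_i <- 0.02
    sel <- sim$p_j <= p_j
    emp <- mean(sim$p_i[sel] <= p_i)
    th <- expected_quantile_cum(p_i, p_j, spec)
    se <- sqrt(th * (1 - th) / sum(sel))
    expect_lt(abs(th - emp), 4 * se)
  }
})

test_that("point expected quantile: independence, single component, quadrature", {
  spec0 <- make_spec(0, 0.9, 3)
  expect_identical(expected_quantile_point(c(.01, .5), .05, spec0), c(.01, .5))

  # pi0 = 1: closed-form conditional normal tail vs direct numeric conditional
  spec1 <- make_spec(0.6, 1, 2)
  z_i <- p_to_z(0.01); z_j <- p_to_z(0.2)
  direct <- {
    m <- 0.6 * z_j; s <- sqrt(1 - 0.36)
    pnorm((-z_i - m) / s) + pnorm((z_i - m) / s, lower.tail = FALSE)
  }
  expect_equal(expected_quantile_point(0.01, 0.2, spec1), direct,
               tolerance = 1e-12)

  # integrating the point quantile over the conditional margin reproduces the
  # cumulative quantile on a 5 x 5 grid
  spec <- make_spec(0.5, 0.9, 3)
  f_absz <- function(t) 2 * (0.9 * dnorm(t) + 0.1 * dnorm(t, sd = sqrt(10)))
  for (p_i in c(0.001, 0.01, 0.05, 0.2, 0.8)) {
    for (p_j in c(0.005, 0.02, 0.1, 0.4, 0.9)) {
      zj <- p_to_z(p_j)
      num <- integrate(function(t) {
        sapply(t, function(tt) {
          expected_quantile_point(p_i, max(z_to_p(tt), 1e-300), spec)
        }) * f_absz(t)
      }, zj, 40, rel.tol = 1e-9)$value
      den <- integrate(f_absz, zj, 40, rel.tol = 1e-9)$value
      expect_equal(num / den, expected_quantile_cum(p_i, p_j, spec),
                   tolerance = 1e-4)
    }
  }
})

test_that("numeric-density path agrees with the closed form and degenerates", {
  mix <- list(pi0 = 0.9, sigma2 = 9)
  h <- discretize_mixture(mix, 201)
  for (p_i in c(0.003, 0.05)) {
    for (p_j in c(0.01, 0.3)) {
      expect_equal(expected_quantile_cum_numeric(p_i, p_j, 0.5, h),
                   expected_quantile_cum(p_i, p_j, make_spec(0.5, 0.9, 3)),
                   tolerance = 1e-3)
    }
  }
  # point mass at zero: reduces to the pi0 = 1 model
  h0 <- data.frame(eta = 0, weight = 1)
  expect_warning(
    v <- expected_quantile_cum_numeric(0.01, 0.05, 0.4, h0),
    "coarse")
  expect_equal(v, expected_quantile_cum(0.01, 0.05, make_spec(0.4, 1, 1)),
               tolerance = 1e-10)
})

test_that("the normal-mixture approximation is robust to heavy-tailed effects", {
  # H ~ scaled t3 (heavy tails) differs markedly from the normal assumption;
  # the approximation fitted by EM to data generated under it should still
  # produce expected quantiles close to the exact numeric computation
  nu <- 3; scale <- 2
  set.seed(101)
  n <- 1e5
  eta <- ifelse(runif(n) < 0.1, scale * rt(n, df = nu), 0)
  fit <- fit_null_mixture(eta + rnorm(n))
  spec_fit <- bivariate_null_spec(0.5, fit)
  grid <- seq(-80, 80, length.out = 1601)
  w_t <- dt(grid / scale, df = nu) / scale
  w_t <- 0.1 * w_t / sum(w_t)
  h_t <- rbind(data.frame(eta = 0, weight = 0.9),
               data.frame(eta = grid, weight = w_t))
  for (p_i in c(1e-6, 1e-4, 1e-3)) {
    for (p_j in c(0.001, 0.01, 0.1)) {
      truth <- expected_quantile_cum_numeric(p_i, p_j, 0.5, h_t)
      approx <- expected_quantile_cum(p_i, p_j, spec_fit)
      # error bounded well within a 1.5-fold band across the grid
      expect_lt(abs(log(approx / truth)), log(1.5))
    }
  }
})
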