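test_that("meff spans its extremes for k = 9 conditionals", {
  set.seed(50)
  base <- runif(200)
  # perfectly rank-correlated columns: one effective test
  x <- sapply(1:9, function(k) base * k)     # same ranks, different scales
  m1 <- meff(x)
  expect_equal(m1$meff, 1)
  expect_equal(m1$eigen_variance, 9)
  # independent columns: essentially a Bonferroni correction
  y <- matrix(runif(9 * 5000), ncol = 9)
  m2 <- meff(y)
  expect_equal(m2$meff, 10, tolerance = 0.05)
})

test_that("meff on two perfectly correlated blocks matches the hand eigenvalues", {
  set.seed(51)
  a <- runif(300); b <- runif(300)
  x <- cbind(sapply(1:4, function(k) a * k), sapply(1:5, function(k) b * k))
  m <- meff(x)
  # block-diagonal all-ones blocks of sizes 4 and 5: eigenvalues {4, 5, 0 x 7}
  ev <- c(4, 5, rep(0, 7))
  expect_equal(m$eigen_variance, var(ev), tolerance = 0.05)
  expect_equal(m$meff, 1 + 9 * (1 - var(ev) / 9), tolerance = 0.1)
})

test_that("meff input guards", {
  expect_error(meff(matrix(runif(100), ncol = 1)), "at least 2")
  expect_error(meff(cbind(rep(1, 100), runif(100))), "constant")
  expect_error(meff(matrix(runif(20), ncol = 2)), "fewer than 50")
})

test_that("combined_bound averages false-discovery counts across conditionals", {
  expect_equal(combined_bound(3e-5, 12, 1), 3e-5)
  expect_equal(combined_bound(c(1e-5, 3e-5), c(10, 20), 2),
               2 * (1e-4 + 6e-4) / 30)
  expect_warning(v <- combined_bound(c(1e-5, 3e-5), c(0, 0), 2), "undefined")
  expect_true(is.na(v))
  # homogeneous of degree 1 in the bounds
  expect_equal(combined_bound(7 * c(1e-5, 3e-5), c(10, 20), 2),
               7 * combined_bound(c(1e-5, 3e-5), c(10, 20), 2))
})

test_that("ld_prune keeps the best SNP per LD block", {
  declared <- data.frame(snp_id = c("A", "B", "C"),
                         score = c(0.001, 0.01, 0.02))
  ld <- data.frame(id_a = c("A", "B", "A"), id_b = c("B", "C", "C"),
                   r2 = c(0.5, 0.05, 0.02))
  expect_equal(ld_prune(declared, ld), c("A", "C"))
  # nothing in LD: unchanged
  expect_equal(ld_prune(declared, transform(ld, r2 = r2 / 100)),
               c("A", "B", "C"))
  # all in strong LD: single best kept
  expect_equal(ld_prune(declared, transform(ld, r2 = 1)), "A")
  expect_error(ld_prune(declared, transform(ld, r2 = 2)), "r2")
  # greedy guarantee: no retained pair with r2 >= threshold
  set.seed(52)
  ids <- paste0("v", 1:40)
  dec <- data.frame(snp_id = ids, score = runif(40))
  pairs <- t(combn(ids, 2))
  ld2 <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                    r2 = runif(nrow(pairs)))
  kept <- ld_prune(dec, ld2, r2_max = 0.5)
  key <- paste(ld2$id_a, ld2$id_b)
  for (i in seq_along(kept)) {
    for (j in seq_along(kept)) {
      if (i >= j) next
      hit <- ld2$r2[key %in% c(paste(kept[i], kept[j]),
                               paste(kept[j], kept[i]))]
      expect_true(all(hit < 0.5))
    }
  }
})

test_that("conditional_cutoff separates pleiotropic from independent traits", {
  # independent traits: conditioning must not relax the significance cutoff,
  # so no network edge is drawn
  for (k in 1:3) {
    sim <- simulate_pair(sim_config(n_snps = 20000, pi0_i = 0.95,
                                    pi0_j = 0.95, sigma_i = 4, sigma_j = 4,
                                    overlap = NULL, rho = 0, seed = 60 + k))
    st <- conditional_cutoff(sim, make_spec(0, 0.95, 4))
    expect_false(st$edge)
  }
  # complete pleiotropy: SNPs strong for the conditional trait carry
  # principal signal, so the cutoff relaxes well past the edge threshold
  sim <- simulate_pair(sim_config(n_snps = 20000, pi0_i = 0.95, pi0_j = 0.95,
                                  sigma_i = 4, sigma_j = 4, overlap = 1,
                                  rho = 0, seed = 64))
  st <- conditional_cutoff(sim, make_spec(0, 0.95, 4))
  expect_true(st$defined)
  expect_gt(st$fold_ratio, 1)
  expect_equal(st$edge, st$p_star >= 4e-7)
})

test_that("conditional_cutoff flags undefined configurations", {
  pairs <- data.frame(p_i = runif(100, 0.5, 1), p_j = runif(100, 0.5, 1))
  st <- conditional_cutoff(pairs, make_spec(0, 0.9, 3))
  expect_false(st$defined)
  expect_true(is.na(st$p_star))
})

test_that("qq_conditional emits per-cutoff series and flags empty subsets", {
  set.seed(55)
  pairs <- data.frame(p_j = runif(5000), p_adj = runif(5000))
  qq <- qq_conditional(pairs, cutoffs = c(1, 0.1))
  expect_setequal(unique(qq$cutoff), c(1, 0.1))
  # all-null data hugs the diagonal
  full <- qq[qq$cutoff == 1, ]
  expect_lt(max(abs(full$neglog10_observed - full$neglog10_expected)), 0.6)
  expect_warning(qq_conditional(pairs, cutoffs = c(1, 1e-9)), "omitted")
})

test_that("qq series shift left under pleiotropic enrichment", {
  spec <- make_spec(0.5, 0.9, 3)
  sim <- simulate_pair(sim_config(n_snps = 20000, pi0_i = 0.9, pi0_j = 0.9,
                                  sigma_i = 3, sigma_j = 3, overlap = 0.9,
                                  rho = 0.5, seed = 56))
  tab <- adjust_pairs(sim, spec)
  qq <- qq_conditional(tab, cutoffs = c(1, 0.01))
  med_shift <- function(co) {
    s <- qq[qq$cutoff == co, ]
    median(s$neglog10_observed - s$neglog10_expected)
  }
  expect_gt(med_shift(0.01), med_shift(1))
})

test_that("TDT calibration inverts the case-control variance identity", {
  n0 <- 2943; n1_true <- 4126
  m_target <- (n0 + n1_true) / (n0 * n1_true)
  # constant-M construction: median(M) = m_target exactly
  f <- rep(0.25, 101)
  se <- sqrt(m_target / (f * (1 - f)))
  cal <- tdt_effective_cases(se, f, p = rep(0.8, 101), n0 = n0)
  expect_equal(cal$n_cases_equiv, n1_true, tolerance = 1e-6)
  # symmetric design: median(M) = 2/n0 gives n1 = n0
  se2 <- sqrt((2 / n0) / (f * (1 - f)))
  expect_equal(tdt_effective_cases(se2, f, rep(0.9, 101), n0)$n_cases_equiv,
               n0, tolerance = 1e-6)
  # boundary: no finite solution
  se3 <- sqrt((1 / n0) / (f * (1 - f)))
  expect_error(tdt_effective_cases(se3, f, rep(0.9, 101), n0), "no finite")
  # null filter applies
  expect_error(tdt_effective_cases(se, f, p = rep(0.1, 101), n0 = n0),
               "no null SNPs")
})
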