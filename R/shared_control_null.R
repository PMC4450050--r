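#' Correlation of null Z scores induced by shared controls
#'
#' When two case-control studies draw on an overlapping control pool, the Z
#' scores they produce at a SNP null for both traits are positively
#' correlated. Asymptotically (group sizes above ~100) the correlation is
#' \deqn{\rho = \frac{N_0\sqrt{N_i N_j}}
#'   {\sqrt{(N_{0i}+N_0)(N_{0j}+N_0)(N_i+N_{0i}+N_0)(N_j+N_{0j}+N_0)}}}
#' where \eqn{N_i, N_j} are case counts, \eqn{N_{0i}, N_{0j}} unique-control
#' counts and \eqn{N_0} the shared-control count. With no sharing
#' (\eqn{N_0 = 0}) the studies are independent and \eqn{\rho = 0}.
#'
#' @param design A [study_pair_design()] (or a bare list with the same count
#'   fields).
#' @return The correlation `rho` in `[0, 1)`.
#' @export
#' @examples
#' rho_shared(study_pair_design(6087, 6088, 0, 0, 15171))
rho_shared <- function(design) {
  Ni <- design$n_cases_i; Nj <- design$n_cases_j
  N0i <- design$n_controls_unique_i; N0j <- design$n_controls_unique_j
  N0 <- design$n_controls_shared
  if (any(c(Ni, Nj, N0i, N0j, N0) < 0)) stop("negative study count")
  if (N0 == 0) return(0)
  N0 * sqrt(Ni * Nj) /
    sqrt((N0i + N0) * (N0j + N0) * (Ni + N0i + N0) * (Nj + N0j + N0))
}

#' Combine the null correlation and the effect-size mixture
#'
#' Bundles the shared-control correlation `rho` with a fitted (or specified)
#' conditional-trait effect mixture into the bivariate null model used by the
#' expected-quantile and cFDR machinery: under the principal null, the Z-score
#' pair is centred bivariate normal with covariance `[[1, rho], [rho, 1]]`
#' (conditional trait null, probability `pi0`) or `[[1, rho], [rho, 1 +
#' sigma2]]` (conditional trait non-null).
#'
#' @param rho Null Z correlation in `[0, 1)`, usually from [rho_shared()].
#' @param mixture A `null_mixture` fit, or a list with elements `pi0` and
#'   `sigma2`.
#' @return An object of class `bivariate_null_spec`.
#' @export
bivariate_null_spec <- function(rho, mixture) {
  if (!is.finite(rho) || rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (is.null(mixture$pi0) || is.null(mixture$sigma2)) {
    stop("mixture must supply pi0 and sigma2")
  }
  if (mixture$pi0 < 0 || mixture$pi0 > 1) stop("pi0 must be in [0, 1]")
  if (mixture$sigma2 < 0) stop("sigma2 must be >= 0")
  structure(list(rho = rho, pi0 = mixture$pi0, sigma2 = mixture$sigma2),
            class = "bivariate_null_spec")
}

# P(X > a, Y > b) for standard bivariate normal with correlation r.
# Deterministic Genz TVPACK algorithm (abs. error well below 1e-10).
.pbvn_upper <- function(a, b, r) {
  if (r == 0) {
    return(stats::pnorm(a, lower.tail = FALSE) *
             stats::pnorm(b, lower.tail = FALSE))
  }
  as.numeric(mvtnorm::pmvnorm(lower = c(a, b), upper = c(Inf, Inf),
                              corr = matrix(c(1, r, r, 1), 2),
                              algorithm = mvtnorm::TVPACK(abseps = 1e-12)))
}

#' Two-sided bivariate normal tail probability
#'
#' Computes \eqn{\Lambda_{(\rho,\sigma^2)}(z_i, z_j) = P(|X| > z_i, |Y| >
#' z_j)} for a centred bivariate normal `(X, Y)` with covariance
#' `[[1, rho], [rho, 1 + sigma2]]`, by quadrant decomposition of the bivariate
#' normal CDF. The second coordinate is rescaled to unit variance, giving an
#' effective correlation `rho / sqrt(1 + sigma2)`.
#'
#' @param z_i,z_j Non-negative |Z| thresholds (vectors are recycled).
#' @param rho Correlation of the underlying unit-variance pair, `|rho| < 1`.
#' @param sigma2 Non-negative variance inflation of the second coordinate.
#' @return Probability vector, `P(|X| > z_i, |Y| > z_j)`.
#' @seealso [lambda_tail()] for the univariate margin `P(|Y| > z_j)`.
#' @export
tail_prob <- function(z_i, z_j, rho, sigma2 = 0) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (any(z_i < 0) || any(z_j < 0)) stop("z thresholds must be >= 0")
  n <- max(length(z_i), length(z_j))
  z_i <- rep_len(z_i, n); z_j <- rep_len(z_j, n)
  s <- sqrt(1 + sigma2)
  r <- rho / s
  b <- z_j / s
  out <- numeric(n)
  for (k in seq_len(n)) {
    # P(|X|>a, |Y|>b) = 2 [ P(X>a, Y>b; r) + P(X>a, Y>b; -r) ] by symmetry
    out[k] <- 2 * (.pbvn_upper(z_i[k], b[k], r) + .pbvn_upper(z_i[k], b[k], -r))
  }
  pmin(pmax(out, 0), 1)
}

#' Univariate two-sided tail of the inflated conditional margin
#'
#' \eqn{\lambda_{\sigma^2}(z_j) = P(|Y| > z_j)} for `Y ~ N(0, 1 + sigma2)`.
#'
#' @inheritParams tail_prob
#' @return Probability vector.
#' @export
lambda_tail <- function(z_j, sigma2 = 0) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  2 * stats::pnorm(z_j / sqrt(1 + sigma2), lower.tail = FALSE)
}

#' Cumulative expected quantile of the principal p value
#'
#' The expected quantile \eqn{p' = \Pr(P_i \le p_i \mid P_j \le p_j,
#' H_0^{(i)})} of a principal-trait p value, given that the conditional-trait
#' p value falls at or below `p_j`, under the shared-control null. With
#' independent studies (`rho = 0`) or a vacuous conditioning event (`p_j = 1`)
#' this is exactly `p_i`; with shared controls it exceeds `p_i` for small
#' thresholds, quantifying how far raw principal p values are biased downward
#' within conditional-selected SNP sets.
#'
#' Computed from the two-component model as
#' \deqn{\frac{\pi_0 \Lambda_{(\rho,0)}(z_i,z_j) + (1-\pi_0)
#'   \Lambda_{(\rho,\sigma^2)}(z_i,z_j)}
#'   {\pi_0 \lambda_0(z_j) + (1-\pi_0) \lambda_{\sigma^2}(z_j)}}
#' with `z = qnorm(1 - p/2)`.
#'
#' @param p_i,p_j P values in (0, 1] (vectors recycled).
#' @param spec A [bivariate_null_spec()].
#' @return Expected quantiles in (0, 1].
#' @export
expected_quantile_cum <- function(p_i, p_j, spec) {
  stopifnot(inherits(spec, "bivariate_null_spec"))
  if (any(p_i <= 0 | p_i > 1) || any(p_j <= 0 | p_j > 1)) {
    stop("p values must be in (0, 1]")
  }
  n <- max(length(p_i), length(p_j))
  p_i <- rep_len(p_i, n); p_j <- rep_len(p_j, n)
  if (spec$rho == 0) return(p_i)  # independence factorises num and denom
  out <- p_i
  todo <- p_j < 1                 # p_j = 1 conditions on a sure event
  if (any(todo)) {
    z_i <- p_to_z(p_i[todo]); z_j <- p_to_z(p_j[todo])
    num <- spec$pi0 * tail_prob(z_i, z_j, spec$rho, 0) +
      (1 - spec$pi0) * tail_prob(z_i, z_j, spec$rho, spec$sigma2)
    den <- spec$pi0 * lambda_tail(z_j, 0) +
      (1 - spec$pi0) * lambda_tail(z_j, spec$sigma2)
    out[todo] <- pmin(num / den, 1)
  }
  out
}

#' Point expected quantile of the principal p value
#'
#' \eqn{\Pr(P_i \le p_i \mid P_j = p_j, H_0^{(i)})}: the partial derivative of
#' the cumulative expected quantile with respect to the conditioning
#' threshold, i.e. the expected quantile given an exact conditional-trait p
#' value. It is a density-weighted mixture of conditional-normal tail
#' probabilities: component `k` (variance `v_k` of the conditional-trait Z,
#' either 1 or `1 + sigma2`) contributes `P(|X| >= z_i)` with
#' `X ~ N(rho * z_j / v_k, 1 - rho^2 / v_k)`, weighted by its marginal
#' density at `z_j`. Conditioning is on the magnitude `|Z_j| = z_j`; by
#' symmetry of the centred model the two signed conditionals give equal tail
#' probabilities, so a single evaluation at `+z_j` is used.
#'
#' @param p_i P values in (0, 1] (vector recycled).
#' @param p_j P values in (0, 1]; `p_j = 1` is handled as `z_j = 0`.
#' @param spec A [bivariate_null_spec()].
#' @return Probabilities in (0, 1].
#' @export
expected_quantile_point <- function(p_i, p_j, spec) {
  stopifnot(inherits(spec, "bivariate_null_spec"))
  if (any(p_i <= 0 | p_i > 1) || any(p_j <= 0 | p_j > 1)) {
    stop("p values must be in (0, 1]")
  }
  n <- max(length(p_i), length(p_j))
  p_i <- rep_len(p_i, n); p_j <- rep_len(p_j, n)
  if (spec$rho == 0) return(p_i)
  z_i <- p_to_z(p_i); z_j <- p_to_z(p_j)
  v <- c(1, 1 + spec$sigma2)
  w <- c(spec$pi0, 1 - spec$pi0)
  num <- 0; den <- 0
  for (k in 1:2) {
    dens <- w[k] * stats::dnorm(z_j, sd = sqrt(v[k]))
    m <- spec$rho * z_j / v[k]
    s <- sqrt(1 - spec$rho^2 / v[k])
    tail2 <- stats::pnorm((-z_i - m) / s) + stats::pnorm((z_i - m) / s,
                                                         lower.tail = FALSE)
    num <- num + dens * tail2
    den <- den + dens
  }
  pmin(num / den, 1)
}

#' Discretise the fitted effect-size mixture on a grid
#'
#' Represents the distribution of the latent conditional-trait effect H as a
#' weighted grid: a point mass `pi0` at zero plus a discretised `N(0, sigma2)`
#' spanning six standard deviations either side.
#'
#' @param mixture A `null_mixture` fit or list with `pi0`, `sigma2`.
#' @param n_grid Number of grid points for the continuous component
#'   (default 101).
#' @return Data frame with columns `eta` (effect value) and `weight`
#'   (probability mass, summing to 1), usable as `h_density` in
#'   [expected_quantile_cum_numeric()].
#' @export
discretize_mixture <- function(mixture, n_grid = 101L) {
  sigma <- sqrt(mixture$sigma2)
  eta <- seq(-6 * sigma, 6 * sigma, length.out = n_grid)
  w <- stats::dnorm(eta, sd = sigma)
  w <- (1 - mixture$pi0) * w / sum(w)
  out <- rbind(data.frame(eta = 0, weight = mixture$pi0),
               data.frame(eta = eta, weight = w))
  out[out$weight > 0, , drop = FALSE]
}

#' Expected quantile under an arbitrary effect-size distribution
#'
#' Evaluates the cumulative expected quantile by quadrature over the latent
#' conditional-trait effect, dropping the assumption that the non-null
#' component of H is normal. For each grid effect `eta`, the Z-score pair
#' under the principal null is bivariate normal with mean `(0, eta)` and
#' covariance `[[1, rho], [rho, 1]]`; tail masses are mixed with the supplied
#' weights. With `h_density` set to a discretised point-mass-plus-normal
#' mixture (see [discretize_mixture()]) this agrees with
#' [expected_quantile_cum()].
#'
#' @param p_i,p_j P values in (0, 1] (scalars or equal-length vectors).
#' @param rho Null Z correlation in `[0, 1)`.
#' @param h_density Data frame with columns `eta` and `weight`: a tabulated
#'   distribution of H (weights non-negative; normalised internally). Fewer
#'   than 51 grid points triggers a coarse-grid warning.
#' @return Probabilities in (0, 1].
#' @export
expected_quantile_cum_numeric <- function(p_i, p_j, rho, h_density) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (any(h_density$weight < 0)) stop("h_density weights must be non-negative")
  if (nrow(h_density) < 51) {
    warning("fewer than 51 grid points in h_density; quadrature may be coarse")
  }
  w <- h_density$weight / sum(h_density$weight)
  eta <- h_density$eta
  n <- max(length(p_i), length(p_j))
  p_i <- rep_len(p_i, n); p_j <- rep_len(p_j, n)
  z_i <- p_to_z(p_i); z_j <- p_to_z(p_j)
  out <- numeric(n)
  for (q in seq_len(n)) {
    a <- z_i[q]; b <- z_j[q]
    # margin: P(|Z_j| >= b | eta), Z_j ~ N(eta, 1)
    den <- sum(w * (stats::pnorm(eta - b) + stats::pnorm(-eta - b)))
    num <- 0
    for (g in seq_along(eta)) {
      if (w[g] == 0) next
      num <- num + w[g] * .pbvn_abs_shifted(a, b, rho, eta[g])
    }
    out[q] <- min(num / den, 1)
  }
  out
}

# P(|X| > a, |Y| > b) for (X, Y) ~ N((0, eta), [[1, rho], [rho, 1]]).
# Expressed through upper-orthant probabilities only (TVPACK's domain) by
# inclusion-exclusion over the four quadrants.
.pbvn_abs_shifted <- function(a, b, rho, eta) {
  if (a == 0 && b == 0) return(1)
  corr <- matrix(c(1, rho, rho, 1), 2)
  alg <- mvtnorm::TVPACK(abseps = 1e-12)
  U <- function(x, y) {  # P(X > x, Y > y)
    as.numeric(mvtnorm::pmvnorm(lower = c(x, y), upper = c(Inf, Inf),
                                mean = c(0, eta), corr = corr,
                                algorithm = alg))
  }
  px_hi <- stats::pnorm(a, lower.tail = FALSE)            # P(X > a)
  px_lo <- stats::pnorm(-a)                               # P(X < -a)
  py_hi <- stats::pnorm(b, mean = eta, lower.tail = FALSE) # P(Y > b)
  # quadrants: (X>a,Y>b); (X>a,Y<-b); (X<-a,Y>b); (X<-a,Y<-b)
  q1 <- U(a, b)
  q2 <- px_hi - U(a, -b)
  q3 <- py_hi - U(-a, b)
  py_gt_negb <- stats::pnorm(-b, mean = eta, lower.tail = FALSE)
  q4 <- 1 - (1 - px_lo) - py_gt_negb + U(-a, -b)
  min(max(q1 + q2 + q3 + q4, 0), 1)
}
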