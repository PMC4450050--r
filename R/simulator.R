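#' Configuration for the paired summary-statistic simulator
#'
#' Defaults reproduce the reference simulation scenario: 20,000 SNPs, all
#' null for the principal trait, null for the conditional trait with
#' probability 0.9, non-null conditional effects drawn `N(0, 3^2)`, and a
#' shared-control correlation of 0.5 (the typical value between study pairs
#' sharing most of their control pool).
#'
#' @param n_snps Number of SNPs.
#' @param pi0_i,pi0_j Null proportions for the principal and conditional
#'   trait.
#' @param sigma_i,sigma_j Standard deviations of the non-null standardised
#'   effect sizes.
#' @param overlap Probability that a SNP non-null for the conditional trait
#'   is also non-null for the principal trait (pleiotropy). `NULL` (default)
#'   draws the two labels independently; otherwise the principal marginal
#'   `1 - pi0_i` is preserved by adjusting the rate on conditionally-null
#'   SNPs.
#' @param design A [study_pair_design()], or `NULL` to give `rho` directly.
#' @param rho Null Z correlation, used when `design` is `NULL`.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 20000L, pi0_i = 1, pi0_j = 0.9,
                       sigma_i = 3, sigma_j = 3, overlap = NULL,
                       design = NULL, rho = 0.5, seed = 1L) {
  if (any(c(pi0_i, pi0_j) < 0 | c(pi0_i, pi0_j) > 1)) {
    stop("null proportions must be in [0, 1]")
  }
  if (any(c(sigma_i, sigma_j) <= 0)) stop("effect SDs must be positive")
  if (!is.null(overlap) && (overlap < 0 || overlap > 1)) {
    stop("overlap must be in [0, 1]")
  }
  if (!is.null(design)) rho <- design$rho
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  structure(list(n_snps = as.integer(n_snps), pi0_i = pi0_i, pi0_j = pi0_j,
                 sigma_i = sigma_i, sigma_j = sigma_j, overlap = overlap,
                 design = design, rho = rho, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate paired GWAS summary statistics with shared-control correlation
#'
#' Per SNP: the latent conditional effect is `eta_j = 0` with probability
#' `pi0_j`, else `N(0, sigma_j^2)`; the principal label follows the
#' `pi0_i`/`overlap` rule and `eta_i` analogously. The observed Z pair is
#' bivariate normal with mean `(eta_i, eta_j)`, unit variances and
#' correlation `rho` (the shared-control correlation of the noise), and
#' two-sided p values are `2 * pnorm(-|Z|)`.
#'
#' Each SNP consumes a fixed number of draws from a single seeded stream, so
#' enlarging `n_snps` extends the table without perturbing earlier SNPs.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `snp_id`, `chrom`, `pos`, `p_i`, `z_i`
#'   (absolute), `p_j`, `z_j`, `z_i_signed`, `z_j_signed`, `eta_i`, `eta_j`,
#'   `nonnull_i`, `nonnull_j`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  set.seed(config$seed)
  # 6 N(0,1) draws per SNP, consumed row-wise: prefix-stable in n_snps
  draws <- matrix(stats::rnorm(6 * n), nrow = n, byrow = TRUE)
  u_j <- stats::pnorm(draws[, 1])
  u_i <- stats::pnorm(draws[, 2])
  nonnull_j <- u_j > config$pi0_j
  if (is.null(config$overlap)) {
    nonnull_i <- u_i > config$pi0_i
  } else {
    q1 <- 1 - config$pi0_i           # target principal non-null rate
    qj <- 1 - config$pi0_j
    p_given_null_j <- if (config$pi0_j > 0) {
      (q1 - qj * config$overlap) / config$pi0_j
    } else 0
    if (p_given_null_j < 0 || p_given_null_j > 1) {
      stop("overlap incompatible with the marginal null proportions")
    }
    pr <- ifelse(nonnull_j, config$overlap, p_given_null_j)
    nonnull_i <- u_i > 1 - pr
  }
  eta_j <- ifelse(nonnull_j, config$sigma_j * draws[, 3], 0)
  eta_i <- ifelse(nonnull_i, config$sigma_i * draws[, 4], 0)
  e1 <- draws[, 5]
  e2 <- config$rho * e1 + sqrt(1 - config$rho^2) * draws[, 6]
  z_i_s <- eta_i + e1
  z_j_s <- eta_j + e2
  data.frame(snp_id = sprintf("snp%06d", seq_len(n)),
             chrom = "1", pos = seq_len(n),
             p_i = z_to_p(abs(z_i_s)), z_i = abs(z_i_s),
             p_j = z_to_p(abs(z_j_s)), z_j = abs(z_j_s),
             z_i_signed = z_i_s, z_j_signed = z_j_s,
             eta_i = eta_i, eta_j = eta_j,
             nonnull_i = nonnull_i, nonnull_j = nonnull_j,
             stringsAsFactors = FALSE)
}

#' Genotype-level Monte-Carlo oracle for the shared-control correlation
#'
#' Simulates null SNPs at the allele-count level: for each SNP a population
#' MAF is drawn uniformly, binomial allele counts are sampled for both case
#' groups, both unique-control groups and the shared-control group, and each
#' study's allele-frequency-difference Z score is computed against its full
#' (unique + shared) control pool. The empirical correlation of the Z pairs
#' is the model-free check on the asymptotic formula of [rho_shared()].
#'
#' @param n_snps Number of null SNPs to simulate.
#' @param maf_range Length-2 vector of population MAF bounds in (0, 0.5].
#' @param design A [study_pair_design()] (all group sizes at least 10).
#' @param seed Integer seed.
#' @return Data frame with columns `z_i`, `z_j` (signed Z scores).
#' @export
simulate_genotype_studies <- function(n_snps, maf_range = c(0.05, 0.5),
                                      design, seed = 1L) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must lie in (0, 0.5]")
  }
  sizes <- c(design$n_cases_i, design$n_cases_j,
             design$n_controls_unique_i + design$n_controls_shared,
             design$n_controls_unique_j + design$n_controls_shared)
  if (any(sizes < 10)) stop("all group sizes must be >= 10")
  set.seed(seed)
  f <- stats::runif(n_snps, maf_range[1], maf_range[2])
  draw <- function(n_sub) stats::rbinom(n_snps, 2 * n_sub, f)
  a_i <- draw(design$n_cases_i)
  a_j <- draw(design$n_cases_j)
  c_i <- if (design$n_controls_unique_i > 0) draw(design$n_controls_unique_i) else 0
  c_j <- if (design$n_controls_unique_j > 0) draw(design$n_controls_unique_j) else 0
  c_s <- if (design$n_controls_shared > 0) draw(design$n_controls_shared) else 0
  z_of <- function(case_cnt, n_case, ctrl_cnt, n_ctrl) {
    p1 <- case_cnt / (2 * n_case)
    p0 <- ctrl_cnt / (2 * n_ctrl)
    fp <- (case_cnt + ctrl_cnt) / (2 * (n_case + n_ctrl))
    (p1 - p0) / sqrt(fp * (1 - fp) * (1 / (2 * n_case) + 1 / (2 * n_ctrl)))
  }
  data.frame(
    z_i = z_of(a_i, design$n_cases_i, c_i + c_s,
               design$n_controls_unique_i + design$n_controls_shared),
    z_j = z_of(a_j, design$n_cases_j, c_j + c_s,
               design$n_controls_unique_j + design$n_controls_shared))
}

#' Score declared SNPs against known simulation labels
#'
#' @param declared_ids Character vector of declared SNP ids.
#' @param labels Data frame with columns `snp_id` and `nonnull_i` (logical
#'   truth for the principal trait), covering every declared id.
#' @return A list of class `sim_evaluation` with `v` (false discoveries), `r`
#'   (total discoveries) and `q` (the ratio `v / r`, taken as 0 when nothing
#'   was declared).
#' @export
evaluate_fdr <- function(declared_ids, labels) {
  idx <- match(declared_ids, labels$snp_id)
  if (anyNA(idx)) {
    stop("declared id(s) missing from labels: ",
         paste(utils::head(declared_ids[is.na(idx)], 5), collapse = ", "))
  }
  r <- length(declared_ids)
  v <- if (r) sum(!labels$nonnull_i[idx]) else 0L
  structure(list(v = v, r = r, q = if (r) v / r else 0),
            class = "sim_evaluation")
}
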