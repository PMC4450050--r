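#' Effective number of tests from the eigenvalue variance of a rank-correlation matrix
#'
#' When one trait is conditioned separately on k others, the k per-SNP cFDR
#' series are highly mutually correlated (all are correlated with the
#' principal p value), so a Bonferroni correction across the k conditionals is
#' far too severe. Following the eigenvalue-variance approach, a Spearman
#' rank-correlation matrix Omega is estimated across the k cFDR columns
#' (restricted to potentially non-null SNPs), and the effective number of
#' tests is
#' `Meff = 1 + k * (1 - Var(lambda_obs) / k)`,
#' where `Var(lambda_obs)` is the sample variance (divisor k-1) of Omega's
#' eigenvalues: k for perfectly correlated columns (one effective test,
#' `Meff = 1`) down to 0 for uncorrelated columns (`Meff = k + 1`).
#'
#' @param cfdr_columns Matrix or data frame with one column of per-SNP cFDR
#'   values per conditional trait (k >= 2 columns). Rows should already be
#'   restricted to potentially non-null SNPs; see `restrict_threshold`.
#' @param restrict_threshold Optional: keep only rows whose row-minimum cFDR
#'   is below this value before computing Omega (at least 50 rows must
#'   remain). `NULL` uses all rows.
#' @return A list of class `mtc_result` with `meff`, `eigen_variance`, `k`,
#'   `n_rows`.
#' @export
meff <- function(cfdr_columns, restrict_threshold = NULL) {
  x <- as.matrix(cfdr_columns)
  k <- ncol(x)
  if (k < 2) stop("need at least 2 conditional-trait columns")
  if (!is.null(restrict_threshold)) {
    x <- x[apply(x, 1, min) < restrict_threshold, , drop = FALSE]
  }
  if (nrow(x) < 50) stop("fewer than 50 SNPs available for the correlation matrix")
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("constant cFDR column: rank correlation undefined")
  }
  omega <- stats::cor(x, method = "spearman")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  v <- stats::var(ev)
  structure(list(meff = 1 + k * (1 - v / k), eigen_variance = v,
                 k = k, n_rows = nrow(x)),
            class = "mtc_result")
}

#' Combined FDR bound across conditional traits
#'
#' The expected number of false discoveries for trait i conditioning on trait
#' j is at most `c_ji * n_ji` (bound times declared count); averaging over the
#' conditional traits and multiplying by the effective number of tests gives
#' the combined bound
#' `c0 = Meff * sum_j(c_ji * n_ji) / sum_j(n_ji)`.
#'
#' @param c_ji Numeric vector of per-conditional-trait FDR upper bounds.
#' @param n_ji Integer vector of per-conditional-trait declared counts.
#' @param meff Effective number of tests (scalar, or an `mtc_result`).
#' @return The combined bound `c0` (NA with a warning when every `n_ji` is 0).
#' @export
combined_bound <- function(c_ji, n_ji, meff) {
  if (inherits(meff, "mtc_result")) meff <- meff$meff
  if (length(c_ji) != length(n_ji)) stop("c_ji and n_ji lengths differ")
  if (all(n_ji == 0)) {
    warning("no SNPs declared for any conditional trait: combined bound undefined")
    return(NA_real_)
  }
  meff * sum(c_ji * n_ji) / sum(n_ji)
}

#' Greedy LD pruning of declared SNPs
#'
#' Orders the declared SNPs by increasing score (their best cFDR across
#' conditional traits) and sweeps left to right, at each step keeping the
#' current SNP and removing every later-ranked SNP in LD with it at
#' `r^2 >=` `r2_max`. Ideally at most one SNP per LD block survives.
#'
#' @param declared Data frame with columns `snp_id` and `score` (per-SNP
#'   minimum cFDR; lower is better).
#' @param r2_pairs Data frame with columns `id_a`, `id_b`, `r2`; treated as
#'   symmetric, absent pairs as `r2 = 0`.
#' @param r2_max Pruning threshold (default 0.1).
#' @return Character vector of retained SNP ids, in score order.
#' @export
ld_prune <- function(declared, r2_pairs, r2_max = 0.1) {
  if (nrow(r2_pairs) && (any(r2_pairs$r2 < 0) || any(r2_pairs$r2 > 1))) {
    stop("r2 values must lie in [0, 1]")
  }
  ord <- declared$snp_id[order(declared$score)]
  high <- r2_pairs[r2_pairs$r2 >= r2_max, , drop = FALSE]
  key <- c(paste(high$id_a, high$id_b), paste(high$id_b, high$id_a))
  kept <- character(0)
  alive <- ord
  while (length(alive)) {
    cur <- alive[1]
    kept <- c(kept, cur)
    alive <- alive[-1]
    if (length(alive)) {
      alive <- alive[!paste(cur, alive) %in% key]
    }
  }
  kept
}

#' Conditional significance cutoff and pleiotropy edge statistic
#'
#' Quantifies how far conditioning relaxes the principal trait's significance
#' threshold: `p_star` is the largest principal p value whose cFDR given
#' `P_j <= p_cond` does not exceed the unconditional FDR at the genome-wide
#' threshold, i.e. the solution of
#' `cfdr_hat(p_star | p_cond) = ufdr_hat(p_gw)`, located by bisection over
#' the empirical estimator. The fold ratio `p_star / p_gw` summarises the
#' gain; an edge is drawn in the pleiotropy network when `p_star >=
#' edge_threshold`. Because `p_cond` is fixed, declaring SNPs at
#' `(p_star, p_cond)` still controls the FDR at `ufdr_hat(p_gw)`.
#'
#' @param pairs Data frame with columns `p_i`, `p_j`.
#' @param spec A [bivariate_null_spec()].
#' @param p_cond Conditioning threshold (default `5e-6`).
#' @param p_gw Genome-wide significance threshold (default `5e-8`).
#' @param edge_threshold Cutoff on `p_star` for declaring a network edge
#'   (default `4e-7`).
#' @return A list of class `pleiotropy_stat` with `p_star`, `fold_ratio`,
#'   `edge`, `target_ufdr` and `defined` (FALSE when no SNP reaches `p_gw` or
#'   no SNP has `p_j <= p_cond`).
#' @export
conditional_cutoff <- function(pairs, spec, p_cond = 5e-6, p_gw = 5e-8,
                               edge_threshold = 4e-7) {
  undefined <- function() {
    structure(list(p_star = NA_real_, fold_ratio = NA_real_, edge = FALSE,
                   target_ufdr = NA_real_, defined = FALSE),
              class = "pleiotropy_stat")
  }
  if (!any(pairs$p_i <= p_gw) || !any(pairs$p_j <= p_cond)) return(undefined())
  target <- as.numeric(ufdr_hat(pairs$p_i, p_gw))
  p_star <- .largest_p_with(function(lp) {
    as.numeric(cfdr_hat(pairs, 10^lp, p_cond, spec)) <= target
  }, log10(min(pairs$p_i)) - 2)
  if (p_star == 0) return(undefined())
  structure(list(p_star = p_star, fold_ratio = p_star / p_gw,
                 edge = p_star >= edge_threshold,
                 target_ufdr = target, defined = TRUE),
            class = "pleiotropy_stat")
}

#' Conditional Q-Q series for the adjusted principal p values
#'
#' For each conditioning cutoff, ranks the adjusted principal p values
#' (`p_adj`, the expected quantile) of the SNPs with `p_j` at or below the
#' cutoff against uniform order-statistic quantiles, emitting plot-ready
#' `-log10` columns. A leftward shift of a series with decreasing cutoff
#' indicates enrichment of principal-trait signal among
#' conditional-trait-associated SNPs, i.e. pleiotropy.
#'
#' @param pairs Data frame with columns `p_j` and `p_adj` (from
#'   [cfdr_table()] or [adjust_pairs()]).
#' @param cutoffs Descending vector of `p_j` thresholds (default
#'   `c(1, 0.1, 0.01, 1e-3, 1e-4)`).
#' @return Data frame with columns `cutoff`, `neglog10_expected`,
#'   `neglog10_observed`; cutoffs with no qualifying SNPs are omitted with a
#'   warning.
#' @export
qq_conditional <- function(pairs, cutoffs = c(1, 0.1, 0.01, 1e-3, 1e-4)) {
  out <- list()
  for (co in cutoffs) {
    sub <- pairs$p_adj[pairs$p_j <= co]
    if (!length(sub)) {
      warning(sprintf("no SNPs with p_j <= %g; series omitted", co))
      next
    }
    m <- length(sub)
    out[[length(out) + 1]] <- data.frame(
      cutoff = co,
      neglog10_expected = -log10(seq_len(m) / (m + 1)),
      neglog10_observed = -log10(sort(sub)))
  }
  if (!length(out)) return(data.frame(cutoff = numeric(0),
                                      neglog10_expected = numeric(0),
                                      neglog10_observed = numeric(0)))
  do.call(rbind, out)
}

#' Effective case count for a TDT study from null-SNP standard errors
#'
#' For a case-control study under Hardy-Weinberg and the null, the variance
#' of the log odds ratio is `(n0 + n1) / (n0 * n1 * f * (1 - f))` with `n0`
#' controls, `n1` cases and control MAF `f`. A family-based TDT study has no
#' controls, but the quantity `M = se^2 * f * (1 - f)` computed at null SNPs
#' (p > 0.5) plays the role of `(n0 + n1) / (n0 * n1)`. Equating the median
#' of M with that expression, with each TDT family contributing the
#' information of one control (fixing `n0`), yields the equivalent case count
#' `n1 = 1 / (median(M) - 1/n0)`.
#'
#' @param se Standard errors of the TDT log odds ratios.
#' @param maf Matched minor allele frequencies.
#' @param p Matched p values; only SNPs with `p > 0.5` (consistent with the
#'   null) enter the calibration.
#' @param n0 Assumed equivalent control count (number of families).
#' @return A list of class `tdt_calibration` with `m_values`, `m_median`,
#'   `n_controls_equiv`, `n_cases_equiv`, `n_snps_used`.
#' @export
tdt_effective_cases <- function(se, maf, p, n0) {
  if (n0 < 1) stop("n0 must be >= 1")
  keep <- p > 0.5
  if (!any(keep)) stop("no null SNPs (p > 0.5) available")
  m <- se[keep]^2 * maf[keep] * (1 - maf[keep])
  m_med <- stats::median(m)
  if (m_med <= 1 / n0) {
    stop("median(M) <= 1/n0: no finite equivalent case count")
  }
  structure(list(m_values = m, m_median = m_med, n_controls_equiv = n0,
                 n_cases_equiv = 1 / (m_med - 1 / n0),
                 n_snps_used = sum(keep)),
            class = "tdt_calibration")
}
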