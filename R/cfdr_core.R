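#' Empirical unconditional FDR estimate
#'
#' Estimates \eqn{uFDR(p) = \Pr(H_0 \mid P \le p)} at a target p value as the
#' ratio of the expected quantile of `p_target` under the null (the p value
#' itself, after genomic control) to its observed quantile among the supplied
#' p values. The approximation `Pr(H0) = 1` makes the estimate conservative
#' (upward-biased). Counting is inclusive, so the target SNP counts itself and
#' the denominator is at least `1/N`.
#'
#' @param p_values Numeric vector of p values at all N SNPs.
#' @param p_target P value(s) at which to estimate; vectorised.
#' @return uFDR estimates clamped to at most 1; the raw ratio is attached as
#'   attribute `raw` when any value was clamped.
#' @export
#' @examples
#' ufdr_hat(c(0.001, 0.2, 0.5, 1.0), 0.001)  # 0.004
ufdr_hat <- function(p_values, p_target) {
  if (!length(p_values)) stop("empty p value collection")
  N <- length(p_values)
  cnt <- vapply(p_target, function(p) sum(p_values <= p), 0)
  if (any(cnt == 0)) stop("p_target below all observed p values")
  raw <- p_target / (cnt / N)
  out <- pmin(raw, 1)
  if (any(raw > 1)) attr(out, "raw") <- raw
  out
}

#' Empirical conditional FDR estimate with shared-control correction
#'
#' Estimates \eqn{cFDR(p_i | p_j) = \Pr(H_0^{(i)} \mid P_i \le p_i, P_j \le
#' p_j)} as the expected quantile of `p_i` under the shared-control null
#' (numerator, [expected_quantile_cum()]) divided by the observed conditional
#' quantile: the fraction of the `N1` pairs with `p_jk <= p_j` that also have
#' `p_ik <= p_i`. With `rho = 0` the numerator reduces to `p_i`, recovering
#' the split-control estimator. Conservative via `Pr(H0 | Pj <= pj) = 1`.
#'
#' @param pairs Data frame with columns `p_i`, `p_j` (all N SNP pairs).
#' @param p_i,p_j Query threshold pair(s); vectorised (recycled).
#' @param spec A [bivariate_null_spec()].
#' @return cFDR estimates clamped to at most 1, with attributes `numerator`,
#'   `denominator` and `n1` (vectors aligned with the estimates).
#' @export
cfdr_hat <- function(pairs, p_i, p_j, spec) {
  n <- max(length(p_i), length(p_j))
  p_i <- rep_len(p_i, n); p_j <- rep_len(p_j, n)
  n1 <- vapply(p_j, function(pj) sum(pairs$p_j <= pj), 0)
  if (any(n1 == 0)) stop("no pairs satisfy p_jk <= p_j")
  both <- vapply(seq_len(n), function(k) {
    sum(pairs$p_j <= p_j[k] & pairs$p_i <= p_i[k])
  }, 0)
  num <- expected_quantile_cum(p_i, p_j, spec)
  den <- both / n1
  # an empty rectangle has observed quantile 0: the ratio is +Inf, which the
  # probability clamp maps to 1 (never declarable)
  out <- pmin(num / den, 1)
  out[both == 0] <- 1
  attr(out, "numerator") <- num
  attr(out, "denominator") <- den
  attr(out, "n1") <- n1
  out
}

#' Per-SNP uFDR and cFDR table
#'
#' Evaluates [ufdr_hat()] and [cfdr_hat()] at every SNP's own `(p_i, p_j)`
#' pair, returning the adjusted expected quantile, the observed conditional
#' quantile and the two estimates per SNP. uFDR values are additionally made
#' monotone non-decreasing in `p_i` by a running maximum over the sorted p
#' values (column `ufdr_mono`), so that threshold calibration is well-posed
#' under sampling noise.
#'
#' @param pairs Data frame with columns `snp_id` (optional), `p_i`, `p_j`.
#' @param spec A [bivariate_null_spec()].
#' @return `pairs` with added columns `p_adj`, `ufdr`, `ufdr_mono`, `cfdr`,
#'   `cfdr_raw`, `denominator_used`, `n1`.
#' @export
cfdr_table <- function(pairs, spec) {
  N <- nrow(pairs)
  if (!N) stop("empty pair table")
  ord <- order(pairs$p_i)
  cnt_i <- rank(pairs$p_i, ties.method = "max")
  ufdr_raw <- pairs$p_i / (cnt_i / N)
  ufdr <- pmin(ufdr_raw, 1)
  # monotone regularisation: running max in order of increasing p_i
  mono <- numeric(N)
  mono[ord] <- cummax(ufdr[ord])
  n1 <- rank(pairs$p_j, ties.method = "max")
  both <- mapply(function(pi, pj) sum(pairs$p_i <= pi & pairs$p_j <= pj),
                 pairs$p_i, pairs$p_j)
  num <- expected_quantile_cum(pairs$p_i, pairs$p_j, spec)
  den <- both / n1
  raw <- num / den
  out <- pairs
  out$p_adj <- num
  out$ufdr <- ufdr
  out$ufdr_mono <- mono
  out$cfdr <- pmin(raw, 1)
  out$cfdr_raw <- raw
  out$denominator_used <- den
  out$n1 <- n1
  out
}

#' Calibrate uFDR / cFDR significance thresholds to the genome-wide convention
#'
#' Because the (monotonised) uFDR estimate increases with `p_i`, the
#' genome-wide p-value convention `p <= p_gw` (default `5e-8`) corresponds to
#' a least uFDR threshold `beta = max{uFDR(p_ik) : p_ik <= p_gw}`: declaring
#' at `uFDR <= beta` is then equivalent to declaring at `p_i <= p_gw`. The
#' analogous cFDR threshold is `alpha = max{cFDR(p_ik | p_jk) : p_ik <=
#' p_gw}`, capped at `beta` so that SNPs with near-vacuous conditioning
#' (`p_j` close to 1) cannot be declared more leniently than the
#' unconditional rule allows.
#'
#' @param table Output of [cfdr_table()] on the full SNP set.
#' @param p_gw Genome-wide significance p-value threshold (default `5e-8`).
#' @return A list of class `significance_thresholds` with elements `beta_i`,
#'   `alpha_ji`, `capped` (logical), `defined` (logical; `FALSE` when no SNP
#'   reaches `p_gw`) and `p_gw`.
#' @export
calibrate_thresholds <- function(table, p_gw = 5e-8) {
  sel <- table$p_i <= p_gw
  if (!any(sel)) {
    return(structure(list(beta_i = NA_real_, alpha_ji = NA_real_,
                          capped = FALSE, defined = FALSE, p_gw = p_gw),
                     class = "significance_thresholds"))
  }
  beta <- max(table$ufdr_mono[sel])
  alpha_raw <- max(table$cfdr[sel])
  capped <- alpha_raw > beta
  structure(list(beta_i = beta, alpha_ji = min(alpha_raw, beta),
                 capped = capped, defined = TRUE, p_gw = p_gw),
            class = "significance_thresholds")
}

#' @export
print.significance_thresholds <- function(x, ...) {
  if (!x$defined) {
    cat("Significance thresholds undefined (no SNP reaches p_gw =",
        format(x$p_gw), ")\n")
  } else {
    cat(sprintf("beta (uFDR cutoff)  = %.4g\nalpha (cFDR cutoff) = %.4g%s\n",
                x$beta_i, x$alpha_ji,
                if (x$capped) "  [capped at beta]" else ""))
  }
  invisible(x)
}

#' Declare SNPs non-null for the principal trait
#'
#' Declares every SNP with `cfdr <= alpha_ji`, and additionally every SNP
#' with `ufdr_mono <= beta_i` (the unconditionally significant set is always
#' included, mirroring the capping rule).
#'
#' @param table Output of [cfdr_table()] (must carry `snp_id`, or row indices
#'   are used as identifiers).
#' @param thresholds A `significance_thresholds` object.
#' @return Character vector of declared SNP ids (empty, with a warning, when
#'   thresholds are undefined), with attribute `by_rule` separating the
#'   uFDR- and cFDR-declared subsets.
#' @export
declare <- function(table, thresholds) {
  ids <- if (!is.null(table$snp_id)) table$snp_id else as.character(seq_len(nrow(table)))
  if (!thresholds$defined) {
    warning("thresholds undefined; nothing declared")
    out <- character(0)
    attr(out, "by_rule") <- list(ufdr = character(0), cfdr = character(0))
    return(out)
  }
  u_set <- ids[table$ufdr_mono <= thresholds$beta_i]
  c_set <- ids[table$cfdr <= thresholds$alpha_ji]
  out <- union(c_set, u_set)
  attr(out, "by_rule") <- list(ufdr = u_set, cfdr = c_set)
  out
}

#' Union of declared SNPs across conditional traits
#'
#' @param declared_list List of per-conditional-trait declared id vectors
#'   (from [declare()]).
#' @return A list with the per-pair sets and their union; the union is a
#'   superset of every per-pair uFDR-declared set by construction.
#' @export
declare_union <- function(declared_list) {
  list(per_pair = declared_list,
       union = Reduce(union, declared_list, accumulate = FALSE) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
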