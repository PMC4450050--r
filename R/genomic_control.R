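#' Estimate the genomic inflation factor from a null SNP panel
#'
#' Computes the median-based genomic-control inflation factor
#' `lambda = median(z^2) / m0`, where `m0` is the median of the chi-squared
#' distribution with one degree of freedom (taken from the inverse CDF, about
#' 0.4549). The panel should hold SNPs believed unassociated with the traits
#' under study, LD-pruned; its construction is the caller's responsibility.
#'
#' @param null_z Numeric vector of |Z| values at null-panel SNPs (at least 30;
#'   a warning is issued below 200).
#' @return A list of class `gc_result` with elements `lambda_gc` and
#'   `n_null_snps`.
#' @export
estimate_lambda <- function(null_z) {
  if (!length(null_z)) stop("null panel is empty")
  if (any(!is.finite(null_z))) stop("non-finite values in null panel")
  if (length(null_z) < 30) stop("need at least 30 null-panel SNPs")
  if (length(null_z) < 200) {
    warning("fewer than 200 null-panel SNPs; lambda estimate may be unstable")
  }
  m0 <- stats::qchisq(0.5, df = 1)
  lambda <- stats::median(null_z^2) / m0
  structure(list(lambda_gc = lambda, n_null_snps = length(null_z)),
            class = "gc_result")
}

#' Rescale test statistics by a genomic inflation factor
#'
#' Applies genomic control: `z^2 <- z^2 / lambda`, with p values recomputed
#' from the corrected |Z|. Any column named `z`, `z_i` or `z_j` is corrected
#' together with its matching p column; originals are retained in `*_raw`
#' side columns. A `lambda < 1` (deflation) is applied but warned about.
#'
#' @param records Data frame holding `p`/`z` or `p_i`/`z_i`/`p_j`/`z_j`
#'   columns.
#' @param lambda_gc Positive inflation factor, from [estimate_lambda()] or
#'   supplied directly (a `gc_result` is also accepted).
#' @return `records` with corrected `z` and `p` columns and `*_raw` originals.
#' @export
apply_gc <- function(records, lambda_gc) {
  if (inherits(lambda_gc, "gc_result")) lambda_gc <- lambda_gc$lambda_gc
  if (!is.finite(lambda_gc) || lambda_gc <= 0) stop("lambda must be > 0")
  if (lambda_gc < 1) warning("lambda < 1: applying genomic deflation")
  for (zc in intersect(c("z", "z_i", "z_j"), names(records))) {
    pc <- sub("^z", "p", zc)
    if (!pc %in% names(records)) next
    records[[paste0(zc, "_raw")]] <- records[[zc]]
    records[[paste0(pc, "_raw")]] <- records[[pc]]
    records[[zc]] <- records[[zc]] / sqrt(lambda_gc)
    records[[pc]] <- z_to_p(records[[zc]])
  }
  records
}
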