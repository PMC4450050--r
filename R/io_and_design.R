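#' Describe a pair of case-control studies with shared controls
#'
#' Records the case and control group sizes for two case-control GWAS whose
#' control pools may overlap, and derives the correlation `rho` induced on the
#' two studies' null Z scores by the shared controls (see [rho_shared()]).
#'
#' @param n_cases_i,n_cases_j Numbers of cases in the principal and conditional
#'   study (positive integers).
#' @param n_controls_unique_i,n_controls_unique_j Numbers of controls unique to
#'   each study (non-negative integers).
#' @param n_controls_shared Number of control subjects shared between the two
#'   studies (non-negative integer).
#' @return An object of class `study_pair_design`: a list with the five counts
#'   and the derived element `rho`.
#' @export
#' @examples
#' # two studies sharing their entire control pool
#' study_pair_design(2000, 2000, 0, 0, 2000)$rho  # 0.5
study_pair_design <- function(n_cases_i, n_cases_j,
                              n_controls_unique_i = 0L,
                              n_controls_unique_j = 0L,
                              n_controls_shared = 0L) {
  counts <- c(n_cases_i = n_cases_i, n_cases_j = n_cases_j,
              n_controls_unique_i = n_controls_unique_i,
              n_controls_unique_j = n_controls_unique_j,
              n_controls_shared = n_controls_shared)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("all study counts must be finite and non-negative")
  }
  if (n_cases_i < 1 || n_cases_j < 1) stop("each study needs at least one case")
  if (n_controls_unique_i + n_controls_shared < 1 ||
      n_controls_unique_j + n_controls_shared < 1) {
    stop("each study needs at least one control (unique + shared)")
  }
  out <- list(n_cases_i = n_cases_i, n_cases_j = n_cases_j,
              n_controls_unique_i = n_controls_unique_i,
              n_controls_unique_j = n_controls_unique_j,
              n_controls_shared = n_controls_shared)
  out$rho <- rho_shared(out)
  class(out) <- "study_pair_design"
  out
}

#' @export
print.study_pair_design <- function(x, ...) {
  cat("Study pair design\n")
  cat(sprintf("  cases:            %d (principal), %d (conditional)\n",
              x$n_cases_i, x$n_cases_j))
  cat(sprintf("  unique controls:  %d (principal), %d (conditional)\n",
              x$n_controls_unique_i, x$n_controls_unique_j))
  cat(sprintf("  shared controls:  %d\n", x$n_controls_shared))
  cat(sprintf("  null Z correlation rho = %.4f\n", x$rho))
  invisible(x)
}

.std_roles <- c("snp", "chr", "pos", "p", "z", "maf")

#' Read single-study GWAS summary statistics from delimited text
#'
#' Reads a header-bearing TSV or CSV (dialect auto-detected from the header
#' line) of per-SNP association summary statistics. The p-value column is
#' mandatory; the |Z| column is recomputed from p when absent. Rows with
#' missing or non-finite p values are dropped and counted.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping standard roles (`"snp"`,
#'   `"chr"`, `"pos"`, `"p"`, and optionally `"z"`, `"maf"`) to column names in
#'   the file. Roles equal to their default names may be omitted.
#' @return A data frame with columns `snp_id`, `chrom`, `pos`, `p`, `z` (and
#'   `maf` if mapped), one row per retained SNP, with attribute `n_dropped`
#'   recording how many rows were removed for unusable p values.
#' @export
read_summary <- function(path, column_map = character()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  map <- c(snp = "snp", chr = "chr", pos = "pos", p = "p", z = "z", maf = "maf")
  if (length(column_map)) {
    bad <- setdiff(names(column_map), .std_roles)
    if (length(bad)) stop("unknown roles in column_map: ", paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  need <- c("snp", "chr", "pos", "p")
  missing_cols <- need[!map[need] %in% names(df)]
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(sprintf("%s (role %s)", map[missing_cols], missing_cols), collapse = ", "))
  }
  p <- suppressWarnings(as.numeric(df[[map["p"]]]))
  n_unparseable <- sum(!is.na(df[[map["p"]]]) & is.na(p))
  if (n_unparseable > 0) {
    warning(sprintf("%d row(s) with unparseable p values dropped", n_unparseable))
  }
  keep <- is.finite(p) & p >= 0 & p <= 1
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && n_dropped > n_unparseable) {
    message(sprintf("dropped %d row(s) with missing/non-finite p", n_dropped))
  }
  out <- data.frame(snp_id = as.character(df[[map["snp"]]][keep]),
                    chrom  = as.character(df[[map["chr"]]][keep]),
                    pos    = as.integer(df[[map["pos"]]][keep]),
                    p      = p[keep],
                    stringsAsFactors = FALSE)
  if (map["z"] %in% names(df)) {
    z <- suppressWarnings(as.numeric(df[[map["z"]]][keep]))
    out$z <- ifelse(is.finite(z), abs(z), p_to_z(out$p))
  } else {
    out$z <- p_to_z(out$p)
  }
  if (map["maf"] %in% names(df)) {
    out$maf <- suppressWarnings(as.numeric(df[[map["maf"]]][keep]))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write summary statistics or SNP-pair tables as tab-separated text
#'
#' @param records Data frame as returned by [read_summary()] or [harmonize()].
#' @param path Output file path. Output is always tab-separated with a header.
#' @return `path`, invisibly.
#' @export
write_summary <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Pair two studies' summary statistics on their common SNPs
#'
#' Inner-joins two single-study tables on `snp_id`, producing one row per SNP
#' typed in both studies with the principal study's values suffixed `_i` and
#' the conditional study's `_j`. Output order is deterministic (chromosome,
#' position, then SNP id). SNPs present in only one study are dropped and
#' counted.
#'
#' @param records_i,records_j Data frames from [read_summary()] (principal and
#'   conditional study respectively).
#' @return A data frame with columns `snp_id`, `chrom`, `pos`, `p_i`, `z_i`,
#'   `p_j`, `z_j` (plus `maf_i`/`maf_j` when present), with attributes
#'   `n_dropped_i` and `n_dropped_j`.
#' @export
harmonize <- function(records_i, records_j) {
  for (side in list(list(r = records_i, lab = "principal"),
                    list(r = records_j, lab = "conditional"))) {
    dup <- unique(side$r$snp_id[duplicated(side$r$snp_id)])
    if (length(dup)) {
      stop(sprintf("duplicated snp_id in %s study: %s",
                   side$lab, paste(utils::head(dup, 5), collapse = ", ")))
    }
  }
  common <- intersect(records_i$snp_id, records_j$snp_id)
  if (!length(common)) warning("no SNPs shared between the two studies")
  ii <- match(common, records_i$snp_id)
  jj <- match(common, records_j$snp_id)
  out <- data.frame(snp_id = common,
                    chrom = records_i$chrom[ii],
                    pos = records_i$pos[ii],
                    p_i = records_i$p[ii], z_i = records_i$z[ii],
                    p_j = records_j$p[jj], z_j = records_j$z[jj],
                    stringsAsFactors = FALSE)
  if (!is.null(records_i$maf)) out$maf_i <- records_i$maf[ii]
  if (!is.null(records_j$maf)) out$maf_j <- records_j$maf[jj]
  ord <- order(out$chrom, out$pos, out$snp_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_i") <- nrow(records_i) - length(common)
  attr(out, "n_dropped_j") <- nrow(records_j) - length(common)
  out
}

#' Parse genomic exclusion intervals
#'
#' @param x Character vector in `"chr:start-end"` form (1-based, closed), or a
#'   data frame with columns `chrom`, `start`, `end`.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @keywords internal
parse_intervals <- function(x) {
  if (is.data.frame(x)) return(x[c("chrom", "start", "end")])
  m <- regmatches(x, regexec("^(chr)?([^:]+):([0-9,]+)-([0-9,]+)$", x))
  if (any(lengths(m) == 0)) stop("malformed interval; expected chr:start-end")
  data.frame(chrom = vapply(m, `[`, "", 3),
             start = as.numeric(gsub(",", "", vapply(m, `[`, "", 4))),
             end   = as.numeric(gsub(",", "", vapply(m, `[`, "", 5))),
             stringsAsFactors = FALSE)
}

#' Default exclusion: the extended MHC region
#'
#' The MHC shows both extended LD and strong association with immune-mediated
#' disease, which distorts estimates of pleiotropic enrichment; a wide band
#' around it (chr6:24,500,000-34,800,000, NCBI36 coordinates, 1-based closed)
#' is excluded by default.
#'
#' @return One-row data frame with columns `chrom`, `start`, `end`.
#' @export
mhc_interval <- function() {
  data.frame(chrom = "6", start = 24500000, end = 34800000,
             stringsAsFactors = FALSE)
}

#' Apply per-SNP quality-control filters
#'
#' Removes SNPs failing any of: call rate below `call_rate_min`, minor allele
#' frequency below `maf_min`, Hardy-Weinberg deviation `|Z| >` `hwe_z_max`, or
#' position inside an excluded genomic interval (by default the extended MHC).
#' QC summaries are matched by `snp_id`; records without a QC summary are
#' retained with a warning (interval exclusion still applies to them).
#'
#' @param records Data frame with columns `snp_id`, `chrom`, `pos` (single- or
#'   paired-study layout).
#' @param qc Optional data frame with columns `snp_id`, `call_rate`, `maf`,
#'   `hwe_z`.
#' @param call_rate_min,maf_min,hwe_z_max QC thresholds; defaults 0.99, 0.02
#'   and 5.
#' @param exclusions Genomic intervals to drop, as accepted by
#'   [parse_intervals()]; default [mhc_interval()]. Use `NULL` for none.
#' @return The surviving rows, with attribute `removal_counts`, a named integer
#'   vector of per-rule removal counts (a record failing several rules counts
#'   once per rule).
#' @export
qc_filter <- function(records, qc = NULL,
                      call_rate_min = 0.99, maf_min = 0.02, hwe_z_max = 5,
                      exclusions = mhc_interval()) {
  n <- nrow(records)
  fail_call <- fail_maf <- fail_hwe <- rep(FALSE, n)
  if (!is.null(qc) && n > 0) {
    idx <- match(records$snp_id, qc$snp_id)
    if (anyNA(idx)) {
      warning(sprintf("%d record(s) lack QC summaries and are retained",
                      sum(is.na(idx))))
    }
    has <- !is.na(idx)
    fail_call[has] <- qc$call_rate[idx[has]] < call_rate_min
    fail_maf[has]  <- qc$maf[idx[has]] < maf_min
    fail_hwe[has]  <- abs(qc$hwe_z[idx[has]]) > hwe_z_max
  }
  fail_excl <- rep(FALSE, n)
  if (!is.null(exclusions) && n > 0) {
    iv <- parse_intervals(exclusions)
    for (k in seq_len(nrow(iv))) {
      fail_excl <- fail_excl |
        (records$chrom == iv$chrom[k] &
           records$pos >= iv$start[k] & records$pos <= iv$end[k])
    }
  }
  keep <- !(fail_call | fail_maf | fail_hwe | fail_excl)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_counts") <- c(call_rate = sum(fail_call),
                                   maf = sum(fail_maf),
                                   hwe = sum(fail_hwe),
                                   exclusion = sum(fail_excl))
  out
}
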