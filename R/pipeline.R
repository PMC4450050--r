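#' Attach adjusted expected quantiles to a pair table
#'
#' Adds `p_adj`, the cumulative expected quantile evaluated at each SNP's own
#' `(p_i, p_j)`, i.e. the shared-control-corrected principal p value.
#'
#' @param pairs Data frame with columns `p_i`, `p_j`.
#' @param spec A [bivariate_null_spec()].
#' @return `pairs` with an added `p_adj` column.
#' @export
adjust_pairs <- function(pairs, spec) {
  pairs$p_adj <- expected_quantile_cum(pairs$p_i, pairs$p_j, spec)
  pairs
}

#' Run the full shared-control cFDR pipeline for every ordered phenotype pair
#'
#' Orchestrates QC, genomic control, harmonisation, mixture fitting,
#' expected-quantile adjustment, cFDR estimation, threshold calibration,
#' declaration, the region-based FDR bound, and optional LD pruning, writing
#' per-pair artifacts and a run manifest to `out_dir`. Ordered pairs are
#' processed independently: `cfdr(p_i | p_j)` and `cfdr(p_j | p_i)` are
#' different quantities.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{phenotypes}{Named list; each entry a summary-statistic data frame
#'       (layout of [read_summary()]) or a file path to one.}
#'     \item{designs}{Named list keyed `"A|B"` (alphabetical order of the two
#'       phenotype names) with fields `n_cases_a`, `n_cases_b`,
#'       `n_controls_unique_a`, `n_controls_unique_b`, `n_controls_shared`.}
#'     \item{qc}{Optional QC summary data frame (see [qc_filter()]).}
#'     \item{null_panel}{Optional character vector of null-panel SNP ids for
#'       genomic control, applied per phenotype.}
#'     \item{p_gw}{Genome-wide threshold (default `5e-8`).}
#'     \item{r2_pairs}{Optional LD table for pruning (see [ld_prune()]).}
#'     \item{grid_size}{Region grid size (default 200).}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of per-ordered-pair results (pair table,
#'   mixture, thresholds, declared ids, region) plus the manifest, which is
#'   also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  phen <- config$phenotypes
  if (length(phen) < 2) stop("need at least 2 phenotypes")
  nm <- names(phen)
  if (is.null(nm) || any(nm == "")) stop("phenotypes must be named")
  # validate designs up front, before any compute
  for (a in nm) for (b in nm) {
    if (a < b && is.null(config$designs[[paste(a, b, sep = "|")]])) {
      stop("missing design entry for pair ", a, "|", b)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p_gw <- config$p_gw %||% 5e-8
  grid_size <- config$grid_size %||% 200L

  load_phen <- function(x) if (is.character(x)) read_summary(x) else x
  tabs <- lapply(phen, load_phen)
  stage_counts <- list()

  # per-phenotype QC and genomic control
  lambdas <- list()
  for (k in nm) {
    n0 <- nrow(tabs[[k]])
    if (!is.null(config$qc)) {
      tabs[[k]] <- qc_filter(tabs[[k]], config$qc)
    } else {
      tabs[[k]] <- qc_filter(tabs[[k]], NULL)   # interval exclusion only
    }
    if (!is.null(config$null_panel)) {
      zz <- tabs[[k]]$z[tabs[[k]]$snp_id %in% config$null_panel]
      gc <- estimate_lambda(zz)
      lambdas[[k]] <- gc$lambda_gc
      tabs[[k]] <- apply_gc(tabs[[k]], gc)
    }
    stage_counts[[k]] <- c(input = n0, after_qc = nrow(tabs[[k]]))
  }

  design_for <- function(i, j) {
    key <- paste(sort(c(i, j)), collapse = "|")
    d <- config$designs[[key]]
    first <- sort(c(i, j))[1]
    if (i == first) {
      study_pair_design(d$n_cases_a, d$n_cases_b,
                        d$n_controls_unique_a, d$n_controls_unique_b,
                        d$n_controls_shared)
    } else {
      study_pair_design(d$n_cases_b, d$n_cases_a,
                        d$n_controls_unique_b, d$n_controls_unique_a,
                        d$n_controls_shared)
    }
  }

  results <- list()
  for (i in nm) for (j in nm) {
    if (i == j) next
    pair_name <- paste(i, j, sep = "_given_")
    pairs <- harmonize(tabs[[i]], tabs[[j]])
    design <- design_for(i, j)
    mix <- fit_null_mixture(pairs$z_j)
    spec <- bivariate_null_spec(design$rho, mix)
    tab <- cfdr_table(adjust_pairs(pairs, spec), spec)
    thr <- calibrate_thresholds(tab, p_gw = p_gw)
    dec <- suppressWarnings(declare(tab, thr))
    region <- NULL
    if (thr$defined && length(dec)) {
      region <- build_region(pairs, thr$alpha_ji, spec,
                             grid_size = grid_size,
                             augment_p_j = tab$p_j[tab$cfdr <= thr$alpha_ji])
      if (!region$empty) region <- fdr_bound(region)
    }
    pruned <- NULL
    if (!is.null(config$r2_pairs) && length(dec)) {
      sc <- tab$cfdr[match(dec, tab$snp_id)]
      pruned <- ld_prune(data.frame(snp_id = dec, score = sc), config$r2_pairs)
    }
    write_summary(tab, file.path(out_dir, paste0(pair_name, ".cfdr.tsv")))
    writeLines(dec, file.path(out_dir, paste0(pair_name, ".declared.txt")))
    results[[pair_name]] <- list(
      pair = c(principal = i, conditional = j),
      design = design, mixture = mix, thresholds = thr,
      declared = dec, pruned = pruned,
      region = region, table = tab)
  }

  manifest <- list(
    phenotypes = nm,
    p_gw = p_gw,
    lambda_gc = lambdas,
    stage_counts = stage_counts,
    pairs = lapply(results, function(r) {
      list(rho = r$design$rho,
           pi0 = r$mixture$pi0, sigma2 = r$mixture$sigma2,
           beta = r$thresholds$beta_i, alpha = r$thresholds$alpha_ji,
           thresholds_defined = r$thresholds$defined,
           n_declared = length(r$declared),
           fdr_bound = if (!is.null(r$region)) r$region$bound else NA)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
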