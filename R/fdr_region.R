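#' Construct the significance region L in the p-value unit square
#'
#' L is the union of all rectangles `[0, p_i] x [0, p_j]` whose estimated cFDR
#' is at most `alpha`. For each of `grid_size` log-spaced conditioning
#' thresholds `p_j` spanning the observed `p_j` range (augmented with the
#' observed `p_j` of any candidate SNPs), the boundary `p_i` is the largest
#' value with `cfdr_hat(p_i | p_j) <= alpha`, located by bisection in
#' `log10(p_i)`. Because the estimator is noisy, the effective boundary at
#' height `y` is taken as the largest boundary among all grid thresholds at or
#' above `y` (a running suffix maximum), which makes L an exact staircase
#' union of rectangles containing every rectangle it was built from.
#'
#' @param pairs Data frame with columns `p_i`, `p_j` (all N SNP pairs).
#' @param alpha Target cFDR level, usually `alpha_ji` from
#'   [calibrate_thresholds()].
#' @param spec A [bivariate_null_spec()].
#' @param grid_size Number of log-spaced `p_j` grid values (default 200,
#'   minimum 100).
#' @param augment_p_j Extra `p_j` values to add to the grid (e.g. the observed
#'   `p_j` of declared SNPs); deduplicated.
#' @param bisect_tol Bisection tolerance in `log10(p_i)` (default `1e-3`).
#' @return An object of class `region_l`: a list with `alpha`, `boundary` (a
#'   data frame with `p_j`, `p_i_max` and the monotonised `p_i_eff`), `empty`
#'   flag, and the inputs needed by [null_mass()], [largest_rectangle()] and
#'   [fdr_bound()].
#' @export
build_region <- function(pairs, alpha, spec, grid_size = 200L,
                         augment_p_j = NULL, bisect_tol = 1e-3) {
  if (grid_size < 100) stop("grid_size must be >= 100")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  p_j_grid <- 10^seq(log10(min(pairs$p_j)), 0, length.out = grid_size)
  if (!is.null(augment_p_j)) p_j_grid <- c(p_j_grid, augment_p_j)
  # round-off in 10^log10() must not push the grid below the observed minimum
  p_j_grid <- sort(unique(pmin(pmax(p_j_grid, min(pairs$p_j)), 1)))
  lo_all <- log10(min(pairs$p_i)) - 2
  bound_at <- function(pj) {
    .largest_p_with(function(lp) {
      as.numeric(cfdr_hat(pairs, 10^lp, pj, spec)) <= alpha
    }, lo_all, tol = bisect_tol)
  }
  b <- vapply(p_j_grid, bound_at, 0)
  # suffix maximum: effective boundary at height y is the widest rectangle
  # whose top edge is at or above y
  eff <- rev(cummax(rev(b)))
  empty <- all(b == 0)
  if (empty) warning("alpha below the minimum attainable cFDR: region is empty")
  structure(list(alpha = alpha,
                 boundary = data.frame(p_j = p_j_grid, p_i_max = b,
                                       p_i_eff = eff),
                 empty = empty, pairs = pairs, spec = spec,
                 n_snps = nrow(pairs)),
            class = "region_l")
}

# Largest p (as 10^lp, lp in [lo_min, 0]) satisfying predicate f(lp).
# The empirical cFDR is not monotone in p_i -- below the smallest observed
# point the empty-rectangle convention gives 1 -- so a coarse descending scan
# locates the topmost satisfying point before bisection refines the boundary.
.largest_p_with <- function(f, lo_min, tol = 1e-3, coarse = 0.05) {
  if (f(0)) return(1)
  lps <- seq(-coarse, lo_min, by = -coarse)
  hit <- NA_integer_
  for (k in seq_along(lps)) {
    if (f(lps[k])) { hit <- k; break }
  }
  if (is.na(hit)) return(0)
  lo <- lps[hit]
  hi <- if (hit == 1) 0 else lps[hit - 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid)) lo <- mid else hi <- mid
  }
  10^lo
}

#' Test whether p-value pairs lie inside a significance region
#'
#' @param region A `region_l` from [build_region()].
#' @param p_i,p_j P-value coordinates (vectors recycled).
#' @return Logical vector.
#' @export
region_contains <- function(region, p_i, p_j) {
  n <- max(length(p_i), length(p_j))
  p_i <- rep_len(p_i, n); p_j <- rep_len(p_j, n)
  bd <- region$boundary
  idx <- findInterval(p_j, bd$p_j, left.open = TRUE) + 1L
  inside <- idx <= nrow(bd)
  inside[inside] <- p_i[inside] <= bd$p_i_eff[idx[inside]]
  inside
}

# null-model probability P(P_i <= x, P_j <= y | principal null) under spec
.null_rect_prob <- function(x, y, spec, mode = "mass") {
  if (x <= 0 || y <= 0) return(0)
  if (mode == "area") return(x * y)
  z_x <- p_to_z(x); z_y <- p_to_z(y)
  spec$pi0 * tail_prob(z_x, z_y, spec$rho, 0) +
    (1 - spec$pi0) * tail_prob(z_x, z_y, spec$rho, spec$sigma2)
}

#' Expected number of null SNPs in a rectangle or region
#'
#' For a rectangle `[0, p_i] x [0, p_j]` the expected null count is `N` times
#' the null-model probability of the rectangle, mixing the conditional-null
#' and conditional-non-null components of the bivariate model; for a
#' `region_l` it is accumulated exactly over the staircase strips between
#' consecutive boundary heights. `mode = "area"` replaces the model mass by
#' the literal area (the two coincide when `rho = 0` and `pi0 = 1`).
#'
#' @param x Either a length-2 numeric vector `c(p_i, p_j)` (a rectangle) or a
#'   `region_l` object.
#' @param spec A [bivariate_null_spec()]; defaults to the one stored in a
#'   `region_l`.
#' @param N Total number of SNPs; defaults to the count stored in a
#'   `region_l`.
#' @param mode `"mass"` (null-model probability, default) or `"area"`.
#' @return Expected null SNP count (non-negative scalar).
#' @export
null_mass <- function(x, spec = NULL, N = NULL, mode = c("mass", "area")) {
  mode <- match.arg(mode)
  if (inherits(x, "region_l")) {
    spec <- spec %||% x$spec
    N <- N %||% x$n_snps
    bd <- x$boundary
    y <- bd$p_j; w <- bd$p_i_eff
    y_lo <- c(0, y[-length(y)])
    total <- 0
    for (k in seq_along(y)) {
      if (w[k] <= 0) next
      total <- total + (.null_rect_prob(w[k], y[k], spec, mode) -
                          .null_rect_prob(w[k], y_lo[k], spec, mode))
    }
    return(N * total)
  }
  if (length(x) != 2) stop("rectangle must be c(p_i, p_j)")
  if (is.null(spec) || is.null(N)) stop("spec and N required for a rectangle")
  N * .null_rect_prob(x[1], x[2], spec, mode)
}

#' Largest-null-mass rectangle M* inside a region
#'
#' Maximises the expected null count over the rectangles `[0, b(p_j)] x [0,
#' p_j]` generated by the region's (monotonised) boundary, and records
#' `alpha_star`, the estimated cFDR at the selected rectangle's upper-right
#' vertex (usually, but not necessarily, equal to the region's `alpha`).
#'
#' @param region A non-empty `region_l`.
#' @inheritParams null_mass
#' @return List with `m_star` (the `c(p_i, p_j)` vertex), `v_M` and
#'   `alpha_star`.
#' @export
largest_rectangle <- function(region, mode = c("mass", "area")) {
  mode <- match.arg(mode)
  if (region$empty) stop("region is empty")
  bd <- region$boundary
  keep <- bd$p_i_eff > 0
  v <- vapply(which(keep), function(k) {
    .null_rect_prob(bd$p_i_eff[k], bd$p_j[k], region$spec, mode)
  }, 0) * region$n_snps
  k_best <- which(keep)[which.max(v)]
  m_star <- c(p_i = bd$p_i_eff[k_best], p_j = bd$p_j[k_best])
  a_star <- as.numeric(cfdr_hat(region$pairs, m_star[1], m_star[2],
                                region$spec))
  list(m_star = m_star, v_M = max(v), alpha_star = a_star)
}

#' Upper bound on the FDR over the significance region
#'
#' Declaring every SNP whose p-value pair falls in L does not control the FDR
#' at `alpha`, because L is a union of many rectangles each individually
#' controlled at `alpha`: the union accumulates null mass without
#' necessarily accumulating signal. The expected FDR over L is, however,
#' bounded by `alpha_star * v(L) / v(M*)`, where `M*` is the
#' largest-null-mass rectangle inside L and `alpha_star` the estimated cFDR
#' at its upper-right vertex.
#'
#' @param region A non-empty `region_l`.
#' @inheritParams null_mass
#' @return The input region with fields `v_L`, `m_star`, `v_M`, `alpha_star`
#'   and `bound` filled in.
#' @export
fdr_bound <- function(region, mode = c("mass", "area")) {
  mode <- match.arg(mode)
  if (region$empty) stop("region is empty")
  region$v_L <- null_mass(region, mode = mode)
  mr <- largest_rectangle(region, mode = mode)
  if (mr$v_M <= 0) stop("largest rectangle has zero null mass")
  region$m_star <- mr$m_star
  region$v_M <- mr$v_M
  region$alpha_star <- mr$alpha_star
  region$bound <- mr$alpha_star * region$v_L / mr$v_M
  region
}

#' @export
print.region_l <- function(x, ...) {
  cat(sprintf("Significance region L at alpha = %.4g (%d boundary points)%s\n",
              x$alpha, nrow(x$boundary), if (x$empty) " [empty]" else ""))
  if (!is.null(x$bound)) {
    cat(sprintf("  v(L) = %.3f, v(M*) = %.3f at (%.3g, %.3g), alpha* = %.4g\n",
                x$v_L, x$v_M, x$m_star[1], x$m_star[2], x$alpha_star))
    cat(sprintf("  FDR bound alpha* v(L)/v(M*) = %.4g\n", x$bound))
  }
  invisible(x)
}
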