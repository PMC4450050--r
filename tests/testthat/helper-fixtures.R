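# Shared fixtures and tiny independent oracles used across test files.

# write a small summary-statistics file and return its path
write_stats_file <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# mixture spec shorthand
make_spec <- function(rho, pi0, sigma) {
  bivariate_null_spec(rho, list(pi0 = pi0, sigma2 = sigma^2))
}

# brute-force uFDR: direct count, no ranks
ufdr_brute <- function(p_values, p_target) {
  p_target / (sum(p_values <= p_target) / length(p_values))
}

# brute-force cFDR at a query point, split-control (rho = 0) numerator
cfdr_brute0 <- function(pairs, p_i, p_j) {
  n1 <- sum(pairs$p_j <= p_j)
  both <- sum(pairs$p_i <= p_i & pairs$p_j <= p_j)
  p_i / (both / n1)
}

# coarse grid maximisation of the two-component mixture log-likelihood
grid_ml <- function(z, pi0_grid = seq(0.5, 0.999, by = 0.004),
                    sigma2_grid = seq(0.5, 25, by = 0.25)) {
  best <- list(ll = -Inf)
  for (p0 in pi0_grid) {
    d0 <- p0 * dnorm(z)
    for (s2 in sigma2_grid) {
      ll <- sum(log(d0 + (1 - p0) * dnorm(z, sd = sqrt(1 + s2))))
      if (ll > best$ll) best <- list(ll = ll, pi0 = p0, sigma2 = s2)
    }
  }
  best
}
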