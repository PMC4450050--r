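---
title: "Conditional FDR with shared controls: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional FDR with shared controls: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharedcfdr)
```

## The statistical model

We observe, at each of N SNPs, two-sided association p values $(p_i, p_j)$
for a principal trait $i$ and a conditional trait $j$, converted throughout
to Z magnitudes by $|z| = \Phi^{-1}(1 - p/2)$. Signs are never needed:
every quantity in the package depends on effects only through $|Z|$, and the
model below is symmetric about zero.

Three ingredients define the joint null behaviour of a SNP:

1. **Latent conditional effect.** The standardised true effect $\eta$ of a
   SNP on the conditional trait is a draw from
   $H \sim \pi_0\,\delta_0 + (1-\pi_0)\,N(0, \sigma^2)$,
   and the observed Z given the effect is $Z_j \mid \eta \sim N(\eta, 1)$.
   Marginally $Z_j$ is $N(0,1)$ with probability $\pi_0$ and
   $N(0, 1+\sigma^2)$ otherwise; $(\pi_0, \sigma^2)$ are estimated from the
   observed $Z_j$ by EM (`fit_null_mixture()`).

2. **Shared-control correlation.** When the two case–control studies share
   $N_0$ controls, their Z scores at a doubly-null SNP are positively
   correlated with asymptotic correlation
   $$\rho = \frac{N_0\sqrt{N_i N_j}}
     {\sqrt{(N_{0i}+N_0)(N_{0j}+N_0)(N_i+N_{0i}+N_0)(N_j+N_{0j}+N_0)}},$$
   computed by `rho_shared()` from the design counts. $\rho = 0$ exactly
   when no controls are shared. The published typesetting of this formula is
   ambiguous as a fraction; the form above was verified algebraically
   against the product-of-four-factors reading and anchored empirically to a
   genotype-level Monte-Carlo oracle (`simulate_genotype_studies()`), which
   samples binomial allele counts under the design and reproduces $\rho$
   within sampling error.

3. **Bivariate null.** Under the principal null, $(Z_i, Z_j)$ is centred
   bivariate normal with covariance $[[1,\rho],[\rho,1]]$ (conditional-null
   component, weight $\pi_0$) or $[[1,\rho],[\rho,1+\sigma^2]]$ (weight
   $1-\pi_0$).

## Expected quantiles and the cFDR estimator

Shared controls make raw principal p values falsely low within
conditional-selected sets. The corrected numerator of the cFDR estimator is
the *expected quantile*
$p' = \Pr(P_i \le p_i \mid P_j \le p_j, H_0^{(i)})$, a ratio of
two-component mixtures of two-sided bivariate normal tail masses
(`expected_quantile_cum()`). Tail rectangles are evaluated with the
deterministic bivariate-normal CDF (Genz's TVPACK via mvtnorm) at absolute
tolerance well below $10^{-10}$; the variance-inflated component is handled
by rescaling the second coordinate to unit variance, giving effective
correlation $\rho/\sqrt{1+\sigma^2}$.

The estimator itself is
$$\widehat{cFDR}(p_i \mid p_j) = \frac{p'}{\#\{k: p_{ik} \le p_i,\,
  p_{jk} \le p_j\}/N_1},$$
with $N_1$ the number of pairs with $p_{jk} \le p_j$. Counting is inclusive
on both coordinates so a query at an observed SNP always counts itself; the
ratio is clamped to 1 (the raw value is kept in a diagnostic column).
Setting $\Pr(H_0 \mid P_j \le p_j) = 1$ makes the estimator upward-biased
for the null proportion of any *fixed* rectangle — the conservative
direction. Note the conservativeness statement applies to fixed rectangles;
the set declared by thresholding per-SNP estimates is a union of rectangles
and needs the region bound below.

Two variants are provided. `expected_quantile_point()` conditions on an
exact conditional p value ($P_j = p_j$), as a density-weighted mixture of
conditional-normal tails; conditioning is on the magnitude $|Z_j| = z_j$,
and by symmetry the two signed conditionals contribute equal tails, so a
single evaluation at $+z_j$ suffices. The published expression for the
component conditional variance is garbled in the source text; we use the
standard conditional-normal result $1 - \rho^2/(1+\sigma^2)$ and validate it
by quadrature: integrating the point quantile against the conditional
margin reproduces the cumulative quantile to $10^{-4}$ over a grid.
`expected_quantile_cum_numeric()` drops the normality assumption on the
non-null component of H, taking any tabulated effect distribution and
integrating bivariate tail masses over it; with a discretised
point-mass-plus-normal input it cross-validates the closed form to
$10^{-3}$. For a heavy-tailed H (scaled $t_3$), the normal approximation
fitted by EM stays within a 1.5-fold band of the exact computation across
the tested grid, but the error is not uniformly in the conservative
direction: it understates slightly at very small conditional thresholds and
overstates at moderate ones.

## Thresholds, the region L, and the FDR bound

Because the monotonised uFDR estimate increases with $p_i$, the genome-wide
convention $p \le 5\times10^{-8}$ maps to the least threshold
$\beta = \max\{\widehat{uFDR}(p_{ik}) : p_{ik} \le 5\times10^{-8}\}$, and
analogously $\alpha = \max\{\widehat{cFDR}\}$ over the same SNPs, capped at
$\beta$ so that near-vacuous conditioning ($p_j \approx 1$) cannot declare
more leniently than the unconditional rule. Ties at the threshold are
resolved inclusively ($\le$). The uFDR series is made monotone by a running
maximum over sorted $p_i$ before calibration, so the least-threshold
definition is well-posed under sampling noise.

Declaring every SNP with $\widehat{cFDR} \le \alpha$ admits the whole region
$L = \{(p_i, p_j): \widehat{cFDR}(p_i \mid p_j) \le \alpha\}$, a union of
rectangles each controlled at $\alpha$ — but the union accumulates null mass
without necessarily accumulating signal, so the FDR over L can exceed
$\alpha$. `build_region()` traces the boundary of L on a log-spaced grid of
conditioning values (200 by default, augmented with the observed $p_j$ of
candidate SNPs). The empirical estimator is not monotone in $p_i$ — below
the smallest observed point the empty-rectangle convention returns 1 — so
the boundary is located by a coarse descending scan in $\log_{10} p_i$
(step 0.05) followed by bisection to a tolerance of $10^{-3}$. The
effective boundary at height $y$ is the running suffix maximum of the raw
boundary over conditioning values at or above $y$: this is the unique
monotonisation under which L is an exact staircase union containing every
rectangle it was built from, and it makes the strip decomposition of the
null mass exact.

$v(R)$, the expected number of null SNPs in a region, defaults to the
null-model mass $N[\pi_0\Lambda_{(\rho,0)} + (1-\pi_0)\Lambda_{(\rho,\sigma^2)}]$
rather than literal area (the two coincide at $\rho=0$, $\pi_0=1$, which is
the analytically tested limit); `mode = "area"` is available. The reported
bound is $\alpha^{*}\, v(L)/v(M^{*})$, where $M^{*}$ maximises $v$ over the
boundary rectangles and $\alpha^{*}$ is the estimated cFDR at its
upper-right vertex — taken exactly there, not assumed equal to $\alpha$.

## Downstream corrections

Conditioning one trait on $k$ others multiplies tests, but the $k$ cFDR
series are highly mutually correlated, so Bonferroni is far too severe.
Following the eigenvalue-variance approach, a Spearman correlation matrix
$\Omega$ over the $k$ per-SNP cFDR columns yields
$M_{\mathrm{eff}} = 1 + k(1 - \mathrm{Var}(\lambda)/k)$ with the sample
(divisor $k-1$) eigenvalue variance, reproducing the extremes of one
effective test (identical ranks) and $k+1$ (uncorrelated). Which rows are
"potentially non-null" is not prescribed by the method's source; we restrict
to SNPs whose best cFDR is below ten times the declaration threshold
(overridable), which focuses $\Omega$ where correlations matter while
retaining enough rows to estimate it. The combined bound is
$c_0 = M_{\mathrm{eff}} \sum_j c_j n_j / \sum_j n_j$.

LD pruning is the greedy sweep over declared SNPs in increasing order of
best cFDR, removing later-ranked SNPs with $r^2 \ge 0.1$ against any kept
SNP; $r^2$ comes from a user-supplied pair table, never from genotypes. The
pleiotropy summary solves $\widehat{cFDR}(p^{*} \mid 5\times10^{-6}) =
\widehat{uFDR}(5\times10^{-8})$ for the relaxed principal threshold $p^{*}$
with the same scan-plus-bisection search, and draws a network edge when
$p^{*} \ge 4\times10^{-7}$. The TDT calibration equates the median of
$M = \hat\sigma^2 f(1-f)$ at null SNPs ($p > 0.5$) with
$(n_0+n_1)/(n_0 n_1)$ to back out an equivalent case count
$n_1 = 1/(\mathrm{median}(M) - 1/n_0)$.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `call_rate_min`, `maf_min`, `hwe_z_max` | 0.99, 0.02, 5 | Standard array-QC thresholds; records lacking QC summaries pass with a warning, since QC panels are often computed on a separate common-control set |
| MHC exclusion | chr6:24.5–34.8 Mb (1-based, closed) | Extended LD plus strong autoimmune association distorts pleiotropy estimates |
| `tol`, `max_iter` (EM) | $10^{-8}$ relative log-likelihood, 10000 | Convergence is typically within a few dozen iterations |
| `pi0_init`, `sigma2_init` | 0.9, $\max(\mathrm{var}(z)-1, 0.5)$ | Matches the magnitudes seen in immune-disease data; keeps the fit out of the $\sigma^2 \to 0$ degenerate basin |
| `sigma2_floor` | $10^{-2}$ | Keeps the tail-mass formulas well-conditioned; a fit at the floor is flagged non-identifiable |
| `p_gw` | $5\times10^{-8}$ | Genome-wide significance convention |
| `grid_size`, `bisect_tol` | 200, $10^{-3}$ in $\log_{10} p_i$ | Region boundary resolution |
| `r2_max` | 0.1 | LD pruning threshold |
| p-value floor | $10^{-300}$ | Exact zeros are clamped with a warning; estimators divide by p-derived quantities |

Genomic control uses the median-based $\lambda = \mathrm{median}(z^2)/m_0$
with $m_0$ the $\chi^2_1$ median from the inverse CDF, for robustness to
true signal in the panel. $\lambda$ is *not* floored at 1: the source
method does not state a floor, so deflation is applied, with a warning. The
mixture is fitted after genomic control, since the corrected statistics are
the ones modelled everywhere else.

## What the simulator emulates — and what it does not

`simulate_pair()` draws, per SNP, the conditional label and effect from the
mixture, the principal label from a marginal null proportion with an
optional pleiotropic `overlap` (the probability that a conditionally
non-null SNP is also principally non-null; the principal marginal is
preserved, which requires $1-\pi_0^{(i)} \ge \mathrm{overlap}\cdot(1-\pi_0^{(j)})$),
and the Z pair from the bivariate normal with noise correlation $\rho$.
Defaults reproduce the reference scenario: 20,000 SNPs, principal all null,
conditional null with probability 0.9, $\sigma = 3$, $\rho = 0.5$ (a typical
value for study pairs sharing most of their control pool). Each SNP consumes
a fixed number of draws from one seeded stream, so enlarging `n_snps`
extends a table without perturbing earlier SNPs.

The simulator deliberately omits LD between SNPs (the estimators treat SNPs
exchangeably; LD enters only through the user-supplied pruning table),
allele-frequency-dependent power, cryptic relatedness, shared *cases*, and
any joint effect-size distribution for pleiotropic SNPs (shared status is
modelled at the label level, with independent magnitudes). Passing tests
therefore certify the method under its own assumptions — exchangeable SNPs
with exactly the assumed mixture and correlation structure — not its
behaviour on arrayed real data, where LD induces dependence between nearby
test statistics and genomic control is only an approximate fix for
stratification. The genotype-level oracle (`simulate_genotype_studies()`) is
the one place the package steps outside the Z-level model: it validates the
$\rho$ formula from binomial allele counts, using the allele-frequency-
difference Z rather than a logistic regression, which is adequate at the
group sizes tested.

## Numerical and degenerate-input conventions

EM responsibilities and the log-likelihood are computed in log space
(log-sum-exp); the naive density-ratio form produces NaN at $|Z| \gtrsim 40$
where both component densities underflow. Cumulative tail quantities are
computed in double precision without a log-space transform; p values below
$10^{-300}$ are clamped upstream. A query rectangle containing no observed
pairs maps to a cFDR of 1 (never declarable) rather than an error, except
when the conditioning event itself is empty, which errors. Thresholds are
undefined (flagged, nothing declared) when no SNP reaches `p_gw`; an
`alpha` below the minimum attainable cFDR yields an empty region, flagged
with a warning. The design-count validation requires at least one case and
one control per study and rejects negative counts.

## Problem sizes used by the test suite

The suite exercises the estimators at the sizes the method is designed for
while remaining desk-scale: mixture recovery at $n = 20{,}000$ over 10–20
replicate streams; expected-quantile validation against $10^5$–$10^6$
simulated pairs per configuration (20 random configurations); FDR control
at 200 all-null replicates of 2,000 SNPs; the union-effect/region-bound
demonstration at 50 replicates of 5,000 SNPs; Monte-Carlo oracles for tail
probabilities at $2\times10^6$ draws. These sizes were chosen so each
property is resolved well beyond its assertion tolerance.

## Known limitations

* The cFDR machinery is tail-area only; no local (density) FDR is computed.
* The shared-control model covers shared controls, not shared cases or
  related individuals.
* $\widehat{cFDR}(p_i \mid p_j) \ne \widehat{cFDR}(p_j \mid p_i)$: a
  declaration for the principal trait says nothing genome-wide about the
  conditional trait. Ordered pairs are processed independently.
* The conditional-cutoff statistic is an empirical-estimator solve; with
  few SNPs in the conditioning subset it can have no solution and is then
  flagged undefined rather than extrapolated.
* With no true non-null component the mixture likelihood is flat along the
  ridge $(1-\pi_0)\sigma^2 \approx 0$; fits there are reported honestly
  (possibly mid-ridge) and flagged when $\sigma^2$ sits at its floor.
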