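---
title: "Methods: MR gene prioritization and spatial immune-exclusion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MR gene prioritization and spatial immune-exclusion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excluscope)
```

This vignette is the package's own account of its models, the assumptions
they rest on, the tunable parameters, the numerical choices made where the
design was genuinely open, and what the synthetic-data generators do and do
not emulate.

## 1. Two-sample MR on summary statistics

### Model and assumptions

For one gene, the unit of work is a harmonized instrument set: SNPs with
exposure (cis-eQTL) effects $\hat\beta_{Xj} \pm \sigma_{Xj}$ and outcome
(GWAS) effects $\hat\beta_{Yj} \pm \sigma_{Yj}$, both referring to the same
effect allele. Each instrument must be relevant (exposure $p < 5\times10^{-8}$
and $F = (\hat\beta_X/\sigma_X)^2 \ge 10$; weaker instruments bias two-sample
estimates toward the null), independent of confounders, and act on the
outcome only through the exposure. LD clumping at $r^2 < 0.001$
(greedy by ascending p, deterministic tie-break on SNP id) enforces
approximate independence among instruments; the LD matrix is an input, never
computed here.

Harmonization re-signs outcome effects reported on the swapped allele and
drops allele-mismatched SNPs. Palindromic SNPs (A/T, C/G) are dropped when
the exposure EAF is missing or within 0.08 of 0.5 — with near-balanced
frequencies the strand cannot be resolved, and a wrong resolution silently
flips the effect sign. The 0.08 window is the conservative convention in
two-sample MR software; it is a package default, configurable per call.

### Estimators

* **Wald ratio** $b_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order
  (delta) SE $\sigma_{Yj}/|\hat\beta_{Xj}|$. Exposure uncertainty is ignored
  — the standard two-sample convention (NO Measurement Error assumption);
  with instrument-grade exposures ($F \ge 10$, typically far above) the
  neglected term is second-order.
* **IVW** (primary): fixed-effects weighted mean of the $b_j$ with
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, $se = (\sum w_j)^{-1/2}$,
  two-sided normal p. A multiplicative random-effects variant (SE inflated
  by $\sqrt{Q/(n-1)}$ when that ratio exceeds 1) is available as a flag;
  fixed effects is the default because the retention filter conditions on
  low heterogeneity anyway. With a single instrument IVW *is* the Wald
  ratio, delegated explicitly so the identity is exact.
* **MR-Egger**: WLS of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ (weights
  $1/\sigma_{Yj}^2$) with a free intercept, after orienting all exposure
  effects non-negative. The intercept estimates directional pleiotropy;
  both coefficients use t tests with $n-2$ df. Requires $\ge 3$ instruments.
* **Weighted median**: the ratio at interpolated cumulative weight 0.5;
  consistent when $\ge 50\%$ of weight is valid. No closed-form SE exists,
  so it comes from a seeded parametric bootstrap (200 resamples of both
  effect estimates from their sampling distributions).
* **Simple/weighted mode**: argmax of a Gaussian-kernel density of the
  ratios, unweighted and $w_j$-weighted, bandwidth
  $0.9\min(sd, mad)\,n^{-1/5}$ (modified Silverman; the $mad$ guards against
  outlying ratios) times a configurable multiplier, evaluated on a 512-point
  grid spanning the ratio range $\pm 3$ bandwidths. Reported without
  p-values — they are direction/robustness diagnostics here.
* **Cochran's Q** $= \sum w_j (b_j - \hat\beta_{IVW})^2 \sim \chi^2_{n-1}$
  for heterogeneity.

### Two-stage retention and intersection

A gene is TMR-supported when discovery IVW $p < 0.05$, discovery Egger
intercept $p > 0.05$, replication IVW $p < 0.05$, and log-OR signs agree
across cohorts. Two points were genuinely open:

* *"Consistent direction and magnitude"* across stages is implemented as
  direction consistency only — no operational magnitude criterion exists in
  the field, and any ratio-based band would be arbitrary; the choice is
  flagged in the function documentation.
* Heterogeneity (Q) p is reported but **not** a retention criterion; a flag
  (`het_thresh`) can add it. The primary filter names only IVW significance
  and absence of directional pleiotropy.

The SMR screen takes the top cis-eQTL ($p < 10^{-5}$) as sole instrument:
$b_{SMR} = \hat\beta_{GWAS}/\hat\beta_{eQTL}$, tested with
$T = z_1^2 z_2^2/(z_1^2+z_2^2) \sim \chi^2_1$ — an algebraic composition
bounded by the weaker of the two association z-scores, so no amount of eQTL
strength rescues a null GWAS signal. The HEIDI test asks whether the
flanking SNPs, through their LD with the top SNP, tell the same
$b_{SMR}$ story: contrasts $d_i = b_{SMR}(i) - b_{SMR}(top)$ are zero in
expectation under one shared causal variant. Their covariance follows from
the delta method with within-study covariances $r_{ij}\sigma_i\sigma_j$
(eQTL and GWAS samples independent); the statistic $\sum z_{d_i}^2$ is a sum
of correlated $\chi^2_1$ terms, approximated by Satterthwaite moment
matching: with $R$ the correlation matrix of the standardized contrasts,
$T/c \sim \chi^2_\nu$, $c = \mathrm{tr}(R^2)/m$, $\nu = m^2/\mathrm{tr}(R^2)$.
Under identity LD (and a precisely estimated top SNP) this collapses exactly
to $\chi^2_m$, which the tests verify. Eligible flanking SNPs need eQTL
$p < 1.57\times10^{-3}$ and $r^2$ with the top SNP in $[0.05, 0.9]$, capped
at 20 by ascending eQTL p — mirroring the documented defaults of the
standard SMR tool; too few eligible SNPs yields a missing $p_{HEIDI}$, and a
precomputed $p_{HEIDI}$ column is always accepted instead.

Retention then requires TMR support **and** the SMR criterion
($p_{SMR} < 0.05$, $p_{HEIDI} > 0.05$) in at least one cohort
(`smr_cohort_rule = "any"`, the default; `"all"` is offered for a stricter
intersection). Direction classification is sign-based: risk-increasing
requires OR $> 1$ in both TMR cohorts and $b_{SMR} > 0$ in both SMR cohorts;
protective is the mirror; everything else — including exact boundary values
— is discordant, the unambiguous conservative rule.

## 2. Spatial immune-exclusion statistics

Spots are points with coordinates (array or micron units), per-spot signals
(e.g. a marker score, a CTL score) and boolean labels. "Marker-high" and
"immune-high" are operationalized as the upper quartile of the respective
signal (strictly greater than the 0.75 quantile; configurable). No rule is
canonical here, and none needs to be: the permutation null is valid for any
fixed thresholding rule, so the choice affects power, not validity.

Two statistics, both with explicit brute-force oracles in the test suite:

* **Neighborhood**: mean immune signal over each marker-high spot's $k = 6$
  Euclidean nearest neighbors (self excluded, distance ties broken by
  ascending spot index), averaged over marker-high spots. Aggregation is
  mean-over-mean — the simplest reading; medians are a config option.
* **Nearest-neighbor distance**: mean over marker-high spots of the distance
  to the closest immune-high spot (a spot in both sets contributes zero).

Both are invariant under rigid motions of the coordinates; the distance
statistic scales linearly with the coordinates and the neighborhood
statistic is scale-invariant (neighbor sets unchanged) — tested properties.
Hexagonal (Visium-style) layouts need no special handling: the statistics
are kNN/distance-based in the supplied coordinates, not lattice-based.

Significance comes from coordinate-preserving permutations: the immune
values (or the binary immune-high labels) are uniformly shuffled across all
spots $B = 10{,}000$ times (defaults; tests use smaller B), with coordinates
and the marker-high mask fixed. For a binary signal the two schemes coincide
in distribution; both are exposed because real panels sometimes supply
continuous deconvolved proportions and sometimes hard labels. The empirical
p carries the +1 correction, $p = (1 + \#\text{extreme})/(B+1)$ with ties
counting as extreme, hence $p \in [1/(B+1), 1]$ — never exactly zero, and
exact-level valid. Alternatives are fixed by the exclusion hypothesis:
*less* for the neighborhood statistic (exclusion = depressed local immune
signal), *greater* for the distance statistic (exclusion = larger
separation); a two-sided option doubles the smaller one-sided p, capped
at 1. The RNG stream is fully determined by the seed; `exclusion_report`
derives the second test's stream from `seed + 1`.

## 3. Expression stratification

* **Marker-positive cells**: raw count $> 0$. Deliberately simple — at
  single-cell sparsity any detectable expression is the defensible positive
  call, and the rule is exactly testable (flipping one zero flips exactly
  that cell).
* **Marker screen**: per-cell counts-per-10k normalization;
  $\log_2$FC $= \log_2((\bar x_{pos}+1)/(\bar x_{neg}+1))$ on normalized
  means (pseudocount 1 damps the ratio where means are near zero); two-sided
  Wilcoxon rank-sum p per gene; BH FDR over all tested genes; reported genes
  satisfy $|\log_2 FC| \ge 0.5$ and FDR $< 0.05$. The normalization and
  pseudocount are documented stand-ins for a framework default the source
  tooling leaves implicit.
* **Median dichotomization**: low iff value $\le$ median — ties go low, so
  the split is deterministic and order-invariant.
* **Mann–Whitney U**: normal approximation with tie *and* continuity
  corrections; exact enumeration of all $\binom{n_1+n_2}{n_1}$ assignments
  (ties handled by midranks) when both groups have $\le 8$ observations.
  Numerical note: at $n_1 = n_2 = 8$ the continuity-corrected approximation
  tracks the exact two-sided tail within 0.011 uniformly over the U range
  (worst case mid-range); without the correction the error reaches 0.046.
  That bound is a property of the normal approximation itself, verified by
  exact enumeration in the tests, and is why the correction is on by
  default.
* **Spearman**: Pearson correlation of midranks, p from the t approximation
  on $n-2$ df; constant inputs are flagged rather than silently returning
  NaN.
* **Immune-factor panel**: median split on the marker, Mann–Whitney per
  panel gene (CXCL14, TNFSF13B, TNFSF18 by default), BH within the panel,
  direction = high-group median − low-group median. BH is applied within
  each screen/panel, not across modules, mirroring per-analysis testing.

## 4. What the generators emulate — and what they do not

Every generator is a pure function of its seed; identical specs give
byte-identical output.

* `simulate_mr_dataset`: instrument-grade exposures (true effects uniform on
  $[0.08, 0.2]$, $\sigma_X = 0.01$, so $F \gtrsim 60$ and genome-wide
  significance hold by construction), outcomes
  $\beta_Y = \beta\,\beta_X + \delta + \varepsilon$,
  $\sigma_Y = 0.01$. Exposure effects are reported for the
  expression-increasing allele (all positive) — the usual eQTL convention,
  and necessary for a constant directional pleiotropy $\delta$ to be
  estimable: with random instrument signs, Egger's orientation step would
  average $\pm\delta$ to zero. A 10% fraction of SNPs gets palindromic
  alleles with EAF drawn in $(0.45, 0.55)$ — planted to be dropped — and
  30% of outcome records are reported on the swapped allele to exercise
  harmonization. Under these conditions 500 simulations at $\beta = 0.1$
  with 50 instruments give mean IVW bias below 0.005 and CI coverage in
  $[0.92, 0.98]$; at $\beta = 0$ the IVW p-values are uniform; injected
  $\delta = 0.02$ is recovered by the Egger intercept within $\pm 0.005$
  (all recomputed by the acceptance script).
* `simulate_smr_locus`: AR(1) LD $r_{ij} = 0.9^{|i-j|}$ over 31 SNPs,
  z-scores drawn from the standard summary-statistic model
  $z \sim N(z_c\, r_{\cdot c},\, R)$ with causal z-scores 9 (eQTL) and 6
  (GWAS); the shared scenario uses one causal index for both traits, the
  distinct scenario displaces the GWAS causal variant by about a quarter of
  the locus. Real LD is not AR(1); the decay form simply provides a dense,
  positive-definite correlation with a realistic eligible-SNP count
  (roughly 8–16 flanking SNPs pass the HEIDI filter).
* `simulate_spot_grid`: a square unit lattice (16×16 default) with a
  contiguous tumor patch (the ~25% of spots nearest a random center) carrying
  a high marker score (+3); the immune score is baseline 1 plus N(0, 0.5)
  noise, shifted by $-$effect (exclusion, default 2) or $+$effect
  (colocalized) inside the patch, or untouched (null — effect forced to 0,
  making immune values exchangeable so the permutation null is exact by
  construction). Hex packing, multiple tissue domains and spot-level
  mixtures are not emulated; the statistics only consume coordinates, so
  none of that affects their validity, only the realism of power figures.
* `simulate_counts`: negative-binomial counts (size 2), 50 genes × 400 cells,
  half the cells marker-positive (marker zero-truncated there, exactly zero
  elsewhere), five DE genes at fold 4. The marker and DE genes get low base
  means (2 and 1) against a lognormal filler background (median 5) so the
  planted folds perturb per-cell library composition only mildly — in a
  real transcriptome a handful of regulated genes barely moves the library;
  in a 50-gene panel, high-expressed 4-fold genes would, and the CP10K
  screen would then correctly (but unhelpfully for a benchmark) flag every
  filler gene as compositionally shifted.
* `simulate_bulk`: log2-scale Gaussian expression (sd 0.5), marker
  N(5, 1), panel genes shifted down by 2 in marker-high samples.

Passing tests on these generators demonstrate the *statistical machinery* —
calibration under exchangeable nulls, power against planted effects, exact
recovery of planted labels. They do not demonstrate robustness to what the
generators omit: real LD structure, cell-type mixtures within spots,
batch effects, or transcriptome-wide covariance.

## 5. Problem sizes, tolerances and degenerate inputs

The shipped test suite and acceptance script use: 500 MR simulations per
calibration scenario (50 instruments each), 100 loci per HEIDI scenario,
200 null grids at B = 199 and 50 planted grids at B = 999 for the spatial
calibration/power checks, 100 seeds for the marker-screen benchmark, and
oracle comparisons on random grids up to 300 spots — sizes at which every
Monte-Carlo band in the tests is comfortably wider than simulation noise.
Oracle equivalences are asserted at 1e-10 (WLS) and 1e-12 (spatial
statistics); identities (single-instrument IVW = Wald) are asserted
bit-exact.

Degenerate inputs are handled explicitly rather than by crash: empty
instrument intersections and all-filtered genes raise classed, catchable
conditions (the pipeline skips the gene); constant spot signals threshold to
an all-false mask with a warning; constant panel genes are skipped with a
warning; $\hat\beta_{X} = 0$ Wald ratios and single-level partitions are
errors naming the cause; all-tied Mann–Whitney inputs return p = 1.

## 6. Known limitations

* HEIDI's delta-method variances degrade for flanking SNPs near the
  eligibility floor (|z| ≈ 3.2); the eligibility filter exists precisely to
  keep the approximation in its working range, and the distinct-variant
  detection rate (~0.8 at the simulated effect sizes) reflects genuine
  power limits of the screen, not an implementation gap.
* The weighted-median SE is a bootstrap estimate and inherits Monte-Carlo
  noise; 200 resamples keeps it within a few percent, and the resample
  count is a parameter.
* The spatial tests condition on the marker-high mask; they test the immune
  signal's arrangement, not joint randomness of both patterns.
* The pipeline consumes per-gene/per-spot tables; upstream processing
  (alignment, deconvolution, clustering, batch correction) is out of scope
  by design.
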