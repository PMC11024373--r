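---
title: "Pooled-DNA genomic prediction and GWAS: models and methods"
author: "poolgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-DNA genomic prediction and GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolgp)
```

# Overview

`poolgp` analyzes breeding trials in which DNA *pools* — built from the
phenotypic tails of each environment plus a random interquartile pool —
are sequenced instead of individual plants. This vignette documents the
statistical models, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the numerical
decisions a maintainer would want written down.

# Phenotype coding

Two traits are handled as bounded proportions in $[0,1]$:

* **Seed dormancy**: the proportion of *viable* seeds that remain hard
  after 7 days of imbibition. `dormancy_proportion(imbibed, hard, dead)`
  returns `hard / (imbibed + hard)`; dead seed enters neither numerator
  nor denominator, and a zero denominator yields `NA` (flagged missing).
* **Pod dehiscence**: mean per-pod shattering score.
  `rescale_dehiscence()` divides 0–3 suture scores by three so they are
  commensurate with binary 0/1 scores; pool membership is invariant to
  this monotone rescaling.

# Pool construction

`build_pools()` forms, per environment and trait, the high and low
`tail_fraction` (default 0.25) of phenotyped individuals, plus one
interquartile pool per environment shared across traits, drawn uniformly
(seeded) from individuals in *no* tail pool of either trait. Choices:

* Pool size is `round(0.25 * N)` with half-away-from-zero rounding, where
  `N` counts individuals with a non-missing phenotype for the trait —
  e.g. N = 116 gives 29-member pools. The interquartile pool has the same
  nominal size, capped by the number of individuals left outside all
  tails (with weakly correlated traits the four tails can consume most of
  the cohort).
* Ties at the quantile boundary are broken by ascending sample id, making
  membership fully deterministic.
* Equal tissue mass per member is assumed, so a pool's true allele
  frequency is the mean of member frequencies (`pool_true_frequency()`);
  unequal DNA yield per member is *not* modeled.

# Pool allele frequencies and filtering

`estimate_pool_frequency()` converts read counts to the joint 0–2 scale
(`2 * alt/depth`; depth 0 is missing), so pools and individual dosages can
share one genotype matrix.

The depth threshold is calibrated from technical replicates:
`depth_concordance_curve()` bins markers by the smaller replicate depth
and averages $|f_1 - f_2|$ per bin; `select_depth_threshold()` finds the
plateau. The rule: scanning bins in depth order, return the lower edge of
the first bin whose relative improvement over the previous bin falls
below `rel_improvement_tol` (default 5%); a zero/negative improvement
means the plateau already includes the previous bin, whose edge is
returned; a strictly increasing curve returns the deepest edge with a
warning. Bins with fewer than `min_markers` markers are ignored. The rule
is deterministic and reproduces three edge cases exactly: a flat curve
selects the first edge, a geometric decay with ratio 0.5 under tolerance
0.6 selects the second edge, and an increasing curve warns.

`apply_filters()` fixes the stage order: chromosome whitelist → depth
filter (strictly `> min_depth`, default 30) → mean imputation → MAF
filter (folded frequency `< maf_min` removed, default 0.025). Imputation
preserves each marker's observed mean exactly, and the pipeline is
idempotent. The depth statistic is configurable: `"min"` across pooled
samples (the strictest reading, the default) or `"mean"`. With
independent per-pool missingness around 15%, the minimum rule over 24
pools retains only a few percent of markers and leaves *no* missing calls
for the imputation stage to handle; a pipeline that reports missing calls
remaining after its depth filter is therefore operating under a
non-minimum rule, and the end-to-end analyses in this package use
`depth_rule = "mean"` for that reason.

# Relationship matrix

`additive_relationship()` implements VanRaden method 1 on the 0–2 scale,
treating pools and individuals identically. Column allele frequencies are
estimated from the matrix actually supplied (pools + individuals
together), not from an external panel. Monomorphic columns are excluded
from both the centered cross-product and the denominator
$2\sum_m p_m(1-p_m)$, so adding one changes nothing. No shrinkage is
applied. The function returns the raw matrix; `gblup()` adds a ridge
(default $10^{-6}$) to the diagonal for invertibility.

# GBLUP and REML

`gblup(value ~ environment, data, kinship, residual_by = "environment")`
fits

$$ y = X\beta + Zg + \varepsilon,\quad g \sim N(0, A\sigma^2_g),\quad
   \varepsilon_{jk} \sim N(0, \sigma^2_{e(k)}) $$

by REML and returns a classed fit with `print`, `summary`, `coef`,
`predict`, `fitted`, `residuals` and `logLik` methods. Implementation
notes:

* **Homogeneous residuals**: the eigendecomposition of $ZAZ'$ reduces
  REML to a one-dimensional profile over $\delta = \sigma^2_e/\sigma^2_g$
  (EMMA-style); a 121-point log-grid over $[e^{-16}, e^{16}]$ brackets the
  optimum and `optimize()` polishes it to tolerance $10^{-10}$.
* **Heterogeneous residuals / extra random effect**: Nelder–Mead on the
  dense restricted log-likelihood over log-variances, started from the
  homogeneous solution (relative tolerance $10^{-10}$, up to 2000
  evaluations). The optional `extra_random` grouping (e.g. maternal line
  × environment) adds one iid variance component.
* Variances are floored at $10^{-8}\,\mathrm{var}(y)$; a constant
  response collapses to the floor with all-zero GEBVs.
* Fixed-effect factors use treatment contrasts with the lexicographically
  first level as reference; factor terms with fewer than two observed
  levels are dropped automatically, so single-environment training sets
  lose the environment effect rather than failing.
* GEBVs $\hat g = \sigma^2_g A_{\cdot,\mathrm{obs}} Z' V^{-1}(y - X\hat\beta)$
  are produced for every row of $A$, including pools and unphenotyped
  individuals; they lie in the column space of $A$.

A caution on identifiability: as $h^2 \to 1$ the per-environment residual
split is weakly informed and its REML estimate can sit at the boundary,
so ratios of residual variances are only meaningful at moderate
heritability.

# Association scan

`gwas_scan()` adds each marker as a fixed covariate to the null mixed
model. In `"p3d"` mode the variance components are estimated once under
the null; each marker then gets a generalized-least-squares coefficient
with the residual *scale* re-estimated per marker (the GLS F-test form),
which reduces exactly to the OLS t-test when $V \propto I$. Wald p-values
use $t$ with $n - \mathrm{rank}(X) - 1$ degrees of freedom (a z
approximation is deliberately not the default at pool-scale $n$). In
`"exact"` mode components are re-estimated per marker. Markers collinear
with the fixed effects (e.g. one that mirrors an environment indicator)
or without variance are flagged `NA` with a warning.
`bh_qvalues()` applies Benjamini–Hochberg step-up (missing p-values are
propagated and excluded from the test count); `significant_hits()` labels
each hit by whether its *minor* allele (folded frequency from the scanned
panel) moves the trait in the favorable direction.

**Power at pool scale.** With ~24 pool records the Wald $t$ (19 df) for a
QTL carrying even 20% of the genetic variance tops out around 3 under
noiseless frequencies, i.e. $p \gtrsim 3\times10^{-3}$ — so FDR-corrected
discovery at $q < 0.01$ is not reachable at that effect size regardless
of panel size, and the acceptance suite documents this as an expected
shortfall rather than relaxing the threshold. Detections at such
stringency require either more pool records or markers of much larger
effect.

# Direction-aware Fisher combination

`fisher_combine(p1, p2, sign1, sign2, favorable_sign)` merges two scans'
p-values per marker. When the effect signs disagree, the study whose
effect points in the unfavorable direction has its p set to 1 before
computing $\chi^2 = -2(\ln p_1' + \ln p_2')$ against $\chi^2_4$. Masking
triggers only on discordance — two concordant unfavorable effects are
combined untouched. Zero p-values are clamped to the smallest positive
double with a warning. `combine_scans()` intersects markers (by
chromosome/position/alleles when metadata is available), flips the second
study's sign when its ref/alt coding is swapped, excludes true allele
mismatches with a warning, and reports one-study-only markers separately.
Under the null with random signs the masked test is conservative. Note
that self-combination only sharpens evidence below $p \approx 0.285$ at
4 df (the often-quoted $1/e$ break-even is the large-$k$ limit).

# Prediction evaluation

`true_gebvs()` fits the full individual panel (environment fixed effects,
per-environment residuals) to produce reference GEBVs;
`predictive_ability()` scores predictions by Pearson correlation with a
bootstrap standard error over targets (default 1000 resamples, seeded;
Fisher-z $\,(1-r^2)/\sqrt{n-3}$ available as the analytic alternative);
`run_comparison_suite()` repeats this across named training subsets
(all pools, per-state pools, single environments, …), dropping the
environment effect for single-environment subsets.

# The synthetic-data generator

`sim_config()` defaults encode the study conditions the package is
designed around: four site-year environments with cohorts 115/206/109/287,
two traits at $h^2 = 0.5$ with genetic correlation 0.4 at shared QTL,
mean pooled depth 50× and 14.8% missing calls, 25% tails, and pre-flowering
truncation selection between generations. Choices that were genuinely
open, and how they were fixed:

* **Linkage**: founder haplotypes are mosaics of a 20-haplotype ancestral
  panel (about two switch points per chromosome), and meioses place
  Poisson(1) crossovers per chromosome. This produces LD that decays with
  distance — a modeling convenience, not a claim about any species' LD.
* **Environment variance**: fixed environment shifts with SD 0.9 put
  roughly 28% of liability variance between environments at the default
  residual scale.
* **Observation model**: each trait is a Gaussian liability (breeding
  value + environment shift + residual) pushed through a logistic link
  and observed binomially — dormancy as $k/25$ seeds, dehiscence as the
  mean of 50 pod scores — giving bounded, skewed proportions. Negative
  link intercepts (default −1) skew values toward zero. Heritability is
  defined on the liability scale, and
  `simulate_phenotypes(observation = "latent")` exposes that scale
  directly; variance-partition and heritability-recovery checks are
  statements about the latent trait, since the binomial link attenuates
  observed-scale $h^2$ nonlinearly.
* **Read depth**: Poisson by default; a negative-binomial option
  (`nb_size`) models the overdispersion real libraries show. Technical
  replicates additionally carry a pool-construction/library noise floor
  (`noise_eq_depth`, default 30): each library's realized frequency is
  jittered with variance $f(1-f)/30$, i.e. the floor equals binomial
  counting noise at 30 reads. That is precisely what makes
  replicate-concordance curves plateau near 30× — at greater depths
  counting noise is no longer the limiting error — and is the basis for
  the 30-read depth filter. `noise_eq_depth = Inf` gives pure binomial
  sampling.
* **Major QTL**: `major_qtl_fraction` concentrates a chosen fraction of a
  trait's genetic variance in the QTL segregating closest to frequency
  0.5, with a constant effect across environments, for power studies.
* **Determinism**: every stochastic operation takes an explicit seed, and
  a configuration plus seed reproduces byte-identical outputs.

What the generator does **not** emulate: sequence-level reads (no FASTQ,
alignment, or variant calling — simulation starts at read counts),
reference bias, DNA-yield differences among pool members,
species-realistic LD or founder diversity, dominance/epistasis, and
shared missingness structure across pools (missing calls are independent
per pool, which interacts with the `"min"` depth rule as described
above). Passing tests therefore validate the statistical machinery under
these idealizations, not field performance on any particular crop.

# Problem sizes used in the test suite

The shipped tests exercise the oracles at small scale and the pipeline at
the study's own design scale: 50 random REML instances ($n \le 30$)
against a nested grid-search oracle; heritability recovery on cohorts of
500 individuals × 2000 markers across $h^2 \in \{0.2, 0.5, 0.8\}$ (7
seeds each); and 20 end-to-end replicates of the four-environment pooled
design (24 libraries including technical replicates, ~1000 markers).
These sizes give stable Monte-Carlo verdicts for the assertions made
while keeping a full run in minutes on one CPU.
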