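# poolgp

Genomic prediction and genome-wide association from **pooled-DNA
sequencing** of breeding populations.

Phenotyping hundreds of plants is cheap; sequencing each of them is not.
An alternative is to sequence a handful of DNA pools built from the
phenotypic extremes of each field trial: the best and worst 25% of plants
for each trait, plus one random "interquartile" pool per environment that
estimates the population mean allele frequency. Each pool contributes a
single record — its allele frequencies (from read counts) and the mean
phenotype of its members — and those few records are enough to train a
genomic prediction model and to scan for trait-associated loci. `poolgp`
implements that entire analysis chain, plus a breeding-program simulator
used to validate every stage.

The motivating use case is breeding hairy vetch (*Vicia villosa*), an
outcrossing cover-crop legume, against two domestication-limiting traits
measured as bounded proportions: **seed dormancy** (fraction of viable
seeds still hard after 7 days of imbibition, dead seed excluded) and
**pod dehiscence** (mean per-pod shattering score, rescaled from a 0–3
visual scale to 0–1 where needed).

## The model

All samples — pools and individuals — live on a common 0–2 allele scale:
individuals as dosages {0, 1, 2}, pools as twice the alternate-allele read
fraction. Over that joint matrix the package builds the VanRaden realized
additive relationship

    A = W W' / (2 Σ_m p_m (1 − p_m)),   W = M − 2p  (column-centered),

and fits the GBLUP mixed model by REML:

    y = μ + E_k + g + ε,   g ~ N(0, A σ²_g),   ε_jk ~ N(0, σ²_e(k)),

where `E_k` is the fixed site-year (environment) effect and the residual
variance is allowed to differ by environment (a diagonal heteroscedastic
D structure). A pool's record is simply the mean phenotype of its members.
GEBVs (genomic estimated breeding values) are predicted for every row of
`A`, including samples that contributed no phenotype.

On top of the same machinery:

* `gwas_scan()` — kinship-corrected single-marker association
  (EMMAX-style P3D, or exact per-marker REML), Wald tests, and
  Benjamini–Hochberg q-values;
* `fisher_combine()` / `combine_scans()` — a direction-aware Fisher
  combination of two scans (χ² = −2 Σ ln p on 2k df), where a marker whose
  two effect estimates disagree in sign first has the p-value of its
  *unfavorable*-direction study set to 1;
* `depth_concordance_curve()` / `select_depth_threshold()` — read-depth
  threshold calibration from technical-replicate concordance;
* `apply_filters()` — the SNP pipeline: chromosome whitelist → depth
  filter → mean imputation → minor-allele-frequency filter;
* `simulate_population()` & friends — a breeding-program generator with
  linkage, truncation selection, genotype-by-environment interaction,
  correlated traits, and pooled read counts.

## Worked example

Simulate the default study design — four environments with cohorts of
115/206/109/287 plants, two correlated traits at h² = 0.5 — then build
pools, sequence them *in silico* at 50× with 14.8% missing calls, filter,
and train a pool-only GBLUP:

```r
library(poolgp)

cfg  <- sim_config(seed = 42)
pop  <- simulate_population(cfg)
ph   <- simulate_phenotypes(pop)
envs <- levels(pop$env)

specs <- unlist(lapply(seq_along(envs), function(i)
  build_pools(ph, envs[i], seed = 100 + i)), recursive = FALSE)
specs[[1]]
#> Pool 20MD_dehiscence_low [20MD, low_tail]: 29 members; mean phenotype:
#>   dehiscence = 0.134, dormancy = 0.332

freqs <- lapply(specs, function(s) pool_true_frequency(pop$geno, s$members))
reads <- lapply(seq_along(specs), function(i)
  simulate_pool_reads(freqs[[i]], depth_mean = 50, missing_rate = 0.148,
                      seed = 200 + i))
est  <- lapply(reads, estimate_pool_frequency)
Fmat <- do.call(rbind, lapply(est, `[[`, "freq02"))
rownames(Fmat) <- vapply(specs, `[[`, "", "pool_id")
Dmat <- do.call(rbind, lapply(est, `[[`, "depth"))

flt <- apply_filters(Fmat, Dmat, depth_rule = "mean")
flt$report
#> SNP filter report
#>   input                  1000
#>   on main chromosomes    1000
#>   depth > 30             997
#>   after mean imputation  997
#>   MAF >= 0.025           950
#>   missing calls: 15.0% before, 14.9% after depth filter

A <- additive_relationship(rbind(flt$matrix, pop$geno[, colnames(flt$matrix)]))
recs <- data.frame(sample_id   = rownames(Fmat),
                   environment = vapply(specs, `[[`, "", "environment"),
                   value       = vapply(specs, function(s)
                                   s$mean_phenotype[["dormancy"]], 0))
fit <- gblup(value ~ environment, recs, A, residual_by = "environment")
fit
#> GBLUP fit (REML)
#>   records: 20; relationship rows: 737; fixed effects: 4
#>   sigma2_g = 0.3693; sigma2_e = 20MD 0.004163, 21WI 0.01824, ...
#>   h2 = 0.985; restricted logLik = -1.194; converged: TRUE
```

Twenty pool records predict the 717 individual plants' true breeding
values with r ≈ 0.70 here:

```r
tbv <- rowMeans(pop$bv$dormancy)
predictive_ability(predict(fit, rownames(pop$geno)), tbv, seed = 1)
#>   comparison         r         se   n se_method
#> 1       <NA> 0.7015394 0.01992613 717 bootstrap
```

The pool GWAS runs off the same records (`gwas_scan()` with the same
kinship and environment fixed effects); `significant_hits()` labels each
hit by whether its minor allele pushes the trait in the favorable (low)
direction, and `combine_scans()` merges the pool scan with an
individual-panel scan.

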