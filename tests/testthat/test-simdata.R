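test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_qtl_per_trait = 50, n_markers = 20), "exceeds")
  expect_error(sim_config(h2_per_trait = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(missing_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(selection_fraction_pre_flowering = 0), "\\(0, 1\\]")
  expect_error(sim_config(depth_mean = -5), "nonnegative")
  expect_error(sim_config(major_qtl_fraction = 1), "\\[0, 1\\)")
})

small_cfg <- function(...) {
  sim_config(n_individuals_per_env = c(A = 50, B = 50), n_markers = 150,
             n_qtl_per_trait = 10, seed = 5, ...)
}

test_that("population simulation is deterministic and well-formed", {
  cfg <- small_cfg()
  pop1 <- simulate_population(cfg)
  pop2 <- simulate_population(cfg)
  expect_identical(pop1$geno, pop2$geno)
  expect_identical(pop1$effects, pop2$effects)
  expect_true(all(pop1$geno %in% 0:2))
  expect_equal(dim(pop1$geno), c(100, 150))
  # positions strictly increasing within chromosome
  for (chr in unique(pop1$map$chrom))
    expect_false(is.unsorted(pop1$map$pos[pop1$map$chrom == chr], strictly = TRUE))
  # segregating frequencies in (0,1) at most markers
  p <- colMeans(pop1$geno) / 2
  expect_gt(mean(p > 0 & p < 1), 0.9)
})

test_that("h2 = 0 gives all-zero effects and phenotypes carry no signal", {
  cfg <- small_cfg(h2_per_trait = 0)
  pop <- simulate_population(cfg)
  for (e in names(pop$effects$effects_by_env))
    expect_true(all(pop$effects$effects_by_env[[e]] == 0))
  expect_true(all(unlist(pop$bv) == 0))
})

test_that("linked markers are more correlated than distant ones", {
  cfg <- sim_config(n_individuals_per_env = c(A = 300), n_markers = 300,
                    n_chromosomes = 3, seed = 9)
  pop <- simulate_population(cfg)
  g <- pop$geno
  v <- apply(g, 2, var)
  idx <- which(v > 0)
  adj_j <- idx[((idx - 1) %in% idx) &
                 pop$map$chrom[idx] == pop$map$chrom[pmax(idx - 1, 1)]]
  adj <- vapply(adj_j, function(j) abs(cor(g[, j], g[, j - 1])), numeric(1))
  set.seed(1)
  far <- vapply(seq_len(200), function(i) {
    jk <- sample(idx, 2)
    if (pop$map$chrom[jk[1]] == pop$map$chrom[jk[2]]) return(NA_real_)
    abs(cor(g[, jk[1]], g[, jk[2]]))
  }, numeric(1))
  expect_gt(mean(adj), 2 * mean(far, na.rm = TRUE))
})

test_that("variance partition matches h2 on the liability scale", {
  # single environment so between-environment shifts do not dilute R^2
  cfg <- sim_config(n_individuals_per_env = c(A = 2000), n_markers = 400,
                    n_qtl_per_trait = 20, h2_per_trait = 0.5, seed = 3)
  pop <- simulate_population(cfg)
  lat <- simulate_phenotypes(pop, observation = "latent")
  d <- lat[lat$trait == "dormancy", ]
  tb <- pop$bv$dormancy[d$sample_id, "A"]
  r2 <- summary(lm(d$value ~ tb))$r.squared
  expect_gt(r2, 0.4)
  expect_lt(r2, 0.6)
  expect_lt(abs(var(tb) / var(d$value) - 0.5), 0.1)
})

test_that("phenotypes are bounded, skewed proportions with positive trait correlation", {
  cfg <- sim_config(n_individuals_per_env = c(A = 500, B = 500),
                    n_markers = 300, genetic_correlation_between_traits = 0.5,
                    seed = 21)
  pop <- simulate_population(cfg)
  ph <- simulate_phenotypes(pop)
  expect_true(all(ph$value >= 0 & ph$value <= 1))
  expect_identical(ph, simulate_phenotypes(pop))
  wide <- merge(ph[ph$trait == "dormancy", c("sample_id", "value")],
                ph[ph$trait == "dehiscence", c("sample_id", "value")],
                by = "sample_id")
  expect_gt(cor(wide$value.x, wide$value.y), 0.15)
})

test_that("full across-environment genetic correlation gives identical BVs", {
  cfg <- small_cfg(genetic_correlation_across_envs = 1)
  pop <- simulate_population(cfg)
  for (tr in names(pop$bv))
    expect_equal(pop$bv[[tr]][, 1], pop$bv[[tr]][, 2], tolerance = 1e-12)
})

test_that("truncation selection shifts QTL allele frequency favorably", {
  cfg <- sim_config(n_individuals_per_env = c(A = 400), n_markers = 200,
                    n_qtl_per_trait = 1, h2_per_trait = 0.8,
                    major_qtl_fraction = 0, n_generations = 1,
                    selection_fraction_pre_flowering = 0.1, seed = 31)
  moved <- vapply(1:10, function(s) {
    cfg$seed <- 30 + s
    pop <- simulate_population(cfg)
    qtl <- pop$effects$qtl_marker_indices$dormancy
    # sign of the (env A) effect: positive effect allele is unfavorable
    eff_sign <- sign(pop$effects$effects_by_env$A[1, "dormancy"])
    f0 <- mean(pop$geno[, qtl]) / 2
    pop2 <- pop
    for (g in 1:3) pop2 <- simulate_breeding_cycle(pop2, "dormancy",
                                                   seed = cfg$seed + g)
    f3 <- mean(pop2$geno[, qtl]) / 2
    (f3 - f0) * eff_sign
  }, numeric(1))
  # unfavorable allele frequency declines in the large majority of replicates
  expect_gte(sum(moved < 0), 8)
})

test_that("no selection leaves allele frequencies within sampling error", {
  cfg <- small_cfg(selection_fraction_pre_flowering = 1)
  pop <- simulate_population(cfg)
  pop2 <- simulate_breeding_cycle(pop, "dormancy", seed = 77)
  f0 <- colMeans(pop$geno) / 2
  f1 <- colMeans(pop2$geno) / 2
  se <- sqrt(pmax(f0 * (1 - f0), 1e-6) / (2 * nrow(pop2$geno)))
  expect_gt(mean(abs(f1 - f0) < 4 * se), 0.95)
  expect_identical(pop2$geno, simulate_breeding_cycle(pop, "dormancy", seed = 77)$geno)
})

test_that("pooled reads: boundaries, unbiasedness and missingness", {
  r <- simulate_pool_reads(rep(1, 500), depth_mean = 40,
                           noise_eq_depth = Inf, seed = 1)
  expect_true(all(r$alt_reads == r$depth))
  r0 <- simulate_pool_reads(rep(0, 500), depth_mean = 40,
                            noise_eq_depth = Inf, seed = 1)
  expect_true(all(r0$alt_reads == 0))

  r5 <- simulate_pool_reads(rep(0.5, 10000), depth_mean = 30,
                            noise_eq_depth = Inf, seed = 2)
  est <- estimate_pool_frequency(r5)
  fhat <- est$freq02 / 2
  m <- mean(fhat, na.rm = TRUE)
  se <- sd(fhat, na.rm = TRUE) / sqrt(sum(!is.na(fhat)))
  expect_lt(abs(m - 0.5), 3 * se)

  rm <- simulate_pool_reads(rep(0.5, 1e5), depth_mean = 50,
                            missing_rate = 0.148, seed = 3)
  expect_lt(abs(mean(rm$depth == 0) - 0.148), 0.01)

  expect_error(simulate_pool_reads(0.5, depth_mean = -1), "nonnegative")
  expect_error(simulate_pool_reads(1.5, depth_mean = 10), "\\[0, 1\\]")
})
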