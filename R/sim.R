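#' Configuration for the breeding-population simulator
#'
#' Collects every knob of the synthetic breeding program in one validated
#' object. Defaults emulate a multi-environment outcrossing cover-crop
#' breeding program genotyped by pooled sequencing: four site-year
#' environments with cohort sizes 115/206/109/287, two correlated traits
#' (seed dormancy, pod dehiscence) observed as bounded proportions, mean
#' pooled read depth of 50x, and roughly 15% missing marker calls.
#'
#' @param n_founders number of founder individuals.
#' @param n_individuals_per_env named integer vector, cohort size per
#'   environment (names are environment labels, e.g. site-years).
#' @param n_markers number of biallelic SNP markers.
#' @param n_chromosomes number of chromosomes; marker positions are drawn
#'   uniformly along each chromosome and sorted.
#' @param chromosome_length_bp physical length of each chromosome.
#' @param n_ancestral size of the ancestral haplotype pool that founder
#'   haplotypes are mosaics of; smaller values give stronger linkage
#'   disequilibrium.
#' @param ancestral_switch_rate expected number of ancestral-mosaic switch
#'   points per founder haplotype per chromosome.
#' @param crossover_rate expected crossovers per chromosome per meiosis.
#' @param n_generations random-mating generations between the founders and
#'   the phenotyped cohorts.
#' @param n_per_generation size of intermediate random-mating generations.
#' @param n_qtl_per_trait number of causal loci per trait (shared between
#'   the two traits so their effects can be correlated).
#' @param h2_per_trait narrow-sense heritability of the latent liability,
#'   per trait, in `[0, 1]`.
#' @param genetic_correlation_between_traits correlation of the two traits'
#'   additive effects at the shared QTL, in `[-1, 1]`.
#' @param genetic_correlation_across_envs correlation of environment-specific
#'   additive effects, in `[0, 1]`; values below 1 create rank-change
#'   genotype-by-environment interaction.
#' @param residual_sd_per_env residual standard deviation of the liability,
#'   recycled over environments.
#' @param env_effect_sd standard deviation of the fixed environment shifts
#'   on the liability scale. The default 0.9, with unit residual SD and
#'   h2 = 0.5, puts roughly 28% of liability variance between environments.
#' @param dormancy_intercept,dehiscence_intercept logistic-link intercepts
#'   of the two observation models; negative values skew the observed
#'   proportions toward zero.
#' @param n_seeds_per_plant seeds scored per plant for the dormancy assay.
#' @param n_pods_per_plant pods scored per plant for dehiscence.
#' @param depth_mean expected pooled read depth per marker.
#' @param depth_dist `"poisson"` or `"nbinom"` read-depth distribution.
#' @param nb_size negative-binomial size (dispersion) when
#'   `depth_dist = "nbinom"`; smaller is more overdispersed.
#' @param missing_rate fraction of markers with no reads (depth 0) per pool.
#' @param noise_eq_depth pool-construction noise floor for sequencing
#'   libraries, expressed as an equivalent binomial depth: each library's
#'   realized allele frequency is jittered with variance
#'   `f(1-f)/noise_eq_depth`. `Inf` disables the floor (pure binomial
#'   sampling). The default 30 makes technical-replicate concordance
#'   plateau around 30 reads, the depth at which counting noise falls to
#'   the level of the construction noise.
#' @param major_qtl_fraction fraction of each trait's additive genetic
#'   variance carried by a single planted major QTL (0 = none, all QTL
#'   drawn exchangeable). The major locus gets the same effect in every
#'   environment; the remaining QTL are rescaled to carry the rest.
#' @param selection_fraction_pre_flowering fraction of each cohort kept by
#'   truncation selection in [simulate_breeding_cycle()], in `(0, 1]`.
#' @param seed integer seed; together with the configuration it fully
#'   determines every simulated object.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @seealso [simulate_population()], [simulate_phenotypes()],
#'   [simulate_pool_reads()]
#' @export
sim_config <- function(n_founders = 40,
                       n_individuals_per_env = c("20MD" = 115, "21WI" = 206,
                                                 "22MD" = 109, "22WI" = 287),
                       n_markers = 1000,
                       n_chromosomes = 7,
                       chromosome_length_bp = 1e8,
                       n_ancestral = 20,
                       ancestral_switch_rate = 2,
                       crossover_rate = 1,
                       n_generations = 2,
                       n_per_generation = 200,
                       n_qtl_per_trait = 20,
                       h2_per_trait = c(dormancy = 0.5, dehiscence = 0.5),
                       genetic_correlation_between_traits = 0.4,
                       genetic_correlation_across_envs = 0.9,
                       residual_sd_per_env = 1,
                       env_effect_sd = 0.9,
                       dormancy_intercept = -1,
                       dehiscence_intercept = -1,
                       n_seeds_per_plant = 25,
                       n_pods_per_plant = 50,
                       depth_mean = 50,
                       depth_dist = c("poisson", "nbinom"),
                       nb_size = 2,
                       missing_rate = 0.148,
                       noise_eq_depth = 30,
                       major_qtl_fraction = 0,
                       selection_fraction_pre_flowering = 0.25,
                       seed = 1L) {
  depth_dist <- match.arg(depth_dist)
  if (is.null(names(n_individuals_per_env)))
    names(n_individuals_per_env) <- paste0("env", seq_along(n_individuals_per_env))
  if (length(h2_per_trait) == 1)
    h2_per_trait <- c(dormancy = unname(h2_per_trait), dehiscence = unname(h2_per_trait))
  if (is.null(names(h2_per_trait))) names(h2_per_trait) <- c("dormancy", "dehiscence")
  check_prob(h2_per_trait, "h2_per_trait")
  check_prob(missing_rate, "missing_rate")
  if (major_qtl_fraction < 0 || major_qtl_fraction >= 1)
    stop_input("`major_qtl_fraction` must lie in [0, 1)")
  check_prob(genetic_correlation_across_envs, "genetic_correlation_across_envs")
  if (abs(genetic_correlation_between_traits) > 1)
    stop_input("`genetic_correlation_between_traits` must lie in [-1, 1]")
  if (n_qtl_per_trait > n_markers)
    stop_input("n_qtl_per_trait (%d) exceeds n_markers (%d)",
               n_qtl_per_trait, n_markers)
  if (selection_fraction_pre_flowering <= 0 || selection_fraction_pre_flowering > 1)
    stop_input("`selection_fraction_pre_flowering` must lie in (0, 1]")
  if (depth_mean < 0) stop_input("`depth_mean` must be nonnegative")
  if (any(residual_sd_per_env < 0)) stop_input("`residual_sd_per_env` must be nonnegative")
  residual_sd_per_env <- rep_len(residual_sd_per_env, length(n_individuals_per_env))
  names(residual_sd_per_env) <- names(n_individuals_per_env)

  structure(list(
    n_founders = as.integer(n_founders),
    n_individuals_per_env = n_individuals_per_env,
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = chromosome_length_bp,
    n_ancestral = as.integer(n_ancestral),
    ancestral_switch_rate = ancestral_switch_rate,
    crossover_rate = crossover_rate,
    n_generations = as.integer(n_generations),
    n_per_generation = as.integer(n_per_generation),
    n_qtl_per_trait = as.integer(n_qtl_per_trait),
    h2_per_trait = h2_per_trait,
    genetic_correlation_between_traits = genetic_correlation_between_traits,
    genetic_correlation_across_envs = genetic_correlation_across_envs,
    residual_sd_per_env = residual_sd_per_env,
    env_effect_sd = env_effect_sd,
    dormancy_intercept = dormancy_intercept,
    dehiscence_intercept = dehiscence_intercept,
    n_seeds_per_plant = as.integer(n_seeds_per_plant),
    n_pods_per_plant = as.integer(n_pods_per_plant),
    depth_mean = depth_mean,
    depth_dist = depth_dist,
    nb_size = nb_size,
    missing_rate = missing_rate,
    noise_eq_depth = noise_eq_depth,
    major_qtl_fraction = major_qtl_fraction,
    selection_fraction_pre_flowering = selection_fraction_pre_flowering,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Breeding-simulation configuration\n")
  cat(sprintf("  environments: %s\n",
              paste(sprintf("%s (n=%d)", names(x$n_individuals_per_env),
                            x$n_individuals_per_env), collapse = ", ")))
  cat(sprintf("  markers: %d on %d chromosomes; QTL per trait: %d\n",
              x$n_markers, x$n_chromosomes, x$n_qtl_per_trait))
  cat(sprintf("  h2: %s; rG(traits) = %.2f; rG(envs) = %.2f\n",
              paste(sprintf("%s %.2f", names(x$h2_per_trait), x$h2_per_trait),
                    collapse = ", "),
              x$genetic_correlation_between_traits,
              x$genetic_correlation_across_envs))
  cat(sprintf("  depth: %s mean %.0fx, missing %.1f%%, noise floor eq. depth %s\n",
              x$depth_dist, x$depth_mean, 100 * x$missing_rate,
              format(x$noise_eq_depth)))
  invisible(x)
}

# marker map: uniform positions per chromosome, sorted, 1-based
make_marker_map <- function(config) {
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), config$n_markers))
  pos <- integer(config$n_markers)
  for (c in seq_len(config$n_chromosomes)) {
    idx <- which(chrom == c)
    pos[idx] <- sort(sample.int(config$chromosome_length_bp, length(idx)))
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, config$n_markers, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  data.frame(marker_id = sprintf("S%d_%d", chrom, pos),
             chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}

# founder haplotypes as mosaics of an ancestral panel -> realistic LD decay
make_founder_haplotypes <- function(config, map) {
  m <- config$n_markers
  p_anc <- runif(m, 0.05, 0.95)
  anc <- matrix(rbinom(config$n_ancestral * m, 1, rep(p_anc, each = config$n_ancestral)),
                nrow = config$n_ancestral, ncol = m)
  n_hap <- 2L * config$n_founders
  hap <- matrix(0L, n_hap, m)
  for (c in unique(map$chrom)) {
    idx <- which(map$chrom == c)
    gap <- diff(map$pos[idx]) / config$chromosome_length_bp
    p_switch <- pmin(1, config$ancestral_switch_rate * gap)
    for (h in seq_len(n_hap)) {
      state <- integer(length(idx))
      state[1] <- sample.int(config$n_ancestral, 1)
      if (length(idx) > 1) {
        sw <- runif(length(gap)) < p_switch
        for (j in seq_along(gap)) {
          state[j + 1] <- if (sw[j]) sample.int(config$n_ancestral, 1) else state[j]
        }
      }
      hap[h, idx] <- anc[cbind(state, idx)]
    }
  }
  hap
}

# one gamete from a haplotype pair; crossovers Poisson per chromosome
make_gamete <- function(hapA, hapB, map, crossover_rate, chrom_idx) {
  out <- integer(length(hapA))
  for (ci in seq_along(chrom_idx)) {
    idx <- chrom_idx[[ci]]
    k <- rpois(1, crossover_rate)
    start <- sample(0:1, 1)
    if (k == 0) {
      out[idx] <- if (start == 0) hapA[idx] else hapB[idx]
    } else {
      xpos <- sort(runif(k, 0, max(map$pos[idx]) + 1))
      phase <- (start + findInterval(map$pos[idx], xpos)) %% 2
      out[idx] <- ifelse(phase == 0, hapA[idx], hapB[idx])
    }
  }
  out
}

# random-mating offspring haplotypes from a parental haplotype matrix
mate_generation <- function(par_hap, n_off, map, crossover_rate, chrom_idx) {
  n_par <- nrow(par_hap) / 2L
  off <- matrix(0L, 2L * n_off, ncol(par_hap))
  for (i in seq_len(n_off)) {
    pair <- sample.int(n_par, 2, replace = FALSE)
    off[2L * i - 1L, ] <- make_gamete(par_hap[2L * pair[1] - 1L, ],
                                      par_hap[2L * pair[1], ],
                                      map, crossover_rate, chrom_idx)
    off[2L * i, ] <- make_gamete(par_hap[2L * pair[2] - 1L, ],
                                 par_hap[2L * pair[2], ],
                                 map, crossover_rate, chrom_idx)
  }
  off
}

draw_trait_effects <- function(config, map) {
  traits <- names(config$h2_per_trait)
  m <- config$n_markers
  q <- config$n_qtl_per_trait
  envs <- names(config$n_individuals_per_env)
  qtl <- sort(sample.int(m, q))
  rho <- config$genetic_correlation_between_traits
  # correlated effect pair at each shared QTL
  draw_pair <- function() {
    z1 <- rnorm(q); z2 <- rnorm(q)
    out <- cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
    colnames(out) <- traits[1:2]
    out
  }
  b_common <- draw_pair()
  r_env <- config$genetic_correlation_across_envs
  beta <- lapply(envs, function(e) {
    b_env <- draw_pair()
    sqrt(r_env) * b_common + sqrt(1 - r_env) * b_env
  })
  names(beta) <- envs
  structure(list(
    qtl_marker_indices = setNames(rep(list(qtl), length(traits)), traits),
    effects_by_env = beta,   # list env -> q x 2 matrix (columns = traits)
    traits = traits,
    favorable_direction = setNames(rep(-1L, length(traits)), traits)
  ), class = "trait_effects")
}

#' Simulate a multi-environment breeding population
#'
#' Builds founder haplotypes as mosaics of a small ancestral panel (so that
#' linked markers are in linkage disequilibrium), random-mates them for
#' `n_generations`, and then draws one cohort per environment from the last
#' parental generation. Additive QTL effects for the two traits are drawn
#' correlated at a shared set of causal loci, with environment-specific
#' components controlling rank-change genotype-by-environment interaction,
#' and are scaled so that the latent-liability heritability matches
#' `h2_per_trait`.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `"sim_pop"`: a list with elements
#'   `geno` (individuals x markers dosage matrix, values 0/1/2),
#'   `map` (marker metadata: marker_id, chrom, pos, ref, alt),
#'   `env` (factor of environment per individual),
#'   `effects` (QTL indices and per-environment effect sizes),
#'   `bv` (list per trait of individuals x environments true-breeding-value
#'   matrices, centered), `env_effects` (fixed environment shifts, shared
#'   across traits), `haplotypes` (phased 0/1 matrix, two rows per
#'   individual) and `config`.
#' @examples
#' cfg <- sim_config(n_individuals_per_env = c(A = 60, B = 60),
#'                   n_markers = 200, seed = 42)
#' pop <- simulate_population(cfg)
#' dim(pop$geno)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- make_marker_map(config)
  chrom_idx <- split(seq_len(config$n_markers), map$chrom)

  hap <- make_founder_haplotypes(config, map)
  if (config$n_generations > 1) {
    for (g in seq_len(config$n_generations - 1L)) {
      hap <- mate_generation(hap, config$n_per_generation, map,
                             config$crossover_rate, chrom_idx)
    }
  }
  envs <- names(config$n_individuals_per_env)
  cohort_hap <- lapply(envs, function(e) {
    mate_generation(hap, config$n_individuals_per_env[[e]], map,
                    config$crossover_rate, chrom_idx)
  })
  hap_all <- do.call(rbind, cohort_hap)
  n <- nrow(hap_all) / 2L
  geno <- hap_all[seq(1, 2 * n, by = 2), , drop = FALSE] +
    hap_all[seq(2, 2 * n, by = 2), , drop = FALSE]
  env <- factor(rep(envs, times = config$n_individuals_per_env), levels = envs)
  ids <- sprintf("ind_%s_%03d", as.character(env),
                 unlist(lapply(config$n_individuals_per_env, seq_len)))
  rownames(geno) <- ids
  colnames(geno) <- map$marker_id

  effects <- draw_trait_effects(config, map)
  effects <- scale_effects(effects, geno, config)
  bv <- breeding_values(geno, effects)
  env_effects <- setNames(rnorm(length(envs), 0, config$env_effect_sd), envs)

  structure(list(geno = geno, map = map, env = env, effects = effects,
                 bv = bv, env_effects = env_effects, haplotypes = hap_all,
                 config = config),
            class = "sim_pop")
}

# scale QTL effects so var(BV)/ (var(BV)+mean resid var) = h2 per trait,
# averaging realized BV variance over environments; optionally concentrate
# major_qtl_fraction of the genetic variance in one locus
scale_effects <- function(effects, geno, config) {
  mean_res_var <- mean(config$residual_sd_per_env^2)
  frac <- config$major_qtl_fraction %||% 0
  for (t in seq_along(effects$traits)) {
    trait <- effects$traits[t]
    h2 <- config$h2_per_trait[[trait]]
    qtl <- effects$qtl_marker_indices[[trait]]
    W <- geno[, qtl, drop = FALSE]
    target <- if (h2 >= 1) Inf else h2 / (1 - h2) * mean_res_var
    if (h2 == 0) {
      for (e in names(effects$effects_by_env))
        effects$effects_by_env[[e]][, t] <- 0
      next
    }
    if (frac > 0 && length(qtl) > 1) {
      # major locus: the QTL segregating closest to 0.5 (maximal power)
      p_qtl <- colMeans(W) / 2
      j <- which.min(abs(p_qtl - 0.5))
      vj <- var(W[, j])
      a <- sqrt(frac * target / vj)
      v_rest <- mean(vapply(effects$effects_by_env, function(b) {
        b2 <- b[, t]; b2[j] <- 0
        var(drop(W %*% b2))
      }, numeric(1)))
      fac <- if (v_rest == 0) 0 else sqrt((1 - frac) * target / v_rest)
      for (e in names(effects$effects_by_env)) {
        effects$effects_by_env[[e]][, t] <- effects$effects_by_env[[e]][, t] * fac
        effects$effects_by_env[[e]][j, t] <- a
      }
      effects$major_qtl <- c(effects$major_qtl,
                             setNames(qtl[j], trait))
    } else {
      v <- mean(vapply(effects$effects_by_env,
                       function(b) var(drop(W %*% b[, t])), numeric(1)))
      fac <- if (v == 0) 0 else sqrt(target / v)
      for (e in names(effects$effects_by_env))
        effects$effects_by_env[[e]][, t] <- effects$effects_by_env[[e]][, t] * fac
    }
  }
  effects
}

# centered true breeding values: list per trait of n x n_env matrices
breeding_values <- function(geno, effects) {
  out <- list()
  for (t in seq_along(effects$traits)) {
    trait <- effects$traits[t]
    qtl <- effects$qtl_marker_indices[[trait]]
    W <- geno[, qtl, drop = FALSE]
    bv <- vapply(effects$effects_by_env, function(b) drop(W %*% b[, t]),
                 numeric(nrow(geno)))
    bv <- sweep(bv, 2, colMeans(bv))
    rownames(bv) <- rownames(geno)
    out[[trait]] <- bv
  }
  out
}

#' @export
print.sim_pop <- function(x, ...) {
  cat(sprintf("Simulated breeding population: %d individuals, %d markers, %d environments\n",
              nrow(x$geno), ncol(x$geno), nlevels(x$env)))
  print(table(x$env))
  invisible(x)
}

#' Simulate phenotypes for a breeding population
#'
#' Generates long-format phenotype records for the two traits. Each
#' individual's latent liability is its environment-specific true breeding
#' value plus the fixed environment shift plus Gaussian residual noise.
#' Under the default `observation = "binomial"` the liability is passed
#' through a logistic link and observed as bounded, skewed proportions:
#' seed dormancy as the dormant fraction of `n_seeds_per_plant` seeds
#' (binomially sampled), pod dehiscence as the mean of `n_pods_per_plant`
#' Bernoulli pod scores. `observation = "latent"` returns the Gaussian
#' liability itself — the scale on which heritability is defined in the
#' generator.
#'
#' @param pop a [simulate_population()] result.
#' @param observation `"binomial"` (bounded proportions) or `"latent"`
#'   (Gaussian liability).
#' @param seed seed for the residual and observation noise; defaults to
#'   `config$seed + 1` so it is decoupled from the genotype draw.
#' @return A data.frame with columns `sample_id`, `environment`, `trait`,
#'   `value` (class `"phenotype_table"`).
#' @export
simulate_phenotypes <- function(pop, observation = c("binomial", "latent"),
                                seed = pop$config$seed + 1L) {
  stopifnot(inherits(pop, "sim_pop"))
  observation <- match.arg(observation)
  config <- pop$config
  set.seed(seed)
  envs <- levels(pop$env)
  recs <- list()
  for (trait in config_traits(config)) {
    lia <- numeric(nrow(pop$geno))
    for (e in envs) {
      sel <- pop$env == e
      lia[sel] <- pop$bv[[trait]][sel, e] + pop$env_effects[[e]] +
        rnorm(sum(sel), 0, config$residual_sd_per_env[[e]])
    }
    if (observation == "latent") {
      value <- lia
    } else if (trait == "dormancy") {
      p <- plogis(config$dormancy_intercept + lia)
      value <- rbinom(length(lia), config$n_seeds_per_plant, p) /
        config$n_seeds_per_plant
    } else {
      p <- plogis(config$dehiscence_intercept + lia)
      value <- rbinom(length(lia), config$n_pods_per_plant, p) /
        config$n_pods_per_plant
    }
    recs[[trait]] <- data.frame(sample_id = rownames(pop$geno),
                                environment = as.character(pop$env),
                                trait = trait, value = value,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

config_traits <- function(config) names(config$h2_per_trait)

#' Advance a population by one cycle of truncation selection
#'
#' Applies phenotypic truncation selection on one trait (keeping the
#' favorable — low — fraction `selection_fraction_pre_flowering`), then
#' random-mates the survivors to produce a cohort of the same size and
#' environment layout. Selection acts on a noisy phenotype (liability with
#' residual noise), so the response follows the breeders' equation rather
#' than perfect truncation on true breeding value. The unfavorable-allele
#' frequency at the selected trait's QTL declines in expectation.
#'
#' @param pop a `"sim_pop"` object.
#' @param trait trait selected on (default first configured trait).
#' @param seed seed for selection noise and matings.
#' @return A new `"sim_pop"` with offspring genotypes (same map, effects,
#'   environment shifts and configuration).
#' @export
simulate_breeding_cycle <- function(pop, trait = config_traits(pop$config)[1],
                                    seed = pop$config$seed + 101L) {
  stopifnot(inherits(pop, "sim_pop"))
  config <- pop$config
  frac <- config$selection_fraction_pre_flowering
  if (frac <= 0) stop_input("selection fraction must be positive")
  set.seed(seed)
  chrom_idx <- split(seq_len(config$n_markers), pop$map$chrom)

  envs <- levels(pop$env)
  keep <- logical(nrow(pop$geno))
  for (e in envs) {
    sel <- which(pop$env == e)
    lia <- pop$bv[[trait]][sel, e] +
      rnorm(length(sel), 0, config$residual_sd_per_env[[e]])
    n_keep <- max(2L, round_half_up(frac * length(sel)))
    # favorable direction is low trait value
    keep[sel[order(lia)[seq_len(n_keep)]]] <- TRUE
  }
  par_idx <- which(keep)
  par_rows <- as.vector(rbind(2L * par_idx - 1L, 2L * par_idx))
  par_hap <- pop$haplotypes[par_rows, , drop = FALSE]

  off_hap <- lapply(envs, function(e) {
    mate_generation(par_hap, config$n_individuals_per_env[[e]], pop$map,
                    config$crossover_rate, chrom_idx)
  })
  hap_all <- do.call(rbind, off_hap)
  n <- nrow(hap_all) / 2L
  geno <- hap_all[seq(1, 2 * n, by = 2), , drop = FALSE] +
    hap_all[seq(2, 2 * n, by = 2), , drop = FALSE]
  env <- factor(rep(envs, times = config$n_individuals_per_env), levels = envs)
  rownames(geno) <- sprintf("ind_%s_%03d", as.character(env),
                            unlist(lapply(config$n_individuals_per_env, seq_len)))
  colnames(geno) <- pop$map$marker_id

  out <- pop
  out$geno <- geno
  out$env <- env
  out$haplotypes <- hap_all
  out$bv <- breeding_values(geno, pop$effects)
  out
}

#' Simulate pooled sequencing read counts
#'
#' Draws per-marker read depth and alternate-allele read counts for one
#' sequencing library of a DNA pool. Depth is Poisson (or negative
#' binomial) with mean `depth_mean`; a fraction `missing_rate` of markers
#' receives no reads; the alternate read count is binomial in the library's
#' realized allele frequency. Libraries (including technical replicates of
#' the same pool) can carry a small pool-construction/library noise floor:
#' the realized frequency is the true pool frequency jittered with variance
#' `f(1-f)/noise_eq_depth`. With `noise_eq_depth = Inf` the counts are pure
#' binomial draws from the true frequency.
#'
#' @param true_freqs numeric vector of true pool allele frequencies in
#'   `[0, 1]`; names (marker ids) are carried through.
#' @param depth_mean expected depth per marker.
#' @param depth_dist `"poisson"` or `"nbinom"`.
#' @param nb_size negative-binomial size when `depth_dist = "nbinom"`.
#' @param missing_rate fraction of markers set to depth 0.
#' @param noise_eq_depth library noise floor as an equivalent depth
#'   (`Inf` = none).
#' @param seed integer seed.
#' @return data.frame with columns `marker_id`, `alt_reads`, `depth`
#'   (class `"pool_reads"`).
#' @export
simulate_pool_reads <- function(true_freqs, depth_mean = 50,
                                depth_dist = c("poisson", "nbinom"),
                                nb_size = 2, missing_rate = 0,
                                noise_eq_depth = 30, seed = 1L) {
  depth_dist <- match.arg(depth_dist)
  if (depth_mean < 0) stop_input("`depth_mean` must be nonnegative")
  check_prob(true_freqs, "true_freqs")
  check_prob(missing_rate, "missing_rate")
  set.seed(seed)
  m <- length(true_freqs)
  depth <- switch(depth_dist,
                  poisson = rpois(m, depth_mean),
                  nbinom = rnbinom(m, size = nb_size, mu = depth_mean))
  if (missing_rate > 0)
    depth[runif(m) < missing_rate] <- 0L
  f <- true_freqs
  if (is.finite(noise_eq_depth)) {
    f <- f + rnorm(m, 0, sqrt(f * (1 - f) / noise_eq_depth))
    f <- pmin(1, pmax(0, f))
  }
  alt <- rbinom(m, depth, f)
  ids <- names(true_freqs) %||% sprintf("m%d", seq_len(m))
  structure(data.frame(marker_id = ids, alt_reads = alt, depth = depth,
                       stringsAsFactors = FALSE),
            class = c("pool_reads", "data.frame"))
}
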