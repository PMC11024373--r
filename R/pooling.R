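#' Rescale pod-dehiscence scores to the unit interval
#'
#' Pod dehiscence is scored visually per pod, either on a 0-3 suture-opening
#' scale or as a binary 0/1 (seed can / cannot fall out). To place both on
#' a common `[0, 1]` scale, 0-3 scores are divided by three; 0/1 scores are
#' left unchanged. The plant value is the mean over its scored pods.
#'
#' @param scores numeric vector of per-pod scores for one plant.
#' @param scale `"zero_one"` or `"zero_to_three"`.
#' @return The plant mean on the `[0, 1]` scale.
#' @examples
#' rescale_dehiscence(c(3, 3, 3), "zero_to_three")  # 1
#' rescale_dehiscence(c(0, 1, 1, 0), "zero_one")    # 0.5
#' @export
rescale_dehiscence <- function(scores, scale = c("zero_one", "zero_to_three")) {
  scale <- match.arg(scale)
  if (length(scores) == 0) stop_input("no scores supplied")
  rng <- if (scale == "zero_one") c(0, 1) else c(0, 3)
  if (any(!is.finite(scores)) || any(scores < rng[1]) || any(scores > rng[2]))
    stop_input("scores outside the declared %s range [%g, %g]",
               scale, rng[1], rng[2])
  if (scale == "zero_to_three") scores <- scores / 3
  mean(scores)
}

#' Dormant-seed proportion with dead-seed exclusion
#'
#' Seed dormancy is the proportion of viable seeds that stay hard (fail to
#' imbibe water) after 7 days. Dead seeds are excluded from both numerator
#' and denominator.
#'
#' @param n_imbibed seeds that imbibed water (germinable).
#' @param n_hard_viable hard seeds confirmed viable (dormant).
#' @param n_dead dead seeds (excluded).
#' @return `n_hard_viable / (n_imbibed + n_hard_viable)`; `NA` when no
#'   viable seeds were observed. Vectorized.
#' @examples
#' dormancy_proportion(20, 5, 0)   # 0.20
#' dormancy_proportion(20, 3, 2)   # 3/23
#' @export
dormancy_proportion <- function(n_imbibed, n_hard_viable, n_dead = 0) {
  if (any(n_imbibed < 0) || any(n_hard_viable < 0) || any(n_dead < 0))
    stop_input("seed counts must be nonnegative")
  denom <- n_imbibed + n_hard_viable
  out <- ifelse(denom == 0, NA_real_, n_hard_viable / denom)
  out
}

#' Construct trait-tail and interquartile DNA pools for one environment
#'
#' For each trait, the best (low) and worst (high) `tail_fraction` of the
#' phenotyped individuals form one pool each; ties at the quantile boundary
#' are broken deterministically by ascending sample id. One additional
#' interquartile pool of the same nominal size is drawn uniformly at random
#' (seeded) from individuals that fall in no tail pool of either trait —
#' it estimates the environment's mean allele frequency. Tail pool size is
#' `round(tail_fraction * N)` (half away from zero), where `N` counts the
#' individuals with a non-missing phenotype for that trait.
#'
#' @param phenotypes a long phenotype table (`sample_id`, `environment`,
#'   `trait`, `value`).
#' @param environment environment label to pool within.
#' @param traits traits to build tail pools for (default: all traits
#'   present in the environment).
#' @param tail_fraction fraction in each tail (default 0.25).
#' @param seed seed for the interquartile draw.
#' @return list of pool specifications (class `"pool_spec"` each): fields
#'   `pool_id`, `environment`, `target_trait` (`NA` for the interquartile
#'   pool), `category` (`high_tail`, `low_tail`, `interquartile_random`),
#'   `members`, and `mean_phenotype` (named per trait, mean over members
#'   with non-missing values).
#' @export
build_pools <- function(phenotypes, environment, traits = NULL,
                        tail_fraction = 0.25, seed = 1L) {
  ph <- phenotypes[phenotypes$environment == environment &
                     !is.na(phenotypes$value), , drop = FALSE]
  if (nrow(ph) == 0) stop_input("no phenotypes for environment '%s'", environment)
  traits <- traits %||% sort(unique(ph$trait))
  if (length(unique(ph$sample_id)) < 8)
    stop_input("need at least 8 phenotyped individuals in '%s'", environment)

  specs <- list()
  tail_members <- character(0)
  for (trait in traits) {
    pht <- ph[ph$trait == trait, , drop = FALSE]
    pht <- pht[order(pht$value, pht$sample_id), , drop = FALSE]
    n <- nrow(pht)
    n_tail <- round_half_up(tail_fraction * n)
    if (2 * n_tail > n)
      stop_input("tail pools would overlap for trait '%s' (N = %d)", trait, n)
    low_ids <- pht$sample_id[seq_len(n_tail)]
    # high tail: largest values, ties broken by ascending id
    phd <- pht[order(-pht$value, pht$sample_id), , drop = FALSE]
    high_ids <- phd$sample_id[seq_len(n_tail)]
    tail_members <- union(tail_members, c(low_ids, high_ids))
    specs[[paste0(environment, "_", trait, "_low")]] <-
      pool_spec(paste0(environment, "_", trait, "_low"), environment, trait,
                "low_tail", low_ids, ph)
    specs[[paste0(environment, "_", trait, "_high")]] <-
      pool_spec(paste0(environment, "_", trait, "_high"), environment, trait,
                "high_tail", high_ids, ph)
  }
  all_ids <- sort(unique(ph$sample_id))
  remaining <- setdiff(all_ids, tail_members)
  n_iq <- min(length(remaining),
              round_half_up(tail_fraction * length(all_ids)))
  set.seed(seed)
  iq_ids <- sort(sample(remaining, n_iq))
  specs[[paste0(environment, "_interquartile")]] <-
    pool_spec(paste0(environment, "_interquartile"), environment, NA_character_,
              "interquartile_random", iq_ids, ph)
  specs
}

pool_spec <- function(pool_id, environment, target_trait, category, members, ph) {
  if (anyDuplicated(members)) stop_input("duplicate pool members")
  means <- vapply(sort(unique(ph$trait)), function(tr) {
    v <- ph$value[ph$trait == tr & ph$sample_id %in% members]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  structure(list(pool_id = pool_id, environment = environment,
                 target_trait = target_trait, category = category,
                 members = members, mean_phenotype = means),
            class = "pool_spec")
}

#' @export
print.pool_spec <- function(x, ...) {
  cat(sprintf("Pool %s [%s, %s]: %d members; mean phenotype: %s\n",
              x$pool_id, x$environment, x$category, length(x$members),
              paste(sprintf("%s = %.3f", names(x$mean_phenotype),
                            x$mean_phenotype), collapse = ", ")))
  invisible(x)
}

#' True allele frequency of an equal-tissue DNA pool
#'
#' Under equal tissue contribution from every member, the pool's allele
#' frequency at each marker is the mean of the members' allele frequencies,
#' i.e. mean(dosage)/2. Members missing a marker call are ignored at that
#' marker.
#'
#' @param genotypes individuals x markers dosage matrix (0/1/2, `NA`
#'   allowed) with sample ids as row names.
#' @param member_ids pool member sample ids.
#' @return named vector of frequencies in `[0, 1]`, one per marker.
#' @export
pool_true_frequency <- function(genotypes, member_ids) {
  if (length(member_ids) == 0) stop_input("empty pool member set")
  missing <- setdiff(member_ids, rownames(genotypes))
  if (length(missing))
    stop_input("members not in genotype matrix: %s",
               paste(head(missing, 5), collapse = ", "))
  colMeans(genotypes[member_ids, , drop = FALSE], na.rm = TRUE) / 2
}

#' Estimate pool allele frequencies from read counts
#'
#' Converts pooled read counts to the 0-2 scale used jointly with
#' individual dosages: twice the alternate-allele read fraction. Markers
#' with zero depth are missing.
#'
#' @param reads a `pool_reads` data.frame (`marker_id`, `alt_reads`,
#'   `depth`).
#' @return list with `freq02` (named numeric, `NA` where depth 0) and
#'   `depth` (named integer).
#' @examples
#' r <- data.frame(marker_id = c("a", "b"), alt_reads = c(15, 0),
#'                 depth = c(30, 40))
#' estimate_pool_frequency(r)$freq02  # 1, 0
#' @export
estimate_pool_frequency <- function(reads) {
  if (any(reads$alt_reads > reads$depth))
    stop_input("alt_reads exceeds depth at %d marker(s)",
               sum(reads$alt_reads > reads$depth))
  if (any(reads$alt_reads < 0) || any(reads$depth < 0))
    stop_input("negative read counts")
  f <- ifelse(reads$depth > 0, 2 * reads$alt_reads / reads$depth, NA_real_)
  list(freq02 = setNames(f, reads$marker_id),
       depth = setNames(reads$depth, reads$marker_id))
}
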