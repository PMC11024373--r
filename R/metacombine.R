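#' Direction-aware Fisher combination of two association tests
#'
#' Merges per-marker p-values from two studies (e.g. a pooled-DNA scan and
#' an individual-genotype scan) with Fisher's combined probability test,
#' after a direction mask: when the two effect estimates disagree in sign,
#' the p-value of the study whose effect points in the unfavorable
#' direction (away from `favorable_sign`) is set to 1, so only
#' direction-consistent evidence accumulates. The statistic is
#' \eqn{\chi^2 = -2(\ln p_1' + \ln p_2')} on `2k = 4` degrees of freedom.
#'
#' @param p1,p2 p-values from study 1 and 2, in `(0, 1]` (`NA` allowed;
#'   propagated). Zeros are clamped to the smallest positive double with a
#'   warning.
#' @param sign1,sign2 effect signs (`+1`/`-1`) on a shared allele coding.
#' @param favorable_sign the sign that improves the trait (`-1` for traits
#'   where lower is better).
#' @return data.frame of class `"combined_result"`: `p1`, `sign1`, `p2`,
#'   `sign2`, `masked_study` (`"none"`, `"study1"`, `"study2"`), `chi2`,
#'   `df`, `p_combined`, `q_combined`.
#' @examples
#' fisher_combine(0.05, 0.05, -1, -1, favorable_sign = -1)
#' fisher_combine(0.01, 0.02, -1, +1, favorable_sign = -1)  # study 2 masked
#' @export
fisher_combine <- function(p1, p2, sign1, sign2, favorable_sign = -1) {
  stopifnot(favorable_sign %in% c(-1, 1))
  k <- max(length(p1), length(p2))
  p1 <- rep_len(as.numeric(p1), k); p2 <- rep_len(as.numeric(p2), k)
  sign1 <- rep_len(sign1, k); sign2 <- rep_len(sign2, k)
  if (any(!sign1[!is.na(sign1)] %in% c(-1, 1)) ||
      any(!sign2[!is.na(sign2)] %in% c(-1, 1)))
    stop_input("effect signs must be -1 or +1")
  for (nm in c("p1", "p2")) {
    p <- get(nm)
    if (any(p == 0, na.rm = TRUE)) {
      warning(sprintf("%s contains zeros; clamped to smallest positive double", nm))
      p[!is.na(p) & p == 0] <- .Machine$double.xmin
      assign(nm, p)
    }
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop_input("p-values must lie in (0, 1]")
  }
  discord <- !is.na(sign1) & !is.na(sign2) & sign1 != sign2
  masked <- rep("none", k)
  masked[discord & sign1 != favorable_sign] <- "study1"
  masked[discord & sign2 != favorable_sign] <- "study2"
  p1m <- ifelse(masked == "study1", 1, p1)
  p2m <- ifelse(masked == "study2", 1, p2)
  chi2 <- -2 * (log(p1m) + log(p2m))
  p_comb <- pchisq(chi2, df = 4, lower.tail = FALSE)
  out <- data.frame(p1 = p1, sign1 = sign1, p2 = p2, sign2 = sign2,
                    masked_study = masked, chi2 = chi2, df = 4,
                    p_combined = p_comb,
                    q_combined = bh_qvalues(p_comb),
                    stringsAsFactors = FALSE)
  class(out) <- c("combined_result", "data.frame")
  out
}

#' Combine two GWAS scans over their shared markers
#'
#' Matches markers between two [gwas_scan()] results — on
#' chromosome/position/alleles when metadata is available, otherwise on
#' marker id — harmonizes allele coding (a ref/alt swap between panels
#' flips the second study's effect sign), applies [fisher_combine()] over
#' the intersection, and reports markers present in only one study
#' separately (they are not combined).
#'
#' @param res1,res2 `gwas_result` data.frames.
#' @param favorable_sign per-trait favorable effect sign (`-1` = lower
#'   trait values are better).
#' @param map1,map2 optional marker metadata with `marker_id`, `chrom`,
#'   `pos`, `ref`, `alt` for positional matching and allele harmonization.
#' @return list of class `"combined_scans"`: `combined` (a
#'   `combined_result` with `marker_id`), `study1_only`, `study2_only`
#'   (marker ids), `n_allele_mismatch`.
#' @export
combine_scans <- function(res1, res2, favorable_sign = -1,
                          map1 = NULL, map2 = NULL) {
  key <- function(res, map) {
    if (!is.null(map)) {
      i <- match(res$marker_id, map$marker_id)
      paste(map$chrom[i], map$pos[i], sep = ":")
    } else if (all(c("chrom", "pos") %in% names(res))) {
      paste(res$chrom, res$pos, sep = ":")
    } else res$marker_id
  }
  k1 <- key(res1, map1); k2 <- key(res2, map2)
  shared <- intersect(k1, k2)
  i1 <- match(shared, k1); i2 <- match(shared, k2)

  flip <- rep(FALSE, length(shared))
  n_mismatch <- 0L
  if (!is.null(map1) && !is.null(map2)) {
    a1 <- map1[match(res1$marker_id[i1], map1$marker_id), c("ref", "alt")]
    a2 <- map2[match(res2$marker_id[i2], map2$marker_id), c("ref", "alt")]
    same <- a1$ref == a2$ref & a1$alt == a2$alt
    flip <- a1$ref == a2$alt & a1$alt == a2$ref
    bad <- !(same | flip)
    n_mismatch <- sum(bad)
    if (n_mismatch) {
      warning(sprintf("%d marker(s) excluded: allele mismatch at the same position",
                      n_mismatch))
      i1 <- i1[!bad]; i2 <- i2[!bad]; flip <- flip[!bad]; shared <- shared[!bad]
    }
  }
  if (length(shared)) {
    s1 <- sign(res1$effect[i1])
    s2 <- sign(res2$effect[i2]) * ifelse(flip, -1, 1)
    s1[!is.na(s1) & s1 == 0] <- NA   # zero effect: no direction, no masking
    s2[!is.na(s2) & s2 == 0] <- NA
    comb <- fisher_combine(res1$p_value[i1], res2$p_value[i2], s1, s2,
                           favorable_sign = favorable_sign)
    comb <- cbind(marker_id = res1$marker_id[i1], comb)
    class(comb) <- c("combined_result", "data.frame")
  } else {
    comb <- NULL
  }
  structure(list(combined = comb,
                 study1_only = res1$marker_id[!(k1 %in% shared)],
                 study2_only = res2$marker_id[!(k2 %in% shared)],
                 n_allele_mismatch = n_mismatch),
            class = "combined_scans")
}

#' @export
print.combined_scans <- function(x, ...) {
  n <- if (is.null(x$combined)) 0L else nrow(x$combined)
  cat(sprintf("Combined association scans: %d shared markers (%d study-1 only, %d study-2 only, %d allele mismatches)\n",
              n, length(x$study1_only), length(x$study2_only),
              x$n_allele_mismatch))
  if (n) {
    nsig <- sum(x$combined$q_combined < 0.01, na.rm = TRUE)
    cat(sprintf("  markers at q < 0.01: %d; masked for direction: %d\n",
                nsig, sum(x$combined$masked_study != "none")))
  }
  invisible(x)
}
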