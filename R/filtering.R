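#' Technical-replicate concordance as a function of read depth
#'
#' Bins markers by the smaller of the two replicate depths and computes the
#' mean absolute difference between the two replicates' allele-frequency
#' estimates per bin. The resulting curve is how a depth threshold is
#' calibrated: frequency estimates get steadily more accurate with depth
#' until library/pool-construction noise dominates and the curve plateaus.
#'
#' @param rep_pairs list of replicate pairs; each pair is a list/length-2
#'   list of `pool_reads` data.frames sharing marker ids.
#' @param bin_edges increasing numeric vector of depth bin edges; bin j is
#'   `[edge_j, edge_{j+1})`.
#' @return Object of class `"concordance_curve"`: data.frame with
#'   `bin_lower`, `bin_upper`, `mean_abs_diff`, `n_markers`.
#' @seealso [select_depth_threshold()]
#' @export
depth_concordance_curve <- function(rep_pairs, bin_edges = seq(0, 100, by = 5)) {
  if (length(bin_edges) < 2 || is.unsorted(bin_edges, strictly = TRUE))
    stop_input("`bin_edges` must be strictly increasing with >= 2 values")
  nb <- length(bin_edges) - 1L
  sum_diff <- numeric(nb)
  n_mark <- integer(nb)
  any_shared <- FALSE
  for (pair in rep_pairs) {
    r1 <- pair[[1]]; r2 <- pair[[2]]
    common <- intersect(r1$marker_id, r2$marker_id)
    if (length(common) == 0) next
    any_shared <- TRUE
    i1 <- match(common, r1$marker_id)
    i2 <- match(common, r2$marker_id)
    d1 <- r1$depth[i1]; d2 <- r2$depth[i2]
    ok <- d1 > 0 & d2 > 0
    if (!any(ok)) next
    f1 <- r1$alt_reads[i1][ok] / d1[ok]
    f2 <- r2$alt_reads[i2][ok] / d2[ok]
    dmin <- pmin(d1[ok], d2[ok])
    bin <- findInterval(dmin, bin_edges, rightmost.closed = FALSE)
    keep <- bin >= 1 & bin <= nb
    ad <- abs(f1 - f2)[keep]
    bin <- bin[keep]
    sum_diff <- sum_diff + as.numeric(tapply(ad, factor(bin, levels = seq_len(nb)),
                                             sum, default = 0))
    n_mark <- n_mark + as.integer(tabulate(bin, nbins = nb))
  }
  if (!any_shared) stop_input("replicate pairs share no markers")
  structure(data.frame(bin_lower = bin_edges[-length(bin_edges)],
                       bin_upper = bin_edges[-1],
                       mean_abs_diff = ifelse(n_mark > 0, sum_diff / n_mark, NA_real_),
                       n_markers = n_mark),
            class = c("concordance_curve", "data.frame"))
}

#' Select a read-depth threshold from a concordance curve
#'
#' Detects the plateau of the replicate-concordance curve: scanning bins in
#' depth order, the threshold is the lower edge of the first bin whose
#' relative improvement over the previous bin drops below
#' `rel_improvement_tol`. A zero or negative improvement means the plateau
#' already includes the previous bin, whose lower edge is returned instead.
#' A strictly increasing curve yields the last bin's lower edge with a
#' warning. Bins holding fewer than `min_markers` markers are ignored.
#'
#' @param curve a [depth_concordance_curve()] result.
#' @param rel_improvement_tol plateau tolerance on the relative per-bin
#'   decrease (default 0.05 = 5% improvement).
#' @param min_markers minimum markers per bin for the bin to count.
#' @return the selected depth threshold (a bin lower edge).
#' @export
select_depth_threshold <- function(curve, rel_improvement_tol = 0.05,
                                   min_markers = 30) {
  cv <- curve[!is.na(curve$mean_abs_diff) & curve$n_markers >= min_markers, ,
              drop = FALSE]
  if (nrow(cv) < 3) stop_input("need at least 3 populated depth bins")
  c_val <- cv$mean_abs_diff
  r <- 1 - c_val[-1] / c_val[-length(c_val)]   # relative decrease at bin j (j >= 2)
  if (all(r < 0)) {
    warning("concordance curve is increasing; returning the deepest bin edge")
    return(cv$bin_lower[nrow(cv)])
  }
  j <- which(r < rel_improvement_tol)[1] + 1L   # index into cv rows
  if (is.na(j)) return(cv$bin_lower[nrow(cv)])
  if (r[j - 1L] <= 0) cv$bin_lower[j - 1L] else cv$bin_lower[j]
}

#' Apply the SNP quality-filter pipeline
#'
#' Reproduces the pooled-sequencing marker pipeline in fixed order:
#' (1) optionally keep only markers on a chromosome whitelist;
#' (2) keep markers whose pooled read depth is strictly greater than
#' `min_depth` (by default in every pooled sample);
#' (3) impute remaining missing calls to the marker mean;
#' (4) drop markers with folded minor allele frequency below `maf_min`,
#' computed from the imputed matrix on the 0-2 scale.
#'
#' @param matrix samples x markers matrix on the 0-2 scale (pools and/or
#'   individuals), `NA` for missing.
#' @param depths pooled read depths: either a pools x markers matrix or a
#'   single per-marker vector, aligned to `matrix` columns.
#' @param min_depth depth threshold; markers need depth strictly greater.
#' @param maf_min minor-allele-frequency threshold; markers strictly below
#'   are removed.
#' @param depth_rule `"min"` (default, strictest: minimum over pooled
#'   samples) or `"mean"` across pooled samples.
#' @param map optional marker metadata (needs `marker_id`, `chrom`) for the
#'   chromosome filter.
#' @param chromosomes optional whitelist of chromosome labels.
#' @return list with `matrix` (filtered, imputed), `depths` (the per-marker
#'   depth statistic for the retained markers) and `report`, a
#'   `"filter_report"` carrying marker counts at every stage
#'   (`input`, `on_chromosomes`, `depth_pass`, `post_imputation`,
#'   `maf_pass`), the missing-call fraction before and after the depth
#'   filter, and the thresholds used.
#' @export
apply_filters <- function(matrix, depths, min_depth = 30, maf_min = 0.025,
                          depth_rule = c("min", "mean"),
                          map = NULL, chromosomes = NULL) {
  depth_rule <- match.arg(depth_rule)
  m0 <- ncol(matrix)
  counts <- c(input = m0)

  if (!is.null(chromosomes)) {
    if (is.null(map)) stop_input("chromosome filter requires `map`")
    keep_ids <- map$marker_id[map$chrom %in% chromosomes]
    sel <- colnames(matrix) %in% keep_ids
    matrix <- matrix[, sel, drop = FALSE]
    depths <- subset_depths(depths, sel)
  }
  counts["on_chromosomes"] <- ncol(matrix)
  if (ncol(matrix) == 0) stop_input("all markers removed at the chromosome filter")

  miss_pre <- mean(is.na(matrix))
  dstat <- if (is.matrix(depths)) {
    if (depth_rule == "min") apply(depths, 2, min) else colMeans(depths)
  } else as.numeric(depths)
  if (length(dstat) != ncol(matrix))
    stop_input("depths not aligned to matrix markers (%d vs %d)",
               length(dstat), ncol(matrix))
  sel <- dstat > min_depth
  matrix <- matrix[, sel, drop = FALSE]
  dstat <- dstat[sel]
  counts["depth_pass"] <- ncol(matrix)
  if (ncol(matrix) == 0) stop_input("all markers removed at the depth filter")
  miss_post <- mean(is.na(matrix))

  # mean imputation preserves each marker's observed mean exactly
  cm <- colMeans(matrix, na.rm = TRUE)
  na_idx <- which(is.na(matrix), arr.ind = TRUE)
  if (nrow(na_idx)) matrix[na_idx] <- cm[na_idx[, 2]]
  counts["post_imputation"] <- ncol(matrix)

  p <- colMeans(matrix) / 2
  maf <- pmin(p, 1 - p)
  sel <- maf >= maf_min
  matrix <- matrix[, sel, drop = FALSE]
  dstat <- dstat[sel]
  counts["maf_pass"] <- ncol(matrix)
  if (ncol(matrix) == 0) stop_input("all markers removed at the MAF filter")

  report <- structure(list(counts = counts,
                           missing_fraction_pre_depth = miss_pre,
                           missing_fraction_post_depth = miss_post,
                           min_depth = min_depth, maf_min = maf_min,
                           depth_rule = depth_rule),
                      class = "filter_report")
  list(matrix = matrix, depths = setNames(dstat, colnames(matrix)),
       report = report)
}

subset_depths <- function(depths, sel) {
  if (is.matrix(depths)) depths[, sel, drop = FALSE] else depths[sel]
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter report\n")
  lab <- c(input = "input", on_chromosomes = "on main chromosomes",
           depth_pass = sprintf("depth > %g", x$min_depth),
           post_imputation = "after mean imputation",
           maf_pass = sprintf("MAF >= %g", x$maf_min))
  for (s in names(x$counts))
    cat(sprintf("  %-22s %d\n", lab[[s]], x$counts[[s]]))
  cat(sprintf("  missing calls: %.1f%% before, %.1f%% after depth filter\n",
              100 * x$missing_fraction_pre_depth,
              100 * x$missing_fraction_post_depth))
  invisible(x)
}
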