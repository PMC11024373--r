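make_reads <- function(ids, alt, depth) {
  data.frame(marker_id = ids, alt_reads = alt, depth = depth,
             stringsAsFactors = FALSE)
}

test_that("concordance curve: identical replicates give zero everywhere", {
  r <- make_reads(sprintf("m%d", 1:100), rbinom(100, 40, 0.5), 40)
  cv <- depth_concordance_curve(list(list(r, r)), bin_edges = c(0, 20, 41, 60))
  expect_true(all(cv$mean_abs_diff[cv$n_markers > 0] == 0))
  expect_error(depth_concordance_curve(
    list(list(make_reads("a", 1, 10), make_reads("b", 1, 10)))), "share")
})

test_that("binomial replicates track the folded-normal accuracy law", {
  set.seed(42)
  f <- 0.5
  depths <- c(30, 60, 120)
  n_per <- 6000
  ids <- sprintf("m%05d", seq_len(3 * n_per))
  d <- rep(depths, each = n_per)
  r1 <- make_reads(ids, rbinom(length(d), d, f), d)
  r2 <- make_reads(ids, rbinom(length(d), d, f), d)
  cv <- depth_concordance_curve(list(list(r1, r2)),
                                bin_edges = c(0, 31, 61, 121))
  expect_false(is.unsorted(rev(cv$mean_abs_diff)))  # decreasing in depth
  for (i in seq_along(depths)) {
    expected <- sqrt(2 / pi) * sqrt(2 * f * (1 - f) / depths[i])
    # folded-normal SD of |f1-f2| divided by sqrt(bin count)
    se <- sqrt((1 - 2 / pi) * 2 * f * (1 - f) / depths[i]) / sqrt(n_per)
    expect_lt(abs(cv$mean_abs_diff[i] - expected), 3 * se + 0.02 * expected)
  }
  # single bin equals the global mean |f1 - f2|
  cv1 <- depth_concordance_curve(list(list(r1, r2)), bin_edges = c(0, 1000))
  expect_equal(cv1$mean_abs_diff,
               mean(abs(r1$alt_reads / r1$depth - r2$alt_reads / r2$depth)))
})

fake_curve <- function(vals, edges = seq(0, length(vals) * 10, by = 10)) {
  structure(data.frame(bin_lower = edges[-length(edges)],
                       bin_upper = edges[-1],
                       mean_abs_diff = vals,
                       n_markers = rep(1000L, length(vals))),
            class = c("concordance_curve", "data.frame"))
}

test_that("plateau detection follows the stated rule", {
  # flat curve: plateau from the very first bin
  expect_equal(select_depth_threshold(fake_curve(rep(0.1, 5))), 0)
  # strictly geometric decay with ratio 0.5 under tol 0.6: second bin edge
  expect_equal(select_depth_threshold(fake_curve(0.4 * 0.5^(0:4)),
                                      rel_improvement_tol = 0.6), 10)
  # increasing curve: warn and return the deepest bin edge
  expect_warning(th <- select_depth_threshold(fake_curve(c(0.1, 0.2, 0.3, 0.4))),
                 "increasing")
  expect_equal(th, 30)
  expect_error(select_depth_threshold(fake_curve(c(0.1, 0.2))), "3")
})

toy_filter_input <- function() {
  vals <- cbind(
    m1 = c(0.5, 0.5, 0.5), m2 = c(0.2, NA, 0.6), m3 = rep(0.02, 3),
    m4 = c(1.98, 2, 2), m5 = c(1, 1, 1), m6 = c(0.5, 0.5, 0.5),
    m7 = rep(0.06, 3), m8 = c(0.1, 0.1, NA), m9 = c(NA, NA, NA),
    m10 = c(0, 0.3, 0.3))
  rownames(vals) <- c("poolA", "poolB", "poolC")
  depths <- rbind(c(25, 31, 35, 40, 33, 30, 50, 44, 0, 39),
                  c(40, 40, 36, 41, 37, 45, 52, 46, 0, 41),
                  c(50, 50, 38, 42, 39, 50, 54, 48, 0, 43))
  colnames(depths) <- colnames(vals)
  list(vals = vals, depths = depths)
}

test_that("filter pipeline matches hand-computed truth and is idempotent", {
  inp <- toy_filter_input()
  out <- apply_filters(inp$vals, inp$depths, min_depth = 30, maf_min = 0.025)
  # m1 (depth 25), m6 (depth exactly 30), m9 (depth 0) fail depth;
  # m3 (maf 0.01) and m4 (folded 0.0033) fail MAF
  expect_identical(colnames(out$matrix), c("m2", "m5", "m7", "m8", "m10"))
  expect_equal(unname(out$report$counts),
               c(10, 10, 7, 7, 5))
  expect_equal(unname(out$matrix[, "m2"]), c(0.2, 0.4, 0.6))  # mean-imputed
  expect_equal(unname(out$matrix[, "m8"]), c(0.1, 0.1, 0.1))
  # imputation preserves each marker's observed mean
  expect_equal(colMeans(out$matrix)[c("m2", "m8")],
               c(m2 = 0.4, m8 = 0.1))
  # idempotence
  again <- apply_filters(out$matrix, out$depths, min_depth = 30, maf_min = 0.025)
  expect_identical(again$matrix, out$matrix)
  expect_equal(unname(again$report$counts), c(5, 5, 5, 5, 5))
})

test_that("chromosome whitelist, mean rule and stage attribution work", {
  inp <- toy_filter_input()
  map <- data.frame(marker_id = colnames(inp$vals),
                    chrom = c(1, 1, 1, 2, 2, 2, 3, 3, 9, 9))
  out <- apply_filters(inp$vals, inp$depths, map = map, chromosomes = 1:7)
  expect_equal(out$report$counts[["on_chromosomes"]], 8)
  expect_false(any(c("m9", "m10") %in% colnames(out$matrix)))

  # mean rule passes m1 (mean depth 38.3) but still drops m9
  out2 <- apply_filters(inp$vals, inp$depths, depth_rule = "mean")
  expect_true("m1" %in% colnames(out2$matrix))
  expect_error(apply_filters(inp$vals, inp$depths, min_depth = 60), "depth")
  expect_error(apply_filters(inp$vals, inp$depths, maf_min = 0.9), "MAF")
})
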