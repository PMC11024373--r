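test_that("dehiscence rescaling maps both scoring scales to [0,1]", {
  expect_equal(rescale_dehiscence(c(3, 3, 3), "zero_to_three"), 1)
  expect_equal(rescale_dehiscence(c(0, 0), "zero_to_three"), 0)
  expect_equal(rescale_dehiscence(c(0, 1, 1, 0), "zero_one"), 0.5)
  expect_equal(rescale_dehiscence(c(1, 2, 3), "zero_to_three"), 2 / 3)
  expect_error(rescale_dehiscence(c(0, 2), "zero_one"), "range")
  expect_error(rescale_dehiscence(4, "zero_to_three"), "range")
})

test_that("dormancy proportion excludes dead seed from both terms", {
  expect_equal(dormancy_proportion(20, 5, 0), 0.2)
  expect_equal(dormancy_proportion(20, 3, 2), 3 / 23)
  expect_equal(dormancy_proportion(25, 0, 0), 0)
  expect_true(is.na(dormancy_proportion(0, 0, 5)))
  expect_error(dormancy_proportion(-1, 2), "nonnegative")
  # vectorized over plants
  expect_equal(dormancy_proportion(c(20, 10), c(5, 10)), c(0.2, 0.5))
})

make_pheno <- function(ids, dorm, deh, env = "E1") {
  rbind(data.frame(sample_id = ids, environment = env, trait = "dormancy",
                   value = dorm, stringsAsFactors = FALSE),
        data.frame(sample_id = ids, environment = env, trait = "dehiscence",
                   value = deh, stringsAsFactors = FALSE))
}

test_that("tail pools take exact quartiles with deterministic tie-breaks", {
  ids <- sprintf("p%02d", 1:8)
  ph <- make_pheno(ids, dorm = 1:8 / 10, deh = 8:1 / 10)
  pools <- build_pools(ph, "E1", seed = 4)
  ps <- pools[["E1_dormancy_high"]]
  expect_setequal(ps$members, c("p07", "p08"))
  expect_setequal(pools[["E1_dormancy_low"]]$members, c("p01", "p02"))
  expect_equal(ps$mean_phenotype[["dormancy"]], mean(c(0.7, 0.8)))

  # pool size round(0.25 * N): N = 116 -> 29
  ids2 <- sprintf("q%03d", 1:116)
  set.seed(1)
  dorm <- runif(116)
  # correlated traits so the two-trait tail union leaves an interquartile
  # remainder of at least the tail size, as in the study populations
  ph2 <- make_pheno(ids2, dorm = dorm, deh = dorm + rnorm(116, 0, 0.15))
  pools2 <- build_pools(ph2, "E1", seed = 4)
  expect_equal(length(pools2[["E1_dormancy_high"]]$members), 29)
  expect_equal(length(pools2[["E1_interquartile"]]$members), 29)

  # a 10-way tie spanning the quantile boundary resolves by ascending id
  vals <- c(rep(0.1, 20), rep(0.5, 10), rep(0.9, 70))
  ids3 <- sprintf("r%03d", 1:100)
  ph3 <- make_pheno(ids3, dorm = vals, deh = rev(vals))
  p_a <- build_pools(ph3, "E1", seed = 1)
  p_b <- build_pools(ph3, "E1", seed = 1)
  expect_identical(p_a[["E1_dormancy_low"]]$members,
                   p_b[["E1_dormancy_low"]]$members)
  # low tail of 25 = the twenty 0.1s plus the five lowest-id 0.5s
  expect_setequal(p_a[["E1_dormancy_low"]]$members,
                  c(ids3[1:20], sprintf("r%03d", 21:25)))
})

test_that("pools partition: tails disjoint, interquartile avoids all tails", {
  set.seed(11)
  ids <- sprintf("s%03d", 1:120)
  ph <- make_pheno(ids, dorm = rnorm(120), deh = rnorm(120))
  pools <- build_pools(ph, "E1", seed = 2)
  for (tr in c("dormancy", "dehiscence")) {
    hi <- pools[[paste0("E1_", tr, "_high")]]$members
    lo <- pools[[paste0("E1_", tr, "_low")]]$members
    expect_length(intersect(hi, lo), 0)
  }
  all_tails <- unique(unlist(lapply(pools[1:4], `[[`, "members")))
  iq <- pools[["E1_interquartile"]]$members
  expect_length(intersect(iq, all_tails), 0)
})

test_that("dehiscence rescaling does not change pool membership", {
  set.seed(3)
  ids <- sprintf("t%03d", 1:60)
  # per-plant mean pod scores on the 0-3 scale and their /3 image
  raw03 <- replicate(60, mean(sample(0:3, 50, replace = TRUE)))
  scaled <- vapply(seq_len(60), function(i)
    rescale_dehiscence(raw03[i], "zero_to_three"), numeric(1))
  expect_equal(scaled, raw03 / 3)
  dorm <- rnorm(60)
  p1 <- build_pools(make_pheno(ids, dorm = dorm, deh = raw03), "E1", seed = 9)
  p2 <- build_pools(make_pheno(ids, dorm = dorm, deh = scaled), "E1", seed = 9)
  expect_identical(lapply(p1, `[[`, "members"), lapply(p2, `[[`, "members"))
})

test_that("pool true frequency is the member mean and order-invariant", {
  g <- rbind(a = c(0, 2, 1), b = c(1, 1, 1), c = c(2, 0, 0))
  colnames(g) <- c("m1", "m2", "m3")
  expect_equal(unname(pool_true_frequency(g, c("a", "b", "c"))),
               c(0.5, 0.5, 1 / 3))
  expect_equal(pool_true_frequency(g, c("c", "a", "b")),
               pool_true_frequency(g, c("a", "b", "c")))
  g2 <- rbind(a = c(2, 2), b = c(2, NA))
  colnames(g2) <- c("m1", "m2")
  expect_equal(unname(pool_true_frequency(g2, c("a", "b"))), c(1, 1))
  expect_error(pool_true_frequency(g, character(0)), "empty")
  # brute-force enumeration oracle on a random 20-member pool
  set.seed(8)
  G <- matrix(rbinom(600, 2, 0.4), 30, 20,
              dimnames = list(sprintf("i%02d", 1:30), NULL))
  mem <- sample(rownames(G), 20)
  brute <- apply(G[mem, ], 2, function(col) sum(col) / (2 * length(col)))
  expect_equal(unname(pool_true_frequency(G, mem)), unname(brute))
})

test_that("read-based frequency estimation uses the 0-2 scale", {
  r <- data.frame(marker_id = c("a", "b", "c", "d"),
                  alt_reads = c(15, 0, 40, 0), depth = c(30, 40, 40, 0))
  est <- estimate_pool_frequency(r)
  expect_equal(unname(est$freq02), c(1, 0, 2, NA))
  expect_error(estimate_pool_frequency(
    data.frame(marker_id = "a", alt_reads = 5, depth = 4)), "exceeds")
  # convergence to 2x true frequency as depth grows
  f <- 0.3
  for (d in c(100, 10000)) {
    set.seed(d)
    rr <- data.frame(marker_id = sprintf("m%d", 1:2000),
                     alt_reads = rbinom(2000, d, f), depth = d)
    err <- abs(mean(estimate_pool_frequency(rr)$freq02) - 2 * f)
    expect_lt(err, 4 * 2 * sqrt(f * (1 - f) / d) / sqrt(2000))
  }
})
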