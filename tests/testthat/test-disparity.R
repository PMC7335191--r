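bins2 <- time_bins(c("older", "younger"), c(260, 252), c(252, 247))

test_that("bin assignment follows the intersection and midpoint rules", {
  ages <- data.frame(label = c("x", "y", "z"),
                     older = c(251, 253, 258),
                     younger = c(249, 249, 256))
  a <- assign_to_bins(ages, bins2)
  expect_equal(a$older, c("y", "z"))
  expect_equal(a$younger, c("x", "y"))
  m <- assign_to_bins(ages, bins2, rule = "midpoint")
  # y's midpoint is 251 -> younger bin only
  expect_equal(m$older, "z")
  expect_equal(m$younger, c("x", "y"))
  # a point age on the boundary joins the bin whose older bound it is
  pt <- data.frame(label = "p", older = 252, younger = 252)
  expect_equal(assign_to_bins(pt, bins2)$younger, "p")
  # labels without ages are refused by name
  bad <- data.frame(label = "q", older = NA_real_, younger = NA_real_)
  expect_error(assign_to_bins(bad, bins2), "q")
})

test_that("total bin memberships equal a brute-force overlap count", {
  set.seed(9)
  bins <- default_time_bins()
  n <- 200
  older <- runif(n, 0, 320)
  younger <- pmax(older - runif(n, 0, 15), 0)
  ages <- data.frame(label = paste0("L", 1:n), older = older,
                     younger = younger)
  a <- assign_to_bins(ages, bins)
  naive <- 0
  for (i in seq_len(n)) for (j in seq_len(nrow(bins))) {
    hit <- older[i] > bins$younger[j] && younger[i] <= bins$older[j]
    if (j == which.min(bins$younger) && older[i] == bins$younger[j])
      hit <- TRUE
    naive <- naive + hit
  }
  expect_equal(sum(lengths(a)), naive)
})

test_that("sum of variances equals mean squared distance to the centroid", {
  set.seed(4)
  sc <- matrix(rnorm(30 * 5), 30, 5,
               dimnames = list(paste0("t", 1:30), NULL))
  ord <- structure(list(scores = sc, labels = rownames(sc)),
                   class = "pcoa_ord")
  sv <- sum_of_variances(ord)
  ctr <- colMeans(sc)
  msd <- mean(rowSums(sweep(sc, 2, ctr)^2))
  expect_equal(sv, msd, tolerance = 1e-12)
  # single point and identical coordinates give zero
  expect_equal(sum_of_variances(ord, "t1"), 0)
  sc2 <- sc; sc2[2:5, ] <- rep(sc2[1, ], each = 4)
  ord2 <- structure(list(scores = sc2, labels = rownames(sc2)),
                    class = "pcoa_ord")
  expect_equal(sum_of_variances(ord2, paste0("t", 1:5)), 0)
  # n-1 denominator option
  expect_equal(sum_of_variances(ord, denominator = "n-1"),
               sum(apply(sc, 2, var)), tolerance = 1e-12)
  expect_error(sum_of_variances(ord, character(0)), "empty")
})

test_that("sum of variances is invariant under orthogonal rotation", {
  set.seed(8)
  sc <- matrix(rnorm(20 * 6), 20, 6,
               dimnames = list(paste0("t", 1:20), NULL))
  rot <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  ord_a <- structure(list(scores = sc, labels = rownames(sc)),
                     class = "pcoa_ord")
  ord_b <- structure(list(scores = sc %*% rot, labels = rownames(sc)),
                     class = "pcoa_ord")
  expect_equal(sum_of_variances(ord_a), sum_of_variances(ord_b),
               tolerance = 1e-8)
  # doubling every coordinate multiplies disparity by 4
  ord_c <- structure(list(scores = 2 * sc, labels = rownames(sc)),
                     class = "pcoa_ord")
  expect_equal(sum_of_variances(ord_c), 4 * sum_of_variances(ord_a),
               tolerance = 1e-12)
})

make_aged_ord <- function(seed, n = 60, ages_max = 80) {
  set.seed(seed)
  sc <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("t", 1:n), NULL))
  age <- runif(n, 0, ages_max)
  structure(list(scores = sc, labels = rownames(sc),
                 ages = data.frame(label = rownames(sc), type = "tip",
                                   older = age, younger = age)),
            class = "pcoa_ord")
}

test_that("bootstrap replicates are seed-deterministic and well-calibrated", {
  ord <- make_aged_ord(10)
  bins <- time_bins(c("B1", "B2"), c(80, 40), c(40, 0))
  a <- assign_to_bins(ord$ages, bins)
  b1 <- bootstrap_disparity(ord, a, bins, n_boot = 100, seed = 99)
  b2 <- bootstrap_disparity(ord, a, bins, n_boot = 100, seed = 99)
  expect_identical(b1$values, b2$values)
  b3 <- bootstrap_disparity(ord, a, bins, n_boot = 100, seed = 100)
  expect_false(identical(b1$values, b3$values))
  # replicate count per non-empty bin equals n_boot
  expect_true(all(lengths(b1$values) == 100))
  # summaries are consistent with stored replicates
  expect_equal(b1$summaries$mean[1], mean(b1$values[[1]]))
  expect_equal(b1$summaries$sd[2], sd(b1$values[[2]]))
})

test_that("bootstrap mean converges to the (n-1)/n-deflated statistic", {
  ord <- make_aged_ord(12, n = 50, ages_max = 10)
  bins <- time_bins("only", 10.5, 0)
  a <- assign_to_bins(ord$ages, bins)
  b <- bootstrap_disparity(ord, a, bins, n_boot = 2000, seed = 7)
  n <- 50
  expected <- (n - 1) / n * b$summaries$observed[1]
  se <- b$summaries$sd[1] / sqrt(2000)
  expect_lt(abs(b$summaries$mean[1] - expected), 3 * se)
})

test_that("degenerate bins are flagged, never fabricated", {
  ord <- make_aged_ord(13, n = 5, ages_max = 10)
  bins <- time_bins(c("void", "all"), c(300, 20), c(20, 0))
  dtt <- disparity_through_time(ord, bins, n_boot = 50, seed = 3)
  expect_true(is.na(dtt$summaries$mean[dtt$summaries$bin == "void"]))
  expect_null(dtt$values[["void"]])
  expect_equal(dtt$summaries$n[dtt$summaries$bin == "all"], 5L)
  # a single-member bin has all replicates equal to zero
  one <- make_aged_ord(14, n = 1, ages_max = 5)
  a1 <- assign_to_bins(one$ages, time_bins("b", 10, 0))
  b1 <- bootstrap_disparity(one, a1, time_bins("b", 10, 0),
                            n_boot = 20, seed = 1)
  expect_true(all(b1$values$b == 0))
})

test_that("a radiating clade shows non-decreasing early disparity", {
  # before any extinction strikes, an expanding clade should not lose
  # disparity from one bin to the next (checked in expectation across
  # replicate simulations)
  bins <- time_bins(c("early", "mid", "late"),
                    c(100, 70, 35), c(70, 35, 0))
  cfg <- sim_config(lambda = 0.06, mu = 0, psi = 0, t_root = 100,
                    min_tips = 15, max_tips = 120, n_char = 40,
                    base_rate = 0.02, miss_frac = 0, inapp_frac = 0,
                    poly_frac = 0,
                    regimes = data.frame(older = 100, younger = 0, mean = 1))
  deltas <- matrix(NA_real_, 20, 2)
  for (r in 1:20) {
    tt <- simulate_fbd_tree(cfg, seed = 200 + r)
    sim <- simulate_branch_rates(tt, cfg, seed = 300 + r)
    ch <- simulate_characters(sim$tree, cfg, seed = 400 + r)
    ms <- build_morphospace(ch$matrix, tree = sim$tree, conf = 0.5)
    dtt <- disparity_through_time(ms, bins, n_boot = 30, seed = 500 + r)
    deltas[r, ] <- diff(dtt$summaries$mean)
  }
  expect_gt(mean(colMeans(deltas, na.rm = TRUE)), 0)
  expect_gt(mean(deltas >= 0, na.rm = TRUE), 0.6)
})
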