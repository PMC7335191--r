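test_that("clock prior derivation follows the height/age arithmetic", {
  cp <- derive_clock_prior(1, 1)
  expect_equal(cp$base_rate, 1)
  expect_equal(cp$mean_log, 0)
  expect_equal(cp$sd_broad, exp(1))
  # random pairs match an independent arithmetic recomputation
  set.seed(77)
  for (i in 1:100) {
    h <- runif(1, 0.5, 100); a <- runif(1, 1, 500)
    cp <- derive_clock_prior(h, a)
    expect_equal(cp$base_rate, round(h / a, 4), tolerance = 1e-12)
    expect_equal(cp$mean_log, log(h / a), tolerance = 1e-12)
    expect_equal(cp$sd_broad, exp(round(h / a, 4)), tolerance = 1e-12)
  }
  # scale consistency: doubling both inputs leaves the base unchanged
  expect_equal(derive_clock_prior(2 * 23.8582, 2 * 325.45)$base_rate,
               derive_clock_prior(23.8582, 325.45)$base_rate)
  expect_error(derive_clock_prior(-1, 10), "positive")
  expect_error(derive_clock_prior(1, 0), "positive")
})

test_that("relative rates convert to absolute rates multiplicatively", {
  expect_equal(relative_to_absolute(1.0, 0.00345), 0.00345)
  expect_equal(relative_to_absolute(2.0, 0.00345), 0.0069)
  v <- c(0.5, 1, 34.1)
  expect_equal(relative_to_absolute(v, 0.00345),
               vapply(v, function(r) r * 0.00345, numeric(1)))
  cp <- derive_clock_prior(23.8582, 325.45)
  expect_equal(relative_to_absolute(2, cp), 2 * cp$base_rate)
  expect_error(relative_to_absolute(-1, 0.003), "positive")
})

test_that("bipartition pooling is conservative and support-aware", {
  tt <- toy_time_tree(rates = c(0.5, 2, 1, 1.2, 1.5, 3))
  ts1 <- tree_sample(list(tt))
  rt1 <- extract_bipartition_rates(ts1)
  # 4-tip rooted bifurcating tree: 4 terminal + 2 internal branches
  expect_equal(nrow(rt1$occurrences), 6)
  expect_equal(nrow(rt1$support), 6)
  # two identical trees: every bipartition has 2 pooled values, support 1
  ts2 <- tree_sample(list(tt, tt))
  rt2 <- extract_bipartition_rates(ts2)
  expect_true(all(rt2$support$n_occurrences == 2))
  expect_true(all(rt2$support$support == 1))
  # occurrence conservation across a heterogeneous sample
  cfg <- sim_config(min_tips = 10, max_tips = 30, n_pseudo_posterior = 7,
                    nni_prob = 0.3)
  tr <- simulate_branch_rates(simulate_fbd_tree(cfg, seed = 21), cfg,
                              seed = 22)
  pp <- make_pseudo_posterior(tr, cfg, seed = 23)
  rt <- extract_bipartition_rates(pp$sample)
  expect_equal(nrow(rt$occurrences),
               sum(vapply(pp$sample$trees,
                          function(t) nrow(t$phylo$edge), 1L)))
  expect_true(all(rt$support$support > 0 & rt$support$support <= 1))
})

test_that("pooled bipartition counts equal a naive split enumeration", {
  cfg <- sim_config(lambda = 0.06, mu = 0.02, psi = 0.02, t_root = 60,
                    regimes = data.frame(older = 60, younger = 0, mean = 1),
                    min_tips = 9, max_tips = 12, n_pseudo_posterior = 5,
                    nni_prob = 0.2)
  tr <- simulate_branch_rates(simulate_fbd_tree(cfg, seed = 31), cfg,
                              seed = 32)
  pp <- make_pseudo_posterior(tr, cfg, seed = 33)
  rt <- extract_bipartition_rates(pp$sample)
  # independent split hashing via phangorn descendant sets
  naive <- character(0)
  for (t in pp$sample$trees) {
    phy <- t$phylo
    for (child in phy$edge[, 2]) {
      tips <- phangorn::Descendants(phy, child, "tips")[[1]]
      naive <- c(naive, paste(sort(phy$tip.label[tips]), collapse = "|"))
    }
  }
  keys <- sort(unique(naive))
  expect_setequal(unique(rt$occurrences$bipartition), keys)
  expect_equal(as.integer(table(rt$occurrences$bipartition)[keys]),
               as.integer(table(naive)[keys]))
})

test_that("branch-rate binning follows overlap and midpoint rules", {
  bins <- time_bins(c("A", "B"), c(252, 247), c(247, 237))
  occ <- data.frame(bipartition = c("x", "y", "z"),
                    rel_rate = c(2, 1, 5),
                    start_age = c(250, 251, 260),
                    end_age = c(240, 249, 255),
                    tree = 1L)
  rt <- structure(list(occurrences = occ,
                       support = data.frame(bipartition = c("x", "y", "z"),
                                            n_occurrences = 1, n_trees = 1,
                                            support = 1),
                       n_trees = 1L), class = "rate_table")
  expect_warning(bin_branch_rates(rt, bins), "outside")
  bs <- suppressWarnings(bin_branch_rates(rt, bins))
  # branch 250-240 contributes to both bins; z (260-255) to neither
  expect_equal(sort(bs$values$A), c(1, 2))
  expect_equal(bs$values$B, 2)
  expect_equal(bs$unbinned, 1L)
  mid <- suppressWarnings(bin_branch_rates(rt, bins, rule = "midpoint"))
  # midpoints 245, 250, 257.5: partition of in-range occurrences
  expect_equal(mid$values$A, 1)
  expect_equal(mid$values$B, 2)
  expect_equal(sum(lengths(mid$values)) + mid$unbinned, nrow(occ))
})

test_that("constant rates give unit bin means; means match accumulation", {
  cfg <- sim_config(min_tips = 20, max_tips = 60, sigma_log = 0,
                    regimes = data.frame(older = 300, younger = 0, mean = 1))
  tr <- simulate_branch_rates(simulate_fbd_tree(cfg, seed = 41), cfg,
                              seed = 42)
  rt <- extract_bipartition_rates(
    make_pseudo_posterior(tr, sim_config(n_pseudo_posterior = 3,
                                         rate_resample_sd = 0),
                          seed = 43)$sample)
  bins <- time_bins(c("old", "new"), c(300, 150), c(150, 0))
  bs <- bin_branch_rates(rt, bins)
  expect_true(all(abs(bs$summaries$mean[bs$summaries$n > 0] - 1) < 1e-12))
  # naive accumulation oracle on lognormal rates
  cfg2 <- sim_config(min_tips = 20, max_tips = 60)
  tr2 <- simulate_branch_rates(simulate_fbd_tree(cfg2, seed = 44), cfg2,
                               seed = 45)
  rt2 <- extract_bipartition_rates(
    make_pseudo_posterior(tr2, sim_config(n_pseudo_posterior = 4),
                          seed = 46)$sample)
  bs2 <- bin_branch_rates(rt2, default_time_bins())
  occ <- rt2$occurrences
  for (j in seq_len(nrow(bs2$summaries))) {
    b <- bs2$summaries[j, ]
    sel <- occ$start_age > b$younger & occ$end_age <= b$older
    if (b$bin == "Neogene+") sel <- sel | occ$start_age == 0
    if (sum(sel) == 0) next
    expect_equal(unname(b$mean), mean(occ$rel_rate[sel]), tolerance = 1e-12)
  }
})

test_that("rate summaries match reference routines and known modes", {
  expect_equal(unname(rate_summary(c(2, 2, 2))[c("mean", "median", "sd")]),
               c(2, 2, 0))
  expect_equal(unname(rate_summary(c(2, 2, 2))["mode"]), 2)
  set.seed(90)
  v <- rlnorm(10000, 0, 0.5)
  s <- rate_summary(v)
  expect_equal(unname(s["mean"]), mean(v), tolerance = 1e-12)
  expect_equal(unname(s["median"]), median(v), tolerance = 1e-12)
  expect_equal(unname(s["sd"]), sd(v), tolerance = 1e-12)
  # lognormal with log-mean 0: median near 1, log-scale KDE mode near 0
  se_med <- 1.2533 * sd(v) / sqrt(length(v))   # asymptotic median SE bound
  expect_lt(abs(s["median"] - 1), 3 * se_med)
  expect_lt(abs(log(s["mode"])), 0.15)
  expect_error(rate_summary(numeric(0)), "empty")
})
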