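test_that("without extinction or fossilisation every tip is extant", {
  cfg <- sim_config(lambda = 0.05, mu = 0, psi = 0, t_root = 80,
                    regimes = data.frame(older = 80, younger = 0, mean = 1),
                    min_tips = 2, max_tips = 1e6)
  for (seed in 1:10) {
    tt <- simulate_fbd_tree(cfg, seed = seed)
    ntip <- length(tt$phylo$tip.label)
    expect_true(all(abs(tt$node_age[seq_len(ntip)]) < 1e-9))
    expect_true(all(startsWith(tt$phylo$tip.label, "t")))
  }
})

test_that("expected tip counts follow the branching-process mean", {
  # pure birth: E[N] = exp(lambda * t)
  cfg <- sim_config(lambda = 0.05, mu = 0, psi = 0, t_root = 100,
                    regimes = data.frame(older = 100, younger = 0, mean = 1),
                    min_tips = 2, max_tips = 1e6)
  n_rep <- 150
  counts <- vapply(seq_len(n_rep), function(s)
    length(simulate_fbd_tree(cfg, seed = 1000 + s)$phylo$tip.label),
    numeric(1))
  expected <- exp(0.05 * 100)
  # geometric offspring distribution: SD ~ mean for a Yule process
  se <- expected / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("every simulated and jittered tree has positive branch durations", {
  cfg <- sim_config(min_tips = 5, max_tips = 80, psi = 0.02,
                    n_pseudo_posterior = 3, age_jitter_sd = 4)
  for (seed in 1:60) {
    tt <- simulate_fbd_tree(cfg, seed = seed)
    e <- tt$phylo$edge
    expect_true(all(tt$node_age[e[, 1]] > tt$node_age[e[, 2]]))
    sim <- simulate_branch_rates(tt, cfg, seed = seed + 1)
    pp <- make_pseudo_posterior(sim, cfg, seed = seed + 2)
    for (jt in pp$sample$trees) {
      ej <- jt$phylo$edge
      expect_true(all(jt$node_age[ej[, 1]] > jt$node_age[ej[, 2]]))
      expect_true(all(jt$rate > 0))
    }
  }
})

test_that("branch rates honour their regimes exactly when noise is zero", {
  cfg <- sim_config(sigma_log = 0, min_tips = 30, max_tips = 100)
  tt <- simulate_fbd_tree(cfg, seed = 5)
  sim <- simulate_branch_rates(tt, cfg, seed = 6)
  expect_equal(sim$tree$rate, sim$truth$regime_mean, tolerance = 1e-12)
  # independent regime lookup from branch midpoints
  iv <- megarates:::branch_intervals(tt)
  mid <- (iv$start_age + iv$end_age) / 2
  want <- ifelse(mid > 251.9, 1.0, ifelse(mid > 237, 2.5, 1.0))
  expect_equal(sim$truth$regime_mean, want)
})

test_that("lognormal rate draws have mean equal to the regime mean", {
  cfg <- sim_config(sigma_log = 0.5, min_tips = 100, max_tips = 400,
                    regimes = data.frame(older = 300, younger = 0, mean = 1))
  rates <- numeric(0)
  s <- 0
  while (length(rates) < 10000) {
    s <- s + 1
    tt <- simulate_fbd_tree(cfg, seed = 7000 + s)
    rates <- c(rates, simulate_branch_rates(tt, cfg, seed = 8000 + s)$tree$rate)
  }
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 1), 3 * se)
})

test_that("zero base rate freezes characters at the root state", {
  cfg <- sim_config(base_rate = 0, n_char = 30, min_tips = 10,
                    max_tips = 40)
  tt <- simulate_fbd_tree(cfg, seed = 11)
  sim <- simulate_branch_rates(tt, cfg, seed = 12)
  ch <- simulate_characters(sim$tree, cfg, seed = 13)
  for (j in 1:30)
    expect_true(all(ch$matrix$states[, j] ==
                      as.character(ch$truth$root_states[j])))
  expect_true(all(ch$truth$changes == 0))
})

test_that("long star-tree branches drive binary characters to a fair coin", {
  star <- structure(list(edge = cbind(5L, 1:4),
                         edge.length = rep(4000, 4),
                         tip.label = paste0("t", 1:4), Nnode = 1L),
                    class = "phylo", order = "cladewise")
  tt <- time_tree(star)
  tt$rate <- rep(1, 4)
  cfg <- sim_config(n_char = 4000, states_per_char = 2, frac_ordered = 0,
                    base_rate = 0.002, t_root = 300)
  ch <- simulate_characters(tt, cfg, seed = 21)
  # expected changes per branch = 8: effectively stationary
  for (i in 1:4) {
    tab <- table(factor(ch$matrix$states[i, ], levels = c("0", "1")))
    expect_gt(chisq.test(tab)$p.value, 0.01)
  }
  # tips are independent: chi-square on the joint table of two tips
  joint <- table(ch$matrix$states[1, ], ch$matrix$states[2, ])
  expect_gt(chisq.test(joint)$p.value, 0.01)
})

test_that("realised change counts scale linearly with rate x duration", {
  cfg <- sim_config(min_tips = 20, max_tips = 60, n_char = 400,
                    base_rate = 0.01, sigma_log = 1.0)
  tt <- simulate_fbd_tree(cfg, seed = 31)
  sim <- simulate_branch_rates(tt, cfg, seed = 32)
  ch <- simulate_characters(sim$tree, cfg, seed = 33)
  mean_changes <- rowMeans(ch$truth$changes)
  expos <- 0.01 * sim$tree$rate * sim$tree$phylo$edge.length
  keep <- mean_changes > 0 & expos > 0.02
  fit <- lm(log(mean_changes[keep]) ~ log(expos[keep]))
  ci <- confint(fit)[2, ]
  expect_true(ci[1] <= 1 && 1 <= ci[2])
  expect_lt(abs(coef(fit)[2] - 1), 0.1)
})

test_that("degradation fractions are honoured and masks recorded", {
  clean <- rand_cm(41, 100, 200, miss = 0)
  cfg0 <- sim_config(miss_frac = 0, inapp_frac = 0, poly_frac = 0)
  out0 <- degrade_matrix(clean, cfg0, seed = 42)
  expect_true(out0$matrix == clean)
  cfg <- sim_config(miss_frac = 0.2, inapp_frac = 0.05, poly_frac = 0.03)
  out <- degrade_matrix(clean, cfg, seed = 43)
  n_cells <- 100 * 200
  p_obs <- mean(is_missing(out$matrix$states))
  expect_lt(abs(p_obs - 0.2), 2.58 * sqrt(0.2 * 0.8 / n_cells))
  expect_equal(is_missing(out$matrix$states) &
                 !is.na(out$matrix$states), out$masks$missing,
               ignore_attr = TRUE)
  expect_equal(sum(is_inapplicable(out$matrix$states)),
               sum(out$masks$inapplicable))
  expect_equal(sum(is_polymorphic(out$matrix$states)),
               sum(out$masks$polymorphic))
  expect_error(sim_config(miss_frac = 0.6, inapp_frac = 0.3,
                          poly_frac = 0.2), "sum below 1")
})

test_that("columns pushed over the missing threshold are the ones dropped", {
  clean <- rand_cm(51, 50, 40, miss = 0)
  cfg <- sim_config(miss_frac = 0.05, inapp_frac = 0, poly_frac = 0)
  dg <- degrade_matrix(clean, cfg, seed = 52)
  m <- dg$matrix
  forced <- c(3, 17, 33)
  for (j in forced) m$states[1:20, j] <- "?"   # 40% missing
  frac <- missing_fraction(m, "per_character")
  expect_true(all(frac[forced] > 0.30))
  expect_true(all(frac[-forced] <= 0.30))
  r <- prep_pipeline(m)
  expect_equal(r$report$dropped_missing, forced)
})

test_that("a zero-noise pseudo-posterior is N identical trees", {
  cfg <- sim_config(min_tips = 15, max_tips = 50, n_pseudo_posterior = 4,
                    age_jitter_sd = 0, rate_resample_sd = 0)
  sim <- simulate_branch_rates(simulate_fbd_tree(cfg, seed = 61), cfg,
                               seed = 62)
  pp <- make_pseudo_posterior(sim, cfg, seed = 63)
  for (jt in pp$sample$trees) {
    expect_equal(jt$node_age, sim$tree$node_age, tolerance = 1e-12)
    expect_equal(jt$rate, sim$tree$rate, tolerance = 1e-12)
  }
})

test_that("pooled rate means converge to the true branch rates with sample size", {
  cfg <- sim_config(min_tips = 40, max_tips = 90, age_jitter_sd = 1,
                    rate_resample_sd = 0.3)
  sim <- simulate_branch_rates(simulate_fbd_tree(cfg, seed = 71), cfg,
                               seed = 72)
  true_keys <- megarates:::edge_bipartitions(sim$tree$phylo)
  rmse <- vapply(c(10, 100, 1000), function(n) {
    cfg_n <- sim_config(min_tips = 40, max_tips = 90, age_jitter_sd = 1,
                        rate_resample_sd = 0.3, n_pseudo_posterior = n)
    pp <- make_pseudo_posterior(sim, cfg_n, seed = 73)
    rt <- extract_bipartition_rates(pp$sample)
    pooled <- tapply(rt$occurrences$rel_rate, rt$occurrences$bipartition,
                     mean)
    sqrt(mean((pooled[true_keys] - sim$tree$rate)^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[3], rmse[2])
})

test_that("the full generator chain is bit-reproducible under a fixed seed", {
  run <- function() {
    cfg <- sim_config(lambda = 0.06, mu = 0.02, psi = 0.02, t_root = 60,
                      regimes = data.frame(older = 60, younger = 0, mean = 1),
                      min_tips = 10, max_tips = 40, n_char = 25,
                      n_pseudo_posterior = 3)
    tt <- simulate_fbd_tree(cfg, seed = 81)
    sim <- simulate_branch_rates(tt, cfg, seed = 82)
    ch <- simulate_characters(sim$tree, cfg, seed = 83)
    dg <- degrade_matrix(ch$matrix, cfg, seed = 84)
    pp <- make_pseudo_posterior(sim, cfg, seed = 85)
    list(tt, sim, ch, dg, pp)
  }
  expect_identical(run(), run())
})

test_that("faster character evolution yields larger terminal-bin disparity", {
  bins <- time_bins("recent", 40, 0)
  base_cfg <- function(base_rate)
    sim_config(lambda = 0.07, mu = 0.02, psi = 0, t_root = 60,
               regimes = data.frame(older = 60, younger = 0, mean = 1),
               min_tips = 12, max_tips = 60, n_char = 40,
               base_rate = base_rate, miss_frac = 0, inapp_frac = 0,
               poly_frac = 0)
  slow_cfg <- base_cfg(0.003)
  fast_cfg <- base_cfg(0.03)
  wins <- logical(50)
  for (r in 1:50) {
    tt <- simulate_fbd_tree(slow_cfg, seed = 900 + r)
    sim <- simulate_branch_rates(tt, slow_cfg, seed = 950 + r)
    disp <- vapply(list(slow = slow_cfg, fast = fast_cfg), function(cf) {
      ch <- simulate_characters(sim$tree, cf, seed = 990 + r)
      ms <- build_morphospace(ch$matrix, tree = sim$tree,
                              include_nodes = FALSE)
      dtt <- disparity_through_time(ms, bins, n_boot = 10, seed = r)
      dtt$summaries$observed[1]
    }, numeric(1))
    wins[r] <- disp["fast"] > disp["slow"]
  }
  expect_lt(binom.test(sum(wins), 50, alternative = "greater")$p.value,
            0.01)
})
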