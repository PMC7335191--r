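#' Simulation configuration
#'
#' Bundles the parameters of the synthetic data generator: a fossilized
#' birth-death tree, branch rates drawn lognormally around epoch-specific
#' regime means, Mk-evolved discrete characters, cell degradation
#' (missing / inapplicable / polymorphic), and a pseudo-posterior sample of
#' jittered trees. Defaults emulate a deep-time amniote-scale study: a
#' ~300 Myr tree with extinct and extant tips, a rate-acceleration regime
#' between the end-Permian extinction (251.9 Ma) and the end of the Middle
#' Triassic (237 Ma), and the published base clock rate of 0.00345
#' substitutions per character per Myr.
#'
#' @param lambda speciation rate per lineage per Myr.
#' @param mu extinction rate per lineage per Myr.
#' @param psi fossil-sampling rate per lineage per Myr.
#' @param t_root root age in Ma.
#' @param regimes data frame (`older`, `younger`, `mean`) of relative-rate
#'   regime means; must tile `[t_root, 0]` without overlap.
#' @param sigma_log SD of log relative rate around the regime mean.
#' @param n_char number of characters.
#' @param states_per_char candidate state counts (sampled per character).
#' @param frac_ordered fraction of ordered characters.
#' @param base_rate base clock rate, substitutions per character per Myr.
#' @param miss_frac,inapp_frac,poly_frac cell-degradation fractions (must
#'   sum below 1).
#' @param n_pseudo_posterior number of trees in the pseudo-posterior.
#' @param age_jitter_sd SD (Myr) of node-age jitter in the pseudo-posterior.
#' @param rate_resample_sd lognormal SD of rate resampling about the true
#'   branch rates.
#' @param nni_prob probability of a nearest-neighbour-interchange
#'   perturbation per eligible internal branch per pseudo-posterior tree.
#' @param strat_range_myr half-width (Myr) of the synthetic stratigraphic
#'   age range given to fossil tips.
#' @param min_tips,max_tips,max_lineages resimulation bounds for the tree
#'   generator (trees outside the tip range are rejected and redrawn).
#' @param min_root_age minimum age (Ma) of the returned tree's root (the
#'   first surviving bifurcation); trees not spanning this deep are
#'   rejected, emulating taxon sampling that targets the full time window.
#' @param coverage_bins optional data frame (`older`, `younger`) of
#'   intervals, each of which must contain at least `coverage_min` branch
#'   midpoints for a simulated tree to be accepted. This emulates a sampling
#'   design that deliberately covers every stratigraphic interval of
#'   interest rather than sampling lineages uniformly.
#' @param coverage_min minimum branch midpoints per coverage interval.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(lambda = 0.05, mu = 0.034, psi = 0.01, t_root = 300,
                       regimes = data.frame(older = c(300, 251.9, 237),
                                            younger = c(251.9, 237, 0),
                                            mean = c(1.0, 2.5, 1.0)),
                       sigma_log = 0.3, n_char = 100,
                       states_per_char = 2:5, frac_ordered = 0.25,
                       base_rate = 0.00345, miss_frac = 0.15,
                       inapp_frac = 0.02, poly_frac = 0.02,
                       n_pseudo_posterior = 100, age_jitter_sd = 2,
                       rate_resample_sd = 0.1, nni_prob = 0,
                       strat_range_myr = 2.5, min_tips = 10, max_tips = 400,
                       min_root_age = 0, coverage_bins = NULL,
                       coverage_min = 3, max_lineages = 50000) {
  stopifnot(lambda > 0, mu >= 0, psi >= 0, t_root > 0, sigma_log >= 0,
            n_char >= 0, frac_ordered >= 0, frac_ordered <= 1,
            base_rate >= 0, n_pseudo_posterior >= 1, age_jitter_sd >= 0,
            rate_resample_sd >= 0)
  fr <- c(miss_frac, inapp_frac, poly_frac)
  if (any(fr < 0) || any(fr >= 1) || sum(fr) >= 1)
    stop("degradation fractions must lie in [0, 1) and sum below 1")
  regimes <- regimes[order(-regimes$older), ]
  if (abs(regimes$older[1] - t_root) > 1e-9 ||
      abs(regimes$younger[nrow(regimes)]) > 1e-9 ||
      (nrow(regimes) > 1 &&
       any(abs(regimes$older[-1] - regimes$younger[-nrow(regimes)]) > 1e-9)))
    stop("regimes must tile [t_root, 0] without gaps or overlap")
  if (any(regimes$mean <= 0)) stop("regime means must be positive")
  cfg <- as.list(environment())
  cfg$fr <- NULL
  structure(cfg, class = "sim_config")
}

#' Simulate a fossilized birth-death tree
#'
#' Forward birth-death simulation from a single lineage at `t_root`:
#' lineages speciate at `lambda` and go extinct at `mu`; fossils are sampled
#' along lineages at `psi`, and an extinct lineage with at least one fossil
#' sample is retained as a fossil tip at the age of its youngest sample
#' (sampled ancestors are not placed as separate degree-2 nodes; no
#' downstream analysis distinguishes them). Unsampled extinct lineages are
#' pruned; all extant tips are retained. Resimulates (up to `retry`) when
#' the number of sampled tips falls outside `[min_tips, max_tips]`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param retry resimulation cap.
#' @return a [time_tree()]; fossil tips are labelled `f<k>`, extant tips
#'   `t<k>`.
#' @export
simulate_fbd_tree <- function(config, seed, retry = 100) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  for (attempt in seq_len(retry)) {
    res <- try_fbd_once(config)
    if (!is.null(res)) return(res)
  }
  stop("no surviving sampled tree in ", retry, " attempts; ",
       "increase lambda or psi")
}

try_fbd_once <- function(config) {
  lambda <- config$lambda; mu <- config$mu; psi <- config$psi
  # lineage records; ages in Ma (decreasing toward the present)
  parent <- integer(0); birth <- numeric(0); death <- numeric(0)
  fate <- character(0)
  new_lineage <- function(p, b) {
    parent <<- c(parent, p); birth <<- c(birth, b)
    death <<- c(death, NA_real_); fate <<- c(fate, "")
    length(parent)
  }
  root_id <- new_lineage(0L, config$t_root)
  queue <- root_id
  while (length(queue)) {
    if (length(parent) > config$max_lineages)
      stop("simulation exceeded max_lineages; reduce lambda or t_root")
    l <- queue[1]; queue <- queue[-1]
    wait <- stats::rexp(1, lambda + mu)
    end <- birth[l] - wait
    if (end <= 0) {
      death[l] <- 0; fate[l] <- "present"
    } else if (stats::runif(1) < lambda / (lambda + mu)) {
      death[l] <- end; fate[l] <- "speciation"
      queue <- c(queue, new_lineage(l, end), new_lineage(l, end))
    } else {
      death[l] <- end; fate[l] <- "extinction"
    }
  }
  # fossil sampling on extinct terminal lineages
  tip_age <- rep(NA_real_, length(parent))
  is_tip <- rep(FALSE, length(parent))
  for (l in seq_along(parent)) {
    if (fate[l] == "present") {
      is_tip[l] <- TRUE; tip_age[l] <- 0
    } else if (fate[l] == "extinction" && psi > 0) {
      dur <- birth[l] - death[l]
      nf <- stats::rpois(1, psi * dur)
      if (nf > 0) {
        times <- stats::runif(nf, min = death[l], max = birth[l])
        is_tip[l] <- TRUE
        tip_age[l] <- min(times)  # youngest sample
      }
    }
  }
  n_tips <- sum(is_tip)
  if (n_tips < max(config$min_tips, 2) || n_tips > config$max_tips)
    return(NULL)

  # prune to sampled tips, collapsing single-child chains
  kids <- split(seq_along(parent), factor(parent, levels = seq_along(parent)))
  build <- function(l) {
    if (is_tip[l])
      return(list(tip = TRUE, lineage = l, age = tip_age[l]))
    if (fate[l] != "speciation") return(NULL)
    subs <- Filter(Negate(is.null), lapply(kids[[l]], build))
    if (length(subs) == 0) return(NULL)
    if (length(subs) == 1) return(subs[[1]])
    list(tip = FALSE, age = death[l], children = subs)
  }
  top <- build(root_id)
  if (is.null(top) || isTRUE(top$tip)) return(NULL)
  if (top$age < config$min_root_age) return(NULL)
  tt <- nested_to_time_tree(top, config$strat_range_myr)
  if (!is.null(config$coverage_bins)) {
    iv <- branch_intervals(tt)
    mid <- (iv$start_age + iv$end_age) / 2
    cb <- config$coverage_bins
    for (j in seq_len(nrow(cb))) {
      n_in <- sum(mid <= cb$older[j] & mid > cb$younger[j])
      if (n_in < config$coverage_min) return(NULL)
    }
  }
  tt
}

# turn the nested (tip/age/children) structure into a time_tree
nested_to_time_tree <- function(top, strat_half) {
  tips <- list(); nodes <- list(); edges <- list()
  n_node <- 0L
  walk <- function(x) {
    if (x$tip) {
      tips[[length(tips) + 1]] <<- x
      return(list(id = -length(tips), age = x$age))  # negative = tip index
    }
    n_node <<- n_node + 1L
    my <- n_node
    nodes[[my]] <<- x$age
    for (ch in x$children) {
      r <- walk(ch)
      edges[[length(edges) + 1]] <<- c(my, r$id, x$age - r$age)
    }
    list(id = my, age = x$age)
  }
  walk(top)
  ntip <- length(tips)
  em <- do.call(rbind, edges)
  edge <- cbind(ifelse(em[, 1] > 0, em[, 1] + ntip, -em[, 1]),
                ifelse(em[, 2] > 0, em[, 2] + ntip, -em[, 2]))
  tip_ages <- vapply(tips, `[[`, numeric(1), "age")
  labels <- ifelse(tip_ages > 0, paste0("f", seq_len(ntip)),
                   paste0("t", seq_len(ntip)))
  phy <- structure(list(edge = edge, edge.length = em[, 3],
                        tip.label = labels, Nnode = n_node),
                   class = "phylo", order = "cladewise")
  rng <- cbind(older = tip_ages + ifelse(tip_ages > 0, strat_half, 0),
               younger = pmax(tip_ages - ifelse(tip_ages > 0, strat_half, 0), 0))
  rownames(rng) <- labels
  time_tree(phy, tip_ages = stats::setNames(tip_ages, labels),
            tip_age_range = rng)
}

#' Draw branch rates from epoch-specific lognormal regimes
#'
#' Each branch's relative rate is lognormal with log-mean
#' `log(regime mean) - sigma_log^2 / 2` (so the arithmetic mean equals the
#' regime mean) and log-SD `sigma_log`, where the regime is looked up at the
#' branch midpoint age (a branch crossing a regime boundary takes its
#' midpoint's regime).
#'
#' @param tree a [time_tree()].
#' @param config a [sim_config()] supplying `regimes` and `sigma_log`.
#' @param seed RNG seed.
#' @return list with `tree` (rates attached) and `truth` (per-branch data
#'   frame: midpoint age, regime mean, drawn rate).
#' @export
simulate_branch_rates <- function(tree, config, seed) {
  stopifnot(inherits(tree, "time_tree"), inherits(config, "sim_config"))
  set.seed(seed)
  iv <- branch_intervals(tree)
  mid <- (iv$start_age + iv$end_age) / 2
  reg <- config$regimes
  regime_mean <- vapply(mid, function(a) {
    j <- which(a <= reg$older & (a > reg$younger |
                                   (reg$younger == min(reg$younger) &
                                      a >= reg$younger)))[1]
    reg$mean[j]
  }, numeric(1))
  rates <- stats::rlnorm(length(mid),
                         meanlog = log(regime_mean) - config$sigma_log^2 / 2,
                         sdlog = config$sigma_log)
  tree$rate <- rates
  list(tree = tree,
       truth = data.frame(midpoint_age = mid, regime_mean = regime_mean,
                          rate = rates))
}

#' Simulate discrete characters along a rate-scaled tree
#'
#' Each character evolves by a continuous-time Markov chain: unordered
#' characters jump uniformly among the other `k - 1` states; ordered
#' characters step to a neighbouring state. The per-branch departure rate
#' from an interior state is `base_rate * rel_rate` per Myr, so a branch's
#' expected number of changes is proportional to rate times duration.
#' Root states are uniform. Simulation is by exact event sampling
#' (Gillespie), so the ground truth records the realised change count per
#' branch and character.
#'
#' @param tree a [time_tree()] with branch rates.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `matrix` (a [character_matrix()] over the tips) and
#'   `truth` (`root_states`, `k`, `ordered`, `changes` edge-by-character
#'   count matrix, `node_states`).
#' @export
simulate_characters <- function(tree, config, seed) {
  stopifnot(inherits(tree, "time_tree"), inherits(config, "sim_config"))
  if (is.null(tree$rate)) stop("tree has no branch rates")
  set.seed(seed)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  e <- phy$edge
  dur <- phy$edge.length
  # original-edge indices ordered parents-before-children
  po <- ape::reorder.phylo(phy, "postorder")
  ekey <- function(m) m[, 1] * (nn + 1) + m[, 2]
  ord <- rev(match(ekey(po$edge), ekey(e)))
  n_char <- config$n_char
  spc <- config$states_per_char
  k_vec <- if (length(spc) == 1) rep(as.integer(spc), n_char)
           else sample(spc, n_char, replace = TRUE)
  ordered <- stats::runif(n_char) < config$frac_ordered
  root_states <- vapply(k_vec, function(k) sample.int(k, 1) - 1L, integer(1))
  states <- matrix(0L, nn, n_char)
  changes <- matrix(0L, nrow(e), n_char)
  for (j in seq_len(n_char)) {
    k <- k_vec[j]
    states[ntip + 1, j] <- root_states[j]
    if (k < 2 || config$base_rate == 0) {
      states[, j] <- root_states[j]
      next
    }
    for (r in ord) {
      par_state <- states[e[r, 1], j]
      nu <- config$base_rate * tree$rate[r]
      res <- gillespie_mk(par_state, k, nu, dur[r], ordered[j])
      states[e[r, 2], j] <- res$state
      changes[r, j] <- res$n_changes
    }
  }
  tip_states <- matrix(as.character(states[seq_len(ntip), , drop = FALSE]),
                       nrow = ntip,
                       dimnames = list(phy$tip.label, NULL))
  list(matrix = character_matrix(tip_states, ordering = ordered),
       truth = list(root_states = root_states, k = k_vec, ordered = ordered,
                    changes = changes, node_states = states))
}

# exact CTMC endpoint + change count for one branch; departure rate `nu`
# from interior states (end states of an ordered chain leave at nu/2)
gillespie_mk <- function(state, k, nu, t, ordered) {
  n_changes <- 0L
  remaining <- t
  repeat {
    out_rate <- if (!ordered) nu
    else if (state == 0L || state == k - 1L) nu / 2 else nu
    if (out_rate <= 0) break
    wait <- stats::rexp(1, out_rate)
    if (wait >= remaining) break
    remaining <- remaining - wait
    state <- if (!ordered) {
      cand <- setdiff(0:(k - 1L), state)
      if (length(cand) == 1) cand else sample(cand, 1)
    } else if (state == 0L) 1L
    else if (state == k - 1L) k - 2L
    else state + sample(c(-1L, 1L), 1)
    n_changes <- n_changes + 1L
  }
  list(state = state, n_changes = n_changes)
}

#' Degrade a clean matrix with missing / inapplicable / polymorphic cells
#'
#' Cells are independently converted to missing, inapplicable, or a
#' polymorphic set (the true state plus one other state observed in the
#' column) at the configured fractions, and the conversion masks are
#' recorded so that preparation filters can be checked against known ground
#' truth.
#'
#' @param x a [character_matrix()] with fully scored single-state cells.
#' @param config a [sim_config()] supplying the fractions.
#' @param seed RNG seed.
#' @return list with `matrix` (degraded) and `masks` (logical matrices
#'   `missing`, `inapplicable`, `polymorphic`).
#' @export
degrade_matrix <- function(x, config, seed) {
  stopifnot(inherits(x, "character_matrix"), inherits(config, "sim_config"))
  set.seed(seed)
  s <- x$states
  u <- matrix(stats::runif(length(s)), nrow(s))
  m1 <- config$miss_frac
  m2 <- m1 + config$inapp_frac
  m3 <- m2 + config$poly_frac
  miss <- u < m1
  inapp <- u >= m1 & u < m2
  poly <- u >= m2 & u < m3
  out <- s
  out[miss] <- MISSING_TOKEN
  out[inapp] <- INAPPLICABLE_TOKEN
  if (any(poly)) {
    for (idx in which(poly)) {
      j <- (idx - 1) %/% nrow(s) + 1
      col_states <- unique(s[, j])
      others <- setdiff(col_states, s[idx])
      if (!length(others)) { poly[idx] <- FALSE; next }
      other <- if (length(others) == 1) others else sample(others, 1)
      out[idx] <- make_poly_token(c(s[idx], other))
    }
  }
  list(matrix = character_matrix(out, ordering = x$ordering,
                                 character_labels = x$character_labels),
       masks = list(missing = miss, inapplicable = inapp, polymorphic = poly))
}

#' Generate a pseudo-posterior sample of dated trees
#'
#' Produces `n_pseudo_posterior` copies of a rate-annotated tree with
#' internal node ages jittered by a truncated normal (respecting
#' parent-older-than-child ordering and fixed tip ages) and branch rates
#' redrawn lognormally about the true rates. Topology is held fixed by
#' default; with `nni_prob > 0`, eligible internal branches undergo random
#' nearest-neighbour interchanges where node ages permit, for
#' topology-uncertainty experiments.
#'
#' @param sim a [simulate_branch_rates()] result (or a rate-carrying
#'   [time_tree()]).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `sample` (a [tree_sample()]) and `truth` (the
#'   generating tree).
#' @export
make_pseudo_posterior <- function(sim, config, seed) {
  tree <- if (inherits(sim, "time_tree")) sim else sim$tree
  stopifnot(inherits(tree, "time_tree"), inherits(config, "sim_config"))
  if (is.null(tree$rate)) stop("tree has no branch rates")
  set.seed(seed)
  n <- config$n_pseudo_posterior
  trees <- vector("list", n)
  for (i in seq_len(n)) trees[[i]] <- jitter_tree(tree, config)
  list(sample = tree_sample(trees, label = "pseudo-posterior"), truth = tree)
}

jitter_tree <- function(tree, config) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  age <- tree$node_age
  e <- phy$edge

  if (config$nni_prob > 0) {
    sw <- nni_perturb(phy, age, config$nni_prob)
    phy <- sw$phy; e <- phy$edge
    attr(phy, "order") <- NULL
  }

  # max sampled-tip age within each node's subtree bounds the jitter below
  po <- ape::reorder.phylo(phy, "postorder")
  floor_age <- c(age[seq_len(ntip)], rep(-Inf, phy$Nnode))
  for (r in seq_len(nrow(po$edge)))
    floor_age[po$edge[r, 1]] <- max(floor_age[po$edge[r, 1]],
                                    floor_age[po$edge[r, 2]])
  new_age <- age
  if (config$age_jitter_sd > 0) {
    parent_of <- integer(nn)
    parent_of[e[, 2]] <- e[, 1]
    pre <- rev(seq_len(nrow(po$edge)))
    # root first
    root <- ntip + 1L
    new_age[root] <- rtruncnorm1(age[root], config$age_jitter_sd,
                                 lo = floor_age[root], hi = Inf)
    for (r in pre) {
      ch <- po$edge[r, 2]
      if (ch <= ntip) next
      new_age[ch] <- rtruncnorm1(age[ch], config$age_jitter_sd,
                                 lo = floor_age[ch],
                                 hi = new_age[po$edge[r, 1]])
    }
  }
  lens <- new_age[e[, 1]] - new_age[e[, 2]]
  phy$edge.length <- lens
  rates <- tree$rate
  if (config$rate_resample_sd > 0)
    rates <- stats::rlnorm(length(rates),
                           meanlog = log(rates) -
                             config$rate_resample_sd^2 / 2,
                           sdlog = config$rate_resample_sd)
  time_tree(phy, tip_ages = stats::setNames(age[seq_len(ntip)],
                                            phy$tip.label),
            tip_age_range = tree$tip_age_range, rates = rates)
}

# one truncated-normal draw by inverse-CDF (exact, no rejection loop)
rtruncnorm1 <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi <= plo) return(max(lo, min(mean, hi)))
  stats::qnorm(stats::runif(1, plo, phi), mean, sd)
}

# random NNI moves on eligible internal branches where ages permit
nni_perturb <- function(phy, age, prob) {
  ntip <- length(phy$tip.label)
  e <- phy$edge
  internal <- which(e[, 2] > ntip)
  for (r in internal) {
    if (stats::runif(1) >= prob) next
    u <- e[r, 1]; v <- e[r, 2]
    ch_v <- which(e[, 1] == v)
    ch_u <- setdiff(which(e[, 1] == u), r)
    if (!length(ch_v) || !length(ch_u)) next
    a <- ch_v[1]      # child of v to move up
    s <- ch_u[1]      # sibling subtree to move down
    # validity: v must stay older than s's top; u older than a's top
    if (age[v] <= age[e[s, 2]] || age[u] <= age[e[a, 2]]) next
    tmp <- e[a, 2]
    e[a, 2] <- e[s, 2]
    e[s, 2] <- tmp
    e[a, 1] <- v; e[s, 1] <- u
  }
  phy$edge <- e
  list(phy = phy)
}
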