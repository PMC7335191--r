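#' Ancestral state estimation under the Mk model
#'
#' Augments a character matrix with one pseudo-taxon row per internal node of
#' a fixed dated tree, for morphospace construction. For each character the
#' per-character substitution rate is estimated by maximum likelihood under a
#' symmetric Mk model (all exchanges equal for unordered characters; a
#' nearest-neighbour stepping chain for ordered ones), tips with missing
#' scores contribute flat partial likelihoods, and each internal node is
#' assigned the state with the highest marginal probability. Nodes whose best
#' state falls below the confidence threshold are scored as missing, so
#' low-information reconstructions do not masquerade as data.
#'
#' @param x a prepared [character_matrix()] (no inapplicable/polymorphic
#'   cells).
#' @param tree a [time_tree()] or `"phylo"` with branch lengths in Myr; all
#'   tips must be rows of `x`.
#' @param method reconstruction method; `"mk_marginal"` (marginal maximum
#'   likelihood) is currently implemented.
#' @param conf confidence threshold in `(0, 1]`: below it a node's character
#'   is scored missing (default 0.80).
#' @return a [character_matrix()] with `n_taxa(x) + Nnode` rows; node rows
#'   are labelled `node_<id>` (or the tree's node labels when present).
#' @export
ancestral_states <- function(x, tree, method = c("mk_marginal"),
                             conf = 0.80) {
  method <- match.arg(method)
  stopifnot(inherits(x, "character_matrix"))
  phy <- if (inherits(tree, "time_tree")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"))
  absent <- setdiff(phy$tip.label, taxon_names(x))
  if (length(absent))
    stop("tree tip(s) absent from matrix: ", paste(absent, collapse = ", "))
  if (any(is_inapplicable(x$states)) || any(is_polymorphic(x$states)))
    stop("matrix must be prepared (no inapplicable or polymorphic cells)")

  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  node_labels <- if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
    phy$node.label else paste0("node_", ntip + seq_len(nnode))

  anc <- matrix(MISSING_TOKEN, nrow = nnode, ncol = n_characters(x),
                dimnames = list(node_labels, NULL))
  for (j in seq_len(n_characters(x))) {
    obs <- x$states[phy$tip.label, j]
    scored <- !is_missing(obs)
    vals <- unique(obs[scored])
    if (length(vals) == 0) next           # nothing to reconstruct
    if (length(vals) == 1) {              # invariant character
      anc[, j] <- vals
      next
    }
    space <- if (x$ordering[j]) {
      as.character(seq(min(as.integer(vals)), max(as.integer(vals))))
    } else sort(vals)
    marg <- mk_marginal(phy, obs, space, ordered = x$ordering[j])
    best <- apply(marg, 1, which.max)
    bestp <- marg[cbind(seq_len(nnode), best)]
    tok <- space[best]
    tok[bestp < conf] <- MISSING_TOKEN
    anc[, j] <- tok
  }
  character_matrix(rbind(x$states, anc), ordering = x$ordering,
                   character_labels = x$character_labels)
}

# marginal posterior state probabilities at internal nodes for one discrete
# character under Mk; rate estimated by ML unless supplied. Nnode x k matrix
mk_marginal <- function(phy, obs, space, ordered, rate = NULL) {
  k <- length(space)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  # unit-rate symmetric generator: complete graph (unordered) or path chain
  adj <- if (ordered && k > 1) {
    a <- matrix(0, k, k)
    for (i in seq_len(k - 1)) { a[i, i + 1] <- 1; a[i + 1, i] <- 1 }
    a
  } else {
    a <- matrix(1, k, k); diag(a) <- 0; a
  }
  q0 <- adj
  diag(q0) <- -rowSums(adj)
  eg <- eigen(q0, symmetric = TRUE)

  po <- ape::reorder.phylo(phy, "postorder")
  e <- po$edge
  len <- po$edge.length
  nn <- ntip + nnode

  # tip conditionals
  tipl <- matrix(1, ntip, k)
  for (i in seq_len(ntip)) {
    if (!is_missing(obs[i])) {
      tipl[i, ] <- 0
      tipl[i, match(obs[i], space)] <- 1
    }
  }

  pmat <- function(rate, t) {
    eg$vectors %*% (exp(rate * eg$values * t) * t(eg$vectors))
  }

  down_pass <- function(rate) {
    dn <- matrix(1, nn, k)
    dn[seq_len(ntip), ] <- tipl
    scale_log <- 0
    msg <- matrix(NA_real_, nrow(e), k)  # P(t) %*% L_child per edge
    for (r in seq_len(nrow(e))) {
      p <- pmat(rate, len[r])
      m <- as.vector(p %*% dn[e[r, 2], ])
      msg[r, ] <- m
      dn[e[r, 1], ] <- dn[e[r, 1], ] * m
      mx <- max(dn[e[r, 1], ])
      if (mx > 0 && mx < 1e-12) {
        dn[e[r, 1], ] <- dn[e[r, 1], ] / mx
        scale_log <- scale_log + log(mx)
      }
    }
    list(dn = dn, msg = msg, scale_log = scale_log)
  }
  loglik <- function(rate) {
    d <- down_pass(rate)
    root <- e[nrow(e), 1]
    log(sum(d$dn[root, ] / k)) + d$scale_log
  }
  if (is.null(rate)) {
    h <- sum(len) / nrow(e)
    opt <- stats::optimize(function(lr) loglik(exp(lr)),
                           interval = log(c(1e-6, 100) / max(h, 1e-8)),
                           maximum = TRUE)
    rate <- exp(opt$maximum)
  }

  d <- down_pass(rate)
  root <- e[nrow(e), 1]
  # up-pass: up[v,] = likelihood of all data outside v's subtree given the
  # state at v; root prior uniform
  up <- matrix(NA_real_, nn, k)
  up[root, ] <- 1 / k
  for (r in rev(seq_len(nrow(e)))) {
    par <- e[r, 1]; child <- e[r, 2]
    if (child <= ntip) next
    sib <- d$dn[par, ] / d$msg[r, ]  # product of the other children's messages
    sib[!is.finite(sib)] <- 0
    pre <- up[par, ] * sib
    p <- pmat(rate, len[r])
    up[child, ] <- as.vector(t(p) %*% pre)
  }
  marg <- matrix(NA_real_, nnode, k)
  for (v in (ntip + 1):nn) {
    w <- d$dn[v, ] * up[v, ]
    tot <- sum(w)
    marg[v - ntip, ] <- if (tot > 0) w / tot else rep(1 / k, k)
  }
  marg
}
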