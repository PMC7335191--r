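# fixture builders and independent oracles used across the suite

# random prepared character matrix (single-state tokens + "?" only)
rand_cm <- function(seed, n_taxa = 10, n_char = 20, frac_ordered = 0.3,
                    miss = 0.1, max_state = 3) {
  set.seed(seed)
  s <- matrix(as.character(sample(0:max_state, n_taxa * n_char, TRUE)),
              n_taxa, n_char,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  s[matrix(runif(length(s)) < miss, n_taxa)] <- "?"
  character_matrix(s, ordering = seq_len(n_char) <= frac_ordered * n_char)
}

# random raw matrix including inapplicable and polymorphic cells
rand_cm_raw <- function(seed, n_taxa = 10, n_char = 20, miss = 0.1,
                        inapp = 0.05, poly = 0.05, max_state = 3) {
  set.seed(seed)
  s <- matrix(as.character(sample(0:max_state, n_taxa * n_char, TRUE)),
              n_taxa, n_char,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  u <- matrix(runif(length(s)), n_taxa)
  s[u < miss] <- "?"
  s[u >= miss & u < miss + inapp] <- "-"
  pol <- u >= miss + inapp & u < miss + inapp + poly
  s[pol] <- "{01}"
  character_matrix(s, ordering = rep(FALSE, n_char))
}

# naive per-pair double loop MORD (independent of the package implementation)
mord_oracle <- function(cm) {
  s <- cm$states
  n <- nrow(s)
  rng <- vapply(seq_len(ncol(s)), function(j) {
    v <- suppressWarnings(as.numeric(s[, j]))
    v <- v[!is.na(v)]
    if (length(v)) diff(range(v)) else 0
  }, numeric(1))
  d <- matrix(0, n, n, dimnames = list(rownames(s), rownames(s)))
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    num <- 0; den <- 0; comp <- 0
    for (j in seq_len(ncol(s))) {
      a <- s[i, j]; b <- s[k, j]
      if (a == "?" || b == "?") next
      comp <- comp + 1
      if (cm$ordering[j]) {
        if (rng[j] == 0) next
        num <- num + abs(as.numeric(a) - as.numeric(b))
        den <- den + rng[j]
      } else {
        num <- num + (a != b)
        den <- den + 1
      }
    }
    d[i, k] <- d[k, i] <- if (den > 0) num / den else if (comp > 0) 0 else NA
  }
  d
}

# orthogonal-Procrustes residual after centring (rotation/reflection only)
procrustes_resid <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  sv <- svd(crossprod(xc, yc))       # minimise ||xc R - yc|| over orthogonal R
  rot <- sv$u %*% t(sv$v)
  sqrt(sum((xc %*% rot - yc)^2) / nrow(x))
}

# hand-rolled tricube local-linear smoother at evaluation points
local_linear_oracle <- function(x, y, span, grid) {
  n <- length(x)
  q <- floor(n * span)
  vapply(grid, function(g) {
    dd <- abs(x - g)
    h <- sort(dd)[q]
    w <- pmax(1 - (dd / h)^3, 0)^3
    ok <- w > 0
    fit <- stats::lm.wfit(cbind(1, x[ok] - g), y[ok], w[ok])
    fit$coefficients[1]
  }, numeric(1))
}

# tiny dated tree with per-edge rates, built directly from newick
toy_time_tree <- function(newick = "((a:1,b:1):1,(c:0.5,d:0.5):1.5);",
                          rates = NULL, tip_ages = NULL) {
  phy <- ape::read.tree(text = newick)
  time_tree(phy, rates = rates, tip_ages = tip_ages)
}

# exhaustive-enumeration marginal ancestral probabilities under Mk with a
# fixed rate (sums over all internal-node state assignments)
mk_marginal_enum <- function(phy, obs, space, ordered, rate) {
  k <- length(space)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  adj <- if (ordered && k > 1) {
    a <- matrix(0, k, k)
    for (i in seq_len(k - 1)) { a[i, i + 1] <- 1; a[i + 1, i] <- 1 }
    a
  } else { a <- matrix(1, k, k); diag(a) <- 0; a }
  q0 <- adj; diag(q0) <- -rowSums(adj)
  eg <- eigen(q0, symmetric = TRUE)
  pmat <- function(t) eg$vectors %*% (exp(rate * eg$values * t) * t(eg$vectors))
  e <- phy$edge
  plist <- lapply(phy$edge.length, pmat)
  assigns <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  post <- matrix(0, nnode, k)
  tip_idx <- match(obs, space)  # NA = missing
  for (r in seq_len(nrow(assigns))) {
    st <- assigns[r, ]
    state_of <- function(node) {
      if (node <= ntip) tip_idx[node] else st[node - ntip]
    }
    lik <- 1 / k
    for (b in seq_len(nrow(e))) {
      sp <- state_of(e[b, 1]); sc <- state_of(e[b, 2])
      lik <- lik * if (is.na(sc)) 1 else plist[[b]][sp, sc]
    }
    for (v in seq_len(nnode)) post[v, st[v]] <- post[v, st[v]] + lik
  }
  sweep(post, 1, rowSums(post), "/")
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
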