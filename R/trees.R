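#' Time-calibrated trees with branch rates
#'
#' A `time_tree` wraps an [ape::read.tree()]-style `"phylo"` topology with
#' the temporal and rate information the downstream analyses need: node ages
#' in Ma before present, stratigraphic age ranges for fossil tips, and a
#' relative clock rate per branch. Branch lengths are durations in Myr; ages
#' are anchored so that the youngest sampled tip sits at its configured age
#' (0 Ma for extant tips).
#'
#' @param phy a `"phylo"` tree with `edge.length` in Myr.
#' @param tip_ages optional named numeric vector of tip ages (Ma); missing
#'   names default to 0 (extant).
#' @param tip_age_range optional two-column matrix (older, younger bounds in
#'   Ma) with tip names as row names; defaults to point ranges at each tip's
#'   implied age.
#' @param rates optional numeric vector of relative clock rates, one per row
#'   of `phy$edge`; must be positive where present.
#' @param support optional numeric vector of branch support values in (0,1],
#'   one per edge (NA allowed).
#' @return an object of class `time_tree` with elements `phylo`, `node_age`
#'   (length `Ntip + Nnode`), `tip_age_range`, `rate`, `support`.
#' @export
time_tree <- function(phy, tip_ages = NULL, tip_age_range = NULL,
                      rates = NULL, support = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length(s)")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  ages_cfg <- rep(0, ntip)
  names(ages_cfg) <- phy$tip.label
  if (!is.null(tip_ages)) {
    unknown <- setdiff(names(tip_ages), phy$tip.label)
    if (length(unknown)) stop("unknown tip(s) in tip_ages: ",
                              paste(unknown, collapse = ", "))
    ages_cfg[names(tip_ages)] <- tip_ages
  }

  depth <- node_depths(phy)
  # anchor: the youngest configured tip (ties: the deepest) at its age
  tip_depth <- depth[seq_len(ntip)]
  cand <- which(ages_cfg == min(ages_cfg))
  anchor <- cand[which.max(tip_depth[cand])]
  root_age <- tip_depth[anchor] + ages_cfg[anchor]
  node_age <- root_age - depth
  names(node_age) <- c(phy$tip.label, rep("", nnode))
  mism <- abs(node_age[seq_len(ntip)] - ages_cfg) > 1e-6
  if (any(mism))
    warning("configured tip age(s) inconsistent with branch lengths: ",
            paste(phy$tip.label[mism], collapse = ", "))

  if (is.null(tip_age_range)) {
    tip_age_range <- cbind(older = node_age[seq_len(ntip)],
                           younger = node_age[seq_len(ntip)])
    rownames(tip_age_range) <- phy$tip.label
  } else {
    tip_age_range <- tip_age_range[phy$tip.label, , drop = FALSE]
  }

  if (!is.null(rates)) {
    if (length(rates) != nrow(phy$edge))
      stop("`rates` must have one value per branch")
    if (any(rates[!is.na(rates)] <= 0))
      stop("branch rates must be positive")
  }
  out <- structure(
    list(phylo = phy, node_age = node_age, tip_age_range = tip_age_range,
         rate = rates, support = support),
    class = "time_tree"
  )
  validate_time_tree(out)
  out
}

# depth of every node from the root (root = 0), parents before children
node_depths <- function(phy) {
  depth <- numeric(length(phy$tip.label) + phy$Nnode)
  po <- ape::reorder.phylo(phy, "postorder")
  e <- po$edge
  len <- po$edge.length
  for (k in rev(seq_len(nrow(e)))) depth[e[k, 2]] <- depth[e[k, 1]] + len[k]
  depth
}

#' @rdname time_tree
#' @param x a `time_tree`.
#' @export
root_age <- function(x) {
  stopifnot(inherits(x, "time_tree"))
  ntip <- length(x$phylo$tip.label)
  unname(x$node_age[ntip + 1])
}

validate_time_tree <- function(x, tol = 1e-9) {
  e <- x$phylo$edge
  dur <- x$node_age[e[, 1]] - x$node_age[e[, 2]]
  zero <- x$phylo$edge.length == 0
  if (any(dur[!zero] <= 0))
    stop("parent ages must exceed child ages (found non-positive duration)")
  ntip <- length(x$phylo$tip.label)
  implied <- x$node_age[seq_len(ntip)]
  r <- x$tip_age_range
  bad <- implied > r[, 1] + tol | implied < r[, 2] - tol
  if (any(bad))
    warning("tip age outside stated stratigraphic range: ",
            paste(x$phylo$tip.label[bad], collapse = ", "))
  invisible(x)
}

#' @export
print.time_tree <- function(x, ...) {
  ntip <- length(x$phylo$tip.label)
  fossil <- sum(x$node_age[seq_len(ntip)] > 1e-8)
  cat(sprintf("time_tree: %d tips (%d fossil), root age %.2f Ma%s\n",
              ntip, fossil, root_age(x),
              if (!is.null(x$rate)) ", branch rates present" else ""))
  invisible(x)
}

# per-branch age intervals: start (older) and end (younger) in Ma
branch_intervals <- function(x) {
  e <- x$phylo$edge
  data.frame(start_age = unname(x$node_age[e[, 1]]),
             end_age = unname(x$node_age[e[, 2]]))
}

#' Ordered samples of dated trees
#'
#' A `tree_sample` is an ordered collection of [time_tree()] objects over an
#' identical taxon set, typically a (pseudo-)posterior sample from a dated
#' Bayesian analysis.
#'
#' @param trees list of `time_tree` objects.
#' @param label optional source tag.
#' @return an object of class `tree_sample`.
#' @export
tree_sample <- function(trees, label = NULL) {
  if (!length(trees)) stop("tree sample must be non-empty")
  if (!all(vapply(trees, inherits, logical(1), "time_tree")))
    stop("all elements must be time_tree objects")
  taxa <- sort(trees[[1]]$phylo$tip.label)
  same <- vapply(trees, function(t) identical(sort(t$phylo$tip.label), taxa),
                 logical(1))
  if (!all(same)) stop("all trees must share one taxon set")
  structure(list(trees = trees, label = label), class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("tree_sample: %d trees, %d taxa%s\n", length(x$trees),
              length(x$trees[[1]]$phylo$tip.label),
              if (!is.null(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.tree_sample <- function(x) length(x$trees)
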