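#' Cailliez additive constant
#'
#' The smallest constant `c >= 0` such that adding `c` to every off-diagonal
#' dissimilarity makes the configuration Euclidean, i.e. the double-centred
#' Gower matrix of the corrected dissimilarities has no negative eigenvalues.
#' Computed by Cailliez's closed-form construction (the largest eigenvalue of
#' a 2n x 2n block matrix), with a bisection search over the smallest
#' PSD-restoring constant as a fallback when the eigenproblem fails to
#' produce a finite value.
#'
#' @param d a symmetric dissimilarity matrix, a `dist`, or a `mord_dist`.
#' @param tol eigenvalue tolerance for "no negative eigenvalues".
#' @return a single nonnegative number.
#' @references Cailliez, F. (1983). The analytical solution of the additive
#'   constant problem. Psychometrika 48, 305-308.
#' @export
cailliez_constant <- function(d, tol = 1e-8) {
  d <- as_dissim_matrix(d)
  n <- nrow(d)
  delta1 <- gower_center(d^2)
  delta2 <- gower_center(d)  # note: centring -0.5*J d J
  big <- rbind(cbind(matrix(0, n, n), 2 * delta1),
               cbind(-diag(n), -4 * delta2))
  ev <- eigen(big, only.values = TRUE)$values
  re <- Re(ev[abs(Im(ev)) < 1e-8 * (1 + max(abs(Re(ev))))])
  cc <- if (length(re)) max(re) else NA_real_
  if (!is.finite(cc)) cc <- cailliez_bisection(d, tol = tol)
  max(0, cc)
}

# smallest c making -0.5 J (d + c)^2 J PSD, by bisection
cailliez_bisection <- function(d, tol = 1e-8, c_tol = 1e-9, max_iter = 200) {
  psd_ok <- function(cc) {
    dd <- d + cc
    diag(dd) <- 0
    ev <- eigen(gower_center(dd^2), symmetric = TRUE,
                only.values = TRUE)$values
    min(ev) >= -tol * max(1, max(abs(ev)))
  }
  if (psd_ok(0)) return(0)
  lo <- 0
  hi <- max(d)
  it <- 0
  while (!psd_ok(hi)) {
    hi <- hi * 2
    it <- it + 1
    if (it > 60) stop("Cailliez bisection failed to bracket a PSD constant")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (psd_ok(mid)) hi <- mid else lo <- mid
    if (hi - lo < c_tol) break
  }
  hi
}

gower_center <- function(a) {
  n <- nrow(a)
  jm <- diag(n) - matrix(1 / n, n, n)
  -0.5 * jm %*% a %*% jm
}

as_dissim_matrix <- function(d) {
  if (inherits(d, "mord_dist")) {
    if (nrow(d$flagged_pairs))
      stop("distance matrix has pair(s) with no comparable characters: ",
           paste(paste(d$flagged_pairs$taxon_a, d$flagged_pairs$taxon_b,
                       sep = "--"), collapse = ", "))
    d <- d$d
  }
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("`d` must be a square dissimilarity matrix")
  if (anyNA(d)) stop("`d` contains NA dissimilarities")
  if (max(abs(d - t(d))) > 1e-8) stop("`d` must be symmetric")
  d
}

#' Principal coordinates analysis with optional Cailliez correction
#'
#' Classical multidimensional scaling: the squared dissimilarities are
#' double-centred (`-1/2 J D^2 J`), eigendecomposed, and scores are formed
#' from eigenvectors scaled by the square roots of their eigenvalues. With
#' `correction = "cailliez"` the [cailliez_constant()] is added to all
#' off-diagonal dissimilarities first, so the corrected configuration is
#' Euclidean and all retained axes have positive eigenvalues. Axes whose
#' eigenvalue is below `1e-8` times the largest are dropped as numerical
#' noise.
#'
#' @param d a symmetric dissimilarity matrix, `dist`, or [mord_distance()]
#'   result.
#' @param correction `"cailliez"` (default) or `"none"`.
#' @return an object of class `pcoa_ord`: `scores` (labels x axes),
#'   `eigenvalues` (descending, retained axes), `eigenvalues_all`,
#'   `cailliez_constant`, `axes_retained`, `variance_explained` (fractions of
#'   the summed positive eigenvalues), and `ages` (provenance slot filled by
#'   [build_morphospace()]).
#' @export
pcoa <- function(d, correction = c("cailliez", "none")) {
  correction <- match.arg(correction)
  d <- as_dissim_matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("obj", seq_len(nrow(d)))
  cc <- 0
  if (correction == "cailliez") {
    cc <- cailliez_constant(d)
    if (cc > 0) {
      d <- d + cc
      diag(d) <- 0
    }
  }
  b <- gower_center(d^2)
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lambda <- eg$values
  tol <- 1e-8 * max(abs(lambda))
  keep <- which(lambda > tol)
  if (!length(keep))
    stop("degenerate ordination: no eigenvalue above tolerance")
  scores <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lambda[keep]), length(keep))
  rownames(scores) <- labels
  colnames(scores) <- paste0("PCo", seq_along(keep))
  pos_sum <- sum(lambda[lambda > 0])
  structure(
    list(scores = scores, eigenvalues = lambda[keep],
         eigenvalues_all = lambda, cailliez_constant = cc,
         axes_retained = length(keep),
         variance_explained = lambda[keep] / pos_sum,
         labels = labels, ages = NULL),
    class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("pcoa_ord: %d objects, %d axes retained (Cailliez c = %.4g)\n",
              nrow(x$scores), x$axes_retained, x$cailliez_constant))
  cat(sprintf("  first two axes explain %.1f%% + %.1f%% of positive variance\n",
              100 * x$variance_explained[1],
              if (x$axes_retained > 1) 100 * x$variance_explained[2] else 0))
  invisible(x)
}

#' @export
plot.pcoa_ord <- function(x, axes = c(1, 2), col = NULL, ...) {
  a1 <- axes[1]; a2 <- axes[2]
  if (is.null(col)) {
    col <- "grey25"
    if (!is.null(x$ages) && "type" %in% names(x$ages))
      col <- ifelse(x$ages$type == "node", "tomato", "grey25")
  }
  graphics::plot(x$scores[, a1], x$scores[, a2], col = col, pch = 19,
       xlab = sprintf("PCo%d (%.1f%%)", a1, 100 * x$variance_explained[a1]),
       ylab = sprintf("PCo%d (%.1f%%)", a2, 100 * x$variance_explained[a2]),
       ...)
  invisible(x)
}
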