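#' Maximum observable rescaled distance (MORD) between taxa
#'
#' For every pair of taxa, over the characters both are scored for, the
#' per-character difference is `|x_i - x_j|` for ordered characters and a 0/1
#' mismatch indicator for unordered ones; the pair's distance is the summed
#' difference divided by the summed maximum observable difference (the
#' column's observed state range for ordered characters, 1 for unordered).
#' MORD is therefore bounded in `[0, 1]` and robust to the incomparable-cell
#' structure of palaeontological matrices.
#'
#' The input must already be prepared: no inapplicable and no polymorphic
#' cells (see [prep_pipeline()]). Pairs with zero mutually scored characters
#' have no defined distance; they are returned as `NA` and listed in
#' `flagged_pairs`, and ordination refuses such matrices.
#'
#' @param x a prepared [character_matrix()].
#' @return an object of class `mord_dist`: list with `d` (symmetric distance
#'   matrix), `comparable` (per-pair counts of mutually scored characters),
#'   and `flagged_pairs` (data frame of pairs with no comparable characters).
#' @references Lloyd, G. T. (2016). Estimating morphological diversity and
#'   tempo with discrete character-taxon matrices. Biological Journal of the
#'   Linnean Society 118, 131-151.
#' @export
mord_distance <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  s <- x$states
  if (any(is_inapplicable(s)))
    stop("matrix contains inapplicable cells; run the preparation pipeline first")
  if (any(is_polymorphic(s)))
    stop("matrix contains polymorphic cells; run the preparation pipeline first")
  n <- nrow(s)
  if (n < 2) stop("need at least 2 taxa")
  scored <- !is_missing(s)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (j in seq_len(ncol(s))) {
    sc <- scored[, j]
    if (sum(sc) < 2) next
    v <- suppressWarnings(as.numeric(s[, j]))
    both <- outer(sc, sc, "&")
    if (x$ordering[j]) {
      rng <- diff(range(v[sc]))
      if (rng == 0) next  # constant column: nothing observable
      dlt <- abs(outer(v, v, "-"))
      dlt[!both] <- 0
      num <- num + ifelse(both, dlt, 0)
      den <- den + rng * both
    } else {
      # unordered: identity comparison on tokens
      mis <- outer(s[, j], s[, j], "!=")
      num <- num + ifelse(both & mis, 1, 0)
      den <- den + both
    }
  }
  comparable <- tcrossprod(scored * 1L)
  d <- ifelse(den > 0, num / den, ifelse(comparable > 0, 0, NA_real_))
  diag(d) <- 0
  dimnames(d) <- list(rownames(s), rownames(s))
  dimnames(comparable) <- dimnames(d)
  flagged <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)
  flagged_pairs <- data.frame(
    taxon_a = rownames(s)[flagged[, 1]],
    taxon_b = rownames(s)[flagged[, 2]],
    stringsAsFactors = FALSE)
  structure(list(d = d, comparable = comparable,
                 flagged_pairs = flagged_pairs),
            class = "mord_dist")
}

#' @export
print.mord_dist <- function(x, ...) {
  n <- nrow(x$d)
  cat(sprintf("mord_dist: %d taxa, distances in [%.3f, %.3f]\n", n,
              min(x$d, na.rm = TRUE), max(x$d, na.rm = TRUE)))
  if (nrow(x$flagged_pairs))
    cat(sprintf("  %d pair(s) with no comparable characters (flagged)\n",
                nrow(x$flagged_pairs)))
  invisible(x)
}

#' @export
as.dist.mord_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}
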