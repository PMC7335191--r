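#' Assign labelled age ranges to time bins
#'
#' Under the default `"intersection"` rule a label joins every bin its age
#' range overlaps (a fossil known from 253--249 Ma counts in both a 260--252
#' and a 252--247 bin); point ages join the single containing bin, with the
#' older bound inclusive and the younger bound exclusive. Under `"midpoint"`
#' each label joins only the bin containing its range midpoint.
#'
#' @param ages data frame with columns `label`, `older`, `younger` (Ma); the
#'   `ages` slot of a [build_morphospace()] result has this shape.
#' @param bins a [time_bins()] set.
#' @param rule `"intersection"` (default) or `"midpoint"`.
#' @return named list (one element per bin) of label vectors.
#' @export
assign_to_bins <- function(ages, bins, rule = c("intersection", "midpoint")) {
  rule <- match.arg(rule)
  stopifnot(inherits(bins, "time_bins"))
  need <- c("label", "older", "younger")
  stopifnot(all(need %in% names(ages)))
  bad <- is.na(ages$older) | is.na(ages$younger)
  if (any(bad))
    stop("label(s) without age: ", paste(ages$label[bad], collapse = ", "))
  older <- ages$older
  younger <- ages$younger
  if (rule == "midpoint") {
    mid <- (older + younger) / 2
    older <- mid
    younger <- mid
  }
  mem <- bin_membership(older, younger, bins)
  out <- lapply(seq_len(nrow(bins)), function(j) ages$label[mem[, j]])
  names(out) <- bins$name
  out
}

#' Sum of variances disparity
#'
#' The disparity of a set of points in an ordination: the per-axis variances
#' of their scores summed over all retained axes. With the population
#' denominator `n` (the default) this equals the mean squared distance to
#' the group centroid, and it is invariant under orthogonal rotation of the
#' axes.
#'
#' @param ord a `pcoa_ord` from [pcoa()] or [build_morphospace()].
#' @param labels subset of `ord$labels` (default all).
#' @param denominator `"n"` (population variance, default) or `"n-1"`.
#' @return a single nonnegative number; 0 for a single point.
#' @export
sum_of_variances <- function(ord, labels = NULL,
                             denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(ord, "pcoa_ord"))
  if (is.null(labels)) labels <- ord$labels
  if (!length(labels)) stop("empty label subset")
  idx <- match(labels, ord$labels)
  if (anyNA(idx))
    stop("unknown label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  sc <- ord$scores[idx, , drop = FALSE]
  n <- nrow(sc)
  ctr <- colMeans(sc)
  ss <- sum(sweep(sc, 2, ctr)^2)
  if (denominator == "n") ss / n
  else if (n > 1) ss / (n - 1) else 0
}

#' Bootstrapped disparity per time bin
#'
#' For each bin, resamples its members with replacement (same size) `n_boot`
#' times and computes [sum_of_variances()] on each replicate, giving the
#' bootstrap distribution summarised in published disparity-through-time box
#' plots. Bins with no members are flagged empty and carry no fabricated
#' values.
#'
#' @param ord a `pcoa_ord`.
#' @param assignment named list of per-bin label vectors from
#'   [assign_to_bins()].
#' @param bins the [time_bins()] used for the assignment.
#' @param n_boot bootstrap replicates per bin (default 100).
#' @param seed RNG seed (required, for reproducible replicate vectors).
#' @param denominator passed to [sum_of_variances()].
#' @return an object of class `disparity_dtt` (a time-bin series): `bins`,
#'   `values` (list of replicate vectors), `members`, and `summaries` (per
#'   bin: n, observed statistic, bootstrap mean/median/quartiles/sd).
#' @export
bootstrap_disparity <- function(ord, assignment, bins, n_boot = 100, seed,
                                denominator = "n") {
  stopifnot(inherits(ord, "pcoa_ord"), inherits(bins, "time_bins"))
  if (missing(seed)) stop("`seed` is required for reproducibility")
  if (n_boot < 1) stop("n_boot must be >= 1")
  set.seed(seed)
  values <- vector("list", nrow(bins))
  names(values) <- bins$name
  observed <- rep(NA_real_, nrow(bins))
  for (j in seq_len(nrow(bins))) {
    members <- assignment[[bins$name[j]]]
    if (is.null(members) || length(members) < 1) next
    observed[j] <- sum_of_variances(ord, members, denominator)
    values[[j]] <- vapply(seq_len(n_boot), function(b)
      sum_of_variances(ord,
                       members[sample.int(length(members),
                                          length(members), replace = TRUE)],
                       denominator),
      numeric(1))
  }
  summaries <- data.frame(
    bin = bins$name,
    older = bins$older, younger = bins$younger,
    n = vapply(bins$name, function(b) length(assignment[[b]]), 1L),
    observed = observed,
    mean = vapply(values, function(v) if (is.null(v)) NA_real_ else mean(v), 1),
    median = vapply(values, function(v) if (is.null(v)) NA_real_ else stats::median(v), 1),
    q1 = vapply(values, function(v) if (is.null(v)) NA_real_ else unname(stats::quantile(v, .25)), 1),
    q3 = vapply(values, function(v) if (is.null(v)) NA_real_ else unname(stats::quantile(v, .75)), 1),
    sd = vapply(values, function(v) if (is.null(v)) NA_real_ else stats::sd(v), 1),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(bins = bins, values = values,
                 members = assignment[bins$name], summaries = summaries,
                 n_boot = n_boot, statistic = "sum_of_variances"),
            class = c("disparity_dtt", "bin_series"))
}

#' Disparity through time
#'
#' End-to-end disparity series: assigns the ordination's labels to time bins
#' by their recorded age ranges and bootstraps the sum of variances in each
#' bin. Empty bins are reported as absent, never interpolated.
#'
#' @param ord a `pcoa_ord` with an `ages` provenance slot (see
#'   [build_morphospace()]).
#' @param bins a [time_bins()] set.
#' @param rule bin-assignment rule, see [assign_to_bins()].
#' @param n_boot,seed,denominator passed to [bootstrap_disparity()].
#' @param include_nodes include internal-node pseudo-taxa (default `TRUE`);
#'   set `FALSE` to bin sampled tips only.
#' @return a `disparity_dtt` object.
#' @export
disparity_through_time <- function(ord, bins, rule = "intersection",
                                   n_boot = 100, seed,
                                   denominator = "n", include_nodes = TRUE) {
  stopifnot(inherits(ord, "pcoa_ord"))
  if (is.null(ord$ages))
    stop("ordination has no age provenance; build it with build_morphospace()")
  ages <- ord$ages
  if (!include_nodes) ages <- ages[ages$type != "node", ]
  ages <- ages[!is.na(ages$older), ]
  assignment <- assign_to_bins(ages, bins, rule)
  bootstrap_disparity(ord, assignment, bins, n_boot = n_boot, seed = seed,
                      denominator = denominator)
}

#' @export
print.bin_series <- function(x, ...) {
  cat(sprintf("%s through time: %d bins (%d non-empty)\n",
              if (!is.null(x$statistic)) x$statistic else "values",
              nrow(x$bins), sum(!is.na(x$summaries$mean))))
  print.data.frame(
    x$summaries[, intersect(c("bin", "n", "observed", "mean", "median", "sd"),
                            names(x$summaries))],
    row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.bin_series <- function(object, ...) object$summaries

#' Plot a disparity (or rate) time-bin series
#'
#' Box plots of the per-bin distributions at bin midpoints on a reversed Ma
#' axis, with the per-bin means connected by a trendline and a one-standard-
#' deviation envelope shaded around them.
#'
#' @param x a `bin_series` object.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.bin_series <- function(x, ...) {
  s <- x$summaries
  ok <- !is.na(s$mean)
  if (!any(ok)) stop("no non-empty bins to plot")
  mid <- (s$older + s$younger) / 2
  ylim <- range(unlist(x$values), na.rm = TRUE)
  graphics::plot(NA, xlim = rev(range(c(s$older, s$younger))), ylim = ylim,
                 xlab = "Age (Ma)",
                 ylab = if (!is.null(x$statistic)) x$statistic else "value",
                 ...)
  up <- s$mean + s$sd; lo <- s$mean - s$sd
  graphics::polygon(c(mid[ok], rev(mid[ok])), c(up[ok], rev(lo[ok])),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  for (j in which(ok))
    graphics::boxplot(x$values[[j]], at = mid[j], add = TRUE, boxwex = 4,
                      axes = FALSE, outline = FALSE)
  graphics::lines(mid[ok], s$mean[ok], col = "steelblue", lwd = 2)
  graphics::points(mid[ok], s$mean[ok], pch = 18, col = "steelblue")
  invisible(x)
}
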