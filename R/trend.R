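#' Segmented LOESS trendline with bootstrap confidence envelope
#'
#' Local linear regression (tricube weights, via [stats::loess()] with
#' `degree = 1` and exact `"direct"` fitting) of a quantity against age,
#' fitted independently within each segment so that the trend is not
#' smoothed across major geological boundaries. The 95% confidence envelope
#' is a percentile bootstrap over data points within each segment. Segments
#' with fewer than `min_n` points are skipped with a warning (sparse
#' intervals produce extremely broad, uninformative envelopes).
#'
#' @param x ages (Ma).
#' @param y values (rates or disparity) paired with `x`.
#' @param span LOESS span (default 0.75).
#' @param segments a [time_bins()] set of segment boundaries, or `NULL` for
#'   one segment spanning the data; the default era-level segmentation is
#'   available via `era_segments()`.
#' @param n_boot bootstrap resamples for the envelope (default 200).
#' @param seed RNG seed for the bootstrap.
#' @param n_grid evaluation points per segment.
#' @param min_n minimum points per segment (default 5).
#' @return an object of class `loess_trend`: data frame with `segment`,
#'   `x`, `fit`, `lo`, `hi` plus a `skipped` attribute naming skipped
#'   segments.
#' @export
loess_trend <- function(x, y, span = 0.75, segments = NULL, n_boot = 200,
                        seed = 1, n_grid = 50, min_n = 5) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (is.null(segments))
    segments <- time_bins("all", max(x) + 1e-9, min(x) - 1e-9)
  stopifnot(inherits(segments, "time_bins"))
  set.seed(seed)
  out <- list()
  skipped <- character(0)
  mem <- bin_membership(x, x, segments)
  for (j in seq_len(nrow(segments))) {
    inseg <- mem[, j]
    n <- sum(inseg)
    if (n < max(min_n, 2)) {
      if (n > 0) skipped <- c(skipped, segments$name[j])
      next
    }
    xs <- x[inseg]; ys <- y[inseg]
    grid <- seq(min(xs), max(xs), length.out = n_grid)
    fit <- fit_local_linear(xs, ys, span, grid)
    boots <- matrix(NA_real_, n_boot, n_grid)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boots[b, ] <- tryCatch(fit_local_linear(xs[idx], ys[idx], span, grid),
                             error = function(e) rep(NA_real_, n_grid))
    }
    lo <- apply(boots, 2, stats::quantile, probs = 0.025, na.rm = TRUE)
    hi <- apply(boots, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
    out[[segments$name[j]]] <- data.frame(segment = segments$name[j],
                                          x = grid, fit = fit, lo = lo,
                                          hi = hi, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("segment(s) skipped for low sample size: ",
            paste(skipped, collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no segment had enough points to fit")
  rownames(res) <- NULL
  structure(res, class = c("loess_trend", "data.frame"), skipped = skipped)
}

fit_local_linear <- function(x, y, span, grid) {
  fit <- stats::loess(y ~ x, span = span, degree = 1, family = "gaussian",
                      surface = "direct")
  stats::predict(fit, newdata = data.frame(x = grid))
}

#' Era-level trend segments
#'
#' Paleozoic / Mesozoic / Cenozoic boundaries for segmenting trendlines at
#' the two mass-extinction horizons the analyses straddle.
#'
#' @return a [time_bins()] object.
#' @export
era_segments <- function() {
  time_bins(c("Paleozoic", "Mesozoic", "Cenozoic"),
            older = c(541, 251.902, 66), younger = c(251.902, 66, 0))
}

#' @export
plot.loess_trend <- function(x, ...) {
  graphics::plot(NA, xlim = rev(range(x$x)), ylim = range(c(x$lo, x$hi)),
                 xlab = "Age (Ma)", ylab = "fitted value", ...)
  for (seg in unique(x$segment)) {
    s <- x[x$segment == seg, ]
    graphics::polygon(c(s$x, rev(s$x)), c(s$hi, rev(s$lo)),
                      col = grDevices::adjustcolor("grey", 0.5), border = NA)
    graphics::lines(s$x, s$fit, lwd = 2, col = "steelblue")
  }
  invisible(x)
}

#' Regression between phenotypic and molecular log rates
#'
#' Ordinary least squares of log phenotypic rates on log molecular rates
#' across paired bipartitions, with the two-sided slope test. A slope
#' indistinguishable from zero (tiny R-squared, large p) indicates
#' decoupling between phenotypic and molecular evolution.
#'
#' @param phen,mol positive paired rate vectors (one value per
#'   bipartition).
#' @param log_transform take logs first (default `TRUE`).
#' @return an object of class `rate_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, and the underlying `lm` fit.
#' @export
rate_disparity_regression <- function(phen, mol, log_transform = TRUE) {
  if (length(phen) != length(mol)) stop("paired samples required")
  if (length(phen) < 3) stop("need at least 3 pairs")
  if (log_transform) {
    if (any(phen <= 0) || any(mol <= 0))
      stop("rates must be positive for log transformation")
    phen <- log(phen); mol <- log(mol)
  }
  if (stats::var(mol) == 0) stop("zero variance in predictor")
  fit <- stats::lm(phen ~ mol)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_value = s$coefficients[2, 4],
                 n = length(phen), fit = fit),
            class = "rate_regression")
}

#' @export
print.rate_regression <- function(x, ...) {
  cat(sprintf("rate_regression: n = %d, slope = %.4g, R-squared = %.4g, p = %.4g\n",
              x$n, x$slope, x$r_squared, x$p_value))
  invisible(x)
}
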