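#' Check parametric-test assumptions for grouped values
#'
#' Per-group Shapiro-Wilk normality tests, a pooled Fligner-Killeen test of
#' homogeneity of variances, and a Shapiro-Wilk test on group-mean-centred
#' residuals, the assumption battery run before choosing between parametric
#' and nonparametric pairwise comparisons. Skewness and kurtosis are
#' recorded per group as distribution diagnostics. Groups with fewer than 3
#' values or zero variance are flagged untestable. Shapiro-Wilk is defined
#' for at most 5000 values; larger groups are tested on a deterministic
#' evenly spaced subsample.
#'
#' @param groups named list of (>= 2) numeric vectors.
#' @param alpha significance level used for the pass/fail summary (default
#'   0.05).
#' @return an object of class `assumption_report`: per-group data frame
#'   (`n`, `shapiro_p`, `skewness`, `kurtosis`, `untestable`),
#'   `fligner_p`, `residual_shapiro_p`, and `pass` (all tests above
#'   `alpha`).
#' @export
assess_assumptions <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must be a list of at least 2 value vectors")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  per <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    untestable <- length(v) < 3 || stats::sd(v) == 0
    data.frame(group = g, n = length(v),
               shapiro_p = if (untestable) NA_real_ else safe_shapiro(v),
               skewness = sample_skewness(v),
               kurtosis = sample_kurtosis(v),
               untestable = untestable, stringsAsFactors = FALSE)
  }))
  testable <- !per$untestable
  fligner_p <- if (sum(testable) >= 2) {
    v <- unlist(groups[testable], use.names = FALSE)
    f <- factor(rep(names(groups)[testable],
                    lengths(groups[testable])))
    stats::fligner.test(v, f)$p.value
  } else NA_real_
  resid <- unlist(lapply(groups[testable], function(v) v - mean(v)),
                  use.names = FALSE)
  residual_p <- if (length(resid) >= 3 && stats::sd(resid) > 0)
    safe_shapiro(resid) else NA_real_
  pass <- all(per$shapiro_p[testable] > alpha, na.rm = FALSE) &&
    isTRUE(fligner_p > alpha) && isTRUE(residual_p > alpha)
  structure(list(per_group = per, fligner_p = fligner_p,
                 residual_shapiro_p = residual_p, alpha = alpha,
                 pass = isTRUE(pass)),
            class = "assumption_report")
}

safe_shapiro <- function(v) {
  if (length(v) > 5000)
    v <- v[round(seq(1, length(v), length.out = 5000))]
  stats::shapiro.test(v)$p.value
}

sample_skewness <- function(v) {
  n <- length(v)
  if (n < 3 || stats::sd(v) == 0) return(NA_real_)
  m <- mean(v)
  mean((v - m)^3) / (mean((v - m)^2))^1.5
}

sample_kurtosis <- function(v) {
  n <- length(v)
  if (n < 3 || stats::sd(v) == 0) return(NA_real_)
  m <- mean(v)
  mean((v - m)^4) / (mean((v - m)^2))^2 - 3
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("assumption_report (alpha = %.3g): %s\n", x$alpha,
              if (x$pass) "assumptions met" else "assumptions NOT met"))
  print.data.frame(x$per_group, row.names = FALSE, digits = 4)
  cat(sprintf("  Fligner-Killeen p = %.4g; residual Shapiro-Wilk p = %.4g\n",
              x$fligner_p, x$residual_shapiro_p))
  invisible(x)
}

# transform registry; log/sqrt refuse negatives, exp is scaled to avoid
# overflow on large inputs
transform_fun <- function(name) {
  switch(name,
    none = identity,
    sqrt = function(v) { if (any(v < 0)) NULL else sqrt(v) },
    cbrt = function(v) sign(v) * abs(v)^(1 / 3),
    log = function(v) { if (any(v <= 0)) NULL else log(v) },
    exp = function(v) exp(v / max(abs(v), 1)),
    stop("unknown transform: ", name))
}

#' Search for a variance-stabilising transformation
#'
#' Applies each candidate transformation in the listed order and re-runs the
#' assumption battery; the first transformation after which all tests pass
#' at `alpha` is returned. Transformations whose domain excludes the data
#' (square root or log of negatives) are skipped with a note. Returns
#' `transform = "none"` untouched if the raw data already pass, and
#' `transform = NA` when nothing passes.
#'
#' @param groups named list of numeric vectors.
#' @param transforms candidate transformations, tried in order.
#' @param alpha significance level.
#' @return list with `transform` (name or `NA`), `groups` (transformed
#'   values), `report` (the passing [assess_assumptions()] report, or the
#'   raw-data report when nothing passes), `skipped` (transforms skipped on
#'   domain grounds).
#' @export
transform_search <- function(groups,
                             transforms = c("sqrt", "cbrt", "log", "exp"),
                             alpha = 0.05) {
  raw <- assess_assumptions(groups, alpha)
  if (raw$pass)
    return(list(transform = "none", groups = groups, report = raw,
                skipped = character(0)))
  skipped <- character(0)
  for (tr in transforms) {
    f <- transform_fun(tr)
    tg <- lapply(groups, f)
    if (any(vapply(tg, is.null, logical(1)))) {
      skipped <- c(skipped, tr)
      next
    }
    rep <- assess_assumptions(tg, alpha)
    if (rep$pass)
      return(list(transform = tr, groups = tg, report = rep,
                  skipped = skipped))
  }
  list(transform = NA_character_, groups = groups, report = raw,
       skipped = skipped)
}

#' Assumption-driven pairwise comparisons across time bins
#'
#' For every pair of groups the procedure is: check the parametric
#' assumptions ([assess_assumptions()]); if they fail, search the
#' transformation ladder ([transform_search()]); if a transformation
#' restores them, compare with a two-sample t-test on the transformed
#' values, otherwise fall back to the Wilcoxon rank-sum (Mann-Whitney)
#' test. P-values are adjusted across all pairs and the full decision trail
#' (assumption p-values, transform used, test used, effect direction on the
#' original scale) is recorded.
#'
#' @param groups named list of (>= 2) numeric vectors, keyed by bin.
#' @param alpha significance level for assumption checks (default 0.05).
#' @param adjust p-value adjustment across pairs: `"holm"` (default),
#'   `"bonferroni"`, `"BH"`, or `"none"`.
#' @param transforms candidate transformations for [transform_search()].
#' @return an object of class `pairwise_comparison`: `decisions` (one row
#'   per unordered pair: `group_a`, `group_b`, `test`, `transform`,
#'   `p_raw`, `p_adjusted`, `direction`, assumption p-values) plus the
#'   adjustment method.
#' @export
pairwise_compare <- function(groups, alpha = 0.05,
                             adjust = c("holm", "bonferroni", "BH", "none"),
                             transforms = c("sqrt", "cbrt", "log", "exp")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ga <- groups[[a]]; gb <- groups[[b]]
    ts <- transform_search(list(ga, gb), transforms = transforms,
                           alpha = alpha)
    use_t <- !is.na(ts$transform)
    if (use_t) {
      tt <- stats::t.test(ts$groups[[1]], ts$groups[[2]])
      p <- tt$p.value
      test <- "t"
    } else {
      # exact enumeration for small samples; normal approximation with
      # continuity correction otherwise (and automatically under ties)
      wt <- suppressWarnings(
        stats::wilcox.test(ga, gb, exact = (length(ga) <= 50 &&
                                              length(gb) <= 50),
                           correct = TRUE))
      p <- wt$p.value
      test <- "wilcoxon"
    }
    rep <- ts$report
    rows[[k]] <- data.frame(
      group_a = a, group_b = b, test = test,
      transform = if (use_t) ts$transform else NA_character_,
      p_raw = p, p_adjusted = NA_real_,
      direction = sign(mean(ga) - mean(gb)),
      shapiro_p_a = rep$per_group$shapiro_p[1],
      shapiro_p_b = rep$per_group$shapiro_p[2],
      fligner_p = rep$fligner_p,
      residual_shapiro_p = rep$residual_shapiro_p,
      stringsAsFactors = FALSE)
  }
  decisions <- do.call(rbind, rows)
  decisions$p_adjusted <- stats::p.adjust(decisions$p_raw, method = adjust)
  structure(list(decisions = decisions, adjust = adjust, alpha = alpha),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("pairwise_comparison: %d pairs, %s-adjusted\n",
              nrow(x$decisions), x$adjust))
  d <- x$decisions
  d$sig <- ifelse(d$p_adjusted < x$alpha, "*", "")
  print.data.frame(d[, c("group_a", "group_b", "test", "transform",
                         "p_raw", "p_adjusted", "sig")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.pairwise_comparison <- function(object, ...) object$decisions
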