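#' Missing-data fraction of a character matrix
#'
#' Fraction of cells scored as missing (`"?"`). Inapplicable cells are a
#' conceptually distinct category and are NOT counted as missing here:
#' missingness means the taxon occupies the character's space but is unscored,
#' inapplicability means the character does not exist for the taxon.
#'
#' @param x a [character_matrix()].
#' @param scope `"overall"` for one fraction over all cells, or
#'   `"per_character"` for a vector of per-character fractions (denominator =
#'   number of taxa).
#' @return numeric fraction(s) in `[0, 1]`.
#' @export
missing_fraction <- function(x, scope = c("overall", "per_character")) {
  stopifnot(inherits(x, "character_matrix"))
  scope <- match.arg(scope)
  if (length(x$states) == 0) stop("empty matrix")
  miss <- is_missing(x$states)
  if (scope == "overall") mean(miss) else colMeans(miss)
}

prep_report <- function(n_char_in, n_char_out, n_taxa_in, n_taxa_out,
                        dropped_missing = integer(0),
                        dropped_inapplicable = integer(0),
                        rescored_cells = 0L, polymorphic_converted = 0L,
                        overall_missing_fraction = NA_real_,
                        missing_fraction_pre_rescore = NA_real_) {
  structure(list(n_char_in = n_char_in, n_char_out = n_char_out,
                 n_taxa_in = n_taxa_in, n_taxa_out = n_taxa_out,
                 dropped_missing = dropped_missing,
                 dropped_inapplicable = dropped_inapplicable,
                 rescored_cells = rescored_cells,
                 polymorphic_converted = polymorphic_converted,
                 overall_missing_fraction = overall_missing_fraction,
                 missing_fraction_pre_rescore = missing_fraction_pre_rescore),
            class = "prep_report")
}

#' @export
print.prep_report <- function(x, ...) {
  cat("matrix preparation report\n")
  cat(sprintf("  characters: %d -> %d (%d dropped for missingness, %d for inapplicability)\n",
              x$n_char_in, x$n_char_out, length(x$dropped_missing),
              length(x$dropped_inapplicable)))
  cat(sprintf("  taxa: %d -> %d\n", x$n_taxa_in, x$n_taxa_out))
  cat(sprintf("  cells rescored inapplicable->missing: %d; polymorphisms converted: %d\n",
              x$rescored_cells, x$polymorphic_converted))
  if (!is.na(x$overall_missing_fraction))
    cat(sprintf("  overall missing fraction: %.3f\n", x$overall_missing_fraction))
  invisible(x)
}

#' Drop characters with excessive missing data
#'
#' Removes every character whose missing fraction is strictly greater than
#' `threshold` ("more than 30% missing" with the default). Inapplicable cells
#' do not count toward the missing fraction. Taxa are untouched.
#'
#' @param x a [character_matrix()].
#' @param threshold maximum tolerated missing fraction, in `(0, 1]`.
#' @return list with elements `matrix` (filtered [character_matrix()]) and
#'   `report` (a `prep_report`).
#' @export
filter_missing <- function(x, threshold = 0.30) {
  stopifnot(inherits(x, "character_matrix"))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  frac <- missing_fraction(x, "per_character")
  drop <- which(frac > threshold)
  keep <- setdiff(seq_len(n_characters(x)), drop)
  if (!length(keep))
    warning("all characters removed by the missing-data filter")
  out <- subset_characters(x, keep)
  rep <- prep_report(
    n_char_in = n_characters(x), n_char_out = length(keep),
    n_taxa_in = n_taxa(x), n_taxa_out = n_taxa(x),
    dropped_missing = drop,
    overall_missing_fraction =
      if (length(keep)) mean(is_missing(out$states)) else NA_real_)
  list(matrix = out, report = rep)
}

#' Drop widely inapplicable characters, rescore the rest
#'
#' Removes every character that is inapplicable for strictly more than
#' `threshold` of taxa; in the retained characters, every remaining
#' inapplicable cell is rescored as missing (the taxon is then placed in the
#' character's space agnostically rather than being forced into a space it
#' does not occupy).
#'
#' @inheritParams filter_missing
#' @param threshold maximum tolerated inapplicable fraction, in `(0, 1]`.
#' @return list with elements `matrix` and `report`; the output matrix
#'   contains no inapplicable cells.
#' @export
filter_inapplicable <- function(x, threshold = 0.05) {
  stopifnot(inherits(x, "character_matrix"))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  frac <- colMeans(is_inapplicable(x$states))
  drop <- which(frac > threshold)
  keep <- setdiff(seq_len(n_characters(x)), drop)
  out <- subset_characters(x, keep)
  inapp <- is_inapplicable(out$states)
  out$states[inapp] <- MISSING_TOKEN
  rep <- prep_report(
    n_char_in = n_characters(x), n_char_out = length(keep),
    n_taxa_in = n_taxa(x), n_taxa_out = n_taxa(x),
    dropped_inapplicable = drop, rescored_cells = sum(inapp),
    overall_missing_fraction =
      if (length(keep)) mean(is_missing(out$states)) else NA_real_)
  list(matrix = out, report = rep)
}

#' Convert polymorphic scorings to missing
#'
#' Every polymorphic cell (for example `"{01}"`) becomes missing (`"?"`), as
#' is standard before distance-based disparity analysis of discrete
#' characters.
#'
#' @inheritParams filter_missing
#' @return list with elements `matrix` and `report`.
#' @export
polymorphisms_to_missing <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  pol <- is_polymorphic(x$states)
  out <- x
  out$states[pol] <- MISSING_TOKEN
  rep <- prep_report(
    n_char_in = n_characters(x), n_char_out = n_characters(x),
    n_taxa_in = n_taxa(x), n_taxa_out = n_taxa(x),
    polymorphic_converted = sum(pol),
    overall_missing_fraction = mean(is_missing(out$states)))
  list(matrix = out, report = rep)
}

#' Drop taxa by name
#'
#' Removes the named taxa (rows); characters are untouched and the order of
#' the remaining taxa is preserved.
#'
#' @inheritParams filter_missing
#' @param names character vector of taxon names to remove; all must be
#'   present.
#' @return a [character_matrix()].
#' @export
drop_taxa <- function(x, names) {
  stopifnot(inherits(x, "character_matrix"))
  unknown <- setdiff(names, taxon_names(x))
  if (length(unknown))
    stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
  keep <- !(taxon_names(x) %in% names)
  character_matrix(x$states[keep, , drop = FALSE], ordering = x$ordering,
                   character_labels = x$character_labels)
}

#' Disparity-ready matrix preparation pipeline
#'
#' Applies, in order: the missing-data character filter
#' ([filter_missing()], default threshold 0.30), the inapplicability filter
#' with rescoring ([filter_inapplicable()], default threshold 0.05), and
#' polymorphism conversion ([polymorphisms_to_missing()]). Thresholds at each
#' stage use the taxon counts of the matrix entering that stage. The output
#' matrix contains no inapplicable or polymorphic cells and the consolidated
#' report carries the overall missing fraction both directly after the
#' missing-data filter and at the end (the two bracket the effect of
#' rescoring).
#'
#' @inheritParams filter_missing
#' @param max_missing,max_inapplicable stage thresholds.
#' @param drop optional character vector of taxa to remove first.
#' @return list with elements `matrix` and `report`.
#' @export
prep_pipeline <- function(x, max_missing = 0.30, max_inapplicable = 0.05,
                          drop = NULL) {
  stopifnot(inherits(x, "character_matrix"))
  n_char_in <- n_characters(x)
  n_taxa_in <- n_taxa(x)
  if (!is.null(drop) && length(drop)) x <- drop_taxa(x, drop)
  s1 <- filter_missing(x, max_missing)
  frac_post_filter <- s1$report$overall_missing_fraction
  s2 <- filter_inapplicable(s1$matrix, max_inapplicable)
  # map stage-2 drop indices back to original character indices
  kept1 <- setdiff(seq_len(n_characters(x)), s1$report$dropped_missing)
  s3 <- polymorphisms_to_missing(s2$matrix)
  rep <- prep_report(
    n_char_in = n_char_in, n_char_out = n_characters(s3$matrix),
    n_taxa_in = n_taxa_in, n_taxa_out = n_taxa(s3$matrix),
    dropped_missing = s1$report$dropped_missing,
    dropped_inapplicable = kept1[s2$report$dropped_inapplicable],
    rescored_cells = s2$report$rescored_cells,
    polymorphic_converted = s3$report$polymorphic_converted,
    overall_missing_fraction = s3$report$overall_missing_fraction,
    missing_fraction_pre_rescore = frac_post_filter)
  list(matrix = s3$matrix, report = rep)
}

subset_characters <- function(x, keep) {
  character_matrix(x$states[, keep, drop = FALSE],
                   ordering = x$ordering[keep],
                   character_labels = x$character_labels[keep])
}
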