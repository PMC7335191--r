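#' Named stratigraphic time bins
#'
#' A `time_bins` object is an ordered set of named geological intervals in Ma
#' before present, ordered from oldest to youngest, non-overlapping, each
#' spanning `[older, younger)` — the older bound is inclusive and the younger
#' bound exclusive, so boundary ages are unambiguous.
#'
#' @param name character vector of bin names.
#' @param older,younger numeric bounds in Ma; `older > younger` within each
#'   bin.
#' @return an object of class `time_bins` (a validated data frame).
#' @examples
#' time_bins(c("Lopingian", "Early Triassic"), c(259.5, 251.9), c(251.9, 247.2))
#' @export
time_bins <- function(name, older, younger) {
  if (length(name) != length(older) || length(older) != length(younger))
    stop("name, older and younger must have equal length")
  if (any(!(older > younger)))
    stop("inverted bin(s): ",
         paste(name[!(older > younger)], collapse = ", "))
  ord <- order(-older)
  name <- name[ord]; older <- older[ord]; younger <- younger[ord]
  if (length(name) > 1) {
    gap <- older[-1] - younger[-length(name)]
    if (any(gap > 1e-9))
      stop("overlapping bins: ",
           paste(paste(name[c(which(gap > 1e-9), which(gap > 1e-9) + 1)],
                       collapse = " / "), collapse = "; "))
  }
  structure(data.frame(name = name, older = older, younger = younger,
                       stringsAsFactors = FALSE),
            class = c("time_bins", "data.frame"))
}

#' Read a time-bin configuration file
#'
#' Reads named intervals from a TSV/CSV file with columns `name`, `older`,
#' `younger` (bounds in Ma) and returns a validated, ordered [time_bins()]
#' set.
#'
#' @param path path to the config file; the delimiter (tab or comma) is
#'   sniffed from the header line.
#' @return a [time_bins()] object.
#' @export
read_time_bins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("name", "older", "younger")
  if (!all(need %in% names(df)))
    stop("bin config must have columns: ", paste(need, collapse = ", "))
  time_bins(df$name, df$older, df$younger)
}

#' Default stage-level time bins, Permian to Neogene
#'
#' ICS-style series/epoch boundaries (Ma) spanning the Carboniferous to the
#' present, at the granularity used to track disparity and rate change across
#' the Permian--Triassic and Cretaceous--Paleogene boundaries.
#'
#' @return a [time_bins()] object.
#' @export
default_time_bins <- function() {
  time_bins(
    name = c("Pennsylvanian", "Cisuralian", "Guadalupian", "Lopingian",
             "Early Triassic", "Middle Triassic", "Late Triassic",
             "Early Jurassic", "Middle Jurassic", "Late Jurassic",
             "Early Cretaceous", "Late Cretaceous", "Paleocene", "Eocene",
             "Oligocene", "Neogene+"),
    older = c(323.2, 298.9, 273.0, 259.5, 251.9, 247.2, 237.0, 201.4,
              174.7, 161.5, 145.0, 100.5, 66.0, 56.0, 33.9, 23.0),
    younger = c(298.9, 273.0, 259.5, 251.9, 247.2, 237.0, 201.4, 174.7,
                161.5, 145.0, 100.5, 66.0, 56.0, 33.9, 23.0, 0.0)
  )
}

#' @export
print.time_bins <- function(x, ...) {
  cat(sprintf("time_bins: %d intervals, %.1f-%.1f Ma\n", nrow(x),
              max(x$older), min(x$younger)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# logical matrix [n ranges x n bins]: does age range [older_i, younger_i]
# intersect bin j? A bin holds ages a with b_younger < a <= b_older (older
# bound inclusive, younger exclusive); the youngest bin additionally closes
# at its younger bound so that present-day (0 Ma) material is binnable.
bin_membership <- function(range_older, range_younger, bins) {
  nb <- nrow(bins)
  youngest <- which.min(bins$younger)
  out <- matrix(FALSE, length(range_older), nb)
  for (j in seq_len(nb)) {
    b_old <- bins$older[j]; b_young <- bins$younger[j]
    hit <- range_older > b_young & range_younger <= b_old
    if (j == youngest) hit <- hit | (range_older == b_young)
    out[, j] <- hit
  }
  colnames(out) <- bins$name
  out
}
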