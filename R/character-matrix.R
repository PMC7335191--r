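#' Discrete morphological character matrices
#'
#' A `character_matrix` holds a rectangular taxa-by-characters block of
#' discrete morphological scorings, the kind of matrix assembled for
#' phylogenetic inference and reused for disparity analyses. Cells hold
#' single-digit state tokens (`"0"`--`"9"`), the missing token `"?"`, the
#' inapplicable token `"-"` (a taxon for which the character does not exist,
#' conceptually distinct from missing), or a polymorphic set written
#' `"{01}"`. Each character carries an ordering flag: ordered characters are
#' compared on the integer scale of their states, unordered characters only by
#' identity.
#'
#' @param states character matrix (taxa in rows, characters in columns) of
#'   state tokens. Row names are taxon names and must be unique and non-empty.
#' @param ordering logical vector, one element per character; `TRUE` marks an
#'   ordered character. Defaults to all unordered.
#' @param character_labels optional character vector of labels, one per
#'   character.
#' @return an object of class `character_matrix`.
#' @examples
#' m <- character_matrix(
#'   matrix(c("0", "1", "0", "?", "1", "{01}"), nrow = 2,
#'          dimnames = list(c("t1", "t2"), NULL))
#' )
#' n_taxa(m)
#' @export
character_matrix <- function(states, ordering = NULL, character_labels = NULL) {
  if (!is.matrix(states) || !is.character(states))
    stop("`states` must be a character matrix")
  taxa <- rownames(states)
  if (is.null(taxa) || anyNA(taxa) || any(!nzchar(taxa)))
    stop("taxon names (row names) must be present and non-empty")
  if (anyDuplicated(taxa))
    stop("duplicate taxon names: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (is.null(ordering)) ordering <- rep(FALSE, ncol(states))
  if (length(ordering) != ncol(states))
    stop("`ordering` must have one flag per character")
  if (!is.null(character_labels) && length(character_labels) != ncol(states))
    stop("`character_labels` must have one label per character")

  bad <- !vapply(states, is_valid_token, logical(1))
  if (any(bad))
    stop("invalid state token(s): ",
         paste(utils::head(unique(states[bad]), 5), collapse = ", "))
  # polymorphic sets need >= 2 distinct states
  pol <- is_polymorphic(states)
  if (any(pol)) {
    sizes <- vapply(poly_states(states[pol]), function(s) length(unique(s)), 1L)
    if (any(sizes < 2))
      stop("polymorphic cells must contain at least 2 distinct states")
  }
  # ordered characters need integer-orderable tokens
  for (j in which(as.logical(ordering))) {
    col <- states[, j]
    obs <- col[!is_missing(col) & !is_inapplicable(col)]
    obs <- unique(unlist(c(obs[!is_polymorphic(obs)], poly_states(obs[is_polymorphic(obs)]))))
    if (length(obs) && any(!grepl("^[0-9]$", obs)))
      stop("ordered character ", j, " has non-integer state tokens")
  }
  structure(
    list(states = states, ordering = as.logical(ordering),
         character_labels = character_labels),
    class = "character_matrix"
  )
}

# token predicates -------------------------------------------------------

MISSING_TOKEN <- "?"
INAPPLICABLE_TOKEN <- "-"

is_valid_token <- function(x) {
  grepl("^[0-9]$", x) || x == MISSING_TOKEN || x == INAPPLICABLE_TOKEN ||
    grepl("^\\{[0-9]{2,}\\}$", x)
}

#' @rdname character_matrix
#' @param x object to test / query.
#' @export
is_missing <- function(x) x == MISSING_TOKEN

#' @rdname character_matrix
#' @export
is_inapplicable <- function(x) x == INAPPLICABLE_TOKEN

#' @rdname character_matrix
#' @export
is_polymorphic <- function(x) startsWith(x, "{")

# list of character vectors of states inside polymorphic tokens
poly_states <- function(x) {
  lapply(strsplit(gsub("[{}]", "", x), ""), identity)
}

# canonical polymorphic token from a set of single-character states
make_poly_token <- function(states) {
  paste0("{", paste(sort(unique(states)), collapse = ""), "}")
}

#' @rdname character_matrix
#' @export
n_taxa <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  nrow(x$states)
}

#' @rdname character_matrix
#' @export
n_characters <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  ncol(x$states)
}

#' @rdname character_matrix
#' @export
taxon_names <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  rownames(x$states)
}

#' @export
print.character_matrix <- function(x, ...) {
  s <- x$states
  cat(sprintf("character_matrix: %d taxa x %d characters (%d ordered)\n",
              nrow(s), ncol(s), sum(x$ordering)))
  cat(sprintf("  missing %d, inapplicable %d, polymorphic %d of %d cells\n",
              sum(is_missing(s)), sum(is_inapplicable(s)),
              sum(is_polymorphic(s)), length(s)))
  invisible(x)
}

#' @export
`==.character_matrix` <- function(e1, e2) {
  identical(unclass(e1)[c("states", "ordering")],
            unclass(e2)[c("states", "ordering")])
}
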