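#' Read a NEXUS discrete character matrix
#'
#' Parses a NEXUS `CHARACTERS` or `DATA` block of standard (discrete) data
#' into a [character_matrix()]. The morphology dialect is handled explicitly:
#' `"?"` maps to missing, the gap symbol (default `"-"`) maps to
#' inapplicable, and polymorphic scorings written `"{01}"` or `"(01)"` map to
#' polymorphic sets. Per-character ordering flags are read from an
#' `ASSUMPTIONS` block `TYPESET` line (`ord:`/`unord:` lists, as written by
#' common morphology tools) when present; characters default to unordered.
#'
#' @param path path to a NEXUS file.
#' @param gap_means_inapplicable if `TRUE` (default) the FORMAT gap symbol is
#'   read as inapplicable; set `FALSE` to fold gaps into missing for files
#'   that use `"-"` loosely.
#' @return a [character_matrix()].
#' @seealso [write_nexus_matrix()]
#' @export
read_nexus_matrix <- function(path, gap_means_inapplicable = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # NEXUS comments

  block <- extract_block(txt, c("characters", "data"))
  if (is.null(block))
    stop("no CHARACTERS/DATA block found in ", path)

  dims <- regmatches(block, regexpr("(?i)dimensions[^;]*;", block, perl = TRUE))
  ntax <- as_int_field(dims, "ntax")
  nchar_ <- as_int_field(dims, "nchar")
  if (is.na(nchar_)) stop("DIMENSIONS must state NCHAR")

  fmt <- regmatches(block, regexpr("(?i)format[^;]*;", block, perl = TRUE))
  missing_sym <- sym_field(fmt, "missing", "?")
  gap_sym <- sym_field(fmt, "gap", "-")

  mat_txt <- regmatches(block,
                        regexpr("(?is)\\bmatrix\\b(.*?);", block, perl = TRUE))
  if (!length(mat_txt)) stop("no MATRIX statement found in ", path)
  mat_txt <- sub("(?i)^matrix", "", mat_txt, perl = TRUE)
  mat_txt <- sub(";\\s*$", "", mat_txt)
  rows <- strsplit(mat_txt, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]

  taxa <- character(0)
  cells <- list()
  for (ln in seq_along(rows)) {
    row <- rows[ln]
    m <- regexpr("^('[^']+'|\\S+)", row)
    name <- regmatches(row, m)
    name <- gsub("^'|'$", "", name)
    body <- trimws(substring(row, attr(m, "match.length") + 1))
    toks <- tokenize_states(body, missing_sym, gap_sym,
                            gap_means_inapplicable)
    if (name %in% taxa) {
      # interleaved continuation
      cells[[name]] <- c(cells[[name]], toks)
    } else {
      taxa <- c(taxa, name)
      cells[[name]] <- toks
    }
  }
  if (!is.na(ntax) && length(taxa) != ntax)
    stop("NTAX=", ntax, " but ", length(taxa), " taxa parsed")
  lens <- lengths(cells)
  if (length(unique(lens)) > 1 || (length(lens) && lens[1] != nchar_))
    stop("ragged matrix: expected ", nchar_, " characters, got rows of length ",
         paste(unique(lens), collapse = ", "))

  states <- matrix(MISSING_TOKEN, nrow = length(taxa), ncol = nchar_,
                   dimnames = list(taxa, NULL))
  for (i in seq_along(taxa)) if (nchar_ > 0) states[i, ] <- cells[[taxa[i]]]

  ordering <- rep(FALSE, nchar_)
  assum <- extract_block(txt, "assumptions")
  if (!is.null(assum)) {
    ts <- regmatches(assum, regexpr("(?i)typeset[^;]*;", assum, perl = TRUE))
    if (length(ts)) ordering <- parse_typeset(ts, nchar_)
  }
  character_matrix(states, ordering = ordering)
}

# first BEGIN <name>; ... END; block (case-insensitive), NULL if absent
extract_block <- function(txt, names) {
  for (nm in names) {
    pat <- paste0("(?is)begin\\s+", nm, "\\s*;(.*?)end\\s*;")
    m <- regexpr(pat, txt, perl = TRUE)
    if (m > 0) {
      block <- regmatches(txt, m)
      return(sub(paste0("(?is)^begin\\s+", nm, "\\s*;"), "",
                 sub("(?is)end\\s*;$", "", block, perl = TRUE), perl = TRUE))
    }
  }
  NULL
}

as_int_field <- function(stmt, field) {
  if (!length(stmt)) return(NA_integer_)
  m <- regmatches(stmt, regexpr(paste0("(?i)", field, "\\s*=\\s*[0-9]+"),
                                stmt, perl = TRUE))
  if (!length(m)) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", m))
}

sym_field <- function(stmt, field, default) {
  if (!length(stmt)) return(default)
  m <- regmatches(stmt, regexpr(paste0("(?i)", field, "\\s*=\\s*\\S"),
                                stmt, perl = TRUE))
  if (!length(m)) return(default)
  substring(m, nchar(m))
}

tokenize_states <- function(body, missing_sym, gap_sym, gap_inapp) {
  chars <- strsplit(gsub("\\s", "", body), "")[[1]]
  toks <- character(0)
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1
      set <- character(0)
      while (j <= n && chars[j] != close) {
        if (grepl("[0-9]", chars[j])) set <- c(set, chars[j])
        else if (chars[j] != ",")
          stop("malformed polymorphism near position ", j)
        j <- j + 1
      }
      if (j > n) stop("unterminated polymorphism in matrix row")
      if (length(unique(set)) < 2)
        stop("polymorphism with fewer than 2 distinct states")
      toks <- c(toks, make_poly_token(set))
      i <- j + 1
    } else {
      tok <- if (ch == missing_sym) MISSING_TOKEN
             else if (ch == gap_sym) {
               if (gap_inapp) INAPPLICABLE_TOKEN else MISSING_TOKEN
             } else ch
      toks <- c(toks, tok)
      i <- i + 1
    }
  }
  toks
}

# TYPESET * name = ord: 1-3 5, unord: 4 6-10;
parse_typeset <- function(ts, nchar_) {
  ordering <- rep(FALSE, nchar_)
  body <- sub("(?i)^typeset[^=]*=", "", ts, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  parts <- strsplit(body, ",")[[1]]
  for (p in parts) {
    kv <- strsplit(trimws(p), ":")[[1]]
    if (length(kv) != 2) next
    type <- tolower(trimws(kv[1]))
    idx <- parse_index_list(kv[2])
    idx <- idx[idx >= 1 & idx <= nchar_]
    if (type %in% c("ord", "ordered")) ordering[idx] <- TRUE
  }
  ordering
}

parse_index_list <- function(s) {
  out <- integer(0)
  for (tok in strsplit(trimws(s), "\\s+")[[1]]) {
    if (grepl("-", tok)) {
      ab <- as.integer(strsplit(tok, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else out <- c(out, as.integer(tok))
  }
  out
}

#' Write a character matrix to NEXUS
#'
#' Emits a NEXUS file with a `DATA` block (standard datatype, `"?"` missing,
#' `"-"` gap/inapplicable, polymorphisms as `"{01}"`) and, when any character
#' is ordered, an `ASSUMPTIONS` block with a `TYPESET` recording the ordering
#' flags, so that [read_nexus_matrix()] recovers the matrix exactly.
#'
#' @param x a [character_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(x, path) {
  stopifnot(inherits(x, "character_matrix"))
  s <- x$states
  quote_name <- function(nm)
    ifelse(grepl("[^A-Za-z0-9_.]", nm), paste0("'", nm, "'"), nm)
  rows <- vapply(seq_len(nrow(s)), function(i)
    paste0(quote_name(rownames(s)[i]), "  ", paste(s[i, ], collapse = "")),
    character(1))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(s), ncol(s)),
    "  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"0123456789\";",
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;"
  )
  if (any(x$ordering)) {
    ord <- which(x$ordering)
    unord <- which(!x$ordering)
    parts <- c(
      if (length(ord)) paste0("ord: ", compress_index_list(ord)),
      if (length(unord)) paste0("unord: ", compress_index_list(unord))
    )
    lines <- c(lines,
               "BEGIN ASSUMPTIONS;",
               paste0("  TYPESET * default = ", paste(parts, collapse = ", "), ";"),
               "END;")
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}

compress_index_list <- function(idx) {
  idx <- sort(idx)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)])
  }, character(1)), collapse = " ")
}
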