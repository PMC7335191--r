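#' Read dated trees with branch metadata comments
#'
#' Reads one or more trees from a plain Newick file or a NEXUS `TREES` block,
#' retaining BEAST-style square-bracket metacomments (`[&rate=2.0,...]`)
#' attached to nodes or branches. Branch lengths are interpreted as durations
#' in Myr; node ages are computed by root-to-node path sums with the youngest
#' tip anchored at its configured age. Tip ages may be supplied via the
#' `age_key` metacomment on tips, via `tip_ages`, or default to 0 (extant).
#'
#' @param path path to the tree file.
#' @param rate_key metacomment key holding the relative clock rate (default
#'   `"rate"`). Set `NULL` to skip rate extraction (plain Newick dialect).
#' @param rate_aliases additional keys accepted for `rate_key`, tried in
#'   order (for example MrBayes-style `"rate_median"`/`"rate_mean"` keys).
#' @param age_key metacomment key holding fixed tip ages in Ma.
#' @param tip_ages optional named numeric vector of tip ages (Ma), overriding
#'   metacomment ages.
#' @return a [tree_sample()].
#' @export
read_annotated_trees <- function(path, rate_key = "rate",
                                 rate_aliases = c("rate_median", "rate_mean"),
                                 age_key = "age", tip_ages = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  newicks <- extract_newick_strings(txt)
  if (!length(newicks)) stop("no trees found in ", path)
  translate <- attr(newicks, "translate")
  trees <- lapply(newicks, function(s)
    annotated_newick_to_time_tree(s, rate_key, rate_aliases, age_key,
                                  tip_ages, translate))
  tree_sample(trees, label = basename(path))
}

# pull tree strings out of plain-newick or NEXUS TREES input, applying any
# TRANSLATE table
extract_newick_strings <- function(txt) {
  if (grepl("(?i)^\\s*#nexus", txt, perl = TRUE)) {
    block <- extract_block(txt, "trees")
    if (is.null(block)) stop("NEXUS file has no TREES block")
    translate <- NULL
    tr <- regmatches(block, regexpr("(?is)\\btranslate\\b(.*?);", block,
                                    perl = TRUE))
    if (length(tr)) {
      body <- sub("(?i)^translate", "", sub(";\\s*$", "", tr), perl = TRUE)
      entries <- strsplit(body, ",")[[1]]
      translate <- vapply(entries, function(en) {
        kv <- strsplit(trimws(en), "\\s+")[[1]]
        stats::setNames(gsub("^'|'$", "", kv[2]), kv[1])
      }, character(1), USE.NAMES = FALSE)
      names(translate) <- vapply(entries, function(en)
        strsplit(trimws(en), "\\s+")[[1]][1], character(1))
    }
    lines <- regmatches(block,
                        gregexpr("(?i)\\btree\\s+[^=]+=[^;]*;", block,
                                 perl = TRUE))[[1]]
    out <- vapply(lines, function(ln) {
      s <- sub("(?i)^\\s*tree\\s+[^=]+=\\s*", "", ln, perl = TRUE)
      sub("^\\s*\\[&[RU]\\]\\s*", "", s)   # rooted/unrooted flag
    }, character(1), USE.NAMES = FALSE)
    attr(out, "translate") <- translate
    out
  } else {
    parts <- strsplit(txt, ";")[[1]]
    parts <- trimws(parts)
    parts <- parts[grepl("\\(", parts)]
    if (length(parts)) paste0(parts, ";") else character(0)
  }
}

annotated_newick_to_time_tree <- function(s, rate_key, rate_aliases,
                                          age_key, tip_ages,
                                          translate = NULL) {
  p <- parse_annotated_newick(s)
  if (!is.null(translate)) {
    hit <- p$label %in% names(translate)
    p$label[hit] <- translate[p$label[hit]]
  }
  is_tip <- !(seq_along(p$parent) %in% p$parent)
  ntip <- sum(is_tip)
  if (ntip < 2) stop("tree has fewer than 2 tips")
  # renumber: tips 1..ntip (in parse order), internals ntip+1.. (parse order,
  # root first since the root is created first)
  new_id <- integer(length(p$parent))
  new_id[is_tip] <- seq_len(ntip)
  new_id[!is_tip] <- ntip + seq_len(sum(!is_tip))
  root_old <- which(is.na(p$parent))
  keep <- seq_along(p$parent) != root_old
  edge <- cbind(new_id[p$parent[keep]], new_id[keep])
  lens <- p$length[keep]
  if (anyNA(lens)) stop("tree has branch(es) without lengths")
  if (any(lens < 0)) stop("negative branch length(s)")
  phy <- structure(list(edge = edge, edge.length = lens,
                        tip.label = p$label[is_tip],
                        Nnode = sum(!is_tip)),
                   class = "phylo", order = "cladewise")

  meta <- p$meta  # list per original node
  rates <- NULL
  if (!is.null(rate_key)) {
    keys_all <- unique(unlist(lapply(meta, names)))
    key <- c(rate_key, rate_aliases)
    key <- key[key %in% keys_all]
    if (!length(key)) {
      if (any(lengths(meta) > 0))
        stop("rate key '", rate_key, "' not found; available keys: ",
             paste(keys_all, collapse = ", "))
      rates <- NULL
    } else {
      key <- key[1]
      val <- vapply(meta, function(m)
        if (!is.null(m[[key]])) as.numeric(m[[key]]) else NA_real_, numeric(1))
      # a branch's rate is the value attached to its child node
      old_of_new <- order(new_id)  # old index for each new id
      rates <- val[old_of_new[edge[, 2]]]
    }
  }

  ages <- stats::setNames(rep(NA_real_, ntip), phy$tip.label)
  if (!is.null(age_key)) {
    for (old in which(is_tip)) {
      m <- meta[[old]]
      if (!is.null(m[[age_key]]))
        ages[p$label[old]] <- as.numeric(m[[age_key]])
    }
  }
  if (!is.null(tip_ages)) ages[names(tip_ages)] <- tip_ages
  ages[is.na(ages)] <- 0
  time_tree(phy, tip_ages = ages, rates = rates)
}

# low-level scanner: returns parent/label/length vectors plus a list of
# parsed metacomment key=value sets, one entry per node in creation order
# (root first)
parse_annotated_newick <- function(s) {
  s <- trimws(s)
  chars <- strsplit(s, "")[[1]]
  n_guess <- sum(chars == ",") * 2 + 2
  parent <- rep(NA_integer_, n_guess)
  label <- rep("", n_guess)
  len <- rep(NA_real_, n_guess)
  meta <- vector("list", n_guess)
  n_nodes <- 1L  # root
  cur <- 1L
  i <- 1L
  n <- length(chars)
  reading_len <- FALSE
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      n_nodes <- n_nodes + 1L
      parent[n_nodes] <- cur
      cur <- n_nodes
      reading_len <- FALSE
      i <- i + 1L
    } else if (ch == ",") {
      n_nodes <- n_nodes + 1L
      parent[n_nodes] <- parent[cur]
      cur <- n_nodes
      reading_len <- FALSE
      i <- i + 1L
    } else if (ch == ")") {
      cur <- parent[cur]
      reading_len <- FALSE
      i <- i + 1L
    } else if (ch == "[") {
      j <- i
      depth_sq <- 0L
      repeat {
        if (chars[j] == "[") depth_sq <- depth_sq + 1L
        if (chars[j] == "]") depth_sq <- depth_sq - 1L
        if (depth_sq == 0L) break
        j <- j + 1L
        if (j > n) stop("unterminated metacomment near position ", i)
      }
      com <- paste(chars[(i + 1):(j - 1)], collapse = "")
      meta[[cur]] <- c(meta[[cur]], parse_metacomment(com))
      i <- j + 1L
    } else if (ch == ":") {
      reading_len <- TRUE
      i <- i + 1L
      num <- ""
      while (i <= n && grepl("[-0-9eE.+]", chars[i])) {
        num <- paste0(num, chars[i]); i <- i + 1L
      }
      len[cur] <- as.numeric(num)
    } else if (ch == ";") {
      break
    } else if (ch == "'") {
      j <- i + 1L
      while (j <= n && chars[j] != "'") j <- j + 1L
      label[cur] <- paste(chars[(i + 1):(j - 1)], collapse = "")
      i <- j + 1L
    } else if (grepl("\\s", ch)) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !chars[j] %in% c("(", ")", ",", ":", ";", "[", "'"))
        j <- j + 1L
      label[cur] <- paste0(label[cur],
                           trimws(paste(chars[i:(j - 1)], collapse = "")))
      i <- j
    }
  }
  list(parent = parent[seq_len(n_nodes)], label = label[seq_len(n_nodes)],
       length = len[seq_len(n_nodes)], meta = meta[seq_len(n_nodes)])
}

# "&rate=2.0,height=1" -> named list; values kept as strings, {..} sets kept
# verbatim
parse_metacomment <- function(com) {
  com <- sub("^&", "", com)
  out <- list()
  # split on commas not inside braces
  parts <- character(0)
  depth <- 0L
  buf <- ""
  for (ch in strsplit(com, "")[[1]]) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "," && depth == 0L) { parts <- c(parts, buf); buf <- "" }
    else buf <- paste0(buf, ch)
  }
  parts <- c(parts, buf)
  for (p in parts) {
    kv <- regmatches(p, regexpr("=", p), invert = TRUE)[[1]]
    if (length(kv) == 2) out[[trimws(kv[1])]] <- trimws(kv[2])
  }
  out
}

#' Write a tree sample with rate metacomments
#'
#' Writes each [time_tree()] as a Newick string with `[&rate=...]`
#' metacomments on branches carrying rates (and `[&age=...]` on fossil
#' tips), one tree per line, in the dialect read by
#' [read_annotated_trees()].
#'
#' @param sample a [tree_sample()] (or single `time_tree`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotated_trees <- function(sample, path) {
  if (inherits(sample, "time_tree")) sample <- tree_sample(list(sample))
  stopifnot(inherits(sample, "tree_sample"))
  lines <- vapply(sample$trees, time_tree_to_newick, character(1))
  writeLines(lines, path)
  invisible(path)
}

time_tree_to_newick <- function(tt) {
  phy <- tt$phylo
  ntip <- length(phy$tip.label)
  e <- phy$edge
  children <- split(seq_len(nrow(e)), factor(e[, 1], levels = seq_len(ntip + phy$Nnode)))
  tip_age <- tt$node_age[seq_len(ntip)]
  build <- function(node, edge_idx) {
    kids <- children[[node]]
    core <- if (length(kids)) {
      paste0("(", paste(vapply(kids, function(k) build(e[k, 2], k),
                               character(1)), collapse = ","), ")")
    } else {
      nm <- phy$tip.label[node]
      if (grepl("[^A-Za-z0-9_.]", nm)) nm <- paste0("'", nm, "'")
      nm
    }
    ann <- character(0)
    if (!is.null(tt$rate) && !is.na(edge_idx) && !is.na(tt$rate[edge_idx]))
      ann <- c(ann, sprintf("rate=%.12g", tt$rate[edge_idx]))
    if (node <= ntip && tip_age[node] > 1e-10)
      ann <- c(ann, sprintf("age=%.12g", tip_age[node]))
    com <- if (length(ann)) paste0("[&", paste(ann, collapse = ","), "]") else ""
    br <- if (is.na(edge_idx)) "" else
      sprintf(":%.12g", phy$edge.length[edge_idx])
    paste0(core, com, br)
  }
  root <- ntip + 1L
  paste0(build(root, NA_integer_), ";")
}
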