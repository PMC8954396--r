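# Readers/writers for the plain-text formats every stage touches, plus the
# run configuration container. All readers validate and fail hard on
# malformed input rather than coercing silently.

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased, `N` is mapped to the canonical missing symbol
#' `?`, and the alphabet is restricted to `A,C,G,T,N,-,?`
#' (case-insensitive). Record order is preserved; ids are the first
#' whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("N", MISSING, seqs, fixed = TRUE)
  bad <- regexpr("[^ACGT?-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a single newick tree
#'
#' Accepts optional branch lengths and internal labels; rejects unbalanced
#' parentheses and multi-tree files.
#'
#' @param path Path to a newick file (or a literal newick string via
#'   `text`).
#' @param text Optional newick string; overrides `path`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  s <- if (!is.null(text)) text else {
    if (!file.exists(path)) stop("no such file: ", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  n_close <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in newick: ", n_open, " '(' vs ",
         n_close, " ')'")
  }
  tr <- tryCatch(ape::read.tree(text = s),
                 error = function(e) stop("failed to parse newick: ",
                                          conditionMessage(e)),
                 warning = function(w) stop("failed to parse newick: ",
                                            conditionMessage(w)))
  if (is.null(tr)) stop("failed to parse newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  tr
}

#' Write a tree as newick
#'
#' @param tree A `phylo` object.
#' @param path Output path; `NULL` returns the string.
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Pipeline run configuration
#'
#' @param coverage_threshold Minimum read depth for a consensus call to be
#'   trusted (default 20 reads).
#' @param missing_symbol Canonical missing-data character (default `?`).
#' @param group_assignments Named list mapping group label to character
#'   vectors of taxon ids.
#' @param calibration_file Optional path to a calibration table (see
#'   [read_calibrations()]).
#' @param rng_seed Optional integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(coverage_threshold = 20L, missing_symbol = "?",
                            group_assignments = list(),
                            calibration_file = NULL, rng_seed = NULL) {
  coverage_threshold <- as.integer(coverage_threshold)
  if (is.na(coverage_threshold) || coverage_threshold < 1L) {
    stop("coverage_threshold must be an integer >= 1")
  }
  stopifnot(is.character(missing_symbol), nchar(missing_symbol) == 1L)
  for (g in names(group_assignments)) {
    memb <- group_assignments[[g]]
    if (anyDuplicated(memb)) {
      stop("duplicate taxon id in group '", g, "': ",
           memb[duplicated(memb)][1L])
    }
  }
  structure(list(coverage_threshold = coverage_threshold,
                 missing_symbol = missing_symbol,
                 group_assignments = group_assignments,
                 calibration_file = calibration_file,
                 rng_seed = rng_seed),
            class = "pipeline_config")
}

#' Read group assignments from a two-column TSV (taxon, group)
#'
#' @param path Path to a headerless TSV.
#' @return Named list of taxon-id vectors, one element per group.
#' @export
read_groups <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("taxon", "group"),
                   stringsAsFactors = FALSE)
  split(df$taxon, df$group)
}

#' Write / read per-position coverage as TSV
#'
#' Two columns: 0-based position on the concatenated reference, read depth.
#'
#' @param coverage Integer vector of depths.
#' @param path File path.
#' @return `write_coverage`: `path` invisibly; `read_coverage`: integer
#'   vector.
#' @export
write_coverage <- function(coverage, path) {
  df <- data.frame(pos = seq_along(coverage) - 1L,
                   depth = as.integer(coverage))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  if (!identical(df$pos, seq_len(nrow(df)) - 1L) &&
      !isTRUE(all.equal(df$pos, seq_len(nrow(df)) - 1L))) {
    stop("coverage TSV positions must be 0-based and contiguous")
  }
  as.integer(df$depth)
}

# --- indel matrix TSV ------------------------------------------------------

indel_event_keys <- function(events) {
  key <- sprintf("%s:%d-%d:%s", events$contig, events$start, events$end,
                 events$type)
  ins <- events$type == "ins"
  key[ins] <- paste0(key[ins], ":", events$seq[ins])
  key
}

#' Write a binary indel matrix as TSV
#'
#' One row per taxon; one column per indel event, headed by its key
#' `contig:start-end:type` (insertions additionally carry the inserted
#' sequence so the round-trip is lossless). States are `0`, `1` or `?`.
#'
#' @param m An [indel_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binary_matrix <- function(m, path) {
  stopifnot(inherits(m, "indel_matrix"))
  df <- as.data.frame(m$states, stringsAsFactors = FALSE, optional = TRUE)
  colnames(df) <- indel_event_keys(m$events)
  df <- cbind(taxon = rownames(m$states), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary indel matrix written by [write_binary_matrix()]
#'
#' @param path Path to the TSV.
#' @return An [indel_matrix()].
#' @export
read_binary_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  taxa <- df$taxon
  keys <- setdiff(colnames(df), "taxon")
  pat <- "^(.+):([0-9]+)-([0-9]+):(del|ins)(?::([ACGT]+))?$"
  mt <- regmatches(keys, regexec(pat, keys, perl = TRUE))
  if (any(lengths(mt) == 0L)) {
    stop("malformed indel event key: ", keys[lengths(mt) == 0L][1L])
  }
  events <- data.frame(
    contig = vapply(mt, `[`, "", 2L),
    start = as.integer(vapply(mt, `[`, "", 3L)),
    end = as.integer(vapply(mt, `[`, "", 4L)),
    type = vapply(mt, `[`, "", 5L),
    seq = vapply(mt, function(x) if (nzchar(x[6L])) x[6L] else NA_character_,
                 ""),
    stringsAsFactors = FALSE)
  states <- as.matrix(df[, keys, drop = FALSE])
  rownames(states) <- taxa
  colnames(states) <- keys
  indel_matrix(events, states)
}
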