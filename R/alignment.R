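# Reference-anchored alignment construction from per-sample consensus calls
# with coverage: low-coverage masking, removal of spurious called islands,
# simple indel coding (one binary character per distinct-boundary event),
# and insertion columns keyed by (position, inserted sequence).

#' Reference index: ordered contigs with a concatenated coordinate map
#'
#' @param ids Character vector of contig ids.
#' @param lengths Integer vector of contig lengths (bp).
#' @return A `reference_index` with `$contigs` (id, length) and `$offsets`
#'   (0-based start of each contig on the concatenated axis).
#' @export
reference_index <- function(ids, lengths) {
  stopifnot(length(ids) == length(lengths), !anyDuplicated(ids),
            all(lengths >= 1L))
  lengths <- as.integer(lengths)
  offsets <- cumsum(c(0L, lengths[-length(lengths)]))
  structure(list(contigs = data.frame(id = as.character(ids),
                                      length = lengths,
                                      stringsAsFactors = FALSE),
                 offsets = offsets),
            class = "reference_index")
}

#' Total concatenated reference length
#' @param ref A [reference_index()].
#' @return Integer length in bp.
#' @export
ref_total_length <- function(ref) sum(ref$contigs$length)

# contig index for each 0-based concatenated position
ref_contig_index <- function(ref, pos) {
  findInterval(pos, ref$offsets)
}

# (contig id, local 0-based pos) for concatenated positions
ref_local <- function(ref, pos) {
  ci <- ref_contig_index(ref, pos)
  data.frame(contig = ref$contigs$id[ci],
             local = pos - ref$offsets[ci],
             stringsAsFactors = FALSE)
}

#' Per-sample consensus calls with coverage
#'
#' @param taxon Taxon id.
#' @param call Character vector over the concatenated reference: one of
#'   `A,C,G,T,-` or `?`.
#' @param coverage Integer read depth per position (same length as `call`).
#' @param insertions Data frame with columns `pos` (0-based concatenated
#'   position the insertion precedes), `seq` (inserted bases) and
#'   `coverage`.
#' @return A `sample_consensus` object. Positions with zero coverage are
#'   forced to `?`.
#' @export
sample_consensus <- function(taxon, call, coverage,
                             insertions = data.frame(pos = integer(),
                                                     seq = character(),
                                                     coverage = integer())) {
  stopifnot(length(call) == length(coverage), all(coverage >= 0L))
  bad <- !(call %in% ALN_STATES)
  if (any(bad)) stop("illegal call state at position ", which(bad)[1L] - 1L)
  call[coverage == 0L] <- MISSING
  structure(list(taxon = taxon, call = call,
                 coverage = as.integer(coverage),
                 insertions = insertions),
            class = "sample_consensus")
}

#' Mask consensus calls below a coverage threshold
#'
#' Every position with coverage below the threshold becomes `?`; the
#' coverage track itself is untouched. Insertions supported by
#' sub-threshold coverage are dropped.
#'
#' @param s A [sample_consensus()].
#' @param threshold Minimum read depth (default 20).
#' @return The masked `sample_consensus`.
#' @export
mask_low_coverage <- function(s, threshold = 20L) {
  stopifnot(inherits(s, "sample_consensus"))
  s$call[s$coverage < threshold] <- MISSING
  if (nrow(s$insertions)) {
    s$insertions <- s$insertions[s$insertions$coverage >= threshold, ,
                                 drop = FALSE]
  }
  s
}

#' Remove spurious short called islands
#'
#' Contiguous runs of non-missing calls shorter than `min_island_len` that
#' are flanked by `?` on both sides (or by a contig edge) are set to `?`.
#' Such islands inside capture gaps are the dominant artifact class in
#' mapped consensus data. Insertions whose flanking reference positions are
#' no longer called are dropped.
#'
#' @param s A [sample_consensus()].
#' @param ref A [reference_index()] (runs never span contig boundaries).
#' @param min_island_len Minimum run length to keep (default 10 bp).
#' @return The cleaned `sample_consensus`.
#' @export
clean_spurious_calls <- function(s, ref, min_island_len = 10L) {
  stopifnot(inherits(s, "sample_consensus"), min_island_len >= 1L)
  for (i in seq_len(nrow(ref$contigs))) {
    a <- ref$offsets[i] + 1L
    b <- ref$offsets[i] + ref$contigs$length[i]
    seg <- s$call[a:b]
    r <- rle(seg != MISSING)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # maximal called runs are flanked by '?' or a contig edge by construction
    kill <- which(r$values & r$lengths < min_island_len)
    for (k in kill) seg[starts[k]:ends[k]] <- MISSING
    s$call[a:b] <- seg
  }
  if (nrow(s$insertions)) {
    keep <- vapply(seq_len(nrow(s$insertions)), function(j) {
      p <- s$insertions$pos[j]
      fl <- insertion_flanks(ref, p)
      all(s$call[fl + 1L] != MISSING)
    }, TRUE)
    s$insertions <- s$insertions[keep, , drop = FALSE]
  }
  s
}

# concatenated 0-based flanking positions of an insertion point (clipped at
# contig edges); an insertion at pos p sits between p-1 and p
insertion_flanks <- function(ref, p) {
  L <- ref_total_length(ref)
  anchor <- min(p, L - 1L)
  ci <- ref_contig_index(ref, anchor)
  lo <- ref$offsets[ci]
  hi <- lo + ref$contigs$length[ci] - 1L
  fl <- c(p - 1L, p)
  fl[fl >= lo & fl <= hi]
}

#' Taxa-by-columns capture alignment anchored to reference coordinates
#'
#' @param mat Character matrix over `A,C,G,T,-,?` with taxon rownames.
#' @param cols Data frame of column metadata: `contig`, `pos` (0-based
#'   concatenated reference position, `NA` for insertion columns), `key`
#'   (insertion block key, `NA` for reference columns) and `sub` (offset
#'   within the insertion block).
#' @return A `capture_alignment`.
#' @export
capture_alignment <- function(mat, cols) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), nrow(cols) == ncol(mat))
  bad <- !(mat %in% ALN_STATES)
  if (any(bad)) stop("illegal alignment state")
  structure(list(mat = mat, cols = cols), class = "capture_alignment")
}

#' Binary indel event matrix
#'
#' @param events Data frame with columns `contig`, `start`, `end` (0-based
#'   half-open, contig-local), `type` (`del` or `ins`) and `seq` (inserted
#'   sequence, `NA` for deletions). Events are unique by the full tuple.
#' @param states Character matrix taxa x events over `0`, `1`, `?`.
#' @return An `indel_matrix`.
#' @export
indel_matrix <- function(events, states) {
  stopifnot(is.data.frame(events), is.matrix(states) || nrow(events) == 0L)
  if (nrow(events)) {
    stopifnot(ncol(states) == nrow(events),
              all(states %in% c("0", "1", MISSING)))
    if (anyDuplicated(indel_event_keys(events))) stop("duplicate indel event")
  }
  structure(list(events = events, states = states), class = "indel_matrix")
}

#' Taxa of an alignment or indel matrix
#' @param x A `capture_alignment` or `indel_matrix`.
#' @return Character vector of taxon ids.
#' @export
aln_taxa <- function(x) {
  if (inherits(x, "capture_alignment")) rownames(x$mat)
  else if (inherits(x, "indel_matrix")) rownames(x$states)
  else stop("unsupported object")
}

# maximal '-' runs over reference coordinates, per contig, as global
# half-open intervals
gap_runs <- function(call, ref) {
  out <- vector("list", nrow(ref$contigs))
  for (i in seq_len(nrow(ref$contigs))) {
    a <- ref$offsets[i]
    seg <- call[(a + 1L):(a + ref$contigs$length[i])]
    r <- rle(seg == GAP)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    out[[i]] <- data.frame(gstart = a + starts[w] - 1L, gend = a + ends[w],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build the cleaned alignment and the 0/1 indel matrix
#'
#' Columns are all reference positions plus one insertion column block per
#' distinct (position, inserted sequence) observed in at least one sample.
#' Maximal deletion runs with identical boundaries across taxa form one
#' binary event (simple indel coding); each insertion block forms one
#' event. Gap runs that overlap an event with different boundaries are
#' ambiguous: under the default `to-missing` policy the conflicting run is
#' removed from the nucleotide matrix as `?` and the taxon is `?` for every
#' overlapped event; under `split-events` the taxon keeps state 1 for its
#' own exact event and is `?` only for the others.
#'
#' @param samples List of [sample_consensus()] objects, one per taxon (the
#'   reference taxon should be among them).
#' @param ref A [reference_index()].
#' @param ambiguous_indel_policy `"to-missing"` (default) or
#'   `"split-events"`.
#' @return List with `$aln` ([capture_alignment()]) and `$indels`
#'   ([indel_matrix()]).
#' @export
build_alignment <- function(samples, ref,
                            ambiguous_indel_policy = c("to-missing",
                                                       "split-events")) {
  ambiguous_indel_policy <- match.arg(ambiguous_indel_policy)
  L <- ref_total_length(ref)
  lens <- vapply(samples, function(s) length(s$call), 0L)
  if (any(lens != L)) stop("inconsistent reference lengths across samples")
  taxa <- unname(vapply(samples, function(s) s$taxon, ""))
  if (anyDuplicated(taxa)) stop("duplicate taxon id")
  nt <- length(taxa)

  refmat <- do.call(rbind, lapply(samples, function(s) s$call))
  rownames(refmat) <- taxa

  # ---- deletion runs and events ------------------------------------------
  runs <- lapply(samples, function(s) gap_runs(s$call, ref))
  names(runs) <- taxa
  all_runs <- unique(do.call(rbind, c(runs, list(data.frame(
    gstart = integer(), gend = integer())))))
  if (nrow(all_runs)) {
    all_runs <- all_runs[order(all_runs$gstart, all_runs$gend), ,
                         drop = FALSE]
  }

  # ambiguity: a run is ambiguous iff it overlaps a distinct-boundary run
  run_ambiguous <- function(rn) {
    if (!nrow(all_runs)) return(logical(0))
    vapply(seq_len(nrow(rn)), function(j) {
      ov <- all_runs$gstart < rn$gend[j] & all_runs$gend > rn$gstart[j]
      diffb <- all_runs$gstart != rn$gstart[j] | all_runs$gend != rn$gend[j]
      any(ov & diffb)
    }, TRUE)
  }
  for (t in taxa) {
    rn <- runs[[t]]
    if (!nrow(rn)) next
    amb <- run_ambiguous(rn)
    runs[[t]]$ambiguous <- amb
    if (ambiguous_indel_policy == "to-missing" && any(amb)) {
      for (j in which(amb)) {
        refmat[t, (rn$gstart[j] + 1L):rn$gend[j]] <- MISSING
      }
    }
  }

  # ---- insertion blocks ---------------------------------------------------
  ins_list <- lapply(samples, function(s) {
    if (nrow(s$insertions)) s$insertions[, c("pos", "seq")] else
      data.frame(pos = integer(), seq = character())
  })
  blocks <- unique(do.call(rbind, ins_list))
  if (nrow(blocks)) {
    blocks <- blocks[order(blocks$pos, blocks$seq), , drop = FALSE]
    rownames(blocks) <- NULL
  }
  nb <- nrow(blocks)
  blen <- if (nb) nchar(blocks$seq) else integer()

  # ---- column layout: each block precedes the reference column blocks$pos -
  C <- L + sum(blen)
  # number of insertion columns placed before each reference position
  ins_before <- integer(L + 1L)
  if (nb) {
    add <- tapply(blen, factor(blocks$pos, levels = 0:L), sum)
    add[is.na(add)] <- 0L
    ins_before <- as.integer(add)
  }
  ref_col <- seq_len(L) + cumsum(ins_before[seq_len(L)])  # 1-based columns

  mat <- matrix(MISSING, nrow = nt, ncol = C,
                dimnames = list(taxa, NULL))
  mat[, ref_col] <- refmat

  cols <- data.frame(contig = rep(NA_character_, C), pos = NA_integer_,
                     key = NA_character_, sub = NA_integer_,
                     stringsAsFactors = FALSE)
  loc <- ref_local(ref, 0:(L - 1L))
  cols$contig[ref_col] <- loc$contig
  cols$pos[ref_col] <- 0:(L - 1L)

  block_cols <- vector("list", nb)
  if (nb) {
    # columns of block b sit just before ref column of blocks$pos, after
    # any lexicographically earlier block at the same position
    off <- 0L
    last_pos <- -1L
    for (b in seq_len(nb)) {
      p <- blocks$pos[b]
      if (p != last_pos) {
        base <- if (p < L) ref_col[p + 1L] - ins_before[p + 1L] - 1L else C -
            ins_before[L + 1L]
        off <- 0L
        last_pos <- p
      }
      block_cols[[b]] <- base + off + seq_len(blen[b])
      off <- off + blen[b]
    }
    for (b in seq_len(nb)) {
      bc <- block_cols[[b]]
      anchor <- min(blocks$pos[b], L - 1L)
      ci <- ref_contig_index(ref, anchor)
      key <- sprintf("%s:%d:%s", ref$contigs$id[ci],
                     blocks$pos[b] - ref$offsets[ci], blocks$seq[b])
      cols$contig[bc] <- ref$contigs$id[ci]
      cols$key[bc] <- key
      cols$sub[bc] <- seq_len(blen[b])
    }
  }

  # ---- fill insertion blocks and insertion event states -------------------
  ins_states <- matrix(MISSING, nrow = nt, ncol = nb,
                       dimnames = list(taxa, NULL))
  for (b in seq_len(nb)) {
    bc <- block_cols[[b]]
    fl <- insertion_flanks(ref, blocks$pos[b])
    for (i in seq_len(nt)) {
      s <- samples[[i]]
      carrier <- nrow(s$insertions) &&
        any(s$insertions$pos == blocks$pos[b] &
              s$insertions$seq == blocks$seq[b])
      if (carrier) {
        mat[i, bc] <- strsplit(blocks$seq[b], "")[[1L]]
        ins_states[i, b] <- "1"
      } else if (all(refmat[i, fl + 1L] %in% NUC_STATES)) {
        mat[i, bc] <- GAP
        ins_states[i, b] <- "0"
      }  # else stays '?'
    }
  }

  # ---- deletion event states ---------------------------------------------
  nd <- nrow(all_runs)
  del_states <- matrix(MISSING, nrow = nt, ncol = nd,
                       dimnames = list(taxa, NULL))
  for (e in seq_len(nd)) {
    gs <- all_runs$gstart[e]; ge <- all_runs$gend[e]
    foot <- (gs + 1L):ge
    for (i in seq_len(nt)) {
      t <- taxa[i]
      rn <- runs[[t]]
      own <- nrow(rn) && any(rn$gstart == gs & rn$gend == ge)
      own_amb <- own && rn$ambiguous[rn$gstart == gs & rn$gend == ge][1L]
      cells <- refmat[i, foot]
      if (own && (!own_amb || ambiguous_indel_policy == "split-events")) {
        del_states[i, e] <- "1"
      } else if (all(cells %in% NUC_STATES)) {
        del_states[i, e] <- "0"
      }  # overlap with different boundaries, or missing footprint -> '?'
    }
  }

  del_events <- if (nd) {
    lo <- ref_local(ref, all_runs$gstart)
    data.frame(contig = lo$contig, start = lo$local,
               end = lo$local + (all_runs$gend - all_runs$gstart),
               type = "del", seq = NA_character_, stringsAsFactors = FALSE)
  } else data.frame(contig = character(), start = integer(),
                    end = integer(), type = character(), seq = character(),
                    stringsAsFactors = FALSE)
  ins_events <- if (nb) {
    anchor <- pmin(blocks$pos, L - 1L)
    ci <- ref_contig_index(ref, anchor)
    data.frame(contig = ref$contigs$id[ci],
               start = blocks$pos - ref$offsets[ci],
               end = blocks$pos - ref$offsets[ci],
               type = "ins", seq = blocks$seq, stringsAsFactors = FALSE)
  } else del_events[0L, ]
  events <- rbind(del_events, ins_events)
  states <- cbind(del_states, ins_states)
  if (nrow(events)) colnames(states) <- indel_event_keys(events)

  list(aln = capture_alignment(mat, cols),
       indels = indel_matrix(events, states))
}

#' Fraction of alignment columns scored for a taxon
#'
#' @param aln A [capture_alignment()].
#' @param taxon Taxon id.
#' @return Fraction in `[0, 1]` of columns whose state is not `?`.
#' @export
scored_fraction <- function(aln, taxon) {
  stopifnot(inherits(aln, "capture_alignment"))
  if (!taxon %in% rownames(aln$mat)) stop("unknown taxon: ", taxon)
  mean(aln$mat[taxon, ] != MISSING)
}
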