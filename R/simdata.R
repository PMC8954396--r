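# Synthetic capture-data generator. Emulates the statistical structure of a
# mitochondrial target-capture experiment: a multi-contig reference, sequence
# evolution (substitutions + non-overlapping indels) down a known tree whose
# root equals the reference, regional coverage dropout that increases with
# phylogenetic distance from the reference taxon, and optional introgression
# by column transfer between clades. Everything is deterministic under a
# fixed seed.

#' Simulation parameter set
#'
#' Defaults mirror the capture experiment the package emulates: a ~10^6 bp
#' reference in 19 contigs, Jukes-Cantor substitutions, 0.3 indel events
#' per substitution with geometric lengths (mean 4 bp), and a baseline 8%
#' regional capture-dropout fraction that grows with root-to-tip divergence
#' from the reference so that scored fractions span roughly the 27-92%
#' band. Scale `total_ref_len` down for tests.
#'
#' @param n_contigs Number of reference contigs (default 19).
#' @param total_ref_len Total reference length in bp (default 1e6).
#' @param tree Rooted `phylo` with branch lengths in expected
#'   substitutions/site; `NULL` uses [sim_default_tree()] at run time.
#' @param subst_model `"JC"` or `"HKY"`.
#' @param kappa Transition/transversion rate ratio for HKY (default 2).
#' @param indel_rate Indel events per substitution (default 0.3).
#' @param indel_len_mean Mean indel length, geometric (default 4 bp).
#' @param dropout_base Baseline fraction of the reference falling in
#'   capture-dropout windows (default 0.08).
#' @param dropout_slope Additional dropout fraction per unit root-to-tip
#'   divergence from the reference, in (subs/site)^-1 (default 12: a taxon
#'   0.05 subs/site from the reference loses ~68% of positions).
#' @param dropout_window_mean Mean length of capture/dropout windows
#'   (default 2000 bp; capture failures are regional, not per-base).
#' @param coverage_captured_mean,coverage_dropout_mean Mean read depth in
#'   captured (100) and dropout (2) windows; negative binomial. Captured
#'   windows have a depth floor of `coverage_captured_floor` (default 20)
#'   on top of which the negative binomial varies: a captured position is
#'   by definition well covered, so with no dropout the consensus survives
#'   thresholding everywhere.
#' @param coverage_captured_floor Minimum depth inside captured windows.
#' @param introgression_events List of lists with elements `donor`,
#'   `recipient` (character vectors of tip labels) and `f` (fraction of
#'   eligible polymorphic columns transferred).
#' @param ref_taxon Label of the reference leaf (default `"REF"`).
#' @param rng_seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_contigs = 19L, total_ref_len = 1e6, tree = NULL,
                       subst_model = c("JC", "HKY"), kappa = 2,
                       indel_rate = 0.3, indel_len_mean = 4,
                       dropout_base = 0.08, dropout_slope = 12,
                       dropout_window_mean = 2000,
                       coverage_captured_mean = 100,
                       coverage_captured_floor = 20,
                       coverage_dropout_mean = 2,
                       introgression_events = list(),
                       ref_taxon = "REF", rng_seed = 1L) {
  subst_model <- match.arg(subst_model)
  stopifnot(dropout_base >= 0, dropout_base <= 1, dropout_slope >= 0,
            indel_rate >= 0, indel_len_mean >= 1, kappa > 0)
  for (ev in introgression_events) {
    stopifnot(ev$f >= 0, ev$f <= 1)
  }
  if (!is.null(tree) && any(tree$edge.length < 0)) {
    stop("branch lengths must be >= 0")
  }
  structure(list(n_contigs = as.integer(n_contigs),
                 total_ref_len = as.integer(total_ref_len), tree = tree,
                 subst_model = subst_model, kappa = kappa,
                 indel_rate = indel_rate, indel_len_mean = indel_len_mean,
                 dropout_base = dropout_base, dropout_slope = dropout_slope,
                 dropout_window_mean = dropout_window_mean,
                 coverage_captured_mean = coverage_captured_mean,
                 coverage_captured_floor = coverage_captured_floor,
                 coverage_dropout_mean = coverage_dropout_mean,
                 introgression_events = introgression_events,
                 ref_taxon = ref_taxon, rng_seed = as.integer(rng_seed)),
            class = "sim_params")
}

#' Default simulation tree: a scaled random coalescent
#'
#' Coalescent shapes produce realistic imbalance, but raw coalescent
#' branch lengths can be arbitrarily short, which would make the default
#' world statistically unidentifiable at desk scale; every branch is
#' therefore floored at `min_frac` of the depth before rescaling.
#'
#' @param n_taxa Number of leaves (default 12).
#' @param depth Root-to-tip height in expected substitutions/site
#'   (default 0.05).
#' @param min_frac Minimum branch length as a fraction of `depth`
#'   (default 0.05).
#' @return An ultrametric rooted `phylo` with tips `t1..tn`.
#' @export
sim_default_tree <- function(n_taxa = 12L, depth = 0.05, min_frac = 0.05) {
  tr <- ape::rcoal(n_taxa)
  d <- ape::node.depth.edgelength(tr)
  H <- max(d)
  hgt <- H - d                      # ultrametric node heights, tips at 0
  hgt[-seq_len(length(tr$tip.label))] <-
    pmax(hgt[-seq_len(length(tr$tip.label))], H * min_frac)
  po <- ape::reorder.phylo(tr, "postorder")$edge
  for (k in seq_len(nrow(po))) {    # push parents above children
    if (po[k, 2L] > length(tr$tip.label)) {
      hgt[po[k, 1L]] <- max(hgt[po[k, 1L]], hgt[po[k, 2L]] + H * min_frac)
    }
  }
  tr$edge.length <- hgt[tr$edge[, 1L]] - hgt[tr$edge[, 2L]]
  h2 <- max(hgt)
  tr$edge.length <- tr$edge.length * depth / h2
  tr
}

# graft the reference taxon onto the root with a near-zero branch; the root
# sequence then equals the reference, mirroring reference-mapping geometry
add_reference_tip <- function(tree, label = "REF", len = 1e-9) {
  if (label %in% tree$tip.label) return(tree)
  inner <- sub(";$", "", ape::write.tree(tree))
  ape::read.tree(text = sprintf("(%s:0,%s:%.12g);", inner, label, len))
}

#' Simulate a multi-contig reference
#'
#' Contig lengths are 200 bp plus a random multinomial split of the
#' remainder; bases are i.i.d. uniform.
#'
#' @param params A [sim_params()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return List with `$index` ([reference_index()]), `$seqs` (named contig
#'   strings) and `$concat` (character vector of single bases).
#' @export
simulate_reference <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_contigs
  L <- params$total_ref_len
  if (L < n * 200L) stop("infeasible split: need total_ref_len >= ", n * 200L)
  extra <- as.vector(rmultinom(1L, L - n * 200L, prob = runif(n) + 0.1))
  lens <- 200L + extra
  ids <- sprintf("ctg%02d", seq_len(n))
  concat <- sample(NUC_STATES, L, replace = TRUE)
  idx <- reference_index(ids, lens)
  seqs <- vapply(seq_len(n), function(i) {
    paste(concat[(idx$offsets[i] + 1L):(idx$offsets[i] + lens[i])],
          collapse = "")
  }, "")
  names(seqs) <- ids
  list(index = idx, seqs = seqs, concat = concat)
}

#' @importFrom stats rmultinom
NULL

# draw a footprint of `len` bp inside one contig, avoiding the global pool
# of used positions (with a 1 bp margin so distinct events never merge into
# one gap run); returns 0-based start or NA if no room after `tries` draws
draw_footprint <- function(used, ref, len, tries = 50L) {
  L <- length(used)
  ci_len <- ref$contigs$length
  for (k in seq_len(tries)) {
    start <- sample.int(L - len + 1L, 1L) - 1L
    ci <- ref_contig_index(ref, start)
    if (start + len > ref$offsets[ci] + ci_len[ci]) next
    lo <- max(start - 1L, 0L)
    hi <- min(start + len, L - 1L)
    if (any(used[(lo + 1L):(hi + 1L)])) next
    return(start)
  }
  NA_integer_
}

#' Evolve sequences along a tree from the reference root
#'
#' Per branch, substitutions are Poisson with mean branch length x sites
#' (JC or HKY-kappa base exchange) and indel events are Poisson with mean
#' `indel_rate` x substitutions; indel lengths are geometric. Indel
#' footprints are globally non-overlapping (with a 1 bp margin), so the
#' truth bookkeeping is exact: every leaf gap run corresponds to exactly
#' one recorded event. Substitutions only hit positions not deleted on the
#' lineage; inserted sequence does not mutate further.
#'
#' @param refobj Result of [simulate_reference()].
#' @param tree Rooted `phylo` including the reference tip.
#' @param params A [sim_params()].
#' @param seed Optional seed.
#' @return A `sim_truth` list: `$aln` (truth [capture_alignment()]),
#'   `$indels` (truth [indel_matrix()]), `$leaf_calls` (taxa x ref-length
#'   call matrix), `$leaf_insertions` (per-taxon data frames),
#'   `$branch_subs` (per-edge substitution counts), `$events` (event
#'   records with affected clades), `$tree`, `$divergence` (root-to-tip
#'   path length per leaf) and `$introgressed_cols` (empty here).
#' @export
evolve_alignment <- function(refobj, tree, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- refobj$index
  L <- ref_total_length(ref)
  stopifnot(length(refobj$concat) == L, ape::is.rooted(tree))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L

  used <- logical(L)          # global indel footprint pool (+1 bp margin)
  seqs <- vector("list", ntip + nnode)
  seqs[[root]] <- refobj$concat
  branch_subs <- integer(nrow(tree$edge))
  events <- list()

  edge_order <- order(tree$edge[, 1L])  # preorder-ish: parents before kids
  edge_order <- seq_len(nrow(tree$edge))[order(match(tree$edge[, 1L],
      c(root, tree$edge[, 2L])))]

  tip_sets <- phangorn::Descendants(tree, seq_len(ntip + nnode), "tips")

  for (e in edge_order) {
    par <- tree$edge[e, 1L]; chl <- tree$edge[e, 2L]
    b <- tree$edge.length[e]
    s <- seqs[[par]]
    nsub <- rpois(1L, b * L)
    alive <- which(s != GAP)
    nsub <- min(nsub, length(alive))
    if (nsub > 0L) {
      pos <- if (length(alive) == 1L) alive else sample(alive, nsub)
      s[pos] <- vapply(s[pos], mutate_base, "", model = params$subst_model,
                       kappa = params$kappa)
    }
    branch_subs[e] <- nsub
    nind <- rpois(1L, params$indel_rate * b * L)
    for (j in seq_len(nind)) {
      len <- rgeom(1L, 1 / params$indel_len_mean) + 1L
      type <- if (runif(1L) < 0.5) "del" else "ins"
      flen <- if (type == "del") len else 1L
      start <- draw_footprint(used, ref, flen)
      if (is.na(start)) next
      used[max(start - 1L, 0L):min(start + flen, L - 1L) + 1L] <- TRUE
      clade <- tree$tip.label[tip_sets[[chl]]]
      if (type == "del") {
        if (any(s[(start + 1L):(start + len)] == GAP)) next
        s[(start + 1L):(start + len)] <- GAP
        events[[length(events) + 1L]] <- list(type = "del", gstart = start,
                                              gend = start + len,
                                              seq = NA_character_,
                                              edge = e, clade = clade)
      } else {
        ins_seq <- paste(sample(NUC_STATES, len, replace = TRUE),
                         collapse = "")
        events[[length(events) + 1L]] <- list(type = "ins", gstart = start,
                                              gend = start, seq = ins_seq,
                                              edge = e, clade = clade)
      }
    }
    seqs[[chl]] <- s
  }

  taxa <- tree$tip.label
  leaf_calls <- do.call(rbind, lapply(seq_len(ntip), function(i) seqs[[i]]))
  rownames(leaf_calls) <- taxa

  # leaves below the edge of each insertion event carry (pos, seq)
  leaf_insertions <- setNames(lapply(taxa, function(t) {
    data.frame(pos = integer(), seq = character(), stringsAsFactors = FALSE)
  }), taxa)
  ins_events <- Filter(function(ev) ev$type == "ins", events)
  for (ev in ins_events) {
    for (t in ev$clade) {
      leaf_insertions[[t]] <- rbind(leaf_insertions[[t]],
                                    data.frame(pos = ev$gstart, seq = ev$seq,
                                               stringsAsFactors = FALSE))
    }
  }

  truth <- assemble_truth_alignment(ref, taxa, leaf_calls, events)
  div <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  names(div) <- taxa

  structure(list(aln = truth$aln, indels = truth$indels,
                 leaf_calls = leaf_calls,
                 leaf_insertions = leaf_insertions,
                 branch_subs = branch_subs, events = events, tree = tree,
                 divergence = div, ref = ref,
                 introgressed_cols = integer()),
            class = "sim_truth")
}

mutate_base <- function(b, model, kappa) {
  others <- setdiff(NUC_STATES, b)
  if (model == "JC") return(sample(others, 1L))
  transition <- c(A = "G", G = "A", C = "T", T = "C")[[b]]
  transversions <- setdiff(others, transition)
  w <- ifelse(others == transition, kappa, 1)
  sample(others, 1L, prob = w)
}

# independent assembly of the truth alignment + indel matrix from the event
# records (deliberately not via build_alignment, which is what it oracles)
assemble_truth_alignment <- function(ref, taxa, leaf_calls, events) {
  L <- ref_total_length(ref)
  nt <- length(taxa)
  ins <- Filter(function(ev) ev$type == "ins", events)
  del <- Filter(function(ev) ev$type == "del", events)
  if (length(ins)) {
    o <- order(vapply(ins, `[[`, 0L, "gstart"),
               vapply(ins, `[[`, "", "seq"))
    ins <- ins[o]
  }
  # column items: reference columns plus insertion blocks placed before
  # their anchor position
  piece_list <- list()
  meta_list <- list()
  cursor <- 0L
  loc_all <- ref_local(ref, 0:(L - 1L))
  for (ev in ins) {
    p <- ev$gstart
    if (p > cursor) {
      idx <- (cursor + 1L):p
      piece_list[[length(piece_list) + 1L]] <- leaf_calls[, idx, drop = FALSE]
      meta_list[[length(meta_list) + 1L]] <-
        data.frame(contig = loc_all$contig[idx], pos = idx - 1L,
                   key = NA_character_, sub = NA_integer_,
                   stringsAsFactors = FALSE)
      cursor <- p
    }
    w <- nchar(ev$seq)
    blk <- matrix(GAP, nrow = nt, ncol = w, dimnames = list(taxa, NULL))
    chars <- strsplit(ev$seq, "")[[1L]]
    for (t in intersect(ev$clade, taxa)) blk[t, ] <- chars
    piece_list[[length(piece_list) + 1L]] <- blk
    anchor <- min(p, L - 1L)
    ci <- ref_contig_index(ref, anchor)
    key <- sprintf("%s:%d:%s", ref$contigs$id[ci], p - ref$offsets[ci],
                   ev$seq)
    meta_list[[length(meta_list) + 1L]] <-
      data.frame(contig = ref$contigs$id[ci], pos = NA_integer_, key = key,
                 sub = seq_len(w), stringsAsFactors = FALSE)
  }
  if (cursor < L) {
    idx <- (cursor + 1L):L
    piece_list[[length(piece_list) + 1L]] <- leaf_calls[, idx, drop = FALSE]
    meta_list[[length(meta_list) + 1L]] <-
      data.frame(contig = loc_all$contig[idx], pos = idx - 1L,
                 key = NA_character_, sub = NA_integer_,
                 stringsAsFactors = FALSE)
  }
  mat <- do.call(cbind, piece_list)
  rownames(mat) <- taxa
  cols <- do.call(rbind, meta_list)
  rownames(cols) <- NULL

  # truth indel matrix: deletion events sorted by (gstart, gend), then
  # insertion events; clade members 1, everyone else 0
  if (length(del)) {
    o <- order(vapply(del, `[[`, 0L, "gstart"), vapply(del, `[[`, 0L, "gend"))
    del <- del[o]
  }
  evs <- c(del, ins)
  n_ev <- length(evs)
  states <- matrix("0", nrow = nt, ncol = n_ev, dimnames = list(taxa, NULL))
  rows <- vector("list", n_ev)
  for (k in seq_len(n_ev)) {
    ev <- evs[[k]]
    lo <- ref_local(ref, min(ev$gstart, L - 1L))
    st <- ev$gstart - (min(ev$gstart, L - 1L) - lo$local)
    rows[[k]] <- data.frame(contig = lo$contig, start = st,
                            end = st + (ev$gend - ev$gstart), type = ev$type,
                            seq = ev$seq, stringsAsFactors = FALSE)
    states[intersect(ev$clade, taxa), k] <- "1"
  }
  events_df <- if (n_ev) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               type = character(), seq = character(), stringsAsFactors = FALSE)
  if (n_ev) colnames(states) <- indel_event_keys(events_df)
  list(aln = capture_alignment(mat, cols),
       indels = indel_matrix(events_df, states))
}

#' Overwrite recipient-clade columns with the donor-clade consensus
#'
#' For each event, eligible columns are the reference-anchored alignment
#' columns polymorphic among the union of donor and recipient members and
#' whose donor plurality state is a nucleotide; a random fraction `f` of
#' them is transferred and recorded in the truth.
#'
#' @param sim A `sim_truth` from [evolve_alignment()].
#' @param events List of lists `donor`, `recipient`, `f` (see
#'   [sim_params()]).
#' @param seed Optional seed.
#' @return The modified `sim_truth` with `$introgressed_cols` filled.
#' @export
inject_introgression <- function(sim, events, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (ev in events) {
    if (length(intersect(ev$donor, ev$recipient))) {
      stop("donor and recipient clades overlap")
    }
    stopifnot(all(c(ev$donor, ev$recipient) %in% rownames(sim$aln$mat)))
    refcols <- which(!is.na(sim$aln$cols$pos))
    sub <- sim$aln$mat[c(ev$donor, ev$recipient), refcols, drop = FALSE]
    n_states <- apply(sub, 2L, function(col) {
      length(unique(col[col %in% NUC_STATES]))
    })
    donor_cons <- plurality_state(
      sim$aln$mat[ev$donor, refcols, drop = FALSE], NUC_STATES)
    eligible <- which(n_states >= 2L & donor_cons %in% NUC_STATES)
    if (!length(eligible)) next
    take <- eligible[runif(length(eligible)) < ev$f]
    if (!length(take)) next
    gcols <- refcols[take]
    for (t in ev$recipient) {
      sim$aln$mat[t, gcols] <- donor_cons[take]
      sim$leaf_calls[t, sim$aln$cols$pos[gcols] + 1L] <- donor_cons[take]
    }
    sim$introgressed_cols <- sort(union(sim$introgressed_cols, gcols))
  }
  sim
}

# columnwise plurality over a state set; tie or no determinate member -> '?'
plurality_state <- function(mat, states) {
  counts <- vapply(states, function(s) colSums(mat == s),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1L) counts <- matrix(counts, nrow = 1L,
                                        dimnames = list(NULL, states))
  best <- max.col(counts, ties.method = "first")
  mx <- counts[cbind(seq_len(nrow(counts)), best)]
  n_at_max <- rowSums(counts == mx)
  out <- states[best]
  out[mx == 0 | n_at_max > 1L] <- MISSING
  out
}

#' Impose the capture-coverage model and emit per-sample consensi
#'
#' Each sample's reference axis is partitioned into alternating windows of
#' geometric length; a window is a dropout window with probability
#' `dropout_base + dropout_slope * divergence-from-reference` (capped at
#' 0.95). Coverage is negative binomial: mean 100 in captured windows,
#' mean 2 in dropout windows. The reference taxon is fully captured by
#' construction. Calls are not yet threshold-masked (see
#' [mask_low_coverage()]); only zero-coverage positions become `?`.
#'
#' @param sim A `sim_truth`.
#' @param params A [sim_params()].
#' @param seed Optional seed.
#' @return List of [sample_consensus()] objects, one per leaf.
#' @export
apply_capture_mask <- function(sim, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(sim$leaf_calls)
  taxa <- rownames(sim$leaf_calls)
  lapply(taxa, function(t) {
    if (t == params$ref_taxon) {
      cov <- rep.int(as.integer(params$coverage_captured_mean), L)
    } else {
      pd <- min(params$dropout_base +
                  params$dropout_slope * sim$divergence[[t]], 0.95)
      cov <- integer(L)
      at <- 0L
      fl <- params$coverage_captured_floor
      while (at < L) {
        wl <- min(rgeom(1L, 1 / params$dropout_window_mean) + 1L, L - at)
        dropout <- runif(1L) < pd
        cov[(at + 1L):(at + wl)] <- if (dropout) {
          rnbinom(wl, size = 1, mu = params$coverage_dropout_mean)
        } else {
          fl + rnbinom(wl, size = 10,
                       mu = max(params$coverage_captured_mean - fl, 1))
        }
        at <- at + wl
      }
    }
    ins <- sim$leaf_insertions[[t]]
    if (nrow(ins)) {
      ins$coverage <- cov[pmin(ins$pos, L - 1L) + 1L]
    } else {
      ins$coverage <- integer(0)
    }
    sample_consensus(t, sim$leaf_calls[t, ], cov, ins)
  })
}

#' One-call synthetic capture experiment
#'
#' Runs [simulate_reference()], grafts the reference tip, evolves the
#' alignment, applies introgression events and the coverage model, all
#' under `params$rng_seed`.
#'
#' @param params A [sim_params()].
#' @return List with `$refobj`, `$tree`, `$sim` (the `sim_truth`) and
#'   `$samples` (list of [sample_consensus()]).
#' @export
simulate_capture <- function(params) {
  set.seed(params$rng_seed)
  refobj <- simulate_reference(params)
  tree <- params$tree
  if (is.null(tree)) tree <- sim_default_tree()
  tree <- add_reference_tip(tree, params$ref_taxon)
  sim <- evolve_alignment(refobj, tree, params)
  if (length(params$introgression_events)) {
    sim <- inject_introgression(sim, params$introgression_events)
  }
  samples <- apply_capture_mask(sim, params)
  list(refobj = refobj, tree = tree, sim = sim, samples = samples)
}
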