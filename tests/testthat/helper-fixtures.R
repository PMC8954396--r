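# Shared fixture builders. Everything is generated in code; no data files.

# a tiny two-contig reference with fixed sequence
tiny_ref <- function(lens = c(30L, 20L)) {
  reference_index(sprintf("c%d", seq_along(lens)), lens)
}

# consensus from a call string, uniform coverage unless given
mk_cons <- function(taxon, calls, coverage = NULL, insertions = NULL) {
  call <- strsplit(calls, "")[[1L]]
  if (is.null(coverage)) coverage <- rep(100L, length(call))
  if (is.null(insertions)) {
    insertions <- data.frame(pos = integer(), seq = character(),
                             coverage = integer())
  }
  sample_consensus(taxon, call, coverage, insertions)
}

# capture_alignment straight from equal-length strings
mk_aln <- function(...) {
  seqs <- c(...)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  L <- ncol(mat)
  cols <- data.frame(contig = "c1", pos = 0:(L - 1L), key = NA_character_,
                     sub = NA_integer_, stringsAsFactors = FALSE)
  capture_alignment(mat, cols)
}

# indel matrix from a state-string per taxon ("10?" etc.)
mk_indels <- function(states, contig = "c1") {
  taxa <- names(states)
  sm <- do.call(rbind, strsplit(states, ""))
  rownames(sm) <- taxa
  ne <- ncol(sm)
  events <- data.frame(contig = contig, start = seq_len(ne) * 10L,
                       end = seq_len(ne) * 10L + 2L, type = "del",
                       seq = NA_character_, stringsAsFactors = FALSE)
  colnames(sm) <- mitocapture:::indel_event_keys(events)
  indel_matrix(events, sm)
}

# small end-to-end simulation; dropout off unless asked for
quick_capture <- function(seed, n_taxa = 6L, len = 6000L, depth = 0.04,
                          dropout_base = 0, dropout_slope = 0,
                          indel_rate = 0.3, tree = NULL, ...) {
  set.seed(seed)
  if (is.null(tree)) tree <- sim_default_tree(n_taxa, depth)
  p <- sim_params(n_contigs = 2L, total_ref_len = len, tree = tree,
                  rng_seed = seed, dropout_base = dropout_base,
                  dropout_slope = dropout_slope, indel_rate = indel_rate,
                  ...)
  simulate_capture(p)
}

# four-population tree for ABBA-BABA tests: (((P1,P2),P3),P4)
abba_tree <- function() {
  read_newick(text = paste0(
    "((((a1:0.002,a2:0.002):0.008,(b1:0.002,b2:0.002):0.008):0.01,",
    "(c1:0.002,c2:0.002):0.018):0.02,(o1:0.002,o2:0.002):0.038);"))
}

abba_pops <- function(aln, m) {
  lapply(list(recipient = c("a1", "a2"), sister = c("b1", "b2"),
              donor = c("c1", "c2"), outgroup = c("o1", "o2")),
         function(g) population_consensus(aln, m, g))
}

rf <- function(a, b) phangorn::RF.dist(ape::unroot(a), ape::unroot(b))
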