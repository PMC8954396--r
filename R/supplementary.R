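# Analysis of an externally produced alignment FASTA (e.g. a published
# supplementary alignment): wrap it as a capture_alignment on a single
# flat coordinate axis, derive the 0/1 indel matrix from its gap runs,
# and compute the full panel of variant / distance / ABBA-BABA numbers.

#' Load an aligned FASTA as a capture alignment
#'
#' All sequences must have equal length; the coordinate axis is a single
#' pseudo-contig `"aln"`. `N` is mapped to `?` on read.
#'
#' @param path Path to an aligned FASTA.
#' @return A [capture_alignment()].
#' @export
alignment_from_fasta <- function(path) {
  seqs <- read_fasta(path)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences are not aligned")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  L <- ncol(mat)
  cols <- data.frame(contig = "aln", pos = 0:(L - 1L), key = NA_character_,
                     sub = NA_integer_, stringsAsFactors = FALSE)
  capture_alignment(mat, cols)
}

#' Derive a binary indel matrix from alignment gap runs
#'
#' Maximal `-` runs per taxon become events; identical-boundary runs
#' across taxa form one event (simple indel coding). Runs overlapping an
#' event with different boundaries are handled per the ambiguity policy,
#' as in [build_alignment()].
#'
#' @param aln A [capture_alignment()] over a single flat axis.
#' @param ambiguous_indel_policy `"to-missing"` (default) or
#'   `"split-events"`.
#' @return List `$aln` (possibly with ambiguous runs masked) and
#'   `$indels` ([indel_matrix()]).
#' @export
indels_from_alignment <- function(aln,
                                  ambiguous_indel_policy = c("to-missing",
                                                             "split-events")) {
  ambiguous_indel_policy <- match.arg(ambiguous_indel_policy)
  ref <- reference_index("aln", ncol(aln$mat))
  samples <- lapply(rownames(aln$mat), function(t) {
    sample_consensus(t, aln$mat[t, ],
                     ifelse(aln$mat[t, ] == MISSING, 0L, 100L))
  })
  res <- build_alignment(samples, ref, ambiguous_indel_policy)
  res$aln$cols$contig <- aln$cols$contig[1L]
  res
}

#' Full report on a supplementary alignment
#'
#' Computes the numbers the pipeline reports for a published alignment:
#' alignment length, SNP and indel-event counts over an ingroup, per-taxon
#' scored fractions, intraspecific polymorphism counts and the ABBA-BABA
#' counts for four named roles.
#'
#' @param fasta_path Aligned FASTA path.
#' @param ingroup Taxa over which SNPs/indels are counted.
#' @param species_sets Named list of taxon sets for intraspecific counts.
#' @param abba_roles Optional named list with elements `recipient`,
#'   `sister`, `donor`, `outgroup` (taxon-id vectors).
#' @return List of results.
#' @export
supplementary_alignment_report <- function(fasta_path, ingroup = NULL,
                                           species_sets = list(),
                                           abba_roles = NULL) {
  aln0 <- alignment_from_fasta(fasta_path)
  built <- indels_from_alignment(aln0)
  aln <- built$aln; m <- built$indels
  if (is.null(ingroup)) ingroup <- aln_taxa(aln)
  sf <- vapply(aln_taxa(aln), function(t) scored_fraction(aln, t), 0)
  out <- list(
    alignment_length = ncol(aln$mat),
    n_snp_sites = count_snps(aln, ingroup),
    n_indel_events = count_indel_events(m, ingroup),
    scored_fraction = sf,
    intraspecific = vapply(species_sets, function(s) {
      intraspecific_polymorphisms(aln, m, s)
    }, 0L))
  if (!is.null(abba_roles)) {
    pops <- lapply(abba_roles, function(memb) {
      population_consensus(aln, m, memb)
    })
    out$abba_baba <- abba_baba(pops$recipient, pops$sister, pops$donor,
                               pops$outgroup)
  }
  out
}
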