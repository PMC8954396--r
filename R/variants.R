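# Variant statistics and between-group distance tables. A "SNP" is a
# variable nucleotide column regardless of allele count; gap and missing
# cells never contribute. Pairwise deletion (per-pair comparable columns)
# is used throughout: scored fractions as low as 27% would annihilate
# complete-case analysis.

#' Count SNP columns among a taxon subset
#'
#' A column counts once if at least two distinct nucleotide states
#' (`A,C,G,T`) occur among the subset; gaps and `?` are ignored.
#'
#' @param aln A [capture_alignment()].
#' @param taxa Character vector of taxon ids (default: all).
#' @return Integer count of variable columns.
#' @export
count_snps <- function(aln, taxa = aln_taxa(aln)) {
  if (!length(taxa)) stop("empty taxon subset")
  stopifnot(all(taxa %in% rownames(aln$mat)))
  sub <- aln$mat[taxa, , drop = FALSE]
  present <- vapply(NUC_STATES, function(s) colSums(sub == s) > 0L,
                    logical(ncol(sub)))
  if (ncol(sub) == 1L) present <- matrix(present, nrow = 1L)
  sum(rowSums(present) >= 2L)
}

#' Count variable indel events among a taxon subset
#'
#' An event counts if both state 0 and state 1 occur among the subset.
#'
#' @param m An [indel_matrix()].
#' @param taxa Character vector of taxon ids (default: all).
#' @return Integer count.
#' @export
count_indel_events <- function(m, taxa = aln_taxa(m)) {
  if (!length(taxa)) stop("empty taxon subset")
  if (!nrow(m$events)) return(0L)
  sub <- m$states[taxa, , drop = FALSE]
  sum(colSums(sub == "1") > 0L & colSums(sub == "0") > 0L)
}

#' Intraspecific polymorphism count (SNPs + indel events)
#'
#' @param aln A [capture_alignment()].
#' @param m An [indel_matrix()].
#' @param taxa At least two taxa of one species.
#' @return Integer: [count_snps()] + [count_indel_events()] over the
#'   subset.
#' @export
intraspecific_polymorphisms <- function(aln, m, taxa) {
  if (length(taxa) < 2L) stop("need at least 2 taxa")
  count_snps(aln, taxa) + count_indel_events(m, taxa)
}

# pairwise difference counts between two taxa
pair_diffs <- function(aln, m, a, b) {
  x <- aln$mat[a, ]; y <- aln$mat[b, ]
  comp <- x %in% NUC_STATES & y %in% NUC_STATES
  nd <- sum(comp & x != y)
  if (nrow(m$events)) {
    ex <- m$states[a, ]; ey <- m$states[b, ]
    ecomp <- ex != MISSING & ey != MISSING
    id <- sum(ecomp & ex != ey)
    ne <- sum(ecomp)
  } else {
    id <- 0L; ne <- 0L
  }
  c(nuc = nd, nuc_comp = sum(comp), indel = id, indel_comp = ne)
}

#' Mean pairwise distances between phylogenetic groups
#'
#' Entry (G, H) is the mean over all cross pairs of the number of columns
#' where both taxa carry a nucleotide call and differ, and likewise for
#' determinate 0/1 indel events. Diagonals are within-group mean pairwise
#' differences (0 for singletons). Per-site versions divide each pair by
#' its comparable column count before averaging.
#'
#' @param aln A [capture_alignment()].
#' @param m An [indel_matrix()].
#' @param groups Named list of taxon-id vectors; groups must be disjoint
#'   and nonempty.
#' @return A `group_distance_table`: matrices `$nuc`, `$indel`,
#'   `$nuc_per_site`, `$indel_per_event`.
#' @export
group_distances <- function(aln, m, groups) {
  stopifnot(length(groups) >= 1L, all(lengths(groups) >= 1L))
  all_memb <- unlist(groups)
  if (anyDuplicated(all_memb)) stop("overlapping groups")
  stopifnot(all(all_memb %in% rownames(aln$mat)))
  g <- names(groups)
  ng <- length(g)
  mk <- function() matrix(0, ng, ng, dimnames = list(g, g))
  nuc <- mk(); ind <- mk(); nps <- mk(); ipe <- mk()
  for (i in seq_len(ng)) for (j in i:ng) {
    pairs <- if (i == j) {
      if (length(groups[[i]]) < 2L) NULL else
        combn(groups[[i]], 2L, simplify = FALSE)
    } else {
      unlist(lapply(groups[[i]], function(a) {
        lapply(groups[[j]], function(b) c(a, b))
      }), recursive = FALSE)
    }
    if (is.null(pairs)) next
    d <- vapply(pairs, function(p) pair_diffs(aln, m, p[1L], p[2L]),
                numeric(4L))
    nuc[i, j] <- nuc[j, i] <- mean(d["nuc", ])
    ind[i, j] <- ind[j, i] <- mean(d["indel", ])
    nps[i, j] <- nps[j, i] <- mean(ifelse(d["nuc_comp", ] > 0,
                                          d["nuc", ] / d["nuc_comp", ], NA),
                                   na.rm = TRUE)
    ipe[i, j] <- ipe[j, i] <- mean(ifelse(d["indel_comp", ] > 0,
                                          d["indel", ] / d["indel_comp", ],
                                          NA), na.rm = TRUE)
  }
  structure(list(groups = groups, nuc = nuc, indel = ind,
                 nuc_per_site = nps, indel_per_event = ipe),
            class = "group_distance_table")
}

#' Variant summary for an alignment + indel matrix
#'
#' @param aln A [capture_alignment()].
#' @param m An [indel_matrix()].
#' @param taxa Subset to summarize (default: all).
#' @return A `variant_summary` list: `$n_snp_sites`, `$n_indel_events`,
#'   `$scored_fraction` (named per-taxon vector), `$alignment_length`.
#' @export
variant_summary <- function(aln, m, taxa = aln_taxa(aln)) {
  structure(list(
    n_snp_sites = count_snps(aln, taxa),
    n_indel_events = count_indel_events(m, taxa),
    scored_fraction = vapply(taxa, function(t) scored_fraction(aln, t), 0),
    alignment_length = ncol(aln$mat)),
    class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat("alignment length:", x$alignment_length, "\n")
  cat("SNP sites:", x$n_snp_sites, " indel events:", x$n_indel_events, "\n")
  cat("scored fractions:\n")
  print(round(sort(x$scored_fraction), 3))
  invisible(x)
}
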