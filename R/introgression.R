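# Consensus construction per population and ABBA-BABA counting over pooled
# SNP columns and 0/1 indel events. Population labels are explicit roles
# (recipient / sister / donor / outgroup); the ancestral state is the
# outgroup consensus state, with no ancestral-state reconstruction.

#' Plurality consensus of a population
#'
#' Per nucleotide column and per indel event: the plurality state among
#' non-missing members; ties and all-missing columns give `?`. Gap (`-`)
#' is a votable state for nucleotide columns, but gap-consensus columns
#' are never informative in [abba_baba()] (indel signal enters through the
#' 0/1 events instead).
#'
#' @param aln A [capture_alignment()].
#' @param m An [indel_matrix()].
#' @param members Character vector of member taxon ids.
#' @param label Population label.
#' @return A `population_consensus`: `$nuc` (per-column states) and
#'   `$ind` (per-event states).
#' @export
population_consensus <- function(aln, m, members, label = "pop") {
  if (!length(members)) stop("empty member set")
  stopifnot(all(members %in% rownames(aln$mat)))
  nuc <- plurality_state(aln$mat[members, , drop = FALSE],
                         c(NUC_STATES, GAP))
  ind <- if (nrow(m$events)) {
    plurality_state(m$states[members, , drop = FALSE], c("0", "1"))
  } else character(0)
  structure(list(label = label, nuc = nuc, ind = ind),
            class = "population_consensus")
}

#' ABBA-BABA counts over four population consensuses
#'
#' A pooled character (nucleotide column or indel event) is informative
#' iff all four consensus states are determinate and exactly two states
#' occur among the four; the outgroup (P4) state is taken as ancestral.
#' ABBA: sister (P2) and donor (P3) share the derived state while the
#' recipient (P1) is ancestral. BABA: recipient and donor share the
#' derived state. Other biallelic patterns (e.g. BBAA) count toward
#' `n_informative` only. Nucleotide and indel characters are pooled.
#'
#' @param p1,p2,p3,p4 [population_consensus()] objects over identical
#'   column/event sets: recipient, sister, donor, outgroup.
#' @return An `abba_baba_result`: `$n_abba`, `$n_baba`, `$n_informative`,
#'   `$D` (`(ABBA-BABA)/(ABBA+BABA)`, 0 with `$undefined = TRUE` when both
#'   are 0), `$p_binomial` (two-sided exact sign test) and `$patterns`
#'   (+1 ABBA / -1 BABA / 0 otherwise, in pooled column order, for block
#'   resampling).
#' @export
abba_baba <- function(p1, p2, p3, p4) {
  pops <- list(p1, p2, p3, p4)
  ln <- vapply(pops, function(p) length(p$nuc), 0L)
  li <- vapply(pops, function(p) length(p$ind), 0L)
  if (length(unique(ln)) != 1L || length(unique(li)) != 1L) {
    stop("column/event set mismatch across populations")
  }
  s <- do.call(rbind, lapply(pops, function(p) c(p$nuc, p$ind)))
  nn <- ln[1L]; ni <- li[1L]
  det <- matrix(FALSE, nrow = 4L, ncol = nn + ni)
  if (nn) det[, seq_len(nn)] <- s[, seq_len(nn), drop = FALSE] %in%
      NUC_STATES
  if (ni) det[, nn + seq_len(ni)] <- s[, nn + seq_len(ni), drop = FALSE] %in%
      c("0", "1")
  ok <- colSums(det) == 4L
  anc <- s[4L, ]
  d1 <- s[1L, ] != anc; d2 <- s[2L, ] != anc; d3 <- s[3L, ] != anc
  # biallelic iff some non-ancestral state exists and all non-ancestral
  # states among P1..P3 are identical
  nonanc_same <- rep(TRUE, ncol(s))
  nonanc_same[d1 & d2 & s[1L, ] != s[2L, ]] <- FALSE
  nonanc_same[d1 & d3 & s[1L, ] != s[3L, ]] <- FALSE
  nonanc_same[d2 & d3 & s[2L, ] != s[3L, ]] <- FALSE
  informative <- ok & (d1 | d2 | d3) & nonanc_same
  abba <- informative & !d1 & d2 & d3
  baba <- informative & d1 & !d2 & d3
  n_abba <- sum(abba); n_baba <- sum(baba)
  undefined <- (n_abba + n_baba) == 0L
  D <- if (undefined) 0 else (n_abba - n_baba) / (n_abba + n_baba)
  p <- if (undefined) 1 else
    binom.test(n_abba, n_abba + n_baba, 0.5)$p.value
  patterns <- integer(ncol(s))
  patterns[abba] <- 1L
  patterns[baba] <- -1L
  structure(list(n_abba = n_abba, n_baba = n_baba,
                 n_informative = sum(informative), D = D,
                 undefined = undefined, p_binomial = p,
                 patterns = patterns),
            class = "abba_baba_result")
}

#' @export
print.abba_baba_result <- function(x, ...) {
  cat(sprintf("ABBA = %d  BABA = %d  (informative biallelic: %d)\n",
              x$n_abba, x$n_baba, x$n_informative))
  cat(sprintf("D = %.4f%s  binomial p = %.4g\n", x$D,
              if (x$undefined) " (undefined: no ABBA/BABA sites)" else "",
              x$p_binomial))
  invisible(x)
}

#' Significance of the D statistic
#'
#' Exact two-sided binomial sign test for ABBA = BABA, plus a block
#' bootstrap over contiguous column blocks of the pooled character set.
#'
#' @param res An [abba_baba()] result.
#' @param block_len Block length in pooled columns (default 1000).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional seed.
#' @return List: `$p_binomial`, `$p_boot`, `$D`, `$degenerate` (`TRUE`
#'   when no informative sites or when a single block spans everything,
#'   in which case `p_boot` is 1).
#' @export
dstat_significance <- function(res, block_len = 1000L, n_boot = 1000L,
                               seed = NULL) {
  stopifnot(inherits(res, "abba_baba_result"), block_len >= 1L)
  if (!is.null(seed)) set.seed(seed)
  C <- length(res$patterns)
  if (res$n_abba + res$n_baba == 0L) {
    return(list(p_binomial = 1, p_boot = 1, D = 0, degenerate = TRUE))
  }
  if (block_len >= C) {
    return(list(p_binomial = res$p_binomial, p_boot = 1, D = res$D,
                degenerate = TRUE))
  }
  block_id <- (seq_len(C) - 1L) %/% block_len + 1L
  sums <- tapply(res$patterns, block_id, sum)
  ns <- tapply(abs(res$patterns), block_id, sum)
  nb <- length(sums)
  Dstar <- vapply(seq_len(n_boot), function(i) {
    pick <- sample.int(nb, nb, replace = TRUE)
    tot <- sum(ns[pick])
    if (tot == 0) return(0)
    sum(sums[pick]) / tot
  }, 0)
  p_boot <- min(1, 2 * min(mean(Dstar <= 0), mean(Dstar >= 0)))
  list(p_binomial = res$p_binomial, p_boot = p_boot, D = res$D,
       degenerate = FALSE)
}
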