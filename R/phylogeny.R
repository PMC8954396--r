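# Tree inference at desk scale: Jukes-Cantor distances with pairwise
# deletion, a deterministic Saitou-Nei neighbor joining, vectorized Fitch
# parsimony (gaps and '?' as missing; 0/1 indel events as binary
# characters), heuristic MP search (random stepwise addition + NNI) and
# nonparametric bootstrap over the pooled column set.

JC_CAP <- 5.0

#' Jukes-Cantor distance between two taxa
#'
#' `d = -(3/4) log(1 - (4/3) p)` over pairwise-comparable nucleotide
#' columns. Saturated pairs (`p >= 0.75`) get the cap 5.0 and a
#' `saturated` attribute.
#'
#' @param aln A [capture_alignment()].
#' @param a,b Taxon ids.
#' @return Distance in substitutions/site with attributes `p`,
#'   `n_comparable`, `saturated`.
#' @export
jc_distance <- function(aln, a, b) {
  x <- aln$mat[a, ]; y <- aln$mat[b, ]
  comp <- x %in% NUC_STATES & y %in% NUC_STATES
  n <- sum(comp)
  if (n == 0L) stop("no pairwise-comparable columns for ", a, " / ", b)
  p <- sum(x[comp] != y[comp]) / n
  saturated <- p >= 0.75
  d <- if (saturated) JC_CAP else -0.75 * log(1 - 4 * p / 3)
  structure(d, p = p, n_comparable = n, saturated = saturated)
}

#' Pairwise Jukes-Cantor distance matrix (pairwise deletion)
#'
#' @param aln A [capture_alignment()].
#' @param taxa Taxa to include (default: all).
#' @param weights Optional per-column weights (bootstrap resampling);
#'   only nucleotide columns of the alignment are used.
#' @return Symmetric matrix with attribute `counts` (comparable columns,
#'   or total comparable weight, per pair).
#' @export
jc_dist_matrix <- function(aln, taxa = aln_taxa(aln), weights = NULL) {
  sub <- aln$mat[taxa, , drop = FALSE]
  if (is.null(weights)) weights <- rep(1, ncol(sub))
  stopifnot(length(weights) == ncol(sub))
  nt <- length(taxa)
  D <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
  N <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
  isnuc <- matrix(sub %in% NUC_STATES, nrow = nt)
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    comp <- isnuc[i, ] & isnuc[j, ]
    n <- sum(weights[comp])
    if (n == 0) stop("no pairwise-comparable columns for ", taxa[i], " / ",
                     taxa[j])
    p <- sum(weights[comp & sub[i, ] != sub[j, ]]) / n
    D[i, j] <- D[j, i] <- if (p >= 0.75) JC_CAP else -0.75 * log(1 - 4 * p / 3)
    N[i, j] <- N[j, i] <- n
  }
  attr(D, "counts") <- N
  D
}

#' Neighbor joining with deterministic tie-breaking
#'
#' Standard Saitou-Nei agglomeration. Ties in the Q criterion are broken
#' lexicographically on the smallest tip label of each cluster, so the
#' result is deterministic given the input. Negative branch lengths are
#' clamped to 0.
#'
#' @param D Symmetric distance matrix with taxon dimnames (>= 3 taxa, all
#'   entries finite).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 3L, isTRUE(all(is.finite(D))))
  labs <- rownames(D)
  frags <- labs
  reps <- labs
  d <- D
  n <- nrow(d)
  while (n > 3L) {
    rs <- rowSums(d)
    Q <- (n - 2) * d - outer(rs, rs, "+")
    diag(Q) <- Inf
    cand <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      paste(sort(c(reps[ij[1L]], reps[ij[2L]])), collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- max(0, 0.5 * d[i, j] + (rs[i] - rs[j]) / (2 * (n - 2)))
    lj <- max(0, d[i, j] - li)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], li, frags[j], lj)
    newrep <- min(reps[i], reps[j])
    dk <- pmax(0, 0.5 * (d[i, ] + d[j, ] - d[i, j]))
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frags <- c(frags[keep], newfrag)
    reps <- c(reps[keep], newrep)
    n <- n - 1L
  }
  la <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                                frags[1L], la, frags[2L], lb, frags[3L], lc))
}

# --- Fitch parsimony -------------------------------------------------------

# bitmask encoding of the pooled character set: nucleotide columns use
# 4-bit sets (missing/gap = full set 15), indel events 2-bit sets
# (missing = 3)
encode_characters <- function(aln, m = NULL) {
  taxa <- rownames(aln$mat)
  nucmap <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 15L, "?" = 15L)
  Mn <- matrix(nucmap[aln$mat], nrow = nrow(aln$mat),
               dimnames = list(taxa, NULL))
  if (!is.null(m) && nrow(m$events)) {
    imap <- c("0" = 1L, "1" = 2L, "?" = 3L)
    Mi <- matrix(imap[m$states[taxa, , drop = FALSE]], nrow = length(taxa))
    cbind(Mn, Mi)
  } else Mn
}

as_rooted_binary <- function(tree) {
  tr <- ape::unroot(tree)
  tr <- ape::root(tr, outgroup = tr$tip.label[1L], resolve.root = TRUE)
  ape::reorder.phylo(tr, "postorder")
}

# per-column Fitch step counts on a mask matrix (taxa x columns)
fitch_steps <- function(tree, masks, weights = NULL) {
  tr <- as_rooted_binary(tree)
  nt <- length(tr$tip.label)
  N <- nt + tr$Nnode
  C <- ncol(masks)
  S <- matrix(0L, N, C)
  S[seq_len(nt), ] <- masks[tr$tip.label, , drop = FALSE]
  filled <- c(rep(TRUE, nt), rep(FALSE, tr$Nnode))
  steps <- numeric(C)
  e <- tr$edge
  for (k in seq_len(nrow(e))) {
    p <- e[k, 1L]; ch <- e[k, 2L]
    if (!filled[p]) {
      S[p, ] <- S[ch, ]
      filled[p] <- TRUE
    } else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      empty <- inter == 0L
      steps <- steps + empty
      S[p, ] <- ifelse(empty, bitwOr(S[p, ], S[ch, ]), inter)
    }
  }
  if (is.null(weights)) sum(steps) else sum(steps * weights)
}

#' Fitch parsimony score of a tree
#'
#' Minimum mutation count summed over nucleotide columns (states
#' `A,C,G,T`; `-` and `?` are missing, i.e. the universal state) plus
#' binary indel events (`0/1`, `?` missing). The score is an unrooted
#' quantity: it is invariant under re-rooting.
#'
#' @param tree A `phylo`; its leaves must all occur in the alignment.
#' @param aln A [capture_alignment()].
#' @param m Optional [indel_matrix()] pooled into the character set.
#' @param weights Optional per-pooled-column weights (bootstrap).
#' @return Numeric parsimony steps.
#' @export
fitch_score <- function(tree, aln, m = NULL, weights = NULL) {
  missing_tips <- setdiff(tree$tip.label, rownames(aln$mat))
  if (length(missing_tips)) {
    stop("tree leaf absent from alignment: ", missing_tips[1L])
  }
  masks <- encode_characters(aln, m)
  fitch_steps(tree, masks, weights)
}

# --- heuristic MP search ---------------------------------------------------

# edge-list tree used during stepwise addition: data.frame(parent, child)
# over character ids; internal ids are "#k"
elist_newick <- function(el, root = "#0") {
  kids <- split(el$child, el$parent)
  rec <- function(id) {
    ch <- kids[[id]]
    if (is.null(ch)) return(id)
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

attach_tip_el <- function(el, k, tip, newid) {
  u <- el$parent[k]; v <- el$child[k]
  el$parent[k] <- u; el$child[k] <- newid
  rbind(el, data.frame(parent = c(newid, newid), child = c(v, tip),
                       stringsAsFactors = FALSE))
}

#' Heuristic maximum-parsimony search
#'
#' Random stepwise-addition start trees improved by NNI to a local
#' optimum; the best score over `n_starts` seeded starts is returned. All
#' distinct optimal topologies found are kept and collapsed to a strict
#' consensus.
#'
#' @param aln A [capture_alignment()] (>= 4 taxa).
#' @param m Optional [indel_matrix()].
#' @param n_starts Number of random-addition starts (default 10).
#' @param seed Integer seed.
#' @param taxa Taxa to include (default: all alignment taxa).
#' @param weights Optional pooled-column weights.
#' @return List: `$tree` (best), `$score`, `$trees` (all tied optima),
#'   `$consensus` (strict consensus of the tied optima).
#' @export
mp_search <- function(aln, m = NULL, n_starts = 10L, seed = 1L,
                      taxa = aln_taxa(aln), weights = NULL) {
  stopifnot(length(taxa) >= 4L)
  set.seed(seed)
  masks <- encode_characters(aln, m)
  masks <- masks[taxa, , drop = FALSE]
  sc <- function(tr) fitch_steps(tr, masks, weights)
  best_score <- Inf
  best_trees <- list()
  for (s in seq_len(n_starts)) {
    ord <- sample(taxa)
    el <- data.frame(parent = rep("#0", 3L), child = ord[1:3],
                     stringsAsFactors = FALSE)
    next_id <- 1L
    for (t in ord[-(1:3)]) {
      cand_scores <- vapply(seq_len(nrow(el)), function(k) {
        el2 <- attach_tip_el(el, k, t, paste0("#", next_id))
        sc(ape::read.tree(text = elist_newick(el2)))
      }, 0)
      k_best <- which.min(cand_scores)
      el <- attach_tip_el(el, k_best, t, paste0("#", next_id))
      next_id <- next_id + 1L
    }
    tr <- ape::read.tree(text = elist_newick(el))
    cur <- sc(tr)
    repeat {
      nb <- phangorn::nni(tr)
      nb_scores <- vapply(nb, sc, 0)
      if (min(nb_scores) < cur) {
        tr <- nb[[which.min(nb_scores)]]
        cur <- min(nb_scores)
      } else break
    }
    if (cur < best_score - 1e-9) {
      best_score <- cur
      best_trees <- list(tr)
    } else if (abs(cur - best_score) <= 1e-9) {
      if (!any(vapply(best_trees, function(b) {
        phangorn::RF.dist(b, tr) == 0
      }, TRUE))) {
        best_trees <- c(best_trees, list(tr))
      }
    }
  }
  cons <- if (length(best_trees) > 1L) {
    ape::consensus(best_trees, p = 1)
  } else best_trees[[1L]]
  list(tree = best_trees[[1L]], score = best_score, trees = best_trees,
       consensus = cons)
}

# canonical bipartitions of an unrooted tree (non-trivial splits)
tree_splits <- function(tree) {
  tr <- ape::unroot(tree)
  nt <- length(tr$tip.label)
  anchor <- sort(tr$tip.label)[1L]
  desc <- phangorn::Descendants(tr, seq_len(nt + tr$Nnode), "tips")
  out <- character(0)
  if (tr$Nnode < 2L) return(out)
  for (nd in (nt + 2L):(nt + tr$Nnode)) {  # skip the root trifurcation
    tips <- tr$tip.label[desc[[nd]]]
    if (length(tips) <= 1L || length(tips) >= nt - 1L) next
    if (anchor %in% tips) tips <- setdiff(tr$tip.label, tips)
    out <- c(out, paste(sort(tips), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support on the best tree's bipartitions
#'
#' Resamples the pooled column set (nucleotide columns and indel events
#' together) with replacement, re-infers a tree per replicate (`nj` on
#' weighted JC distances or `mp` with weighted Fitch, one random-addition
#' start), and annotates each bipartition of the best tree with its
#' replicate frequency x 100.
#'
#' @param aln A [capture_alignment()].
#' @param m Optional [indel_matrix()].
#' @param B Number of replicates.
#' @param method `"nj"` or `"mp"`.
#' @param seed Integer seed.
#' @param taxa Taxa to include.
#' @param best Optional precomputed best tree; inferred from the original
#'   data when `NULL`.
#' @return List: `$tree` (best tree with `node.label` supports),
#'   `$support` (named vector per bipartition), `$trees` (replicates).
#' @export
bootstrap_tree <- function(aln, m = NULL, B = 100L,
                           method = c("nj", "mp"), seed = 1L,
                           taxa = aln_taxa(aln), best = NULL) {
  method <- match.arg(method)
  stopifnot(B >= 1L)
  set.seed(seed)
  Cn <- ncol(aln$mat)
  Ce <- if (!is.null(m)) nrow(m$events) else 0L
  C <- Cn + Ce
  infer <- function(w) {
    if (method == "nj") {
      neighbor_joining(jc_dist_matrix(aln, taxa, weights = w[seq_len(Cn)]))
    } else {
      mp_search(aln, m, n_starts = 1L, seed = sample.int(2^30, 1L),
                taxa = taxa, weights = w)$tree
    }
  }
  if (is.null(best)) best <- infer(rep(1, C))
  sp_best <- tree_splits(best)
  counts <- setNames(numeric(length(sp_best)), sp_best)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(C, C, replace = TRUE), C)
    tr_b <- infer(w)
    reps[[b]] <- tr_b
    sp <- tree_splits(tr_b)
    hit <- sp_best %in% sp
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / B
  best <- annotate_supports(best, support)
  list(tree = best, support = support, trees = reps)
}

annotate_supports <- function(tree, support) {
  tr <- tree
  nt <- length(tr$tip.label)
  anchor <- sort(tr$tip.label)[1L]
  desc <- phangorn::Descendants(tr, seq_len(nt + tr$Nnode), "tips")
  labs <- character(tr$Nnode)
  for (nd in (nt + 1L):(nt + tr$Nnode)) {
    tips <- tr$tip.label[desc[[nd]]]
    if (length(tips) <= 1L || length(tips) >= nt - 1L) next
    if (anchor %in% tips) tips <- setdiff(tr$tip.label, tips)
    key <- paste(sort(tips), collapse = "|")
    if (key %in% names(support)) {
      labs[nd - nt] <- sprintf("%g", support[[key]])
    }
  }
  tr$node.label <- labs
  tr
}
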