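# Penalized-likelihood divergence dating on a fixed rooted topology with
# fossil min/max node-age calibrations. The objective is the negative
# Poisson log-likelihood of per-branch substitution counts plus a
# lambda-weighted roughness penalty on rate changes between adjacent
# branches (variance of the root children's rates at the root), minimized
# by alternating 1-D coordinate passes over node ages and branch rates
# with box projection. Deterministic: no RNG anywhere in the fit.

#' A fossil calibration on the MRCA of a leaf set
#'
#' @param leaves Two or more leaf names whose MRCA is constrained. With
#'   exactly two leaves the pair simply spans the MRCA; with more, the
#'   clade is required to be exactly monophyletic in the dated tree.
#' @param min_age,max_age Age bounds in Mya; `0 < min_age <= max_age`.
#' @param label Optional label for error messages.
#' @return A `calibration` object.
#' @export
calibration <- function(leaves, min_age, max_age = Inf, label = NULL) {
  stopifnot(length(leaves) >= 2L, min_age > 0, min_age <= max_age)
  structure(list(leaves = leaves, min_age = min_age, max_age = max_age,
                 label = if (is.null(label))
                   paste(leaves[1:2], collapse = "-") else label),
            class = "calibration")
}

#' Pinaceae fossil calibration set
#'
#' The four clade calibrations used for dating the fir phylogeny:
#' Pinaceae crown 155-308.5 Mya, the *Abies*-*Keteleeria* split
#' 45.5-113.8 Mya, the *Abies* crown 13.5-45.5 Mya, and the
#' *Larix*-*Picea* split 133-308.5 Mya.
#'
#' @param pinaceae,abies_keteleeria,abies,larix_picea Leaf-name vectors
#'   spanning each calibrated MRCA; `NULL` entries are dropped.
#' @return List of [calibration()] objects.
#' @export
pinaceae_calibrations <- function(pinaceae = NULL, abies_keteleeria = NULL,
                                  abies = NULL, larix_picea = NULL) {
  out <- list()
  if (!is.null(pinaceae)) {
    out <- c(out, list(calibration(pinaceae, 155, 308.5, "Pinaceae crown")))
  }
  if (!is.null(abies_keteleeria)) {
    out <- c(out, list(calibration(abies_keteleeria, 45.5, 113.8,
                                   "Abies-Keteleeria")))
  }
  if (!is.null(abies)) {
    out <- c(out, list(calibration(abies, 13.5, 45.5, "Abies crown")))
  }
  if (!is.null(larix_picea)) {
    out <- c(out, list(calibration(larix_picea, 133, 308.5, "Larix-Picea")))
  }
  out
}

#' Read calibrations from TSV (label, leaves comma-separated, min, max)
#' @param path Path to a 4-column TSV with header.
#' @return List of [calibration()] objects.
#' @export
read_calibrations <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    calibration(strsplit(df$leaves[i], ",")[[1L]], df$min[i], df$max[i],
                df$label[i])
  })
}

# x * log(mu) with the x = 0 convention (0 * log(0) = 0), underflow-safe
poisson_loglin <- function(x, mu) {
  out <- x * log(pmax(mu, .Machine$double.xmin))
  out[x == 0] <- 0
  out
}

calibration_node <- function(tree, cal) {
  miss <- setdiff(cal$leaves, tree$tip.label)
  if (length(miss)) stop("calibration '", cal$label,
                         "' names unknown leaf: ", miss[1L])
  nd <- ape::getMRCA(tree, cal$leaves)
  if (length(cal$leaves) > 2L) {
    below <- tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1L]]]
    if (!setequal(below, cal$leaves)) {
      stop("calibration clade '", cal$label,
           "' is not monophyletic in the tree")
    }
  }
  nd
}

#' Penalized-likelihood objective for a dated tree
#'
#' `score = -sum_k [x_k log(r_k t_k) - r_k t_k - log(x_k!)] +
#' lambda * [sum_nonroot (r_k - r_parent(k))^2 + Var(rates of root
#' children)]` where `x_k` is the branch length times `n_sites` rounded
#' to the nearest integer (floored at 0) and `t_k` the branch duration.
#' Lower is better.
#'
#' @param tree Rooted `phylo` with branch lengths in substitutions/site.
#' @param ages Numeric vector of node ages (length `ntip + Nnode`; tip
#'   entries 0).
#' @param rates Per-edge rates, all > 0, on the count scale of `x_k`
#'   (expected substitutions per Mya across the whole alignment; divide
#'   by `n_sites` for per-site rates).
#' @param lambda Smoothing weight (>= 0).
#' @param n_sites Number of alignment sites behind the branch lengths.
#' @return The scalar score.
#' @export
pl_objective <- function(tree, ages, rates, lambda, n_sites) {
  e <- tree$edge
  t_k <- ages[e[, 1L]] - ages[e[, 2L]]
  if (any(t_k <= 0)) stop("non-positive branch duration")
  stopifnot(all(rates > 0), lambda >= 0)
  x <- pmax(round(tree$edge.length * n_sites), 0)
  pois <- -(poisson_loglin(x, rates * t_k) - rates * t_k - lgamma(x + 1))
  root <- length(tree$tip.label) + 1L
  is_rc <- e[, 1L] == root
  pedge <- match(e[, 1L], e[, 2L])
  pen <- sum((rates[!is_rc] - rates[pedge[!is_rc]])^2)
  rc <- rates[is_rc]
  if (length(rc) > 1L) pen <- pen + var(rc)
  sum(pois) + lambda * pen
}

#' Date a tree by penalized likelihood under fossil calibrations
#'
#' Minimizes [pl_objective()] over node ages and branch rates subject to
#' parent-older-than-child ordering and the calibration boxes, by
#' alternating deterministic 1-D coordinate passes (golden-section via
#' [stats::optimize()]) with box projection, from a proportional-depth
#' initialization scaled into the root calibration window.
#'
#' @param tree Rooted `phylo` with branch lengths in substitutions/site.
#' @param calibrations List of [calibration()] objects (at least one with
#'   a finite bound so the time scale is identified).
#' @param lambda Smoothing weight (default 1).
#' @param n_sites Alignment sites behind the branch lengths.
#' @param tol Relative score-change convergence threshold (default 1e-8).
#' @param max_sweeps Maximum coordinate sweeps (default 10000).
#' @return A `chronogram`: `$tree` (input topology with branch lengths in
#'   Mya), `$ages` (per-node, tips 0), `$rates` (per edge, count scale),
#'   `$rates_per_site`, `$lambda`, `$score`, `$converged`, `$clade_ages`
#'   (ages keyed by sorted clade tip sets).
#' @export
date_tree <- function(tree, calibrations, lambda = 1, n_sites,
                      tol = 1e-8, max_sweeps = 10000L) {
  stopifnot(ape::is.rooted(tree), length(calibrations) >= 1L)
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  N <- nt + nn
  root <- nt + 1L
  e <- tree$edge
  ne <- nrow(e)
  x <- pmax(round(tree$edge.length * n_sites), 0)

  lo <- rep(0, N); hi <- rep(Inf, N)
  hi[seq_len(nt)] <- 0
  for (cal in calibrations) {
    nd <- calibration_node(tree, cal)
    lo[nd] <- max(lo[nd], cal$min_age)
    hi[nd] <- min(hi[nd], cal$max_age)
    if (lo[nd] > hi[nd]) {
      stop("infeasible calibration box at '", cal$label, "'")
    }
  }
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(ne)) {                      # child mins push parents up
    lo[po[k, 1L]] <- max(lo[po[k, 1L]], lo[po[k, 2L]])
  }
  for (k in rev(seq_len(ne))) {                 # parent maxes cap children
    if (po[k, 2L] > nt) hi[po[k, 2L]] <- min(hi[po[k, 2L]], hi[po[k, 1L]])
  }
  for (nd in (nt + 1L):N) {
    if (lo[nd] > hi[nd]) {
      stop("infeasible calibrations: node ", nd, " needs age >= ", lo[nd],
           " but is capped at ", hi[nd])
    }
  }

  # proportional-depth initialization scaled into the root window
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  if (max(h) == 0) h <- ape::node.depth(tree) - 1
  relh <- h / max(h)
  root_age <- if (is.finite(hi[root])) {
    (max(lo[root], hi[root] / 2) + hi[root]) / 2
  } else max(1, 2 * lo[root])
  eps <- root_age * 1e-9
  ages <- root_age * relh
  ages[seq_len(nt)] <- 0
  # preorder projection: parents first, so each node fits under its parent
  pre_nodes <- unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1L])
  parent_of <- rep(NA_integer_, N)
  parent_of[e[, 2L]] <- e[, 1L]
  children <- split(e[, 2L], e[, 1L])
  ages[root] <- min(max(ages[root], lo[root]), hi[root])
  for (nd in pre_nodes) {
    if (nd == root) next
    up <- min(hi[nd], ages[parent_of[nd]] - eps)
    if (up < lo[nd]) {
      stop("infeasible calibrations between node ", nd, " (min ", lo[nd],
           ") and its ancestor (", ages[parent_of[nd]], ")")
    }
    ages[nd] <- min(max(ages[nd], lo[nd]), up)
  }

  # rates live on the count scale of x (substitutions per Mya across the
  # whole alignment); per-site rates are derived on output
  t_of <- function(a) a[e[, 1L]] - a[e[, 2L]]
  r0 <- sum(x) / max(sum(t_of(ages)), eps)
  r0 <- max(r0, 1e-12)
  rates <- rep(r0, ne)
  is_rc <- e[, 1L] == root
  pedge <- match(e[, 1L], e[, 2L])
  chedges <- split(seq_len(ne), e[, 1L])   # edges below each node

  score_full <- function() {
    t_k <- t_of(ages)
    pois <- -(poisson_loglin(x, rates * t_k) - rates * t_k - lgamma(x + 1))
    pen <- sum((rates[!is_rc] - rates[pedge[!is_rc]])^2)
    rc <- rates[is_rc]
    if (length(rc) > 1L) pen <- pen + var(rc)
    sum(pois) + lambda * pen
  }

  internal <- (nt + 1L):N
  old <- score_full()
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    for (nd in internal) {
      kids <- children[[as.character(nd)]]
      up_e <- which(e[, 2L] == nd)              # edge above nd (0 for root)
      touch <- c(up_e, chedges[[as.character(nd)]])
      lower <- max(lo[nd], ages[kids] + eps)
      upper <- min(hi[nd], if (length(up_e)) ages[e[up_e, 1L]] - eps else Inf)
      if (!is.finite(upper)) upper <- max(lower * 4, lower + 1)
      if (upper - lower < 4 * eps) next
      f <- function(a) {
        aa <- ages; aa[nd] <- a
        tt <- aa[e[touch, 1L]] - aa[e[touch, 2L]]
        rt <- rates[touch] * tt
        -sum(poisson_loglin(x[touch], rt) - rt)
      }
      opt <- optimize(f, c(lower, upper))
      cand <- c(ages[nd], opt$minimum, lower, upper)
      ages[nd] <- cand[which.min(vapply(cand, f, 0))]
    }
    # exact coordinate updates for rates (positive root of the quadratic
    # stationarity condition), Gauss-Seidel until the block converges
    t_k <- t_of(ages)
    m_rc <- sum(is_rc)
    rmin <- r0 * 1e-9
    for (pass in seq_len(100L)) {
      delta <- 0
      for (k in seq_len(ne)) {
        kids_e <- chedges[[as.character(e[k, 2L])]]
        nbr <- c(if (!is_rc[k]) pedge[k], kids_e)
        A <- length(nbr)
        B <- sum(rates[nbr])
        if (is_rc[k] && m_rc > 1L) {
          s_rest <- sum(rates[is_rc]) - rates[k]
          A <- A + 1 / m_rc
          B <- B + s_rest / (m_rc * (m_rc - 1L))
        }
        r_new <- if (lambda * A > 0) {
          b1 <- t_k[k] - 2 * lambda * B
          (-b1 + sqrt(b1^2 + 8 * lambda * A * x[k])) / (4 * lambda * A)
        } else if (x[k] > 0) x[k] / t_k[k] else rmin
        r_new <- max(r_new, rmin)
        delta <- max(delta, abs(r_new - rates[k]) / max(rates[k], rmin))
        rates[k] <- r_new
      }
      if (delta < 1e-8) break
    }
    new <- score_full()
    if (abs(old - new) < tol * max(1, abs(old))) {
      converged <- TRUE
      old <- new
      break
    }
    old <- new
  }

  # post-hoc invariants
  stopifnot(all(t_of(ages) > 0), all(rates > 0))
  for (cal in calibrations) {
    nd <- calibration_node(tree, cal)
    slack <- 1e-6 * max(1, cal$max_age)
    stopifnot(ages[nd] >= cal$min_age - slack,
              ages[nd] <= cal$max_age + slack)
  }

  out_tree <- tree
  out_tree$edge.length <- t_of(ages)
  desc <- phangorn::Descendants(tree, internal, "tips")
  clade_ages <- setNames(ages[internal], vapply(desc, function(d) {
    paste(sort(tree$tip.label[d]), collapse = "|")
  }, ""))
  structure(list(tree = out_tree, ages = ages, rates = rates,
                 rates_per_site = rates / n_sites,
                 lambda = lambda, score = old, converged = converged,
                 n_sites = n_sites, clade_ages = clade_ages),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("chronogram: %d tips, lambda = %g, score = %.4f%s\n",
              length(x$tree$tip.label), x$lambda, x$score,
              if (x$converged) "" else " (not converged)"))
  ages <- sort(x$clade_ages, decreasing = TRUE)
  print(round(ages, 3))
  invisible(x)
}

#' Choose the smoothing weight by branch-pruning cross-validation
#'
#' For each candidate lambda, each terminal branch whose parent is not
#' the root is pruned in turn, the remaining tree re-dated, and the
#' pruned branch's substitution count predicted from the fitted rate of
#' the merged edge and the (interpolated) attachment age; the lambda
#' minimizing the summed chi-square prediction error wins, with ties
#' going to the larger (smoother) lambda.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param calibrations List of [calibration()] objects.
#' @param n_sites Alignment sites behind the branch lengths.
#' @param grid Candidate lambdas (default `c(0.1, 1, 10, 100, 1000)`).
#' @return List: `$lambda` (selected), `$cv_error` (named per-grid-point).
#' @export
select_lambda <- function(tree, calibrations, n_sites,
                          grid = c(0.1, 1, 10, 100, 1000)) {
  stopifnot(length(grid) >= 1L)
  if (length(grid) == 1L) {
    return(list(lambda = grid, cv_error = setNames(NA_real_, grid)))
  }
  nt <- length(tree$tip.label)
  root <- nt + 1L
  e <- tree$edge
  errs <- setNames(numeric(length(grid)), grid)
  desc <- phangorn::Descendants(tree, seq_len(nt + tree$Nnode), "tips")
  for (gi in seq_along(grid)) {
    lam <- grid[gi]
    tot <- 0
    for (i in seq_len(nt)) {
      pe <- which(e[, 2L] == i)
      p <- e[pe, 1L]
      if (p == root) next   # root-adjacent tips cannot be cross-validated
      g <- e[e[, 2L] == p, 1L]
      sib_e <- setdiff(which(e[, 1L] == p), pe)
      sib <- e[sib_e, 2L]
      pr <- ape::drop.tip(tree, tree$tip.label[i])
      cals2 <- list()
      for (cal in calibrations) {
        lv <- setdiff(cal$leaves, tree$tip.label[i])
        if (length(lv) >= 2L) {
          cals2 <- c(cals2, list(calibration(lv, cal$min_age, cal$max_age,
                                             cal$label)))
        }
      }
      if (!length(cals2)) next
      fit <- date_tree(pr, cals2, lam, n_sites)
      key_g <- paste(sort(setdiff(tree$tip.label[desc[[g]]],
                                  tree$tip.label[i])), collapse = "|")
      age_g <- if (key_g %in% names(fit$clade_ages)) {
        fit$clade_ages[[key_g]]
      } else next
      sib_tips <- tree$tip.label[desc[[sib]]]
      age_s <- if (length(sib_tips) == 1L) 0 else {
        key_s <- paste(sort(sib_tips), collapse = "|")
        fit$clade_ages[[key_s]]
      }
      # merged edge in the pruned tree ends at the sibling subtree root
      pr_nt <- length(pr$tip.label)
      pr_desc <- phangorn::Descendants(pr, seq_len(pr_nt + pr$Nnode),
                                       "tips")
      target <- if (length(sib_tips) == 1L) {
        match(sib_tips, pr$tip.label)
      } else {
        keys <- vapply(pr_desc, function(d) {
          paste(sort(pr$tip.label[d]), collapse = "|")
        }, "")
        which(keys == paste(sort(sib_tips), collapse = "|"))[1L]
      }
      me <- which(pr$edge[, 2L] == target)
      r_hat <- fit$rates[me]
      # interpolate the attachment age along g -> sibling
      l_gp <- tree$edge.length[e[, 2L] == p]
      l_ps <- tree$edge.length[sib_e]
      phi <- if (l_gp + l_ps > 0) l_gp / (l_gp + l_ps) else 0.5
      t_hat <- age_g - phi * (age_g - age_s)
      x_obs <- max(round(tree$edge.length[pe] * n_sites), 0)
      x_hat <- r_hat * t_hat   # rates are on the count scale
      tot <- tot + (x_obs - x_hat)^2 / max(x_hat, 1)
    }
    errs[gi] <- tot
  }
  # CV errors are chi-square-like; differences below 1% of the error scale
  # (well under one substitution) are ties, resolved toward the smoother fit
  best <- which(errs <= min(errs) + 0.01 * (1 + min(errs)))
  list(lambda = grid[max(best)], cv_error = errs)
}

# split the root edge after re-rooting an unrooted tree so that the mean
# root-to-tip depth is equal on both sides (the clock-consistent choice;
# distances alone cannot place the root along its edge)
balance_root_edges <- function(tree) {
  nt <- length(tree$tip.label)
  rc <- which(tree$edge[, 1L] == nt + 1L)
  if (length(rc) != 2L) return(tree)
  tot <- sum(tree$edge.length[rc])
  depth_below <- function(node) {
    if (node <= nt) return(0)
    tips <- phangorn::Descendants(tree, node, "tips")[[1L]]
    d <- ape::node.depth.edgelength(tree)
    mean(d[tips]) - d[node]
  }
  a <- vapply(tree$edge[rc, 2L], depth_below, 0)
  l1 <- min(max((tot + a[2L] - a[1L]) / 2, 0), tot)
  tree$edge.length[rc] <- c(l1, tot - l1)
  tree
}

#' Bootstrap node-age summaries on a fixed topology
#'
#' Per replicate, the pooled column set is resampled, branch lengths are
#' re-fit on the fixed topology by non-negative least squares against the
#' weighted JC distance matrix, the root edge is split evenly, and the
#' tree is dated; ages are summarized per node as the mean and central
#' 95% interval across replicates.
#'
#' @param aln A [capture_alignment()].
#' @param m Optional [indel_matrix()].
#' @param topology Rooted `phylo` covering the alignment taxa to date.
#' @param calibrations List of [calibration()] objects.
#' @param B Replicates (default 100).
#' @param seed Integer seed.
#' @param lambda Smoothing weight (default 1).
#' @return List: `$summary` (data frame clade / mean / lo95 / hi95),
#'   `$ages` (B x clades matrix).
#' @export
bootstrap_ages <- function(aln, m = NULL, topology, calibrations,
                           B = 100L, seed = 1L, lambda = 1) {
  stopifnot(ape::is.rooted(topology), B >= 1L)
  set.seed(seed)
  taxa <- topology$tip.label
  stopifnot(all(taxa %in% rownames(aln$mat)))
  Cn <- ncol(aln$mat)
  Ce <- if (!is.null(m)) nrow(m$events) else 0L
  C <- Cn + Ce
  utop <- ape::unroot(topology)
  nt <- length(taxa)
  og <- topology$tip.label[
    phangorn::Descendants(topology, topology$edge[
      topology$edge[, 1L] == nt + 1L, 2L][1L], "tips")[[1L]]]
  if (length(og) == nt) og <- og[1L]
  rows <- vector("list", B)
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(C, C, replace = TRUE), C)
    dm <- jc_dist_matrix(aln, taxa, weights = w[seq_len(Cn)])
    ft <- phangorn::nnls.tree(dm, utop, method = "unrooted")
    ft$edge.length <- pmax(ft$edge.length, 0)
    rt <- tryCatch(ape::root(ft, outgroup = og, resolve.root = TRUE),
                   error = function(e) {
                     ape::root(ft, outgroup = setdiff(taxa, og),
                               resolve.root = TRUE)
                   })
    rt <- balance_root_edges(rt)
    fit <- date_tree(rt, calibrations, lambda, n_sites = Cn)
    rows[[b]] <- fit$clade_ages
  }
  keys <- names(rows[[1L]])
  ages <- do.call(rbind, lapply(rows, function(r) r[keys]))
  colnames(ages) <- keys
  summary <- data.frame(
    clade = keys,
    mean = colMeans(ages),
    lo95 = apply(ages, 2L, quantile, 0.025),
    hi95 = apply(ages, 2L, quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, ages = ages)
}
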