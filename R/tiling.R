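# Long-range-PCR amplicon window planner: tile each contig with the
# provably minimal number of 10-12 kb windows, spreading the unavoidable
# overlap as evenly as possible.

#' Plan amplicon windows over contigs
#'
#' Per contig the window count is the minimum `k = ceiling(length /
#' max_len)`. Windows get equal length `ceiling(length / k)`; when that
#' would fall below `min_len`, the length is pinned to `min_len`. Window
#' starts are spread evenly (largest-remainder placement), so consecutive
#' windows overlap minimally and the union covers the contig exactly.
#' Contigs shorter than `min_len` are skipped with a warning.
#'
#' @param contigs Data frame with columns `id` and `length`, or a named
#'   numeric vector of lengths.
#' @param min_len,max_len Allowed window length band in bp (defaults
#'   10,000-12,000).
#' @return An `amplicon_plan`: `$windows` (contig, start, end; 0-based
#'   half-open), `$summary` (per-contig window count and total bp) and the
#'   length band.
#' @export
plan_amplicons <- function(contigs, min_len = 10000L, max_len = 12000L) {
  if (min_len > max_len) stop("min_len > max_len")
  if (!is.data.frame(contigs)) {
    contigs <- data.frame(id = names(contigs), length = as.integer(contigs),
                          stringsAsFactors = FALSE)
  }
  short <- contigs$length < min_len
  if (any(short)) {
    warning("skipping ", sum(short), " contig(s) shorter than min_len: ",
            paste(contigs$id[short], collapse = ", "))
    contigs <- contigs[!short, , drop = FALSE]
  }
  win <- lapply(seq_len(nrow(contigs)), function(i) {
    L <- contigs$length[i]
    k <- ceiling(L / max_len)
    w <- ceiling(L / k)
    if (w < min_len) w <- min_len
    starts <- if (k == 1L) 0L else floor((0:(k - 1L)) * (L - w) / (k - 1L))
    data.frame(contig = contigs$id[i], start = as.integer(starts),
               end = as.integer(starts + w), stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, c(win, list(data.frame(contig = character(),
                                                   start = integer(),
                                                   end = integer()))))
  summary <- data.frame(
    contig = contigs$id,
    length = contigs$length,
    n_windows = vapply(win, nrow, 0L),
    total_bp = vapply(win, function(d) sum(d$end - d$start), 0L),
    stringsAsFactors = FALSE)
  structure(list(windows = windows, summary = summary,
                 min_len = min_len, max_len = max_len),
            class = "amplicon_plan")
}

#' Write an amplicon plan as BED (0-based half-open)
#'
#' @param plan An [plan_amplicons()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(plan, path) {
  stopifnot(inherits(plan, "amplicon_plan"))
  w <- plan$windows
  w$name <- sprintf("%s_amp%03d", w$contig,
                    unlist(lapply(split(seq_len(nrow(w)), w$contig)[
                      unique(w$contig)], seq_along)))
  write.table(w[, c("contig", "start", "end", "name")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
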