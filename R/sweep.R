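#' Diversity and differentiation scan at sweep resolution
#'
#' [window_stats()] at 10-kb resolution without the (slow, unused) Tajima's
#' D columns: per window pi in each population, F_ST and ROD (ROD is `NA`
#' where `pi_wild = 0`).
#'
#' @inheritParams window_stats
#' @param window window size in bp (default 10 kb).
#' @return A `window_stats` data.frame.
#' @export
scan_windows <- function(m, meta, layout, window = 1e4) {
  window_stats(m, meta, layout, window = window, tajima = FALSE)
}

# nearest-rank upper-tail threshold: the k-th largest value where
# k = n - floor(q * n); calling ">= threshold" keeps the top (1-q) tail,
# with ties at the threshold included.
upper_tail_threshold <- function(x, q) {
  x <- x[!is.na(x)]
  n <- length(x)
  k <- n - floor(q * n)
  if (k < 1L) k <- 1L
  sort(x, decreasing = TRUE)[k]
}

#' Call selection (domestication-sweep) windows
#'
#' A window is called as under selection iff its ROD and its F_ST both lie
#' in the upper tail of the pooled empirical distributions: value >= the
#' nearest-rank upper-`(1-q)` threshold of each statistic, computed over the
#' windows where that statistic is defined.  Windows with an undefined ROD
#' (`pi_wild = 0`) or F_ST are never called and do not enter the pools.
#'
#' @param t a `window_stats` table (needs `rod` and `fst` columns).
#' @param q empirical quantile (default 0.95, i.e. top 5% of both tails).
#' @param min_defined minimum number of windows with both statistics
#'   defined (default 20).
#' @return `t` with added logical column `called` plus attributes
#'   `threshold_rod` and `threshold_fst`.
#' @export
call_selection_windows <- function(t, q = 0.95, min_defined = 20L) {
  stopifnot(q >= 0, q < 1)
  ok <- !is.na(t$rod) & !is.na(t$fst)
  if (sum(ok) < min_defined)
    stop("too few windows with both ROD and F_ST defined (",
         sum(ok), " < ", min_defined, ")")
  thr_rod <- upper_tail_threshold(t$rod, q)
  thr_fst <- upper_tail_threshold(t$fst, q)
  t$called <- ok & t$rod >= thr_rod & t$fst >= thr_fst
  attr(t, "threshold_rod") <- thr_rod
  attr(t, "threshold_fst") <- thr_fst
  t
}

#' Merge called windows into sweep regions
#'
#' Adjacent (book-ended) called windows on the same chromosome are merged;
#' the total merged extent always equals window size times the number of
#' called windows.
#'
#' @param t output of [call_selection_windows()] (needs `called`).
#' @return data.frame of class `sweep_regions`: `chrom`, `start`, `end`
#'   (0-based half-open), `n_windows`, `mean_rod`, `mean_fst`, with
#'   attributes `n_regions` and `n_singletons`.
#' @export
merge_called <- function(t) {
  cw <- t[which(t$called), , drop = FALSE]
  if (!nrow(cw)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      mean_rod = numeric(), mean_fst = numeric())
  } else {
    cw <- cw[order(cw$chrom, cw$start), ]
    new_run <- c(TRUE, !(cw$chrom[-1] == cw$chrom[-nrow(cw)] &
                           cw$start[-1] == cw$end[-nrow(cw)]))
    grp <- cumsum(new_run)
    out <- do.call(rbind, lapply(split(cw, grp), function(g) data.frame(
      chrom = g$chrom[1], start = g$start[1], end = g$end[nrow(g)],
      n_windows = nrow(g), mean_rod = mean(g$rod), mean_fst = mean(g$fst),
      stringsAsFactors = FALSE)))
    rownames(out) <- NULL
  }
  attr(out, "n_regions") <- nrow(out)
  attr(out, "n_singletons") <- sum(out$n_windows == 1L)
  class(out) <- c("sweep_regions", "data.frame")
  out
}

#' Attach overlapping genes to sweep regions
#'
#' A gene is listed for a region iff its span overlaps the region by at
#' least 1 bp; a gene spanning two regions is listed in both but counted
#' once in the unique-gene attribute.
#'
#' @param regions a `sweep_regions` data.frame (0-based half-open).
#' @param genes a [gene_set()].
#' @return `regions` with a list-column `genes` of overlapping gene ids and
#'   attribute `n_genes` (number of distinct genes across all regions).
#' @export
annotate_regions <- function(regions, genes) {
  gl <- rep(list(character(0)), nrow(regions))
  if (nrow(regions) && nrow(genes$genes)) {
    rg <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start + 1, regions$end))
    gg <- GenomicRanges::GRanges(
      genes$genes$chrom,
      IRanges::IRanges(genes$genes$start + 1, genes$genes$end))
    hit <- GenomicRanges::findOverlaps(rg, gg)
    hl <- split(genes$genes$id[S4Vectors::subjectHits(hit)],
                S4Vectors::queryHits(hit))
    gl[as.integer(names(hl))] <- unname(hl)
  }
  regions$genes <- gl
  attr(regions, "n_genes") <- length(unique(unlist(gl)))
  regions
}

#' Genome fraction covered by sweep regions
#'
#' `100 * total region bp / total genome bp`, reported to 2 decimals.
#'
#' @param regions a `sweep_regions` data.frame (or any data.frame with
#'   `start`, `end`).
#' @param layout a [genome_layout()].
#' @return Percentage (numeric scalar, 2 decimals).
#' @export
genome_fraction <- function(regions, layout) {
  tot <- genome_length(layout)
  stopifnot(tot > 0)
  round(100 * sum(as.numeric(regions$end) - as.numeric(regions$start)) / tot, 2)
}

#' Full composite sweep scan
#'
#' Runs [scan_windows()], [call_selection_windows()], [merge_called()] and
#' (optionally) [annotate_regions()] in sequence.
#'
#' @inheritParams scan_windows
#' @param q empirical tail quantile (default 0.95).
#' @param genes optional [gene_set()] for region annotation.
#' @return list with `windows` (called window table), `regions`
#'   (`sweep_regions`), `genome_fraction` (percent).
#' @export
sweep_scan <- function(m, meta, layout, window = 1e4, q = 0.95, genes = NULL) {
  t <- scan_windows(m, meta, layout, window = window)
  t <- call_selection_windows(t, q = q)
  regions <- merge_called(t)
  if (!is.null(genes)) regions <- annotate_regions(regions, genes)
  list(windows = t, regions = regions,
       genome_fraction = genome_fraction(regions, layout))
}
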