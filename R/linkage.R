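#' Pairwise r-squared between nearby SNPs
#'
#' Composite (Rogers-Huff style) linkage disequilibrium for unphased data:
#' the squared Pearson correlation of dosage vectors over samples called at
#' both sites.  Pairs never cross chromosomes; pairs farther apart than
#' `max_dist`, with a monomorphic member, or with fewer than 3 shared
#' non-missing samples are skipped.
#'
#' @inheritParams site_stats
#' @param max_dist maximum pair distance in bp (default 1 Mb).
#' @param maf_min sites below this MAF (within the subset) are excluded
#'   (default 0: all polymorphic sites).
#' @return data.frame with columns `chrom`, `i`, `j` (variant indices in
#'   `m`), `dist` (bp) and `r2`.
#' @export
pairwise_r2 <- function(m, subset = NULL, max_dist = 1e6, maf_min = 0) {
  idx <- sample_index(m, subset)
  d <- m$dosage[, idx, drop = FALSE]
  ss <- site_stats(m, idx)
  usable <- which(!is.na(ss$maf) & ss$maf > 0 & ss$maf >= maf_min)
  out <- vector("list", 0L)
  has_na <- anyNA(d)
  for (cc in unique(m$variants$chrom)) {
    vi <- usable[m$variants$chrom[usable] == cc]
    if (length(vi) < 2L) next
    pos <- m$variants$pos[vi]
    o <- order(pos)
    vi <- vi[o]; pos <- pos[o]
    x <- t(d[vi, , drop = FALSE])          # samples x sites
    # blocked band computation to bound memory
    block <- 512L
    nb <- length(vi)
    for (b0 in seq(1L, nb, by = block)) {
      b1 <- min(b0 + block - 1L, nb)
      hi <- findInterval(pos[b1] + max_dist, pos)
      cols <- b0:hi
      cm <- suppressWarnings(
        if (has_na) cor(x[, b0:b1, drop = FALSE], x[, cols, drop = FALSE],
                        use = "pairwise.complete.obs")
        else cor(x[, b0:b1, drop = FALSE], x[, cols, drop = FALSE]))
      if (has_na) {
        called <- !is.na(x[, cols, drop = FALSE])
        nshared <- crossprod(called[, (b0:b1) - b0 + 1L, drop = FALSE],
                             called)
        cm[nshared < 3L] <- NA_real_
      }
      ii <- rep(b0:b1, times = length(cols))
      jj <- rep(cols, each = b1 - b0 + 1L)
      keep <- jj > ii & (pos[jj] - pos[ii]) <= max_dist & !is.na(cm)
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, i = vi[ii[keep]], j = vi[jj[keep]],
        dist = pos[jj[keep]] - pos[ii[keep]],
        r2 = as.vector(cm)[keep]^2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), i = integer(), j = integer(),
                      dist = integer(), r2 = numeric()))
  do.call(rbind, out)
}

#' LD decay curve
#'
#' Mean r-squared per physical distance bin, pooled across chromosomes.
#' Bins are contiguous from 0 with width `bin_width`; empty bins are kept
#' with count 0 and `NA` mean.
#'
#' @param pairs output of [pairwise_r2()] (needs `dist` and `r2`).
#' @param bin_width bin width in bp (default 1 kb).
#' @return data.frame of class `ld_decay` with columns `bin_start`,
#'   `bin_end`, `center`, `n_pairs`, `mean_r2`.
#' @export
ld_decay_curve <- function(pairs, bin_width = 1000) {
  stopifnot(nrow(pairs) >= 1L)
  k <- pmax(ceiling(pairs$dist / bin_width), 1L)   # dist in (0, bw] -> bin 1
  nb <- max(k)
  n <- tabulate(k, nbins = nb)
  s <- numeric(nb)
  agg <- rowsum(pairs$r2, k)
  s[as.integer(rownames(agg))] <- agg[, 1L]
  out <- data.frame(bin_start = (seq_len(nb) - 1) * bin_width,
                    bin_end = seq_len(nb) * bin_width,
                    center = (seq_len(nb) - 0.5) * bin_width,
                    n_pairs = n,
                    mean_r2 = ifelse(n > 0, s / pmax(n, 1L), NA_real_))
  class(out) <- c("ld_decay", "data.frame")
  out
}

#' LD half-decay distance
#'
#' The curve maximum is taken as the first populated bin's mean; the
#' half-decay distance is the smallest distance at which the binned mean
#' falls to half that maximum, linearly interpolated between the straddling
#' bin centers.  `NA` (with a warning) if the curve never falls to half.
#'
#' @param curve an `ld_decay` curve from [ld_decay_curve()].
#' @return Distance in bp, or `NA` if undefined.
#' @export
half_decay_distance <- function(curve) {
  pop <- which(curve$n_pairs > 0)
  if (!length(pop)) stop("curve has no populated bins")
  maxv <- curve$mean_r2[pop[1]]
  if (!is.finite(maxv) || maxv <= 0) {
    warning("curve maximum is not positive; half-decay undefined")
    return(NA_real_)
  }
  half <- maxv / 2
  below <- pop[curve$mean_r2[pop] <= half]
  if (!length(below)) {
    warning("LD never decays to half of its maximum within the curve")
    return(NA_real_)
  }
  b <- below[1]
  prev <- pop[pop < b]
  if (!length(prev)) return(curve$center[b])
  a <- prev[length(prev)]
  y0 <- curve$mean_r2[a]; y1 <- curve$mean_r2[b]
  x0 <- curve$center[a]; x1 <- curve$center[b]
  if (y0 == y1) return(x1)
  x0 + (x1 - x0) * (y0 - half) / (y0 - y1)
}

#' Population LD decay summary
#'
#' Convenience wrapper: pairwise r2 within one population, binned decay
#' curve and half-decay distance.
#'
#' @inheritParams fst_windows
#' @param population `"wild"` or `"cultivated"`.
#' @param max_dist,bin_width see [pairwise_r2()] and [ld_decay_curve()].
#' @param maf_min MAF cutoff for the sites entering the curve (default
#'   0.05, the usual practice for LD summaries; rare variants carry little
#'   LD information and their abundance differs between populations).
#' @return list with `curve` (class `ld_decay`) and `half_decay` (bp).
#' @export
ld_decay <- function(m, meta, population, max_dist = 1e6, bin_width = 1000,
                     maf_min = 0.05) {
  idx <- pop_index(m, meta, population)
  pr <- pairwise_r2(m, idx, max_dist = max_dist, maf_min = maf_min)
  if (!nrow(pr)) return(list(curve = NULL, half_decay = NA_real_))
  curve <- ld_decay_curve(pr, bin_width = bin_width)
  list(curve = curve, half_decay = half_decay_distance(curve))
}
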