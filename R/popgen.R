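#' Tile a genome into non-overlapping windows
#'
#' @param layout a [genome_layout()].
#' @param size window size in bp; the final window on each chromosome may be
#'   shorter.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   tiling each chromosome.
#' @export
make_windows <- function(layout, size) {
  stopifnot(size > 0)
  out <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    cc <- layout$chromosomes$chrom[i]
    L <- layout$chromosomes$length[i]
    start <- seq(0, L - 1, by = size)
    data.frame(chrom = cc, start = start, end = pmin(start + size, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# index of the window containing each variant (NA if outside all windows);
# windows assumed non-overlapping
window_of <- function(variants, windows) {
  idx <- rep(NA_integer_, nrow(variants))
  for (cc in unique(variants$chrom)) {
    w <- which(windows$chrom == cc)
    if (!length(w)) next
    v <- which(variants$chrom == cc)
    p0 <- variants$pos[v] - 1L                 # 0-based position
    o <- order(windows$start[w])
    w <- w[o]
    k <- findInterval(p0, windows$start[w])
    inside <- k >= 1L & p0 < windows$end[w][pmax(k, 1L)]
    idx[v[inside]] <- w[k[inside]]
  }
  idx
}

#' Per-site allele statistics
#'
#' For each SNP, over a sample subset: alternate-allele count, number of
#' called alleles, alternate-allele frequency `p`, minor allele frequency and
#' missing-call fraction.  Sites with zero called alleles have `NA`
#' frequencies.
#'
#' @param m a [genotype_matrix()].
#' @param subset sample labels, indices or logical mask (default: all).
#' @return data.frame with one row per SNP: `alt_count`, `n_alleles`, `p`,
#'   `maf`, `missing`.
#' @export
site_stats <- function(m, subset = NULL) {
  idx <- sample_index(m, subset)
  d <- m$dosage[, idx, drop = FALSE]
  called <- !is.na(d)
  n_alleles <- 2L * rowSums(called)
  alt <- rowSums(d, na.rm = TRUE)
  p <- ifelse(n_alleles > 0, alt / n_alleles, NA_real_)
  data.frame(alt_count = alt, n_alleles = n_alleles, p = p,
             maf = pmin(p, 1 - p),
             missing = 1 - rowSums(called) / length(idx))
}

# per-site unbiased heterozygosity 2p(1-p) c/(c-1); NA where c < 2
site_pi_hat <- function(ss) {
  c_ <- ss$n_alleles
  ifelse(c_ >= 2, 2 * ss$p * (1 - ss$p) * c_ / (c_ - 1), NA_real_)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site unbiased diversity `2p(1-p) c/(c-1)` (with `c` the called-allele
#' count) summed per window and divided by window length in bp.  Windows
#' without usable SNPs get 0; sites with fewer than two called alleles are
#' skipped.
#'
#' @inheritParams site_stats
#' @param windows window tiling from [make_windows()].
#' @return Numeric vector of per-bp pi, one per window row.
#' @export
pi_windows <- function(m, subset = NULL, windows) {
  ss <- site_stats(m, subset)
  ph <- site_pi_hat(ss)
  wi <- window_of(m$variants, windows)
  ok <- !is.na(ph) & !is.na(wi)
  tot <- numeric(nrow(windows))
  if (any(ok)) {
    agg <- rowsum(ph[ok], wi[ok])
    tot[as.integer(rownames(agg))] <- agg[, 1L]
  }
  tot / (windows$end - windows$start)
}

# Tajima (1989) constants for n sequences
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' The 1989 statistic computed per window from the number of segregating
#' sites `S` and the mean pairwise difference sum; the sample-size constants
#' use the median called-allele count over the window's segregating sites
#' (rounded, ties down) because missingness can make counts vary per site.
#' Windows with `S = 0` (or an undefined variance term) are `NA`.
#'
#' @inheritParams pi_windows
#' @return Numeric vector of D values (NA where undefined), one per window.
#' @export
tajimas_d_windows <- function(m, subset = NULL, windows) {
  ss <- site_stats(m, subset)
  wi <- window_of(m$variants, windows)
  seg <- !is.na(ss$p) & ss$n_alleles >= 2 & ss$p > 0 & ss$p < 1
  ph <- site_pi_hat(ss)
  out <- rep(NA_real_, nrow(windows))
  for (w in unique(wi[seg & !is.na(wi)])) {
    i <- which(seg & !is.na(wi) & wi == w)
    S <- length(i)
    n <- floor(median(ss$n_alleles[i]) + 0.5)
    if (S == 0L || n < 2L) next
    k <- sum(ph[i])
    cst <- tajima_constants(n)
    vr <- cst$e1 * S + cst$e2 * S * (S - 1)
    if (vr <= 0) next
    out[w] <- (k - S / cst$a1) / sqrt(vr)
  }
  out
}

# Weir & Cockerham (1984) per-site variance components a, b, c for two
# populations, from dosage matrices (rows = sites).
wc84_components <- function(d1, d2) {
  n1 <- rowSums(!is.na(d1))
  n2 <- rowSums(!is.na(d2))
  p1 <- rowSums(d1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(d2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(d1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(d2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1
  list(a = ifelse(usable, a, NA_real_), b = ifelse(usable, b, NA_real_),
       c = ifelse(usable, cc, NA_real_))
}

#' Windowed Weir-Cockerham F_ST
#'
#' Per-site WC84 variance components combined per window by ratio of sums
#' (`sum(a) / sum(a+b+c)`); sites with a zero denominator or with either
#' population uncalled are skipped, and windows with no usable site are `NA`.
#'
#' @param m a [genotype_matrix()].
#' @param meta a [sample_metadata()] assigning samples to `wild` /
#'   `cultivated`.
#' @param windows window tiling from [make_windows()].
#' @return Numeric vector of F_ST per window (NA where undefined).
#' @export
fst_windows <- function(m, meta, windows) {
  iw <- pop_index(m, meta, "wild")
  ic <- pop_index(m, meta, "cultivated")
  comp <- wc84_components(m$dosage[, iw, drop = FALSE],
                          m$dosage[, ic, drop = FALSE])
  wi <- window_of(m$variants, windows)
  den <- comp$a + comp$b + comp$c
  ok <- !is.na(den) & den != 0 & !is.na(wi)
  out <- rep(NA_real_, nrow(windows))
  if (any(ok)) {
    num <- rowsum(comp$a[ok], wi[ok])
    dd <- rowsum(den[ok], wi[ok])
    out[as.integer(rownames(num))] <- num[, 1L] / dd[, 1L]
  }
  out
}

#' Reduction of diversity (ROD)
#'
#' `ROD = 1 - pi_cultivated / pi_wild`; `NA` where `pi_wild = 0`.
#'
#' @param pi_wild,pi_cul non-negative per-window diversity values.
#' @return Numeric vector of ROD values.
#' @export
rod <- function(pi_wild, pi_cul) {
  stopifnot(all(pi_wild >= 0, na.rm = TRUE), all(pi_cul >= 0, na.rm = TRUE))
  ifelse(!is.na(pi_wild) & pi_wild > 0, 1 - pi_cul / pi_wild, NA_real_)
}

#' Mean pairwise SNP difference count between samples
#'
#' Average over all sample pairs of the number of sites at which the two
#' samples carry different (both non-missing) dosages.
#'
#' @inheritParams site_stats
#' @return A single number.
#' @export
mean_pairwise_snp_count <- function(m, subset = NULL) {
  idx <- sample_index(m, subset)
  if (length(idx) < 2L) stop("need at least 2 samples")
  d <- m$dosage[, idx, drop = FALSE]
  n <- length(idx)
  # indicator cross-products count (dosage a, dosage b) site pairs
  A <- lapply(0:2, function(v) {
    x <- d == v
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "numeric"
    x
  })
  diff <- crossprod(A[[1]], A[[2]]) + crossprod(A[[2]], A[[1]]) +
    crossprod(A[[1]], A[[3]]) + crossprod(A[[3]], A[[1]]) +
    crossprod(A[[2]], A[[3]]) + crossprod(A[[3]], A[[2]])
  sum(diff[upper.tri(diff)]) / (n * (n - 1) / 2)
}

#' Partition SNPs by within-population polymorphism
#'
#' Classifies every SNP as shared-polymorphic (polymorphic among called
#' alleles within both populations), wild-only, cultivated-only, or
#' monomorphic (in both); the four counts sum to the number of SNPs.
#'
#' @inheritParams fst_windows
#' @return Named integer vector with elements `shared`, `wild_only`,
#'   `cultivated_only`, `monomorphic`.
#' @export
shared_unique_partition <- function(m, meta) {
  pw <- site_stats(m, pop_index(m, meta, "wild"))
  pc <- site_stats(m, pop_index(m, meta, "cultivated"))
  poly_w <- !is.na(pw$maf) & pw$maf > 0
  poly_c <- !is.na(pc$maf) & pc$maf > 0
  c(shared = sum(poly_w & poly_c),
    wild_only = sum(poly_w & !poly_c),
    cultivated_only = sum(!poly_w & poly_c),
    monomorphic = sum(!poly_w & !poly_c))
}

#' Windowed summary statistics for a two-population panel
#'
#' Computes, per non-overlapping window: SNP count, per-bp pi in each
#' population, Tajima's D in each population, mean MAF per population,
#' Weir-Cockerham F_ST and ROD.
#'
#' @inheritParams fst_windows
#' @param layout a [genome_layout()].
#' @param window window size in bp (100 kb for diversity summaries, 10 kb
#'   for the selection scan).
#' @param tajima compute Tajima's D columns (slowest part; default TRUE).
#' @return data.frame of class `window_stats` with columns `chrom`, `start`,
#'   `end`, `n_snps`, `pi_wild`, `pi_cul`, `tajd_wild`, `tajd_cul`,
#'   `maf_wild`, `maf_cul`, `fst`, `rod`.
#' @export
window_stats <- function(m, meta, layout, window = 1e5, tajima = TRUE) {
  w <- make_windows(layout, window)
  iw <- pop_index(m, meta, "wild")
  ic <- pop_index(m, meta, "cultivated")
  wi <- window_of(m$variants, w)
  w$n_snps <- 0L
  tab <- table(wi)
  w$n_snps[as.integer(names(tab))] <- as.integer(tab)
  w$pi_wild <- pi_windows(m, iw, w)
  w$pi_cul <- pi_windows(m, ic, w)
  if (tajima) {
    w$tajd_wild <- tajimas_d_windows(m, iw, w)
    w$tajd_cul <- tajimas_d_windows(m, ic, w)
  } else {
    w$tajd_wild <- w$tajd_cul <- NA_real_
  }
  mafmean <- function(idx) {
    ss <- site_stats(m, idx)
    ok <- !is.na(ss$maf) & !is.na(wi)
    out <- rep(NA_real_, nrow(w))
    if (any(ok)) {
      s <- rowsum(ss$maf[ok], wi[ok])
      n <- rowsum(rep(1, sum(ok)), wi[ok])
      out[as.integer(rownames(s))] <- s[, 1L] / n[, 1L]
    }
    out
  }
  w$maf_wild <- mafmean(iw)
  w$maf_cul <- mafmean(ic)
  w$fst <- fst_windows(m, meta, w)
  w$rod <- rod(w$pi_wild, w$pi_cul)
  class(w) <- c("window_stats", "data.frame")
  w
}
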