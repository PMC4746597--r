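# fixture builders and independent literal-formula oracles used across tests

make_geno <- function(dosage, pos = NULL, chrom = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  nv <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", nv)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(dosage)))
  v <- data.frame(chrom = chrom, pos = as.integer(pos),
                  id = sprintf("%s_%d", chrom, pos),
                  ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(v, samples, dosage)
}

make_meta <- function(m, n_wild) {
  n <- length(m$samples)
  sample_metadata(data.frame(
    sample = m$samples,
    population = rep(c("wild", "cultivated"), c(n_wild, n - n_wild)),
    evolution_type = rep(c("wild", "landrace"), c(n_wild, n - n_wild)),
    stringsAsFactors = FALSE))
}

one_chrom_layout <- function(len, chrom = "chr1") {
  genome_layout(data.frame(chrom = chrom, length = len,
                           stringsAsFactors = FALSE))
}

# a fast small simulation configuration for unit tests
small_sim <- function(seed, ...) {
  args <- list(L = 4e5, n_chrom = 1L, N_anc = 80L, N_wild = 80L, N_cul = 80L,
               T_split = 40L, bottleneck_size = 8L, bottleneck_duration = 10L,
               sweep_loci = NULL, n_sample_wild = 25L, n_sample_cul = 40L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

random_geno <- function(nsnp, nsamp, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(nsnp, 0.05, 0.95)
  d <- matrix(rbinom(nsnp * nsamp, 2, rep(p, nsamp)), nsnp, nsamp)
  if (miss > 0) d[runif(length(d)) < miss] <- NA
  make_geno(d, pos = sort(sample.int(1e6, nsnp)))
}

## ---- oracles (deliberately written from the definitions, not the package
## ---- implementation paths) ----

# nucleotide diversity: enumerate every pair of called alleles at each site
oracle_pi_window <- function(dosage, window_len) {
  tot <- 0
  for (i in seq_len(nrow(dosage))) {
    d <- dosage[i, ]
    alleles <- unlist(lapply(d[!is.na(d)], function(x) {
      c(rep(1, x), rep(0, 2 - x))
    }))
    c_ <- length(alleles)
    if (c_ < 2) next
    diffs <- 0
    for (a in 1:(c_ - 1)) for (b in (a + 1):c_)
      diffs <- diffs + (alleles[a] != alleles[b])
    tot <- tot + diffs / choose(c_, 2)
  }
  unname(tot / window_len)
}

# Tajima's D straight from the 1989 formulas; khat by allele-pair counting
oracle_tajima <- function(dosage) {
  seg <- apply(dosage, 1L, function(d) {
    d <- d[!is.na(d)]
    length(d) >= 1 && sum(d) > 0 && sum(d) < 2 * length(d)
  })
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  khat <- oracle_pi_window(dosage[seg, , drop = FALSE], 1)  # sum, len 1
  ns <- apply(dosage[seg, , drop = FALSE], 1L,
              function(d) 2 * sum(!is.na(d)))
  n <- floor(median(ns) + 0.5)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) theta-hat, ratio of sums over sites
oracle_wc_fst <- function(d1, d2) {
  num <- den <- 0
  for (i in seq_len(nrow(d1))) {
    x1 <- d1[i, ][!is.na(d1[i, ])]
    x2 <- d2[i, ][!is.na(d2[i, ])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) next
    r <- 2
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) * (ssq - (pbar * (1 - pbar) - ssq * (r - 1) / r -
                                 hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ssq * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    if (a + b + cc == 0) next
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}

# squared Pearson correlation from first principles
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy^2 / (sxx * syy)
}

# IBS distance by the stated scoring table (1 / 0.5 / 0 per site)
oracle_ibs <- function(di, dj) {
  score_tab <- function(a, b) c(1, 0.5, 0)[abs(a - b) + 1]
  ok <- !is.na(di) & !is.na(dj)
  1 - sum(score_tab(di[ok], dj[ok])) / sum(ok)
}

# brute-force pairwise SNP difference count
oracle_pairwise_count <- function(dosage) {
  n <- ncol(dosage)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(dosage[, i]) & !is.na(dosage[, j])
    tot <- tot + sum(dosage[ok, i] != dosage[ok, j])
  }
  tot / choose(n, 2)
}

# exhaustive minimum tag set (set cover) for small candidate sets
oracle_min_tags <- function(cover) {
  n <- length(cover)
  for (k in 1:n) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (cb in combos) {
      if (length(unique(unlist(cover[cb]))) == n) return(cb)
    }
  }
  seq_len(n)
}
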