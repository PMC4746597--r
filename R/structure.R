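#' Identity-by-state distance matrix
#'
#' For each sample pair, per co-called site the allele-sharing score is 1
#' for identical dosages, 0.5 when the genotypes share one allele
#' (dosages differing by 1), and 0 for opposite homozygotes; the distance is
#' 1 minus the average score, i.e. `mean(|d_i - d_j|) / 2` over co-called
#' sites.
#'
#' @inheritParams site_stats
#' @return Symmetric matrix of distances with zero diagonal, labelled by
#'   sample.
#' @export
ibs_distance <- function(m, subset = NULL) {
  idx <- sample_index(m, subset)
  if (length(idx) < 2L) stop("need at least 2 samples")
  d <- m$dosage[, idx, drop = FALSE]
  A <- lapply(0:2, function(v) {
    x <- d == v
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "numeric"
    x
  })
  # sum over sites of |d_i - d_j| via dosage-class cross products
  P01 <- crossprod(A[[1]], A[[2]]); P02 <- crossprod(A[[1]], A[[3]])
  P12 <- crossprod(A[[2]], A[[3]])
  absdiff <- P01 + t(P01) + P12 + t(P12) + 2 * (P02 + t(P02))
  called <- !is.na(d)
  storage.mode(called) <- "numeric"
  cocalled <- crossprod(called)
  if (any(cocalled[upper.tri(cocalled)] == 0))
    stop("some sample pairs share no co-called sites; distance incomplete")
  dist <- absdiff / (2 * cocalled)
  diag(dist) <- 0
  dimnames(dist) <- list(m$samples[idx], m$samples[idx])
  dist
}

#' Principal-component coordinates of samples
#'
#' Eigendecomposition of the sample covariance of the centered,
#' frequency-scaled genotype matrix (missing dosages mean-imputed per SNP;
#' monomorphic SNPs dropped).  Coordinates are deterministic up to sign;
#' variance fractions are non-increasing.
#'
#' @inheritParams site_stats
#' @param k number of components (reduced with a warning if it exceeds the
#'   available rank).
#' @param scale divide each SNP by `sqrt(2 p (1-p))` (default TRUE).
#' @return list with `coords` (samples x k matrix) and `varfrac` (length-k
#'   fractions of total variance).
#' @export
pca_coords <- function(m, subset = NULL, k = 5L, scale = TRUE) {
  idx <- sample_index(m, subset)
  n <- length(idx)
  if (n < 2L) stop("need at least 2 samples")
  d <- m$dosage[, idx, drop = FALSE]
  ss <- site_stats(m, idx)
  keep <- !is.na(ss$maf) & ss$maf > 0
  d <- d[keep, , drop = FALSE]
  p <- ss$p[keep]
  if (!nrow(d)) stop("no polymorphic SNPs for PCA")
  x <- d - 2 * p                       # center by 2p; recycling by row
  x[is.na(x)] <- 0                     # mean imputation after centering
  if (scale) x <- x / sqrt(2 * p * (1 - p))
  sv <- svd(t(x) / sqrt(nrow(x)))      # samples x snps
  ev <- sv$d^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (k > rank) {
    warning("k reduced to available rank ", rank)
    k <- rank
  }
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- m$samples[idx]
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, varfrac = ev[seq_len(k)] / sum(ev))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths
#' are clamped to zero with the deficit transferred to the sibling edge, so
#' total root-to-tip path lengths are preserved where possible.
#'
#' @param d symmetric distance matrix (complete, >= 3 taxa) or `dist`.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(is.na(d))) stop("distance matrix is incomplete")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  clamp_negative_edges(tr)
}

# transfer each negative branch length onto its sibling edge and clamp to 0
# (bounded passes; any residual negatives are clamped outright)
clamp_negative_edges <- function(tr) {
  for (it in seq_len(2L * length(tr$edge.length))) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib)) tr$edge.length[sib[1]] <-
        tr$edge.length[sib[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
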