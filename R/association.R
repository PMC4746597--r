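#' Multi-environment BLUP breeding values
#'
#' Fits the two-way mixed model `weight ~ environment (fixed) + sample
#' (random) + error` by REML (lme4) and returns each sample's random-effect
#' prediction (BLUP), the breeding value used as the GWAS phenotype.
#'
#' @param p a [phenotype_table()] with >= 2 environments and >= 2 samples.
#' @return Named numeric vector of BLUPs (one per sample).
#' @export
blup_phenotype <- function(p) {
  stopifnot(length(unique(p$environment)) >= 2L,
            length(unique(p$sample)) >= 2L)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(hundred_seed_weight ~ environment + (1 | sample), data = p,
                 REML = TRUE))),
    error = function(e) stop("BLUP model failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  re <- lme4::ranef(fit)$sample
  setNames(re[, 1L], rownames(re))
}

#' VanRaden genomic kinship matrix
#'
#' `K = Z Z' / (2 * sum p_k (1 - p_k))` with `Z = dosage - 2p` per SNP and
#' missing dosages mean-imputed per SNP.
#'
#' @inheritParams site_stats
#' @return Symmetric samples x samples kinship matrix.
#' @export
vanraden_kinship <- function(m, subset = NULL) {
  idx <- sample_index(m, subset)
  if (length(idx) < 2L) stop("need at least 2 samples")
  d <- m$dosage[, idx, drop = FALSE]
  ss <- site_stats(m, idx)
  keep <- !is.na(ss$maf) & ss$maf > 0
  if (!any(keep)) stop("all SNPs are monomorphic in the subset")
  d <- d[keep, , drop = FALSE]
  p <- ss$p[keep]
  z <- d - 2 * p
  z[is.na(z)] <- 0
  K <- crossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(m$samples[idx], m$samples[idx])
  K
}

# REML estimate of lambda = sigma2_e / sigma2_g on the null model
# y = X b + u + e, Var(u) = sigma2_g K, via the spectral decomposition of K.
reml_lambda <- function(y, X, eig) {
  n <- length(y)
  p <- ncol(X)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  neg2ll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (eig$values + lam)
    XtWX <- crossprod(Xt * w, Xt)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, backsolve(ch, crossprod(Xt * w, yt),
                                    transpose = TRUE))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    (n - p) * log(s2) - sum(log(w)) + 2 * sum(log(diag(ch)))
  }
  opt <- optimize(neg2ll, interval = c(-14, 14))
  exp(opt$minimum)
}

#' Exact mixed-linear-model association scan
#'
#' Single-marker tests of breeding values under
#' `y = X beta + marker b + u + e`, `u ~ (0, K sigma2_g)`, with an
#' intercept and the first `n_pcs` principal components as fixed
#' covariates.  The variance ratio is estimated once on the null model by
#' REML via the spectral decomposition of `K` and reused for every marker
#' (the standard "P3D"/EMMAX scheme); per-marker Wald t-tests.  SNPs with
#' MAF below `maf_min` or call rate below `callrate_min` are excluded
#' before testing, and the 1/n significance threshold uses the number of
#' tested markers.
#'
#' @param m a [genotype_matrix()].
#' @param y named numeric vector of phenotypes/breeding values; names must
#'   match samples of `m` (the scan runs on the intersection).
#' @param K kinship matrix (default: [vanraden_kinship()] of the scan
#'   samples).  `K = NULL` with `lambda = Inf` gives ordinary least squares.
#' @param n_pcs number of PC covariates (default 5; 0 for none).
#' @param maf_min MAF filter applied before testing (default 0.05).
#' @param callrate_min minimum per-SNP call rate (default 0.9).
#' @param lambda optional fixed variance ratio `sigma2_e / sigma2_g`
#'   (bypasses REML; `Inf` reduces the model to OLS).
#' @return list of class `assoc_result`: `scores` (data.frame `id`,
#'   `chrom`, `pos`, `maf`, `beta`, `se`, `p`), `threshold` (1/n),
#'   `significant` (ids with `p < threshold`), `lambda`, `n_markers`.
#' @export
mlm_scan <- function(m, y, K = NULL, n_pcs = 5L, maf_min = 0.05,
                     callrate_min = 0.9, lambda = NULL) {
  if (is.null(names(y))) stop("y must be named by sample")
  samp <- intersect(m$samples, names(y))
  if (length(samp) < 10L) stop("too few samples with phenotype and genotype")
  mm <- subset_genotypes(m, samples = samp)
  y <- y[samp]
  ss <- site_stats(mm)
  keep <- !is.na(ss$maf) & ss$maf >= maf_min &
    (1 - ss$missing) >= callrate_min
  if (!any(keep)) stop("no markers pass the MAF/call-rate filters")
  mm <- subset_genotypes(mm, variants = which(keep))
  ss <- ss[keep, , drop = FALSE]
  n <- length(samp)

  X <- matrix(1, n, 1)
  colnames(X) <- "(Intercept)"
  if (n_pcs > 0) {
    pcs <- pca_coords(mm, k = n_pcs)$coords
    X <- cbind(X, pcs)
  }
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effect design: collinear covariate among ",
         paste(colnames(X), collapse = ", "))

  use_ols <- !is.null(lambda) && is.infinite(lambda)
  if (use_ols) {
    U <- diag(n)
    w <- rep(1, n)
    lam <- Inf
  } else {
    if (is.null(K)) K <- vanraden_kinship(mm)
    K <- K[samp, samp]
    eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
    eig$values[eig$values < 0] <- 0
    lam <- if (is.null(lambda)) reml_lambda(y, X, eig) else lambda
    U <- eig$vectors
    w <- 1 / (eig$values + lam)
  }
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  G <- mm$dosage
  G[is.na(G)] <- matrix(2 * ss$p, nrow(G), ncol(G))[is.na(G)]  # mean impute
  Gt <- tcrossprod(G, t(U))                   # markers x n, rotated

  p0 <- ncol(X)
  df <- n - p0 - 1L
  if (df < 1L) stop("not enough samples for the fixed-effect design")
  sw <- sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  qrX <- qr(Xw)
  ry <- qr.resid(qrX, yw)                     # y residual on covariates
  nmark <- nrow(Gt)
  beta <- se <- pv <- rep(NA_real_, nmark)
  Gw <- Gt * rep(sw, each = nmark)
  # residualize each (weighted) marker on the covariates, then the marker
  # effect is a simple regression of ry on the residualized marker
  Rg <- t(qr.resid(qrX, t(Gw)))
  gg <- rowSums(Rg^2)
  gy <- as.vector(Rg %*% yw)
  tol <- max(gg, 0) * 1e-10
  ok <- gg > tol
  beta[ok] <- gy[ok] / gg[ok]
  rss <- pmax(sum(ry^2) - ifelse(ok, beta^2 * gg, 0), 0)
  s2 <- rss / df
  se[ok] <- sqrt(s2[ok] / gg[ok])
  tt <- beta / se
  pv[ok] <- 2 * pt(abs(tt[ok]), df, lower.tail = FALSE)
  # markers absorbed by the covariates: no estimable effect
  beta[!ok] <- 0
  pv[!ok] <- 1
  scores <- data.frame(id = mm$variants$id, chrom = mm$variants$chrom,
                       pos = mm$variants$pos, maf = ss$maf,
                       beta = beta, se = se, p = pv,
                       stringsAsFactors = FALSE)
  thr <- significance_threshold(nmark)
  res <- list(scores = scores, threshold = thr,
              significant = scores$id[!is.na(scores$p) & scores$p < thr],
              lambda = lam, n_markers = nmark)
  class(res) <- "assoc_result"
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %d markers, threshold %.3g, %d significant\n",
              x$n_markers, x$threshold, length(x$significant)))
  invisible(x)
}

#' 1/n significance threshold
#'
#' The genome-wide significance cutoff `1 / n_markers`, reported to 3
#' significant figures.
#'
#' @param n_markers number of tested markers (> 0).
#' @return p-value cutoff.
#' @export
significance_threshold <- function(n_markers) {
  stopifnot(n_markers > 0)
  signif(1 / n_markers, 3)
}

#' Candidate regions around association hits
#'
#' Each significant SNP defines a region `[pos - half_decay, pos +
#' half_decay]` clipped to its chromosome; overlapping regions are merged,
#' the most significant SNP within each merged region is its lead, and
#' overlapping genes are listed.
#'
#' @param result an `assoc_result` from [mlm_scan()] (or a data.frame with
#'   `id`, `chrom`, `pos`, `p` of hits only).
#' @param half_decay LD half-decay distance in bp (region half-width).
#' @param genes optional [gene_set()].
#' @param layout optional [genome_layout()] used for clipping.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `lead_id`, `lead_pos`, `lead_p`, `n_hits`, and list-column `genes`
#'   when `genes` is given.
#' @export
candidate_regions <- function(result, half_decay, genes = NULL,
                              layout = NULL) {
  hits <- if (inherits(result, "assoc_result")) {
    result$scores[result$scores$id %in% result$significant, , drop = FALSE]
  } else result
  if (!nrow(hits)) stop("no significant hits")
  start <- pmax(hits$pos - half_decay - 1, 0)       # 0-based half-open
  end <- hits$pos + half_decay
  if (!is.null(layout)) {
    len <- setNames(layout$chromosomes$length, layout$chromosomes$chrom)
    end <- pmin(end, len[hits$chrom])
  }
  o <- order(hits$chrom, start)
  hits <- hits[o, ]; start <- start[o]; end <- end[o]
  grp <- integer(nrow(hits))
  g <- 0L; cur_end <- -Inf; cur_chr <- ""
  for (i in seq_len(nrow(hits))) {
    if (hits$chrom[i] != cur_chr || start[i] > cur_end) {
      g <- g + 1L
      cur_chr <- hits$chrom[i]
      cur_end <- end[i]
    } else cur_end <- max(cur_end, end[i])
    grp[i] <- g
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(hits)), grp), function(ii) {
    lead <- ii[which.min(hits$p[ii])]
    data.frame(chrom = hits$chrom[ii[1]], start = min(start[ii]),
               end = max(end[ii]), lead_id = hits$id[lead],
               lead_pos = hits$pos[lead], lead_p = hits$p[lead],
               n_hits = length(ii), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(genes)) out <- annotate_regions(out, genes)
  out
}
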