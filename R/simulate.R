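#' Parameters for the two-population domestication simulator
#'
#' The defaults describe the package's reference desk-scale world: a 5-Mb
#' genome on 5 chromosomes, diploid population sizes of 500, a
#' 120-generation-old split with a 30-generation bottleneck at 10% of the
#' wild size at the start of the cultivated lineage, three planted sweeps
#' with s = 0.1 on three separate chromosomes (each conditioned on
#' near-fixation by sampling time, avoiding selective interference), and a
#' sampled panel of 105 wild and 262 cultivated accessions.  Mutation and
#' recombination rates are desk-scale placeholders (no demographic
#' parameters exist for the real crop); they are chosen so that 10-kb scan
#' windows carry tens of segregating sites (damping window-level noise in
#' the diversity ratio), a hard-sweep footprint (~40 kb) spans several scan
#' windows but stays well below the chromosome length, and post-fixation
#' diversity recovery stays small relative to background diversity.  The
#' methods vignette motivates each choice.
#'
#' @param L total genome length in bp (split evenly over `n_chrom`).
#' @param n_chrom number of chromosomes (independent WF simulations).
#' @param mu per-bp per-generation mutation rate.
#' @param rho per-bp per-generation recombination rate.
#' @param N_anc,N_wild,N_cul diploid population sizes.
#' @param T_split generations since the wild/cultivated split (0 = one
#'   panmictic population).
#' @param bottleneck_size diploid size of the cultivated lineage during the
#'   bottleneck.
#' @param bottleneck_duration bottleneck length in generations
#'   (<= `T_split`).
#' @param sweep_loci data.frame with `chrom` (index 1..n_chrom), `pos`
#'   (1-based bp within the chromosome) and `s` (selection coefficient per
#'   allele copy); NULL for none.
#' @param n_sample_wild,n_sample_cul diploid sample sizes drawn without
#'   replacement.
#' @param burnin_factor burn-in length as a multiple of `N_anc` generations
#'   (default 10).
#' @param max_retries bound on re-introductions of a lost sweep allele
#'   before erroring.
#' @param seed integer random seed recorded in the output.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(L = 5e6, n_chrom = 5L, mu = 2e-7, rho = 5e-7,
                       N_anc = 500L, N_wild = 500L, N_cul = 500L,
                       T_split = 120L, bottleneck_size = 50L,
                       bottleneck_duration = 30L,
                       sweep_loci = default_sweeps(),
                       n_sample_wild = 105L, n_sample_cul = 262L,
                       burnin_factor = 10, max_retries = 100L, seed = 1L) {
  p <- list(L = L, n_chrom = as.integer(n_chrom), mu = mu, rho = rho,
            N_anc = as.integer(N_anc), N_wild = as.integer(N_wild),
            N_cul = as.integer(N_cul), T_split = as.integer(T_split),
            bottleneck_size = as.integer(bottleneck_size),
            bottleneck_duration = as.integer(bottleneck_duration),
            sweep_loci = sweep_loci,
            n_sample_wild = as.integer(n_sample_wild),
            n_sample_cul = as.integer(n_sample_cul),
            burnin_factor = burnin_factor,
            max_retries = as.integer(max_retries), seed = as.integer(seed))
  stopifnot(p$L > 0, p$n_chrom >= 1L, p$mu > 0, p$rho >= 0, p$N_anc > 0,
            p$N_wild > 0, p$N_cul > 0, p$T_split >= 0,
            p$bottleneck_size > 0, p$bottleneck_duration >= 0,
            p$bottleneck_duration <= max(p$T_split, 0L),
            p$n_sample_wild > 0, p$n_sample_cul > 0)
  if (!is.null(p$sweep_loci) && nrow(p$sweep_loci)) {
    sl <- p$sweep_loci
    stopifnot(all(c("chrom", "pos", "s") %in% names(sl)),
              all(sl$chrom >= 1 & sl$chrom <= p$n_chrom),
              all(sl$pos >= 1 & sl$pos <= floor(p$L / p$n_chrom)))
  }
  class(p) <- "sim_params"
  p
}

#' @rdname sim_params
#' @export
default_sweeps <- function() {
  data.frame(chrom = c(1L, 3L, 5L), pos = 505000L, s = 0.1)
}

#' Simulate a two-population domestication panel
#'
#' Forward Wright-Fisher simulation with discrete generations: an ancestral
#' population is burnt in for `burnin_factor * N_anc` generations, splits
#' `T_split` generations ago, the cultivated lineage passes through a
#' bottleneck and recovers, and beneficial alleles at the sweep loci are
#' positively selected in the cultivated lineage only (re-introduced a
#' bounded number of times if lost by drift).  Output is deterministic
#' given `p$seed`.
#'
#' @param p a [sim_params()] object.
#' @return list with `genotypes` (a [genotype_matrix()] of sites
#'   polymorphic in the sampled panel), `metadata`
#'   (a [sample_metadata()]), and `truth` (class `sim_truth`: parameter
#'   echo, realized sweep table with 10-kb sweep windows and cultivated
#'   allele frequencies, retry count, and a slot for QTL effects filled by
#'   [simulate_phenotypes()]).
#' @export
simulate_two_pop <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  L_chr <- as.integer(floor(p$L / p$n_chrom))
  sl <- p$sweep_loci
  if (is.null(sl)) sl <- data.frame(chrom = integer(), pos = integer(),
                                    s = numeric())
  res <- vector("list", p$n_chrom)
  retries <- 0L
  swfreq <- numeric(nrow(sl))
  for (cc in seq_len(p$n_chrom)) {
    here <- which(sl$chrom == cc)
    r <- .wf_sim_chrom(
      L_chr, p$mu, p$rho, p$N_anc, p$N_wild, p$N_cul, p$T_split,
      p$bottleneck_size, p$bottleneck_duration,
      as.integer(sl$pos[here]), as.numeric(sl$s[here]),
      as.integer(round(p$burnin_factor * p$N_anc)),
      p$n_sample_wild, p$n_sample_cul, p$max_retries)
    res[[cc]] <- r
    retries <- retries + r$retries
    swfreq[here] <- r$sweep_freq
  }
  samples <- c(sprintf("W%03d", seq_len(p$n_sample_wild)),
               sprintf("C%03d", seq_len(p$n_sample_cul)))
  chroms <- sprintf("chr%d", seq_len(p$n_chrom))
  variants <- do.call(rbind, lapply(seq_len(p$n_chrom), function(cc)
    data.frame(chrom = chroms[cc], pos = res[[cc]]$pos,
               id = sprintf("%s_%d", chroms[cc], res[[cc]]$pos),
               stringsAsFactors = FALSE)))
  alleles <- c("A", "C", "G", "T")
  ri <- sample.int(4L, nrow(variants), replace = TRUE)
  variants$ref <- alleles[ri]
  variants$alt <- alleles[(ri + sample.int(3L, nrow(variants),
                                           replace = TRUE) - 1L) %% 4L + 1L]
  dosage <- do.call(rbind, lapply(res, `[[`, "dosage"))
  m <- genotype_matrix(variants, samples, dosage)

  is_wild <- seq_along(samples) <= p$n_sample_wild
  evo <- ifelse(is_wild, "wild",
                sample(c("landrace", "improved"), length(samples), TRUE,
                       prob = c(0.78, 0.22)))
  meta <- sample_metadata(data.frame(
    sample = samples,
    population = ifelse(is_wild, "wild", "cultivated"),
    evolution_type = evo,
    eco_region = sample(c("NR", "HR", "SR"), length(samples), TRUE),
    stringsAsFactors = FALSE))

  sweeps <- if (nrow(sl)) data.frame(
    chrom = chroms[sl$chrom], pos = sl$pos, s = sl$s,
    window_start = (sl$pos - 1L) %/% 10000L * 10000L,
    window_end = (sl$pos - 1L) %/% 10000L * 10000L + 10000L,
    cul_freq = swfreq, stringsAsFactors = FALSE)
  else data.frame(chrom = character(), pos = integer(), s = numeric(),
                  window_start = integer(), window_end = integer(),
                  cul_freq = numeric())
  truth <- structure(list(params = p, sweeps = sweeps, retries = retries,
                          qtl = NULL, env_effects = NULL),
                     class = "sim_truth")
  list(genotypes = m, metadata = meta, truth = truth)
}

#' Layout and fake gene models for a simulated genome
#'
#' `sim_layout()` returns the [genome_layout()] implied by a
#' [sim_params()]; `simulate_genes()` tiles gene models (with a simple
#' UTR5-CDS-intron-CDS-UTR3 structure) at regular spacing over it, giving a
#' [gene_set()] for annotation-dependent stages.
#'
#' @param p a [sim_params()].
#' @return A [genome_layout()].
#' @export
sim_layout <- function(p) {
  L_chr <- as.integer(floor(p$L / p$n_chrom))
  genome_layout(data.frame(chrom = sprintf("chr%d", seq_len(p$n_chrom)),
                           length = L_chr, stringsAsFactors = FALSE))
}

#' @rdname sim_layout
#' @param gene_length,spacing gene span and inter-gene spacing in bp.
#' @export
simulate_genes <- function(p, gene_length = 3000, spacing = 7000) {
  layout <- sim_layout(p)
  rows <- list(); feats <- list()
  k <- 0L
  for (i in seq_len(nrow(layout$chromosomes))) {
    cc <- layout$chromosomes$chrom[i]
    L <- layout$chromosomes$length[i]
    starts <- seq(0, L - gene_length, by = gene_length + spacing)
    for (s0 in starts) {
      k <- k + 1L
      id <- sprintf("gene%05d", k)
      rows[[k]] <- data.frame(id = id, chrom = cc, start = s0,
                              end = s0 + gene_length, strand = "+",
                              stringsAsFactors = FALSE)
      u <- round(gene_length * c(0, .1, .45, .55, .9, 1)) + s0
      feats[[k]] <- data.frame(
        gene_id = id, type = c("UTR5", "CDS", "intron", "CDS", "UTR3"),
        chrom = cc,
        start = u[1:5], end = u[2:6], stringsAsFactors = FALSE)
    }
  }
  gene_set(do.call(rbind, rows), do.call(rbind, feats))
}

#' Simulate multi-environment phenotypes
#'
#' Additive multi-environment phenotypes on a simulated panel:
#' `y = mu + sum(effect * dosage) + environment + GxE + residual`, with the
#' genetic variance scaled so that its fraction of the within-environment
#' total (`Vg / (Vg + Vgxe + Ve)`) equals `h2` in expectation.  QTL SNPs
#' are drawn from the polymorphic markers unless `truth` already carries
#' QTL effects.
#'
#' @param m a [genotype_matrix()].
#' @param truth a `sim_truth` from [simulate_two_pop()] (updated copy is
#'   attached to the result); may be NULL.
#' @param n_env number of environments (default 9).
#' @param h2 heritability in (0,1).
#' @param seed integer seed.
#' @param n_qtl number of QTLs to plant (ignored if `truth$qtl` set).
#' @param n_rep technical replicates per sample x environment (default 4).
#' @param mu_pheno panel mean 100-seed weight in grams.
#' @param sd_pheno within-environment phenotypic standard deviation (g).
#' @param env_sd standard deviation of environment main effects (g).
#' @param gxe_frac fraction of the non-genetic within-environment variance
#'   assigned to genotype-by-environment interaction.
#' @return A [phenotype_table()] with attributes `qtl` (data.frame `id`,
#'   `effect` in grams), `breeding_values` (named vector), `env_effects`
#'   and `truth` (updated `sim_truth` when supplied).
#' @export
simulate_phenotypes <- function(m, truth = NULL, n_env = 9L, h2 = 0.5,
                                seed = 1L, n_qtl = 10L, n_rep = 4L,
                                mu_pheno = 15, sd_pheno = 3, env_sd = 1.5,
                                gxe_frac = 0.3) {
  if (!(h2 > 0 && h2 < 1)) stop("h2 must be in (0, 1)")
  set.seed(seed)
  n <- length(m$samples)
  ss <- site_stats(m)
  if (!is.null(truth) && !is.null(truth$qtl)) {
    qtl <- truth$qtl
  } else {
    ok <- which(!is.na(ss$maf) & ss$maf >= 0.05)
    if (length(ok) < n_qtl) stop("not enough polymorphic SNPs for QTLs")
    pick <- sample(ok, n_qtl)
    qtl <- data.frame(id = m$variants$id[pick], effect = rnorm(n_qtl),
                      stringsAsFactors = FALSE)
  }
  qi <- match(qtl$id, m$variants$id)
  if (anyNA(qi)) stop("QTL ids not present among SNPs")
  G <- m$dosage[qi, , drop = FALSE]
  G[is.na(G)] <- matrix(2 * ss$p[qi], nrow(G), ncol(G))[is.na(G)]
  g <- as.vector(crossprod(G, qtl$effect))
  vg_target <- h2 * sd_pheno^2
  sg <- sd(g)
  if (sg > 0) {
    scale <- sqrt(vg_target) / sg
    g <- g * scale
    qtl$effect <- qtl$effect * scale
  }
  g <- g - mean(g)
  ve_tot <- (1 - h2) * sd_pheno^2
  v_gxe <- gxe_frac * ve_tot
  v_res <- (1 - gxe_frac) * ve_tot
  envs <- sprintf("E%d", seq_len(n_env))
  env_eff <- setNames(rnorm(n_env, 0, env_sd), envs)
  gxe <- matrix(rnorm(n * n_env, 0, sqrt(v_gxe)), n, n_env)
  rows <- expand.grid(replicate = seq_len(n_rep), environment = envs,
                      sample = m$samples, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  si <- match(rows$sample, m$samples)
  ei <- match(rows$environment, envs)
  y <- mu_pheno + g[si] + env_eff[ei] + gxe[cbind(si, ei)] +
    rnorm(nrow(rows), 0, sqrt(v_res))
  y[y <= 0] <- 0.01                       # weights must stay positive
  pt <- phenotype_table(data.frame(
    sample = rows$sample, environment = rows$environment,
    replicate = rows$replicate, hundred_seed_weight = y,
    stringsAsFactors = FALSE))
  attr(pt, "qtl") <- qtl
  attr(pt, "breeding_values") <- setNames(g, m$samples)
  attr(pt, "env_effects") <- env_eff
  if (!is.null(truth)) {
    truth$qtl <- qtl
    truth$env_effects <- env_eff
    attr(pt, "truth") <- truth
  }
  pt
}
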