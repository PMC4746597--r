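#' Pipeline run configuration
#'
#' All stage parameters of the end-to-end analysis in one validated list,
#' pre-filled with the package defaults (100-kb diversity windows, 10-kb
#' sweep windows at the 0.95 empirical tail, 1-kb LD bins, MAF cutoffs of
#' 0.05 for association and 0.10 for array design, 1,680-bp fill windows).
#'
#' @param out_dir output directory (created by [run_pipeline()]).
#' @param seed integer seed driving every stochastic stage.
#' @param sim a [sim_params()] describing the simulated panel, or NULL to
#'   analyse the supplied `vcf`/`meta` inputs instead.
#' @param vcf,meta,gff optional input paths used when `sim` is NULL.
#' @param stats_window,sweep_window,design_window window sizes in bp.
#' @param q sweep-call empirical quantile.
#' @param ld_bin,ld_max_dist LD curve parameters in bp.
#' @param gwas_maf,design_maf MAF cutoffs.
#' @param n_env,h2 phenotype-simulation parameters.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_params(seed = seed),
                            vcf = NULL, meta = NULL, gff = NULL,
                            stats_window = 1e5, sweep_window = 1e4,
                            design_window = 1680, q = 0.95, ld_bin = 1000,
                            ld_max_dist = 1e6, gwas_maf = 0.05,
                            design_maf = 0.10, n_env = 9L, h2 = 0.5) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              vcf = vcf, meta = meta, gff = gff,
              stats_window = stats_window, sweep_window = sweep_window,
              design_window = design_window, q = q, ld_bin = ld_bin,
              ld_max_dist = ld_max_dist, gwas_maf = gwas_maf,
              design_maf = design_maf, n_env = as.integer(n_env), h2 = h2)
  stopifnot(cfg$stats_window > 0, cfg$sweep_window > 0,
            cfg$design_window > 0, cfg$q >= 0, cfg$q < 1,
            cfg$ld_bin > 0, cfg$ld_max_dist > 0,
            cfg$gwas_maf >= 0, cfg$gwas_maf < 0.5,
            cfg$design_maf >= 0, cfg$design_maf < 0.5,
            cfg$n_env >= 2, cfg$h2 > 0, cfg$h2 < 1)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full domestication-scan pipeline
#'
#' Orchestrates simulate (or load) -> windowed statistics -> LD decay ->
#' composite sweep scan -> structure/phylogeny -> phenotypes + GWAS, writing
#' per-stage TSV/BED/Newick outputs, a serialized configuration and a
#' machine-readable `metrics.json` into `config$out_dir`.  Deterministic
#' given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return list with the per-stage results and `metrics` (also written as
#'   JSON), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # validate inputs before any computation
  if (is.null(config$sim)) {
    for (f in c(config$vcf, config$meta))
      if (is.null(f) || !file.exists(f))
        stop("missing input file: ", if (is.null(f)) "(unset)" else f)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(config$sim)) {
    simd <- stage("simulate", simulate_two_pop(config$sim))
    m <- simd$genotypes
    meta <- simd$metadata
    layout <- sim_layout(config$sim)
    genes <- simulate_genes(config$sim)
    write_genotypes(m, file.path(config$out_dir, "panel.vcf"), layout)
    write.table(as.data.frame(simd$metadata),
                file.path(config$out_dir, "metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    m <- stage("io", read_genotypes(config$vcf))
    meta <- stage("io", read_metadata(config$meta))
    genes <- if (!is.null(config$gff)) stage("io", read_genes(config$gff))
             else NULL
    layout <- genome_layout(data.frame(
      chrom = unique(m$variants$chrom),
      length = vapply(unique(m$variants$chrom), function(cc)
        max(m$variants$pos[m$variants$chrom == cc]) + 1, numeric(1))))
    simd <- NULL
  }

  ws <- stage("stats", window_stats(m, meta, layout,
                                    window = config$stats_window))
  write_windows(ws, file.path(config$out_dir, "window_stats.tsv"))

  ld_w <- stage("ld", ld_decay(m, meta, "wild",
                               max_dist = config$ld_max_dist,
                               bin_width = config$ld_bin))
  ld_c <- stage("ld", ld_decay(m, meta, "cultivated",
                               max_dist = config$ld_max_dist,
                               bin_width = config$ld_bin))

  sw <- stage("sweep", sweep_scan(m, meta, layout,
                                  window = config$sweep_window,
                                  q = config$q, genes = genes))
  write_windows(sw$windows, file.path(config$out_dir, "sweep_windows.tsv"))
  write_regions(sw$regions, file.path(config$out_dir, "sweep_regions.bed"))

  ibs <- stage("structure", ibs_distance(m))
  pca <- stage("structure", pca_coords(m, k = min(5L, n_samples(m) - 1L)))
  tree <- stage("structure", nj_tree(ibs))
  write_tree(tree, file.path(config$out_dir, "nj_tree.nwk"))
  write.table(data.frame(sample = rownames(pca$coords), pca$coords),
              file.path(config$out_dir, "pca.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  gwas <- NULL
  blup <- NULL
  if (!is.null(simd)) {
    pheno <- stage("phenotype", simulate_phenotypes(
      m, simd$truth, n_env = config$n_env, h2 = config$h2,
      seed = config$seed))
    cul <- meta$sample[meta$population == "cultivated"]
    blup <- stage("blup", blup_phenotype(pheno[pheno$sample %in% cul, ]))
    hd <- if (is.finite(ld_c$half_decay)) ld_c$half_decay else 1e5
    gwas <- stage("gwas", mlm_scan(m, blup, maf_min = config$gwas_maf))
    write.table(gwas$scores, file.path(config$out_dir, "gwas.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(gwas$significant)) {
      cr <- candidate_regions(gwas, hd, genes = genes, layout = layout)
      write_regions(cr, file.path(config$out_dir, "gwas_regions.bed"))
    }
  }

  metrics <- list(
    seed = config$seed,
    n_snps = n_variants(m),
    n_samples = n_samples(m),
    mean_pi_wild = mean(ws$pi_wild),
    mean_pi_cul = mean(ws$pi_cul),
    mean_tajd_wild = mean(ws$tajd_wild, na.rm = TRUE),
    mean_tajd_cul = mean(ws$tajd_cul, na.rm = TRUE),
    ld_half_decay_wild = ld_w$half_decay,
    ld_half_decay_cul = ld_c$half_decay,
    n_called_windows = sum(sw$windows$called),
    n_sweep_regions = nrow(sw$regions),
    sweep_genome_fraction = sw$genome_fraction,
    gwas_n_markers = if (!is.null(gwas)) gwas$n_markers else NA,
    gwas_threshold = if (!is.null(gwas)) gwas$threshold else NA,
    gwas_n_significant = if (!is.null(gwas)) length(gwas$significant)
                         else NA)
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfgser <- config
  cfgser$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  jsonlite::write_json(unclass(cfgser),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(genotypes = m, metadata = meta, layout = layout,
                 window_stats = ws, ld_wild = ld_w, ld_cul = ld_c,
                 sweep = sw, pca = pca, tree = tree, blup = blup,
                 gwas = gwas, metrics = metrics))
}
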