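# BLUP, VanRaden kinship, exact MLM scan, 1/n threshold, candidate regions

balanced_pheno <- function(n_samp, n_env, n_rep, sg = 2, se = 1,
                           env_eff = NULL, seed = 1) {
  set.seed(seed)
  g <- rnorm(n_samp, 0, sg)
  if (is.null(env_eff)) env_eff <- rnorm(n_env, 0, 1.5)
  rows <- expand.grid(replicate = seq_len(n_rep),
                      environment = sprintf("E%d", seq_len(n_env)),
                      sample = sprintf("S%03d", seq_len(n_samp)),
                      stringsAsFactors = FALSE)
  si <- match(rows$sample, sprintf("S%03d", seq_len(n_samp)))
  ei <- match(rows$environment, sprintf("E%d", seq_len(n_env)))
  y <- 20 + g[si] + env_eff[ei] + rnorm(nrow(rows), 0, se)
  list(pt = phenotype_table(data.frame(rows, hundred_seed_weight = y)),
       g = setNames(g, sprintf("S%03d", seq_len(n_samp))))
}

test_that("BLUPs shrink genotype means by the closed-form balanced factor", {
  bp <- balanced_pheno(40, 6, 3)
  b <- blup_phenotype(bp$pt)
  fit <- lme4::lmer(hundred_seed_weight ~ environment + (1 | sample),
                    data = bp$pt, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "sample"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  mobs <- 6 * 3                       # observations per sample
  shrink <- s2g / (s2g + s2e / mobs)
  means <- tapply(bp$pt$hundred_seed_weight, bp$pt$sample, mean)
  closed <- shrink * (means - mean(means))
  expect_equal(unname(b[names(means)]), as.vector(closed), tolerance = 1e-6)
  # correlation with the generating breeding values is high
  expect_gt(cor(b[names(bp$g)], bp$g), 0.9)
})

test_that("BLUP limit case: (near-)zero residual returns centered means", {
  n <- 12
  g <- seq(-2, 2, length.out = n)
  rows <- expand.grid(replicate = 1:2, environment = c("E1", "E2"),
                      sample = sprintf("S%03d", 1:n),
                      stringsAsFactors = FALSE)
  si <- match(rows$sample, sprintf("S%03d", 1:n))
  y <- 10 + g[si] + ifelse(rows$environment == "E2", 3, 0) +
    rnorm(nrow(rows), 0, 1e-4)
  pt <- phenotype_table(data.frame(rows, hundred_seed_weight = y))
  b <- blup_phenotype(pt)
  expect_equal(unname(b[sprintf("S%03d", 1:n)]), g - mean(g),
               tolerance = 1e-2)
})

test_that("BLUPs are invariant to a consistent environment relabeling", {
  bp <- balanced_pheno(20, 4, 2)
  b1 <- blup_phenotype(bp$pt)
  pt2 <- bp$pt
  map <- c(E1 = "Zp", E2 = "Aq", E3 = "Mx", E4 = "Bb")
  pt2$environment <- unname(map[pt2$environment])
  b2 <- blup_phenotype(phenotype_table(as.data.frame(pt2)))
  expect_equal(b1, b2[names(b1)], tolerance = 1e-8)
})

test_that("VanRaden kinship matches hand computation and is PSD", {
  # single SNP, p = 0.5, dosages [0, 2]: K = [[2,-2],[-2,2]]
  m <- make_geno(matrix(c(0L, 2L), 1))
  K <- vanraden_kinship(m)
  expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  m2 <- random_geno(50, 8, seed = 4)
  dup <- genotype_matrix(m2$variants, c(m2$samples, "dup"),
                         cbind(m2$dosage, m2$dosage[, 3]))
  K2 <- vanraden_kinship(dup)
  expect_equal(K2["dup", "dup"], K2["dup", m2$samples[3]])
  expect_equal(K2, t(K2))
  expect_gte(min(eigen(K2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # outbred panel: diagonal mean near 1
  K3 <- vanraden_kinship(random_geno(400, 60, seed = 9))
  expect_gt(mean(diag(K3)), 0.8)
  expect_lt(mean(diag(K3)), 1.5)

  mono <- make_geno(matrix(c(2L, 2L, 2L), 1))
  expect_error(vanraden_kinship(mono), "monomorphic")
})

test_that("MLM with K = I and infinite variance ratio reduces to OLS", {
  set.seed(12)
  m <- random_geno(60, 40)
  y <- setNames(rnorm(40), m$samples)
  res <- mlm_scan(m, y, K = diag(40), n_pcs = 2L, maf_min = 0,
                  callrate_min = 0, lambda = Inf)
  pcs <- pca_coords(subset_genotypes(m, variants = match(res$scores$id,
                                                         m$variants$id)),
                    k = 2)$coords
  for (k in sample(nrow(res$scores), 8)) {
    g <- m$dosage[match(res$scores$id[k], m$variants$id), ]
    fit <- summary(lm(y ~ pcs + g))$coefficients
    expect_equal(res$scores$beta[k], fit["g", 1], tolerance = 1e-8)
    expect_equal(res$scores$p[k], fit["g", 4], tolerance = 1e-8)
  }
})

test_that("a marker collinear with a PC covariate is absorbed (p = 1)", {
  set.seed(13)
  m <- random_geno(30, 25)
  # plant a marker exactly duplicating another so PC1 won't absorb it, then
  # test the stronger contract: marker equal to an existing covariate
  y <- setNames(rnorm(25), m$samples)
  K <- diag(25)
  res <- mlm_scan(m, y, K = K, n_pcs = 0L, maf_min = 0, callrate_min = 0,
                  lambda = Inf)
  # the intercept absorbs a monomorphic-like marker: craft one constant
  mm <- m
  mm$dosage[1, ] <- 1L                        # constant = intercept direction
  res2 <- mlm_scan(mm, y, K = K, n_pcs = 0L, maf_min = 0, callrate_min = 0,
                   lambda = Inf)
  i <- match(mm$variants$id[1], res2$scores$id)
  expect_equal(res2$scores$beta[i], 0)
  expect_equal(res2$scores$p[i], 1)
  expect_false(is.na(res$threshold))
})

test_that("null phenotypes give calibrated uniform p-values", {
  set.seed(19)
  m <- random_geno(800, 120)
  y <- setNames(rnorm(120), m$samples)
  res <- mlm_scan(m, y, n_pcs = 2L)
  ks <- suppressWarnings(ks.test(res$scores$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(res$scores$p < 0.05) - 0.05), 0.03)
})

test_that("significance threshold reproduces the printed 1/n cutoffs", {
  expect_equal(significance_threshold(207608), 4.82e-6)
  expect_equal(significance_threshold(239658), 4.17e-6)
  expect_equal(significance_threshold(1), 1)
})

test_that("candidate regions center on leads, merge and clip correctly", {
  hits <- data.frame(id = c("a", "b", "c"), chrom = c("chr1", "chr1", "chr2"),
                     pos = c(1000000L, 1050000L, 10000L),
                     p = c(1e-8, 1e-6, 1e-7), stringsAsFactors = FALSE)
  layout <- genome_layout(data.frame(chrom = c("chr1", "chr2"),
                                     length = c(2e6, 2e6)))
  cr <- candidate_regions(hits, half_decay = 130000, layout = layout)
  # two hits 50 kb apart merge; lead is the smaller p
  r1 <- cr[cr$chrom == "chr1", ]
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$lead_id, "a")
  expect_equal(r1$start, 1000000 - 130000 - 1)
  expect_equal(r1$end, 1050000 + 130000)
  # clipping at the chromosome start
  r2 <- cr[cr$chrom == "chr2", ]
  expect_equal(r2$start, 0)
  expect_equal(r2$end, 10000 + 130000)
  # single hit: exact arithmetic of the stated rule
  cr1 <- candidate_regions(hits[1, ], half_decay = 130000)
  expect_equal(cr1$start + 1, 870000)       # 1-based left edge
  expect_equal(cr1$end, 1130000)
  # genes attached by overlap
  genes <- gene_set(data.frame(id = "gX", chrom = "chr1", start = 900000L,
                               end = 910000L, strand = "+"))
  crg <- candidate_regions(hits[1, ], 130000, genes = genes)
  expect_equal(crg$genes[[1]], "gX")
})

test_that("BLUP recovers breeding values from simulated phenotypes", {
  ok <- 0
  for (seed in 1:5) {
    sim <- simulate_two_pop(small_sim(seed))
    ph <- simulate_phenotypes(sim$genotypes, sim$truth, n_env = 5L,
                              h2 = 0.5, seed = seed, n_qtl = 5L, n_rep = 2L)
    b <- blup_phenotype(ph)
    g <- attr(ph, "breeding_values")
    if (cor(b[names(g)], g) >= 0.6) ok <- ok + 1
  }
  expect_gte(ok, 4)
})
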