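# per-site and windowed diversity statistics against hand values and
# literal-formula / brute-force oracles

test_that("site_stats counts alleles, MAF and missingness by hand", {
  m <- make_geno(rbind(c(0L, 1L, 2L),
                       c(0L, 0L, NA),
                       c(2L, 2L, NA)))
  ss <- site_stats(m)
  expect_equal(ss$p, c(0.5, 0, 1))
  expect_equal(ss$maf, c(0.5, 0, 0))
  expect_equal(ss$missing, c(0, 1 / 3, 1 / 3))

  m2 <- make_geno(matrix(c(2L, 2L, 2L, 1L), 1))
  expect_equal(site_stats(m2)$p, 7 / 8)
  expect_equal(site_stats(m2)$maf, 1 / 8)

  expect_error(site_stats(m, integer(0)), "empty")
})

test_that("windowed pi matches the worked example and zero cases", {
  # one site, dosages [0,2], 10-kb window: pi-hat = 4/6 per site
  m <- make_geno(matrix(c(0L, 2L), 1), pos = 5000L)
  w <- make_windows(one_chrom_layout(10000), 10000)
  expect_equal(pi_windows(m, NULL, w), (4 / 6) / 10000, tolerance = 1e-12)

  # monomorphic window -> 0
  m0 <- make_geno(matrix(c(2L, 2L), 1), pos = 5000L)
  expect_equal(pi_windows(m0, NULL, w), 0)

  # window with no SNPs -> 0
  w2 <- make_windows(one_chrom_layout(20000), 10000)
  expect_equal(pi_windows(m, NULL, w2)[2], 0)
})

test_that("pi equals the pairwise-difference enumeration oracle", {
  set.seed(42)
  for (rep in 1:50) {
    nsnp <- sample(3:12, 1)
    m <- random_geno(nsnp, 6, miss = ifelse(rep %% 2, 0, 0.2))
    w <- make_windows(one_chrom_layout(1e6), 1e6)
    expect_equal(pi_windows(m, NULL, w),
                 oracle_pi_window(m$dosage, 1e6), tolerance = 1e-10)
  }
})

test_that("Tajima's D matches a literal-formula oracle and handles S = 0", {
  # three singleton sites over three samples
  m <- make_geno(rbind(c(0L, 0L, 1L), c(0L, 1L, 0L), c(1L, 0L, 0L)))
  w <- make_windows(one_chrom_layout(1000), 1000)
  expect_equal(tajimas_d_windows(m, NULL, w),
               unname(oracle_tajima(m$dosage)), tolerance = 1e-10)

  # S = 0 -> missing, not zero
  m0 <- make_geno(rbind(c(0L, 0L, 0L), c(2L, 2L, 2L)))
  expect_true(is.na(tajimas_d_windows(m0, NULL, w)))

  wbig <- make_windows(one_chrom_layout(1e6), 1e6)
  set.seed(7)
  for (rep in 1:50) {
    m <- random_geno(sample(4:15, 1), sample(4:8, 1),
                     miss = ifelse(rep %% 2, 0, 0.15))
    got <- tajimas_d_windows(m, NULL, wbig)
    want <- unname(oracle_tajima(m$dosage))
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Weir-Cockerham F_ST: fixed difference, no differentiation, oracle", {
  n <- 20
  m <- make_geno(matrix(c(rep(0L, n), rep(2L, n)), 1))
  meta <- make_meta(m, n)
  w <- make_windows(one_chrom_layout(1000), 1000)
  expect_equal(fst_windows(m, meta, w), 1)

  # identical allele frequencies and genotype counts in both pops
  block <- c(rep(0L, 5), rep(1L, 5), rep(2L, 5))
  m2 <- make_geno(matrix(c(block, block), 1))
  meta2 <- make_meta(m2, 15)
  expect_lte(fst_windows(m2, meta2, w), 0)

  # hand-constructed example equals the independent WC84 oracle
  m3 <- make_geno(matrix(c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L), 1))
  meta3 <- make_meta(m3, 4)
  expect_equal(fst_windows(m3, meta3, w),
               oracle_wc_fst(m3$dosage[, 1:4, drop = FALSE],
                             m3$dosage[, 5:8, drop = FALSE]),
               tolerance = 1e-10)

  set.seed(11)
  for (rep in 1:50) {
    m4 <- random_geno(sample(3:10, 1), 12, miss = ifelse(rep %% 2, 0, 0.2))
    meta4 <- make_meta(m4, 6)
    got <- fst_windows(m4, meta4, make_windows(one_chrom_layout(1e6), 1e6))
    want <- oracle_wc_fst(m4$dosage[, 1:6, drop = FALSE],
                          m4$dosage[, 7:12, drop = FALSE])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("ROD follows its definition including undefined pi_wild = 0", {
  expect_equal(rod(2e-4, 2e-4), 0)
  expect_equal(rod(2e-4, 0), 1)
  expect_equal(rod(1e-4, 2e-4), -1)
  expect_true(is.na(rod(0, 1e-4)))
})

test_that("mean pairwise SNP count matches brute force", {
  m <- make_geno(rbind(c(0L, 2L), c(0L, 2L), c(0L, 2L)))
  expect_equal(mean_pairwise_snp_count(m), 3)
  m2 <- make_geno(matrix(c(1L, 1L, 1L, 1L), 2))
  expect_equal(mean_pairwise_snp_count(m2), 0)
  expect_error(mean_pairwise_snp_count(make_geno(matrix(0L, 2, 1))),
               "2 samples")
  set.seed(3)
  for (rep in 1:20) {
    m3 <- random_geno(5, 4, miss = 0.2)
    expect_equal(mean_pairwise_snp_count(m3),
                 oracle_pairwise_count(m3$dosage))
  }
})

test_that("shared/unique partition is exhaustive and mutually exclusive", {
  # rows engineered: shared, wild-only, cultivated-only, monomorphic
  d <- rbind(c(0L, 1L, 0L, 1L),
             c(0L, 2L, 0L, 0L),
             c(1L, 1L, 1L, 2L),   # wild fixed het? dosage 1,1 -> p=0.5 poly
             c(0L, 0L, 0L, 1L),
             c(2L, 2L, 2L, 2L))
  m <- make_geno(d)
  meta <- make_meta(m, 2)
  part <- shared_unique_partition(m, meta)
  expect_equal(sum(part), n_variants(m))
  expect_equal(unname(part["monomorphic"]), 1L)
  expect_equal(unname(part["cultivated_only"]), 1L)  # row 4
  expect_equal(unname(part["wild_only"]), 1L)        # row 2
  expect_equal(unname(part["shared"]), 2L)           # rows 1 and 3

  set.seed(9)
  for (rep in 1:10) {
    mr <- random_geno(30, 8, miss = 0.2)
    expect_equal(sum(shared_unique_partition(mr, make_meta(mr, 4))), 30L)
  }
})

test_that("bottleneck simulations lose diversity genome-wide (pi t-test)", {
  ok_dir <- 0; ok_p <- 0; nrep <- 5
  for (seed in 1:nrep) {
    p <- small_sim(seed, L = 1e6, N_anc = 100L, N_wild = 100L,
                   N_cul = 100L, bottleneck_size = 10L, T_split = 40L,
                   bottleneck_duration = 20L, n_sample_wild = 30L,
                   n_sample_cul = 40L)
    sim <- simulate_two_pop(p)
    ws <- window_stats(sim$genotypes, sim$metadata, sim_layout(p),
                       window = 2e4, tajima = FALSE)
    if (mean(ws$pi_cul) < mean(ws$pi_wild)) ok_dir <- ok_dir + 1
    pt <- t.test(ws$pi_cul, ws$pi_wild, paired = TRUE)$p.value
    if (pt < 0.05) ok_p <- ok_p + 1
  }
  expect_gte(ok_dir, nrep - 1)
  expect_gte(ok_p, nrep - 1)
})
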