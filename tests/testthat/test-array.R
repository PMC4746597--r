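# array-design pipeline: candidate filter, flank uniqueness, greedy tag
# selection, window fill, VIP merge and design summary

test_that("candidate filter applies MAF and missingness cutoffs", {
  d <- rbind(c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),  # maf 0.05
             c(rep(0L, 5), rep(1L, 3), NA, NA),           # maf .1875 miss .2
             c(rep(0L, 4), rep(1L, 3), rep(NA, 3)),       # miss 0.3
             c(rep(0L, 6), rep(2L, 4)))                   # maf 0.4
  m <- make_geno(d)
  keep <- filter_candidates(m)
  expect_setequal(keep, m$variants$id[c(2, 4)])
})

test_that("flank uniqueness flags duplicates, reverse complements and edges", {
  set.seed(10)
  base <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  dup <- substr(base, 1001, 1033)          # 33-mer duplicated verbatim
  rcdup <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      substr(base, 2001, 2033))))
  ref <- Biostrings::DNAStringSet(c(
    chr1 = paste0(base, dup, rcdup)))
  m <- make_geno(matrix(0L, 4, 2),
                 pos = c(1017L, 2017L, 3000L, 10L))
  fu <- flank_unique(m, ref)
  names(fu) <- m$variants$pos
  expect_false(fu[["1017"]])               # verbatim duplicate downstream
  expect_false(fu[["2017"]])               # reverse-complement duplicate
  expect_true(fu[["3000"]])                # unique random context
  expect_true(is.na(fu[["10"]]))           # within 16 bp of the contig end

  # naive string-scan oracle on the same reference
  refstr <- as.character(ref[[1]])
  naive_count <- function(p) {
    kmer <- substr(refstr, p - 16, p + 16)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(kmer)))
    cnt <- 0
    for (i in 1:(nchar(refstr) - 32)) {
      s <- substr(refstr, i, i + 32)
      if (s == kmer || s == rc) cnt <- cnt + 1
    }
    cnt
  }
  expect_equal(naive_count(1017) > 1, TRUE)
  expect_equal(naive_count(3000), 1)
})

test_that("greedy tag selection covers everything and matches brute force", {
  # three SNPs in perfect mutual LD -> one tag
  d <- rbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L), c(2L, 2L, 0L, 0L))
  m <- make_geno(d, pos = c(100L, 200L, 300L))
  expect_length(select_tag_snps(m, m$variants$id), 1L)

  # three mutually independent SNPs -> three tags
  d2 <- rbind(c(0L, 0L, 2L, 2L), c(0L, 2L, 0L, 2L), c(2L, 0L, 0L, 2L))
  m2 <- make_geno(d2, pos = c(100L, 200L, 300L))
  expect_length(select_tag_snps(m2, m2$variants$id), 3L)

  # random 6-SNP instances: tag property holds and greedy is within 2x of
  # the exhaustive minimum set cover
  set.seed(14)
  for (rep in 1:20) {
    mr <- random_geno(6, 10)
    cand <- mr$variants$id
    tags <- select_tag_snps(mr, cand, r2_max = 0.8, window = 1e6)
    pr <- pairwise_r2(mr)
    cov <- lapply(1:6, function(i) {
      strong <- pr[(pr$i == i | pr$j == i) & pr$r2 >= 0.8, ]
      sort(unique(c(i, strong$i, strong$j)))
    })
    tag_idx <- match(tags, mr$variants$id)
    expect_setequal(unique(unlist(cov[tag_idx])), 1:6)  # all tagged
    expect_lte(length(tags), 2 * length(oracle_min_tags(cov)))
  }
})

test_that("window fill prefers genic candidates nearest the tile center", {
  layout <- one_chrom_layout(1680 * 3)
  genes <- gene_set(data.frame(id = "g1", chrom = "chr1", start = 1680L,
                               end = 3360L, strand = "+"))
  # tile 1 holds a tag; tile 2 has genic+intergenic candidates; tile 3 has
  # two intergenic candidates at offsets 100 and 800 (center 840)
  pos <- c(100L,                       # tag in tile 1
           1680L + 100L,              # candidate, intergenic? inside gene
           1680L + 800L,              # candidate inside gene span
           2 * 1680L + 100L, 2 * 1680L + 800L)
  m <- make_geno(matrix(rep(c(0L, 1L, 2L, 0L), 5), 5, byrow = TRUE),
                 pos = pos)
  tags <- m$variants$id[1]
  cands <- m$variants$id
  fills <- fill_windows(tags, cands, m, genes, layout)
  # tile 1 untouched; tile 2 gets the genic candidate nearest center
  # (both candidates genic here: offsets 100 vs 800, center 840 -> 800)
  expect_equal(nrow(fills), 2L)
  expect_true(m$variants$id[3] %in% fills$id)
  expect_equal(fills$reason[fills$id == m$variants$id[3]],
               "window-fill-genic")
  # tile 3: intergenic candidates at offsets 100 and 800 -> 800 wins
  expect_true(m$variants$id[5] %in% fills$id)
  expect_equal(fills$reason[fills$id == m$variants$id[5]],
               "window-fill-intergenic")
  # never adds to a tile that already holds a selected SNP
  expect_false(any(fills$id == m$variants$id[1]))
})

test_that("VIP merge unions without duplicates and warns on unknown ids", {
  m <- random_geno(10, 4, seed = 2)
  des <- array_design(m, tags = m$variants$id[1:3])
  expect_equal(nrow(merge_vip(des, m$variants$id[2], m)), 3L)  # already in
  d2 <- merge_vip(des, m$variants$id[4:5], m)
  expect_equal(nrow(d2), 5L)
  expect_setequal(d2$reason[d2$id %in% m$variants$id[4:5]], "vip")
  expect_warning(d3 <- merge_vip(des, c("nope"), m), "unknown")
  expect_equal(nrow(d3), 3L)
  expect_equal(nrow(merge_vip(des, character(0), m)), 3L)
})

test_that("design summary reproduces the printed coverage arithmetic", {
  # 291,962 SNPs over a 975-Mb 20-chromosome genome -> ~3.3 kb spacing
  layout <- genome_layout(data.frame(chrom = sprintf("chr%02d", 1:20),
                                     length = 975e6 / 20))
  set.seed(6)
  per <- c(rep(14599L, 19), 291962L - 19L * 14599L)
  des <- do.call(rbind, lapply(1:20, function(i) data.frame(
    id = sprintf("c%d_%d", i, seq_len(per[i])),
    chrom = sprintf("chr%02d", i),
    pos = sort(sample.int(975e6 / 20, per[i])),
    reason = "tag", stringsAsFactors = FALSE)))
  sm <- design_summary(des, layout)
  expect_equal(round(sm$mean_spacing / 1000, 1), 3.3)
  expect_equal(sm$n_mapped, 291962L)

  # single SNP on one chromosome -> no gaps, spacing defined by formula
  one <- data.frame(id = "x", chrom = "chr01", pos = 10L, reason = "tag")
  s1 <- design_summary(one, layout)
  expect_true(is.na(s1$frac_gaps_below))

  # context fractions sum to 100% of classified SNPs
  sim <- simulate_two_pop(small_sim(3))
  genes <- simulate_genes(small_sim(3))
  lay <- sim_layout(small_sim(3))
  m <- sim$genotypes
  des2 <- array_design(m, tags = m$variants$id[seq(1, n_variants(m), 7)])
  s2 <- design_summary(des2, lay, genes = genes, m = m)
  expect_equal(sum(s2$context_fractions), 100)
  expect_equal(sum(s2$context_counts), nrow(des2))
})

test_that("pericentromeric assignment uses supplied layout intervals", {
  layout <- genome_layout(
    data.frame(chrom = "chr1", length = 1e6),
    pericentromeric = data.frame(chrom = "chr1", start = 4e5, end = 6e5))
  des <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(100L, 450000L, 900000L), reason = "tag")
  sm <- design_summary(des, layout)
  expect_equal(sm$n_pericentromeric, 1L)
  expect_equal(sm$n_arm, 2L)
})
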