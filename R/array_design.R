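#' Filter array candidate SNPs by MAF and missingness
#'
#' Retains SNPs with minor allele frequency >= `maf_min` and missing-call
#' fraction <= `miss_max`.
#'
#' @inheritParams site_stats
#' @param maf_min minimum MAF (default 0.10).
#' @param miss_max maximum missing fraction (default 0.2).
#' @return Character vector of retained SNP ids.
#' @export
filter_candidates <- function(m, maf_min = 0.10, miss_max = 0.2,
                              subset = NULL) {
  ss <- site_stats(m, subset)
  keep <- !is.na(ss$maf) & ss$maf >= maf_min & ss$missing <= miss_max
  m$variants$id[keep]
}

#' Flank-uniqueness of SNP probe context
#'
#' The `2*flank + 1`-mer centered on each SNP (reference base at the center)
#' must occur exactly once in the reference, counting both strands; SNPs
#' whose context occurs more than once are flagged non-unique.  SNPs within
#' `flank` bp of a sequence end are non-evaluable (`NA`).
#'
#' @param m a [genotype_matrix()].
#' @param reference a [Biostrings::DNAStringSet] named by chromosome.
#' @param flank flank length either side of the SNP (default 16 bp).
#' @return Logical vector per SNP: `TRUE` unique, `FALSE` multi-hit, `NA`
#'   non-evaluable.
#' @export
flank_unique <- function(m, reference, flank = 16L) {
  stopifnot(methods::is(reference, "DNAStringSet"))
  v <- m$variants
  if (!all(unique(v$chrom) %in% names(reference)))
    stop("reference is missing chromosome(s): ",
         paste(setdiff(unique(v$chrom), names(reference)), collapse = ", "))
  lens <- setNames(Biostrings::width(reference), names(reference))
  evaluable <- v$pos - flank >= 1L & v$pos + flank <= unname(lens[v$chrom])
  out <- rep(NA, nrow(v))
  if (!any(evaluable)) return(out)
  i <- which(evaluable)
  kmers <- Biostrings::DNAStringSet(vapply(i, function(k) {
    as.character(Biostrings::subseq(reference[[v$chrom[k]]],
                                    v$pos[k] - flank, v$pos[k] + flank))
  }, character(1)))
  count_hits <- function(q) {
    pd <- Biostrings::PDict(q)
    rowSums(vapply(seq_along(reference), function(s)
      Biostrings::countPDict(pd, reference[[s]]), integer(length(q))))
  }
  hits <- count_hits(kmers) + count_hits(Biostrings::reverseComplement(kmers))
  out[i] <- hits == 1L
  out
}

# r2 adjacency among candidate SNPs within a physical window, per chromosome:
# returns list of integer vectors cov[[k]] = indices (into cand order) tagged
# by candidate k (always including k itself)
tag_adjacency <- function(m, cand_idx, r2_max, window) {
  n <- length(cand_idx)
  cov <- vector("list", n)
  for (k in seq_len(n)) cov[[k]] <- k
  pr <- pairwise_r2(subset_genotypes(m, variants = cand_idx),
                    max_dist = window)
  if (nrow(pr)) {
    strong <- pr[pr$r2 >= r2_max, , drop = FALSE]
    for (r in seq_len(nrow(strong))) {
      i <- strong$i[r]; j <- strong$j[r]
      cov[[i]] <- c(cov[[i]], j)
      cov[[j]] <- c(cov[[j]], i)
    }
  }
  cov
}

#' Greedy tag-SNP selection
#'
#' Greedy set cover over the candidate SNPs: a candidate tags every
#' candidate with `r2 >= r2_max` within `window` bp on the same chromosome
#' (and itself).  Repeatedly picks the candidate tagging the most untagged
#' SNPs (ties broken by leftmost genomic position) until every candidate is
#' tagged.
#'
#' @param m a [genotype_matrix()].
#' @param candidates character vector of candidate SNP ids (e.g. from
#'   [filter_candidates()]).
#' @param r2_max LD threshold at/above which a SNP is considered tagged
#'   (default 0.8).
#' @param window maximum physical distance over which LD is evaluated
#'   (default 500 kb).
#' @return Character vector of tag SNP ids.
#' @export
select_tag_snps <- function(m, candidates, r2_max = 0.8, window = 5e5) {
  ci <- match(candidates, m$variants$id)
  if (anyNA(ci)) stop("unknown candidate id(s)")
  if (!length(ci)) return(character(0))
  ord <- order(m$variants$chrom[ci], m$variants$pos[ci])
  ci <- ci[ord]
  cov <- tag_adjacency(m, ci, r2_max, window)
  n <- length(ci)
  untagged <- rep(TRUE, n)
  tags <- integer(0)
  gain <- vapply(cov, length, integer(1))
  while (any(untagged)) {
    # gain = number of currently untagged candidates each pick would tag;
    # candidates are in (chrom, pos) order so which.max's first-match rule
    # is the leftmost-position tie-break
    gain <- vapply(cov, function(s) sum(untagged[s]), integer(1))
    pick <- which.max(gain)
    tags <- c(tags, pick)
    untagged[cov[[pick]]] <- FALSE
  }
  m$variants$id[ci[sort(tags)]]
}

#' Fill sparse windows with additional SNPs
#'
#' Tiles each chromosome into non-overlapping `window`-bp windows ("even
#' distribution"); every window that contains at least one candidate but no
#' already-selected SNP receives one extra SNP, preferring genic over
#' intergenic candidates, and within a class the candidate nearest the
#' window center (ties to the leftmost).
#'
#' @param tags character vector of already-selected SNP ids.
#' @param candidates character vector of candidate SNP ids.
#' @param m a [genotype_matrix()].
#' @param genes a [gene_set()] used to call candidates genic/intergenic.
#' @param layout a [genome_layout()].
#' @param window fill window size in bp (default 1,680).
#' @return data.frame with columns `id`, `reason` (`window-fill-genic` or
#'   `window-fill-intergenic`) for the added SNPs.
#' @export
fill_windows <- function(tags, candidates, m, genes, layout, window = 1680) {
  w <- make_windows(layout, window)
  ctx <- classify_snp_context(m, genes)
  genic <- ctx != "intergenic"
  wi_all <- window_of(m$variants, w)
  ti <- match(tags, m$variants$id)
  ci <- match(setdiff(candidates, tags), m$variants$id)
  if (anyNA(ti) || anyNA(ci)) stop("unknown SNP id(s)")
  occupied <- unique(wi_all[ti])
  added_id <- character(0)
  added_reason <- character(0)
  cand_by_win <- split(ci, wi_all[ci])
  for (wn in names(cand_by_win)) {
    wix <- as.integer(wn)
    if (wix %in% occupied) next
    cc <- cand_by_win[[wn]]
    pick_from <- if (any(genic[cc])) cc[genic[cc]] else cc
    center <- (w$start[wix] + w$end[wix]) / 2
    dctr <- abs(m$variants$pos[pick_from] - 0.5 - center)  # pos-0.5 = bp midpoint
    pick <- pick_from[order(dctr, m$variants$pos[pick_from])][1]
    added_id <- c(added_id, m$variants$id[pick])
    added_reason <- c(added_reason,
                      if (genic[pick]) "window-fill-genic"
                      else "window-fill-intergenic")
  }
  data.frame(id = added_id, reason = added_reason, stringsAsFactors = FALSE)
}

#' Assemble an array design and supplement VIP SNPs
#'
#' Union of the tag set, the window-fill set and a VIP list; duplicates are
#' collapsed keeping the earliest selection reason, VIP ids not already
#' selected get reason `vip`, and unknown VIP ids are skipped with a
#' warning.
#'
#' @param m a [genotype_matrix()].
#' @param tags character vector of tag SNP ids.
#' @param fills data.frame from [fill_windows()] (or NULL).
#' @param vip character vector of VIP SNP ids (or NULL).
#' @return data.frame of class `array_design` with columns `id`, `chrom`,
#'   `pos`, `reason`.
#' @export
array_design <- function(m, tags, fills = NULL, vip = NULL) {
  sel <- data.frame(id = tags,
                    reason = rep("tag", length(tags)),
                    stringsAsFactors = FALSE)
  if (!is.null(fills) && nrow(fills)) sel <- rbind(sel, fills)
  if (!is.null(vip) && length(vip)) {
    unknown <- setdiff(vip, m$variants$id)
    if (length(unknown))
      warning("skipping unknown VIP id(s): ", paste(unknown, collapse = ", "))
    sel <- rbind(sel, data.frame(id = setdiff(vip, unknown), reason = "vip",
                                 stringsAsFactors = FALSE))
  }
  sel <- sel[!duplicated(sel$id), , drop = FALSE]
  i <- match(sel$id, m$variants$id)
  if (anyNA(i)) stop("unknown SNP id(s) in selection")
  out <- data.frame(id = sel$id, chrom = m$variants$chrom[i],
                    pos = m$variants$pos[i], reason = sel$reason,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("array_design", "data.frame")
  out
}

#' @rdname array_design
#' @param set an existing `array_design`.
#' @export
merge_vip <- function(set, vip, m) {
  unknown <- setdiff(vip, m$variants$id)
  if (length(unknown))
    warning("skipping unknown VIP id(s): ", paste(unknown, collapse = ", "))
  new <- setdiff(setdiff(vip, unknown), set$id)
  if (!length(new)) return(set)
  i <- match(new, m$variants$id)
  out <- rbind(as.data.frame(set),
               data.frame(id = new, chrom = m$variants$chrom[i],
                          pos = m$variants$pos[i], reason = "vip",
                          stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("array_design", "data.frame")
  out
}

#' Array design summary metrics
#'
#' Genome-coverage metrics of a selected SNP set: mean inter-SNP spacing
#' defined as total chromosome bp divided by the number of
#' chromosome-mapped SNPs; the fraction of consecutive-SNP gaps (within a
#' chromosome) below `spacing_threshold`; per-chromosome counts; genomic
#' context class counts/fractions; pericentromeric versus arm counts (when
#' the layout carries pericentromeric intervals); and the number of genes
#' containing at least one selected SNP.
#'
#' @param design an `array_design` data.frame (or any data.frame with `id`,
#'   `chrom`, `pos`).
#' @param layout a [genome_layout()].
#' @param genes optional [gene_set()].
#' @param m optional [genotype_matrix()] restricted context classification
#'   source; when given with `genes`, per-class counts use
#'   [classify_snp_context()].
#' @param spacing_threshold gap threshold in bp (default 9 kb).
#' @return list of summary metrics.
#' @export
design_summary <- function(design, layout, genes = NULL, m = NULL,
                           spacing_threshold = 9000) {
  stopifnot(nrow(design) >= 1L)
  mapped <- design[design$chrom %in% layout$chromosomes$chrom, , drop = FALSE]
  tot_bp <- genome_length(layout)
  gaps <- unlist(lapply(split(mapped$pos, mapped$chrom),
                        function(p) diff(sort(p))), use.names = FALSE)
  out <- list(
    n_selected = nrow(design),
    n_mapped = nrow(mapped),
    mean_spacing = if (nrow(mapped) > 0) tot_bp / nrow(mapped) else NA_real_,
    frac_gaps_below = if (length(gaps)) mean(gaps < spacing_threshold)
                      else NA_real_,
    per_chromosome = table(factor(mapped$chrom,
                                  levels = layout$chromosomes$chrom)))
  if (!is.null(genes) && !is.null(m)) {
    keep <- match(design$id, m$variants$id)
    if (anyNA(keep)) stop("design contains ids absent from the genotype matrix")
    ctx <- classify_snp_context(subset_genotypes(m, variants = keep), genes)
    out$context_counts <- table(factor(
      ctx, levels = c("CDS", "UTR5", "UTR3", "intron", "genic-other",
                      "intergenic")))
    out$context_fractions <- 100 * out$context_counts / length(ctx)
    out$n_genic <- sum(ctx != "intergenic")
    # genes covered by >= 1 selected SNP
    snp <- GenomicRanges::GRanges(design$chrom,
                                  IRanges::IRanges(design$pos, design$pos))
    gg <- GenomicRanges::GRanges(
      genes$genes$chrom,
      IRanges::IRanges(genes$genes$start + 1, genes$genes$end))
    hit <- GenomicRanges::findOverlaps(gg, snp)
    out$genes_covered <- length(unique(S4Vectors::queryHits(hit)))
  }
  peri <- layout$pericentromeric
  if (!is.null(peri) && nrow(mapped)) {
    pg <- GenomicRanges::GRanges(peri$chrom,
                                 IRanges::IRanges(peri$start + 1, peri$end))
    snp <- GenomicRanges::GRanges(mapped$chrom,
                                  IRanges::IRanges(mapped$pos, mapped$pos))
    inperi <- GenomicRanges::countOverlaps(snp, pg) > 0
    out$n_pericentromeric <- sum(inperi)
    out$n_arm <- sum(!inperi)
  }
  out
}
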