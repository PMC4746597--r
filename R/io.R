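#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (the GT FORMAT field is required), drops
#' multi-allelic and non-SNP records with a message reporting the dropped
#' count, and returns dosages of the alternate allele.  Heterozygous calls of
#' either phase count 1; any genotype containing `.` is missing.
#'
#' @param path path to an (optionally compressed) VCF file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  nalt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(ref))
  alt[nalt == 1L] <- as.character(unlist(altl[nalt == 1L]))
  keep <- nalt == 1L & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("read_genotypes: dropped %d multi-allelic/non-SNP record(s)",
                    dropped))
  if (!any(keep)) stop("no biallelic SNPs retained from ", path)
  gt <- gt[keep, , drop = FALSE]
  dos <- gt_to_dosage(gt)
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    id = rownames(gt),
    ref = ref[keep], alt = alt[keep],
    stringsAsFactors = FALSE)
  genotype_matrix(variants, colnames(gt), dos)
}

# GT strings -> alt-allele dosage (NA on any '.')
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".") || length(a) == 0L) return(NA_integer_)
    if (!all(a %in% c("0", "1"))) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  out <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF 4.2 with the GT field only; `read_genotypes()` on the
#' result recovers the same dosages (round-trip identity).
#'
#' @param m a [genotype_matrix()].
#' @param path output path.
#' @param layout optional [genome_layout()] used for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(m, path, layout = NULL) {
  chroms <- unique(m$variants$chrom)
  lens <- if (!is.null(layout)) {
    setNames(layout$chromosomes$length, layout$chromosomes$chrom)[chroms]
  } else {
    vapply(chroms, function(cc) max(m$variants$pos[m$variants$chrom == cc]),
           numeric(1))
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(lens)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", m$samples), collapse = "\t"))
  gtc <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(m$dosage), ncol = ncol(m$dosage))
  ok <- !is.na(m$dosage)
  gt[ok] <- gtc[m$dosage[ok] + 1L]
  body <- paste(m$variants$chrom, m$variants$pos, m$variants$id,
                m$variants$ref, m$variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` features and, when present, CDS / intron / five_prime_UTR /
#' three_prime_UTR children (attached through their `Parent` attribute,
#' following mRNA parents up to the gene).  GFF3 1-based closed coordinates
#' are converted to the package's internal 0-based half-open convention at
#' this boundary.
#'
#' @param path path to a GFF3 file.
#' @return A [gene_set()]; empty (with a warning) if the file has no genes.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  empty <- gene_set(data.frame(id = character(), chrom = character(),
                               start = integer(), end = integer(),
                               strand = character()))
  if (length(gr) == 0L) {
    warning("no features in ", path)
    return(empty)
  }
  typ <- as.character(gr$type)
  gi <- which(typ == "gene")
  if (!length(gi)) {
    warning("no gene features in ", path)
    return(empty)
  }
  gid <- as.character(gr$ID[gi])
  genes <- data.frame(
    id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr))[gi],
    start = GenomicRanges::start(gr)[gi] - 1L,   # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr)[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi],
    stringsAsFactors = FALSE)

  # map transcript ids to their gene so CDS parented by mRNA resolve
  parent1 <- function(x) vapply(x, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  tx <- which(typ %in% c("mRNA", "transcript"))
  tx2gene <- character(0)
  if (length(tx))
    tx2gene <- setNames(parent1(gr$Parent[tx]), as.character(gr$ID[tx]))

  fmap <- c(CDS = "CDS", intron = "intron",
            five_prime_UTR = "UTR5", three_prime_UTR = "UTR3")
  fi <- which(typ %in% names(fmap))
  features <- NULL
  if (length(fi)) {
    par <- parent1(gr$Parent[fi])
    gene_of <- ifelse(par %in% genes$id, par, unname(tx2gene[par]))
    ok <- !is.na(gene_of) & gene_of %in% genes$id
    if (any(ok)) {
      fi <- fi[ok]
      features <- data.frame(
        gene_id = gene_of[ok],
        type = unname(fmap[typ[fi]]),
        chrom = as.character(GenomicRanges::seqnames(gr))[fi],
        start = GenomicRanges::start(gr)[fi] - 1L,
        end = GenomicRanges::end(gr)[fi],
        stringsAsFactors = FALSE)
    }
  }
  gene_set(genes, features)
}

#' Classify the genomic context of each SNP
#'
#' Assigns exactly one label per SNP from `{CDS, UTR5, UTR3, intron,
#' genic-other, intergenic}`.  Where annotations overlap, precedence is
#' CDS > UTR5 > UTR3 > intron > genic-other.  SNPs on chromosomes absent
#' from the gene set are intergenic (with a warning).
#'
#' @param m a [genotype_matrix()].
#' @param g a [gene_set()].
#' @return Character vector, one label per SNP, in variant order.
#' @export
classify_snp_context <- function(m, g) {
  v <- m$variants
  lab <- rep("intergenic", nrow(v))
  if (!nrow(g$genes)) return(lab)
  if (length(setdiff(unique(v$chrom), unique(g$genes$chrom))))
    warning("some SNP chromosomes have no annotated genes; classified intergenic")
  snp <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  paint <- function(lab, df, value) {
    if (is.null(df) || !nrow(df)) return(lab)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end))
    hit <- suppressWarnings(GenomicRanges::findOverlaps(snp, gr))
    lab[unique(S4Vectors::queryHits(hit))] <- value
    lab
  }
  # ascending precedence: later assignments overwrite earlier ones
  lab <- paint(lab, g$genes, "genic-other")
  f <- g$features
  if (!is.null(f) && nrow(f)) {
    for (ty in c("intron", "UTR3", "UTR5", "CDS"))
      lab <- paint(lab, f[f$type == ty, , drop = FALSE], ty)
  }
  lab
}

#' Write / read a window statistics table as BED-compatible TSV
#'
#' The first three columns are `chrom`, `start`, `end` on the BED convention
#' (0-based half-open), followed by the statistics columns; a header line is
#' always written, so `read_windows()` round-trips the table.
#'
#' @param t a window statistics data.frame (e.g. from [window_stats()]).
#' @param path output path.
#' @return `path` (write) or the table (read), invisibly for write.
#' @export
write_windows <- function(t, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(t)))
  first <- c("chrom", "start", "end")
  t <- t[c(first, setdiff(names(t), first))]
  write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write regions to a BED file
#'
#' @param r data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally further columns (written as BED name/score columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(r, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(r)))
  extra <- setdiff(names(r), c("chrom", "start", "end"))
  extra <- extra[!vapply(r[extra], is.list, logical(1))]
  out <- r[c("chrom", "start", "end", extra)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree as Newick text
#'
#' @param tree an [ape::phylo] object or a Newick string.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  if (inherits(tree, "phylo")) ape::write.tree(tree, file = path)
  else writeLines(as.character(tree), path)
  invisible(path)
}
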