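#' SNP genotype matrix
#'
#' Container for biallelic SNP dosages (counts of the alternate allele,
#' 0/1/2, `NA` for missing) over `variants x samples`, with 1-based genomic
#' coordinates.  Variants are stored sorted by `(chrom, pos)` and must be
#' unique biallelic SNPs.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt` (single-base alleles).
#' @param samples character vector of sample labels.
#' @param dosage integer matrix, `nrow(variants)` x `length(samples)`, values
#'   in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `variants`, `samples` and `dosage`.
#' @export
genotype_matrix <- function(variants, samples, dosage) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  variants$chrom <- as.character(variants$chrom)
  variants$id <- as.character(variants$id)
  samples <- as.character(samples)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(variants) || ncol(dosage) != length(samples))
    stop("dosage must be variants x samples")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosage values must be 0, 1, 2 or NA")
  nref <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L
  if (any(nref)) stop("all records must be biallelic SNPs (1-bp ref and alt)")
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  dosage <- dosage[o, , drop = FALSE]
  if (anyDuplicated(variants[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) records")
  rownames(variants) <- NULL
  dimnames(dosage) <- list(variants$id, samples)
  structure(list(variants = variants, samples = samples, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d SNPs x %d samples on %d chromosome(s)\n",
              nrow(x$variants), length(x$samples),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param m a `genotype_matrix`.
#' @export
n_variants <- function(m) nrow(m$variants)

#' @rdname genotype_matrix
#' @export
n_samples <- function(m) length(m$samples)

#' Subset a genotype matrix by samples or variants
#'
#' @param m a [genotype_matrix()].
#' @param samples sample labels or indices to keep.
#' @param variants logical/integer index over variants to keep.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(m, samples = NULL, variants = NULL) {
  v <- m$variants; d <- m$dosage; s <- m$samples
  if (!is.null(variants)) {
    v <- v[variants, , drop = FALSE]
    d <- d[variants, , drop = FALSE]
  }
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, s) else samples
    if (anyNA(idx)) stop("unknown sample label(s)")
    s <- s[idx]
    d <- d[, idx, drop = FALSE]
  }
  genotype_matrix(v, s, d)
}

# resolve a sample subset specification into column indices
sample_index <- function(m, subset) {
  if (is.null(subset)) return(seq_along(m$samples))
  idx <- if (is.character(subset)) match(subset, m$samples)
         else if (is.logical(subset)) which(subset)
         else as.integer(subset)
  if (length(idx) == 0L) stop("empty sample subset")
  if (anyNA(idx) || any(idx < 1L | idx > length(m$samples)))
    stop("sample subset refers to unknown samples")
  idx
}

#' Sample metadata table
#'
#' Validates a per-sample metadata table: `population` is `wild` or
#' `cultivated`; `evolution_type` is `wild`, `landrace`, `improved` or
#' `unknown` (wild population implies wild evolution type); `eco_region` is
#' `NR`, `HR`, `SR` or `unknown`.
#'
#' @param df data.frame with columns `sample`, `population`, and optionally
#'   `evolution_type` and `eco_region` (defaulted to `"unknown"`).
#' @return The validated data.frame with class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  stopifnot(is.data.frame(df), all(c("sample", "population") %in% names(df)))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicate sample labels in metadata")
  if (is.null(df$evolution_type)) df$evolution_type <- "unknown"
  if (is.null(df$eco_region)) df$eco_region <- "unknown"
  if (!all(df$population %in% c("wild", "cultivated")))
    stop("population must be 'wild' or 'cultivated'")
  if (!all(df$evolution_type %in% c("wild", "landrace", "improved", "unknown")))
    stop("invalid evolution_type")
  if (!all(df$eco_region %in% c("NR", "HR", "SR", "unknown")))
    stop("invalid eco_region")
  if (any(df$population == "wild" & df$evolution_type != "wild"))
    stop("population = wild implies evolution_type = wild")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from a TSV file
#'
#' @param path TSV file with header columns `sample`, `population`,
#'   `evolution_type`, `eco_region`.
#' @return A [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path) {
  sample_metadata(read.delim(path, stringsAsFactors = FALSE))
}

# population -> sample-column indices of m, checked against metadata
pop_index <- function(m, meta, population) {
  stopifnot(population %in% c("wild", "cultivated"))
  labs <- meta$sample[meta$population == population]
  idx <- match(intersect(labs, m$samples), m$samples)
  if (length(idx) == 0L) stop(sprintf("no %s samples present", population))
  idx
}

#' Genome layout
#'
#' Chromosome lengths plus optional pericentromeric intervals (0-based
#' half-open, non-overlapping per chromosome and within bounds).
#'
#' @param chromosomes data.frame with columns `chrom`, `length` (bp).
#' @param pericentromeric optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, pericentromeric = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicate chromosome labels")
  if (!is.null(pericentromeric)) {
    p <- pericentromeric
    stopifnot(all(c("chrom", "start", "end") %in% names(p)))
    p$chrom <- as.character(p$chrom)
    len <- setNames(chromosomes$length, chromosomes$chrom)
    if (any(!p$chrom %in% names(len))) stop("pericentromeric interval on unknown chromosome")
    if (any(p$start < 0 | p$end > len[p$chrom] | p$start >= p$end))
      stop("pericentromeric intervals out of chromosome bounds")
    for (cc in unique(p$chrom)) {
      q <- p[p$chrom == cc, ]
      q <- q[order(q$start), ]
      if (nrow(q) > 1 && any(q$start[-1] < q$end[-nrow(q)]))
        stop("pericentromeric intervals overlap")
    }
    pericentromeric <- p
  }
  structure(list(chromosomes = chromosomes, pericentromeric = pericentromeric),
            class = "genome_layout")
}

#' Total genome length of a layout
#' @param layout a [genome_layout()].
#' @return Total length in bp.
#' @export
genome_length <- function(layout) sum(as.numeric(layout$chromosomes$length))

#' Gene set
#'
#' Gene spans and optional sub-features, all on internal 0-based half-open
#' coordinates.
#'
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open, `start < end`, unique ids).
#' @param features optional data.frame with columns `gene_id`, `type` (one of
#'   `CDS`, `intron`, `UTR5`, `UTR3`), `chrom`, `start`, `end`; each feature
#'   must lie within its gene's span.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes, features = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("id", "chrom", "start", "end") %in% names(genes)))
  genes$id <- as.character(genes$id)
  genes$chrom <- as.character(genes$chrom)
  if (is.null(genes$strand)) genes$strand <- "*"
  if (anyDuplicated(genes$id)) stop("duplicate gene ids")
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  if (!is.null(features) && nrow(features)) {
    stopifnot(all(c("gene_id", "type", "start", "end") %in% names(features)))
    features$gene_id <- as.character(features$gene_id)
    if (!all(features$type %in% c("CDS", "intron", "UTR5", "UTR3")))
      stop("feature type must be CDS, intron, UTR5 or UTR3")
    i <- match(features$gene_id, genes$id)
    if (anyNA(i)) stop("feature refers to unknown gene id")
    features$chrom <- genes$chrom[i]
    if (any(features$start < genes$start[i] | features$end > genes$end[i]))
      stop("sub-feature outside gene span")
  }
  structure(list(genes = genes, features = features), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %d genes, %d sub-features\n", nrow(x$genes),
              if (is.null(x$features)) 0L else nrow(x$features)))
  invisible(x)
}

#' Phenotype table
#'
#' Validates rows of `(sample, environment, replicate, hundred_seed_weight)`;
#' weights must be positive and `(sample, environment, replicate)` unique.
#'
#' @param df data.frame with the four columns above.
#' @return The validated data.frame with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("sample", "environment", "replicate", "hundred_seed_weight")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df$sample <- as.character(df$sample)
  df$environment <- as.character(df$environment)
  if (any(!is.finite(df$hundred_seed_weight)) ||
      any(df$hundred_seed_weight <= 0))
    stop("hundred_seed_weight must be positive")
  if (anyDuplicated(df[c("sample", "environment", "replicate")]))
    stop("(sample, environment, replicate) must be unique")
  class(df) <- c("phenotype_table", "data.frame")
  df
}
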