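#' Construct a genotype dataset
#'
#' The central container of the package: a samples x markers matrix of
#' diploid genotype codes together with a marker map and per-sample
#' population labels.  Genotypes are coded as the count of `allele_b`
#' copies: 0 = homozygous `allele_a`, 1 = heterozygous, 2 = homozygous
#' `allele_b`, `NA` = missing.
#'
#' @param geno integer matrix, samples in rows, markers in columns,
#'   values in \{0, 1, 2, NA\}.
#' @param map data frame with columns `marker_id`, `chrom` (integer
#'   autosome number), `pos_bp` (1-based base-pair position), and
#'   optionally `cm`, `allele_a`, `allele_b`.
#' @param samples data frame with columns `sample_id` and `population`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, map, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(map$cm)) map$cm <- 0
  if (is.null(map$allele_a)) map$allele_a <- NA_character_
  if (is.null(map$allele_b)) map$allele_b <- NA_character_
  map$chrom <- as.integer(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  # canonical marker order: by chromosome, then position
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rownames(map) <- NULL
  rownames(samples) <- NULL
  dimnames(geno) <- list(samples$sample_id, map$marker_id)
  ds <- structure(list(geno = geno, map = map, samples = samples),
                  class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

validate_genotype_dataset <- function(ds) {
  geno <- ds$geno; map <- ds$map; samples <- ds$samples
  if (nrow(geno) != nrow(samples))
    stop("genotype matrix has ", nrow(geno), " rows but ", nrow(samples),
         " samples")
  if (ncol(geno) != nrow(map))
    stop("genotype matrix has ", ncol(geno), " columns but ", nrow(map),
         " markers")
  bad <- geno[!is.na(geno)]
  if (length(bad) && any(bad < 0L | bad > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(map$marker_id))
    stop("duplicated marker ids in map")
  if (any(is.na(map$chrom)) || any(map$chrom < 1L))
    stop("chromosome codes must be positive integers")
  if (any(is.na(map$pos_bp)) || any(map$pos_bp < 1))
    stop("positions must be >= 1")
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  pops <- table(x$samples$population)
  cat("genotype_dataset: ", nrow(x$geno), " samples x ", ncol(x$geno),
      " markers on ", length(unique(x$map$chrom)), " chromosomes\n", sep = "")
  cat("populations:", paste(names(pops), pops, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Number of samples / markers in a dataset
#' @param ds a `genotype_dataset`.
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$geno)

#' @rdname n_samples
#' @export
n_markers <- function(ds) ncol(ds$geno)

#' Subset a dataset by marker
#'
#' @param ds a `genotype_dataset`.
#' @param keep logical vector or integer indices over markers.
#' @return A `genotype_dataset` restricted to the kept markers.
#' @export
subset_markers <- function(ds, keep) {
  genotype_dataset(ds$geno[, keep, drop = FALSE],
                   ds$map[keep, , drop = FALSE],
                   ds$samples)
}

#' Subset a dataset by sample
#' @param ds a `genotype_dataset`.
#' @param keep logical vector or integer indices over samples.
#' @return A `genotype_dataset` restricted to the kept samples.
#' @export
subset_samples <- function(ds, keep) {
  genotype_dataset(ds$geno[keep, , drop = FALSE], ds$map,
                   ds$samples[keep, , drop = FALSE])
}

#' Per-marker minor allele frequency
#'
#' Computed over non-missing genotypes; `NaN` for fully missing markers.
#'
#' @param ds a `genotype_dataset`.
#' @return Numeric vector of MAF, one per marker.
#' @export
marker_maf <- function(ds) {
  p <- colMeans(ds$geno, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-marker genotype counts
#'
#' @param ds a `genotype_dataset`.
#' @return Integer matrix with rows `n_aa`, `n_ab`, `n_bb` (counts of the
#'   three genotype codes) and one column per marker.
#' @export
genotype_counts <- function(ds) {
  g <- ds$geno
  rbind(n_aa = colSums(g == 0L, na.rm = TRUE),
        n_ab = colSums(g == 1L, na.rm = TRUE),
        n_bb = colSums(g == 2L, na.rm = TRUE))
}

# deep equality used by round-trip tests
#' Compare two genotype datasets
#' @param a,b `genotype_dataset` objects.
#' @return TRUE if samples, map (id/chrom/pos/alleles) and genotypes agree.
#' @export
datasets_equal <- function(a, b) {
  isTRUE(all.equal(a$samples$sample_id, b$samples$sample_id)) &&
    isTRUE(all.equal(a$samples$population, b$samples$population)) &&
    isTRUE(all.equal(a$map$marker_id, b$map$marker_id)) &&
    isTRUE(all.equal(a$map$chrom, b$map$chrom)) &&
    isTRUE(all.equal(a$map$pos_bp, b$map$pos_bp)) &&
    identical(is.na(a$geno), is.na(b$geno)) &&
    all(a$geno == b$geno, na.rm = TRUE)
}
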