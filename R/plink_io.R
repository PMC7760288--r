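#' Read PLINK text-format genotypes (PED/MAP)
#'
#' PED rows carry six metadata columns (family, individual, father,
#' mother, sex, phenotype) followed by two allele columns per marker;
#' the family-ID column is stored as the population label.  MAP rows are
#' `chrom id cm bp`.  Genotype codes are assigned with `allele_a` equal
#' to the first allele observed for the marker (for a heterozygous first
#' observation the tie is broken lexicographically); `0 0` denotes a
#' missing genotype.  Only autosomes 1-29 are retained; markers on other
#' chromosome codes are dropped with a warning.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @param max_chrom highest autosome number retained (default 29, the
#'   bovine autosome count).
#' @return A [genotype_dataset()].
#' @export
read_plink_text <- function(ped_path, map_path, max_chrom = 29L) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  mf <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(mf)
  if (any(nf < 4L))
    stop("MAP format error: line ", which(nf < 4L)[1L],
         " has fewer than 4 fields")
  map <- data.frame(
    chrom = suppressWarnings(as.integer(vapply(mf, `[`, "", 1L))),
    marker_id = vapply(mf, `[`, "", 2L),
    cm = suppressWarnings(as.numeric(vapply(mf, `[`, "", 3L))),
    pos_bp = suppressWarnings(as.numeric(vapply(mf, `[`, "", 4L))),
    stringsAsFactors = FALSE)
  if (anyNA(map$pos_bp))
    stop("MAP format error: non-numeric position at line ",
         which(is.na(map$pos_bp))[1L])
  if (anyNA(map$chrom))
    stop("MAP format error: non-numeric chromosome at line ",
         which(is.na(map$chrom))[1L])
  n_map <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  pf <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * n_map
  nf <- lengths(pf)
  if (any(nf != want))
    stop("PED format error: line ", which(nf != want)[1L], " has ",
         nf[nf != want][1L], " fields, expected ", want,
         " (6 + 2 x ", n_map, " markers)")
  n_ind <- length(pf)

  samples <- data.frame(
    sample_id = vapply(pf, `[`, "", 2L),
    population = vapply(pf, `[`, "", 1L),
    stringsAsFactors = FALSE)

  keep <- map$chrom >= 1L & map$chrom <= max_chrom
  if (!all(keep))
    warning(sum(!keep), " marker(s) on chromosomes outside 1-", max_chrom,
            " dropped")

  if (n_ind == 0L) {
    map <- map[keep, , drop = FALSE]
    return(genotype_dataset(
      matrix(integer(0), 0L, nrow(map)), map, samples))
  }

  al <- matrix(unlist(pf, use.names = FALSE), nrow = n_ind, byrow = TRUE)
  al <- al[, -(1:6), drop = FALSE]
  a1 <- al[, seq(1L, 2L * n_map, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * n_map, by = 2L), drop = FALSE]

  geno <- matrix(NA_integer_, n_ind, n_map)
  allele_a <- rep(NA_character_, n_map)
  allele_b <- rep(NA_character_, n_map)
  for (j in seq_len(n_map)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- unique(c(x1[!miss], x2[!miss]))
    if (length(obs) > 2L)
      stop("PED format error: marker ", map$marker_id[j],
           " has more than two alleles: ", paste(obs, collapse = "/"))
    if (length(obs) == 0L) next
    i0 <- which(!miss)[1L]
    if (x1[i0] == x2[i0]) {
      aa <- x1[i0]
    } else {
      aa <- min(x1[i0], x2[i0])   # het first: lexicographic tie-break
    }
    ab <- setdiff(obs, aa)
    allele_a[j] <- aa
    allele_b[j] <- if (length(ab)) ab else NA_character_
    g <- (x1 != aa) + (x2 != aa)
    g[miss] <- NA_integer_
    geno[, j] <- as.integer(g)
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b

  genotype_dataset(geno[, keep, drop = FALSE], map[keep, , drop = FALSE],
                   samples)
}

#' Write a dataset as PLINK text PED/MAP
#'
#' Missing genotypes are written as `0 0`; the population label goes to
#' the family-ID column.  The output round-trips exactly through
#' [read_plink_text()].
#'
#' @param ds a [genotype_dataset()].
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map`
#'   are written.
#' @return Invisibly, the two file paths.
#' @export
write_plink_text <- function(ds, prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  m <- ds$map
  writeLines(paste(m$chrom, m$marker_id, m$cm, format(m$pos_bp, scientific = FALSE, trim = TRUE),
                   sep = "\t"), map_path)
  n_map <- nrow(m)
  aa <- m$allele_a; ab <- m$allele_b
  aa[is.na(aa)] <- "A"                      # dataset never observed an allele
  ab[is.na(ab)] <- aa[is.na(ab)]            # monomorphic: code 2 impossible
  lines <- character(nrow(ds$geno))
  for (i in seq_len(nrow(ds$geno))) {
    g <- ds$geno[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2L, ab, aa))
    x2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, ab, aa))
    lines[i] <- paste(ds$samples$population[i], ds$samples$sample_id[i],
                      0, 0, 0, -9,
                      paste(x1, x2, collapse = " "))
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK binary genotypes (BED/BIM/FAM)
#'
#' Supports the SNP-major layout (magic bytes `0x6c 0x1b 0x01`).  BIM
#' allele 1 maps to `allele_a` (code 0 = homozygous allele 1).
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` are read.
#' @param max_chrom highest autosome retained.
#' @return A [genotype_dataset()].
#' @export
read_plink_bed <- function(prefix, max_chrom = 29L) {
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "marker_id", "cm", "pos_bp", "a1", "a2")
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = as.character(fam[[2L]]),
                        population = as.character(fam[[1L]]),
                        stringsAsFactors = FALSE)
  n_ind <- nrow(fam); n_map <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + ceiling(n_ind / 4) * n_map)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes)")
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major BED files are supported")
  body <- raw[-(1:3)]
  bpm <- ceiling(n_ind / 4)
  # 2-bit codes per individual: 00 hom a1, 10 het, 11 hom a2, 01 missing
  lut <- matrix(NA_integer_, 4L, 256L)
  for (byte in 0:255) {
    for (k in 0:3) {
      two <- bitwAnd(bitwShiftR(byte, 2L * k), 3L)
      lut[k + 1L, byte + 1L] <-
        c(0L, NA_integer_, 1L, 2L)[two + 1L]
    }
  }
  geno <- matrix(NA_integer_, n_ind, n_map)
  for (j in seq_len(n_map)) {
    bytes <- as.integer(body[((j - 1L) * bpm + 1L):(j * bpm)])
    codes <- lut[, bytes + 1L]
    geno[, j] <- codes[seq_len(n_ind)]
  }
  map <- data.frame(marker_id = as.character(bim$marker_id),
                    chrom = as.integer(bim$chrom),
                    pos_bp = as.numeric(bim$pos_bp),
                    cm = as.numeric(bim$cm),
                    allele_a = as.character(bim$a1),
                    allele_b = as.character(bim$a2),
                    stringsAsFactors = FALSE)
  keep <- map$chrom >= 1L & map$chrom <= max_chrom
  if (!all(keep))
    warning(sum(!keep), " marker(s) on chromosomes outside 1-", max_chrom,
            " dropped")
  genotype_dataset(geno[, keep, drop = FALSE], map[keep, , drop = FALSE],
                   samples)
}

#' Merge genotype datasets across populations
#'
#' Markers are intersected by id; samples are concatenated with their
#' population labels preserved.  When the allele orientation of a marker
#' is swapped between datasets (allele_a/allele_b exchanged) the
#' genotype codes of the later dataset are flipped (0 <-> 2).  Alleles
#' that cannot be reconciled (e.g. A/G vs A/C) raise an error listing
#' the offending marker ids.
#'
#' @param ... two or more [genotype_dataset()] objects, or a single list
#'   of them.
#' @return A merged [genotype_dataset()].
#' @export
merge_populations <- function(...) {
  dsl <- list(...)
  if (length(dsl) == 1L && !inherits(dsl[[1L]], "genotype_dataset"))
    dsl <- dsl[[1L]]
  if (length(dsl) < 2L) stop("need at least two datasets to merge")
  ids <- Reduce(intersect, lapply(dsl, function(d) d$map$marker_id))
  if (length(ids) == 0L) stop("no markers shared between datasets")
  ref <- dsl[[1L]]
  ridx <- match(ids, ref$map$marker_id)
  map <- ref$map[ridx, , drop = FALSE]
  genos <- vector("list", length(dsl))
  genos[[1L]] <- ref$geno[, ridx, drop = FALSE]
  bad <- character(0)
  for (k in 2:length(dsl)) {
    d <- dsl[[k]]
    j <- match(ids, d$map$marker_id)
    g <- d$geno[, j, drop = FALSE]
    aa <- d$map$allele_a[j]; ab <- d$map$allele_b[j]
    same <- (is.na(aa) | is.na(map$allele_a) | aa == map$allele_a) &
            (is.na(ab) | is.na(map$allele_b) | ab == map$allele_b)
    swap <- (!is.na(aa) & !is.na(map$allele_b) & aa == map$allele_b) |
            (!is.na(ab) & !is.na(map$allele_a) & ab == map$allele_a)
    # a monomorphic marker matching the reference minor allele: flip too
    flip <- !same & swap
    incomp <- !same & !swap
    if (any(incomp)) bad <- union(bad, ids[incomp])
    if (any(flip)) g[, flip] <- 2L - g[, flip, drop = FALSE]
    genos[[k]] <- g
  }
  if (length(bad))
    stop("incompatible alleles at merged marker(s): ",
         paste(sort(bad), collapse = ", "))
  # fill allele info missing in the reference from later datasets
  for (k in 2:length(dsl)) {
    j <- match(ids, dsl[[k]]$map$marker_id)
    fill <- is.na(map$allele_b) & !is.na(dsl[[k]]$map$allele_b[j]) &
      (is.na(dsl[[k]]$map$allele_a[j]) | is.na(map$allele_a) |
         dsl[[k]]$map$allele_a[j] == map$allele_a)
    map$allele_b[fill] <- dsl[[k]]$map$allele_b[j][fill]
  }
  samples <- do.call(rbind, lapply(dsl, `[[`, "samples"))
  genotype_dataset(do.call(rbind, genos), map, samples)
}
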