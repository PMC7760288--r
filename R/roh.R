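#' Sliding-window ROH detection parameters
#'
#' Defaults follow the standard PLINK-style parameterization for a
#' medium-density (50K) bovine array: 20-SNP windows allowing at most
#' one heterozygous and one missing call, a per-SNP window support
#' threshold of 0.05, minimum run length 4 Mb, minimum 20 SNPs per run,
#' minimum density 1 SNP / 100 kb and maximum inter-SNP gap 1 Mb.
#'
#' @param window_snps SNPs per sliding window.
#' @param max_het_per_window maximum heterozygous calls tolerated per window.
#' @param max_miss_per_window maximum missing calls tolerated per window.
#' @param window_threshold minimum fraction of spanning windows that must
#'   be homozygous-compatible for a SNP to support a run.
#' @param min_length_bp minimum run length in base pairs.
#' @param min_snps_in_run minimum number of SNPs in a run.
#' @param min_density_bp maximum base pairs per SNP inside a run
#'   (100000 means at least 1 SNP per 100 kb).
#' @param max_gap_bp maximum gap between consecutive SNPs inside a run.
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(window_snps = 20L, max_het_per_window = 1L,
                       max_miss_per_window = 1L, window_threshold = 0.05,
                       min_length_bp = 4e6, min_snps_in_run = 20L,
                       min_density_bp = 1e5, max_gap_bp = 1e6) {
  p <- list(window_snps = as.integer(window_snps),
            max_het_per_window = as.integer(max_het_per_window),
            max_miss_per_window = as.integer(max_miss_per_window),
            window_threshold = window_threshold,
            min_length_bp = min_length_bp,
            min_snps_in_run = as.integer(min_snps_in_run),
            min_density_bp = min_density_bp,
            max_gap_bp = max_gap_bp)
  if (p$window_snps < 1L || p$min_snps_in_run < 1L ||
      p$min_length_bp <= 0 || p$min_density_bp <= 0 || p$max_gap_bp <= 0 ||
      p$max_het_per_window < 0L || p$max_miss_per_window < 0L)
    stop("ROH parameters must be positive")
  if (p$window_threshold <= 0 || p$window_threshold > 1)
    stop("window_threshold must lie in (0, 1]")
  structure(p, class = "roh_params")
}

#' Per-SNP window support fractions
#'
#' For each SNP on one chromosome, the fraction of `window_snps`-sized
#' windows containing it that hold at most `max_het_per_window`
#' heterozygous and `max_miss_per_window` missing calls.  SNPs near the
#' chromosome ends are spanned by fewer windows.
#'
#' @param geno_row integer genotype codes for one sample on one
#'   chromosome (0/1/2/NA), in map order.
#' @param pos_bp marker positions, strictly increasing.
#' @param params an [roh_params()] object.
#' @return Numeric vector of support fractions, one per SNP, or `NULL`
#'   (with a warning) when the chromosome holds fewer SNPs than one
#'   window.
#' @export
scan_windows <- function(geno_row, pos_bp, params = roh_params()) {
  S <- length(geno_row)
  if (is.unsorted(pos_bp, strictly = TRUE))
    stop("internal error: positions must be strictly increasing")
  w <- params$window_snps
  if (S < w) {
    warning("chromosome with ", S, " SNPs (< window of ", w, ") skipped")
    return(NULL)
  }
  het <- cumsum(geno_row == 1L & !is.na(geno_row))
  mis <- cumsum(is.na(geno_row))
  W <- S - w + 1L
  i <- seq_len(W)
  ok <- (het[i + w - 1L] - c(0, het)[i]) <= params$max_het_per_window &
        (mis[i + w - 1L] - c(0, mis)[i]) <= params$max_miss_per_window
  cok <- cumsum(ok)
  j <- seq_len(S)
  lo <- pmax(1L, j - w + 1L)       # first window index containing SNP j
  hi <- pmin(j, W)                 # last window index containing SNP j
  unname((cok[hi] - c(0, cok)[lo]) / (hi - lo + 1L))
}

# run calling on one sample x chromosome; returns a data.frame of runs
call_runs_one <- function(frac, pos_bp, params) {
  cand <- frac >= params$window_threshold
  out <- list()
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    # split the candidate stretch wherever the inter-SNP gap is too large
    cut <- which(diff(pos_bp[a:b]) > params$max_gap_bp)
    seg_start <- a + c(0L, cut)
    seg_end <- c(a + cut - 1L, b)
    for (s in seq_along(seg_start)) {
      i0 <- seg_start[s]; i1 <- seg_end[s]
      len <- pos_bp[i1] - pos_bp[i0] + 1
      nsnp <- i1 - i0 + 1L
      if (len >= params$min_length_bp && nsnp >= params$min_snps_in_run &&
          nsnp / len >= 1 / params$min_density_bp)
        out[[length(out) + 1L]] <-
          c(start_bp = unname(pos_bp[i0]), end_bp = unname(pos_bp[i1]),
            n_snps = unname(nsnp))
    }
  }
  if (!length(out)) return(NULL)
  as.data.frame(do.call(rbind, out))
}

#' Call runs of homozygosity
#'
#' PLINK-style sliding-window ROH detection: per sample and chromosome,
#' SNPs whose window support fraction (see [scan_windows()]) reaches
#' `window_threshold` are candidates; maximal consecutive candidate
#' stretches are split at gaps above `max_gap_bp` and retained when they
#' satisfy the length, SNP-count and density thresholds.  Heterozygous
#' SNPs may lie inside a retained run (window-governed definition).
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param params an [roh_params()] object.
#' @return An object of class `roh_set`: a data frame with one row per
#'   segment (`sample_id`, `population`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`, `size_class`) carrying the parameters and
#'   the sample table as attributes.
#' @export
call_roh <- function(ds, params = roh_params()) {
  segs <- list()
  chroms <- unique(ds$map$chrom)
  for (ch in chroms) {
    idx <- which(ds$map$chrom == ch)
    if (length(idx) < params$window_snps) {
      warning("chromosome ", ch, " has ", length(idx),
              " SNPs (< window of ", params$window_snps, "); skipped")
      next
    }
    pos <- ds$map$pos_bp[idx]
    for (i in seq_len(n_samples(ds))) {
      frac <- scan_windows(ds$geno[i, idx], pos, params)
      runs <- call_runs_one(frac, pos, params)
      if (is.null(runs)) next
      runs$sample_id <- ds$samples$sample_id[i]
      runs$population <- ds$samples$population[i]
      runs$chrom <- ch
      segs[[length(segs) + 1L]] <- runs
    }
  }
  if (length(segs)) {
    df <- do.call(rbind, segs)
    df$length_bp <- df$end_bp - df$start_bp + 1
    df <- df[, c("sample_id", "population", "chrom", "start_bp", "end_bp",
                 "n_snps", "length_bp")]
    df <- df[order(df$sample_id, df$chrom, df$start_bp), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(sample_id = character(0), population = character(0),
                     chrom = integer(0), start_bp = numeric(0),
                     end_bp = numeric(0), n_snps = integer(0),
                     length_bp = numeric(0))
  }
  out <- structure(df, class = c("roh_set", "data.frame"),
                   params = params, samples = ds$samples)
  classify_roh(out)
}

#' Label ROH segments with size classes
#'
#' Classes are left-closed, right-open on the length in Mb: with the
#' default breaks `(4, 8, 16)` a segment of exactly 16 Mb falls in the
#' `>16` class.
#'
#' @param roh_set an `roh_set` from [call_roh()].
#' @param breaks_mb increasing class boundaries in Mb.
#' @return The `roh_set` with a `size_class` factor column.
#' @export
classify_roh <- function(roh_set, breaks_mb = c(4, 8, 16)) {
  stopifnot(length(breaks_mb) >= 2L, !is.unsorted(breaks_mb, strictly = TRUE))
  nb <- length(breaks_mb)
  labels <- c(paste(breaks_mb[-nb], breaks_mb[-1L], sep = "-"),
              paste0(">", breaks_mb[nb]))
  mb <- roh_set$length_bp / 1e6
  if (nrow(roh_set) && any(mb < breaks_mb[1L]))
    stop("internal inconsistency: segment shorter than the first size class")
  roh_set$size_class <- cut(mb, c(breaks_mb, Inf), labels = labels,
                            right = FALSE)
  roh_set
}

#' Per-sample total ROH length (S_ROH)
#' @param roh_set an `roh_set`.
#' @return Named numeric vector of summed segment lengths in bp, one per
#'   sample in the originating dataset (zero for ROH-free samples).
#' @export
s_roh <- function(roh_set) {
  samples <- attr(roh_set, "samples")
  ids <- if (!is.null(samples)) samples$sample_id else
    unique(roh_set$sample_id)
  tot <- setNames(numeric(length(ids)), ids)
  if (nrow(roh_set)) {
    agg <- tapply(roh_set$length_bp, roh_set$sample_id, sum)
    tot[names(agg)] <- agg
  }
  tot
}

#' @export
print.roh_set <- function(x, ...) {
  cat("roh_set: ", nrow(x), " segments in ",
      length(unique(x$sample_id)), " samples\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Write an ROH set as tab-separated text
#' @param roh_set an `roh_set`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_roh_tsv <- function(roh_set, path) {
  write.table(as.data.frame(roh_set), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write ROH segments as BED (0-based half-open)
#' @param roh_set an `roh_set`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_roh_bed <- function(roh_set, path) {
  df <- data.frame(chrom = roh_set$chrom,
                   start = format(roh_set$start_bp - 1, scientific = FALSE,
                                  trim = TRUE),
                   end = format(roh_set$end_bp, scientific = FALSE,
                                trim = TRUE),
                   name = paste(roh_set$sample_id, roh_set$size_class,
                                sep = "_"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
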