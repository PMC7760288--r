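#' Construct genomic intervals
#'
#' Intervals are held 1-based inclusive internally; BED files (0-based
#' half-open) are converted on the way in and out.
#'
#' @param chrom integer chromosome numbers (1-29).
#' @param start_bp,end_bp 1-based inclusive coordinates, `start <= end`.
#' @param label optional interval names.
#' @return A `genomic_intervals` data frame.
#' @export
genomic_intervals <- function(chrom, start_bp, end_bp, label = NULL) {
  chrom <- as.integer(chrom)
  if (length(chrom) && (any(chrom < 1L) || any(chrom > 29L)))
    stop("chromosomes must lie in 1-29")
  if (any(start_bp > end_bp)) stop("interval start exceeds end")
  if (is.null(label))
    label <- if (length(chrom))
      paste0("region_", seq_along(chrom)) else character(0)
  structure(data.frame(chrom = chrom, start_bp = as.numeric(start_bp),
                       end_bp = as.numeric(end_bp),
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("genomic_intervals", "data.frame"))
}

#' Read a BED file of candidate regions
#'
#' Three or more whitespace-separated columns: chrom, start (0-based),
#' end (half-open), and optionally a name.  A leading `chr` prefix is
#' tolerated.
#'
#' @param path BED file path.
#' @return A [genomic_intervals()] object (1-based inclusive).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(genomic_intervals(integer(0), numeric(0), numeric(0)))
  f <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(f) < 3L))
    stop("BED format error: line ", which(lengths(f) < 3L)[1L],
         " has fewer than 3 fields")
  chrom <- suppressWarnings(as.integer(sub("^chr", "", vapply(f, `[`, "", 1L))))
  if (anyNA(chrom))
    stop("BED format error: non-numeric chromosome at line ",
         which(is.na(chrom))[1L])
  start0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0))
    stop("BED format error: non-numeric coordinate at line ",
         which(is.na(start0) | is.na(end0))[1L])
  bad <- start0 >= end0
  if (any(bad))
    stop("BED format error: start >= end at line ", which(bad)[1L])
  label <- vapply(seq_along(f), function(i)
    if (length(f[[i]]) >= 4L) f[[i]][4L] else paste0("region_", i), "")
  genomic_intervals(chrom, start0 + 1, end0, label)
}

#' Write intervals as BED (0-based half-open)
#' @param intervals a [genomic_intervals()] object.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$chrom,
                   start = format(intervals$start_bp - 1,
                                  scientific = FALSE, trim = TRUE),
                   end = format(intervals$end_bp, scientific = FALSE,
                                trim = TRUE),
                   name = intervals$label)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# overlap length of one interval with a set of segments (same chromosome
# assumed filtered by caller); vectorized over segments
.overlap_bp <- function(seg_start, seg_end, start, end) {
  pmax(0, pmin(seg_end, end) - pmax(seg_start, start) + 1)
}

#' Overlap ROH segments with candidate regions
#'
#' An ROH counts as overlapping when it shares at least
#' `min_overlap_bp` with one or more intervals, and is counted once no
#' matter how many intervals it touches.  The percentage is taken over
#' all ROH segments present in `roh_set` (the pooled total of its
#' populations).
#'
#' @param roh_set an `roh_set`.
#' @param intervals a [genomic_intervals()] object.
#' @param min_overlap_bp minimum shared length in bp (default 1).
#' @return An `overlap_report` list: `n_roh_total`, `n_roh_overlapping`,
#'   `pct_overlapping`, `n_regions_hit`, and `per_region` (data frame
#'   with the number of overlapping ROH and the mean per-sample covered
#'   fraction `froh_region` of each interval).
#' @export
overlap_regions <- function(roh_set, intervals, min_overlap_bp = 1) {
  n_total <- nrow(roh_set)
  samples <- attr(roh_set, "samples")
  n_samples <- if (!is.null(samples)) nrow(samples) else
    length(unique(roh_set$sample_id))
  hit_roh <- rep(FALSE, n_total)
  n_over <- integer(nrow(intervals))
  froh_reg <- numeric(nrow(intervals))
  for (k in seq_len(nrow(intervals))) {
    sel <- which(roh_set$chrom == intervals$chrom[k])
    if (!length(sel)) next
    ov <- .overlap_bp(roh_set$start_bp[sel], roh_set$end_bp[sel],
                      intervals$start_bp[k], intervals$end_bp[k])
    hit <- ov >= min_overlap_bp
    hit_roh[sel[hit]] <- TRUE
    n_over[k] <- sum(hit)
    froh_reg[k] <- region_froh(roh_set, intervals[k, , drop = FALSE],
                               n_samples)
  }
  structure(list(
    n_roh_total = n_total,
    n_roh_overlapping = sum(hit_roh),
    pct_overlapping = if (n_total) 100 * sum(hit_roh) / n_total else 0,
    n_regions_hit = sum(n_over > 0L),
    per_region = data.frame(label = intervals$label,
                            chrom = intervals$chrom,
                            start_bp = intervals$start_bp,
                            end_bp = intervals$end_bp,
                            n_roh_overlapping = n_over,
                            froh_region = froh_reg)),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap: ", x$n_roh_overlapping, "/", x$n_roh_total, " ROH (",
      sprintf("%.2f", x$pct_overlapping), "%) touch ", x$n_regions_hit,
      " region(s)\n", sep = "")
  invisible(x)
}

#' Mean per-sample ROH coverage of one region
#'
#' For each sample, the base pairs of its ROH intersecting the interval
#' divided by the interval length; averaged over all `n_samples`
#' (samples without overlap contribute zero).
#'
#' @param roh_set an `roh_set`.
#' @param interval a single-row [genomic_intervals()] object.
#' @param n_samples number of samples in the denominator; defaults to
#'   the sample table recorded in the `roh_set`.
#' @return The mean covered fraction, in `[0, 1]`.
#' @export
region_froh <- function(roh_set, interval, n_samples = NULL) {
  stopifnot(nrow(interval) == 1L)
  if (is.null(n_samples)) {
    samples <- attr(roh_set, "samples")
    n_samples <- if (!is.null(samples)) nrow(samples) else
      length(unique(roh_set$sample_id))
  }
  if (n_samples < 1L) stop("n_samples must be >= 1")
  sel <- which(roh_set$chrom == interval$chrom)
  if (!length(sel)) return(0)
  ov <- .overlap_bp(roh_set$start_bp[sel], roh_set$end_bp[sel],
                    interval$start_bp, interval$end_bp)
  len <- interval$end_bp - interval$start_bp + 1
  per_sample <- tapply(ov, roh_set$sample_id[sel], sum)
  sum(per_sample) / (len * n_samples)
}

#' Per-SNP ROH incidence
#'
#' For every marker, the fraction of samples whose ROH cover its
#' position — the basis of consensus-ROH (ROH-island) summaries.
#'
#' @param roh_set an `roh_set`.
#' @param map a marker map (`chrom`, `pos_bp`).
#' @param n_samples denominator; defaults to the recorded sample table.
#' @return Numeric vector in `[0, 1]`, one value per marker row.
#' @export
snp_incidence <- function(roh_set, map, n_samples = NULL) {
  if (is.null(n_samples)) {
    samples <- attr(roh_set, "samples")
    n_samples <- if (!is.null(samples)) nrow(samples) else
      length(unique(roh_set$sample_id))
  }
  cnt <- numeric(nrow(map))
  if (nrow(roh_set) && n_samples >= 1L) {
    for (i in seq_len(nrow(roh_set))) {
      inside <- map$chrom == roh_set$chrom[i] &
        map$pos_bp >= roh_set$start_bp[i] &
        map$pos_bp <= roh_set$end_bp[i]
      cnt[inside] <- cnt[inside] + 1
    }
  }
  if (n_samples >= 1L) cnt / n_samples else cnt
}

#' Write an overlap report as tab-separated text
#' @param report an `overlap_report`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_overlap_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_roh_total\t", report$n_roh_total), con)
  writeLines(paste0("# n_roh_overlapping\t", report$n_roh_overlapping),
             con)
  writeLines(paste0("# pct_overlapping\t",
                    sprintf("%.2f", report$pct_overlapping)), con)
  writeLines(paste0("# n_regions_hit\t", report$n_regions_hit), con)
  write.table(report$per_region, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
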