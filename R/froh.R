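#' Autosome length constants
#'
#' The default total autosomal length covered by SNPs, 2,504,168,970 bp,
#' corresponds to the bovine 50K array; per-chromosome covered lengths
#' are taken from the actual marker map via
#' [covered_chromosome_lengths()], not from a reference genome.
#'
#' @param l_autosome total autosomal length covered by SNPs, in bp.
#' @param l_bta optional named numeric vector of per-chromosome covered
#'   lengths (names = chromosome numbers).
#' @return An object of class `genome_constants`.
#' @export
genome_constants <- function(l_autosome = 2504168970, l_bta = NULL) {
  if (l_autosome <= 0) stop("l_autosome must be positive")
  if (!is.null(l_bta)) {
    if (is.null(names(l_bta))) stop("l_bta must be named by chromosome")
    if (any(l_bta <= 0)) stop("per-chromosome lengths must be positive")
  }
  structure(list(l_autosome = l_autosome, l_bta = l_bta),
            class = "genome_constants")
}

#' Chromosome lengths covered by SNPs
#'
#' For each chromosome, `max(pos) - min(pos) + 1`.  Chromosomes with
#' fewer than two markers have no defined span and are excluded with a
#' warning.
#'
#' @param map a marker map (data frame with `chrom`, `pos_bp`).
#' @return Named numeric vector of covered lengths in bp.
#' @export
covered_chromosome_lengths <- function(map) {
  chroms <- sort(unique(map$chrom))
  out <- numeric(0)
  for (ch in chroms) {
    p <- map$pos_bp[map$chrom == ch]
    if (length(p) < 2L) {
      warning("chromosome ", ch, " has < 2 markers; covered length undefined")
      next
    }
    out[as.character(ch)] <- max(p) - min(p) + 1
  }
  out
}

#' Per-individual genomic inbreeding (F_ROH)
#'
#' `froh_total = S_ROH / L_AUTOSOME`, where S_ROH is the summed length
#' of the individual's ROH segments.  Threshold-cumulative values
#' (`froh_ge_4`, `froh_ge_8`, `froh_gt_16`) restrict the sum to segments
#' of at least 4, 8 and 16 Mb; with the default 4 Mb calling threshold
#' `froh_total` equals `froh_ge_4`.  Samples without ROH get zero.
#'
#' @param roh_set an `roh_set` from [call_roh()].
#' @param constants a [genome_constants()] object.
#' @param samples optional sample table (`sample_id`, `population`);
#'   defaults to the one recorded in the `roh_set`.
#' @return Data frame with one row per sample: `sample_id`,
#'   `population`, `n_roh`, `s_roh_bp`, `froh_total`, `froh_ge_4`,
#'   `froh_ge_8`, `froh_gt_16`.
#' @export
froh_individual <- function(roh_set, constants = genome_constants(),
                            samples = NULL) {
  if (is.null(samples)) samples <- attr(roh_set, "samples")
  if (is.null(samples))
    samples <- data.frame(sample_id = unique(roh_set$sample_id),
                          population = NA_character_)
  L <- constants$l_autosome
  sum_ge <- function(min_bp) {
    v <- setNames(numeric(nrow(samples)), samples$sample_id)
    sel <- roh_set$length_bp >= min_bp
    if (any(sel)) {
      agg <- tapply(roh_set$length_bp[sel], roh_set$sample_id[sel], sum)
      v[names(agg)] <- agg
    }
    v
  }
  s_tot <- sum_ge(0)
  nr <- setNames(integer(nrow(samples)), samples$sample_id)
  if (nrow(roh_set)) {
    cnt <- table(roh_set$sample_id)
    nr[names(cnt)] <- as.integer(cnt)
  }
  data.frame(sample_id = samples$sample_id,
             population = samples$population,
             n_roh = as.integer(nr),
             s_roh_bp = as.numeric(s_tot),
             froh_total = as.numeric(s_tot) / L,
             froh_ge_4 = as.numeric(sum_ge(4e6)) / L,
             froh_ge_8 = as.numeric(sum_ge(8e6)) / L,
             froh_gt_16 = as.numeric(sum_ge(16e6)) / L,
             stringsAsFactors = FALSE)
}

#' Per-chromosome genomic inbreeding (F_ROH by chromosome)
#'
#' For each sample and chromosome, the summed ROH length on that
#' chromosome divided by its covered length; zero when the sample has no
#' ROH there.
#'
#' @param roh_set an `roh_set`.
#' @param l_bta named vector of covered chromosome lengths (bp), e.g.
#'   from [covered_chromosome_lengths()].
#' @param samples optional sample table; defaults to the one recorded in
#'   the `roh_set`.
#' @return Long-format data frame: `sample_id`, `population`, `chrom`,
#'   `l_roh_bp`, `l_bta_bp`, `froh_bta`.
#' @export
froh_per_chromosome <- function(roh_set, l_bta, samples = NULL) {
  if (is.null(samples)) samples <- attr(roh_set, "samples")
  miss <- setdiff(unique(roh_set$chrom), as.integer(names(l_bta)))
  if (length(miss))
    stop("ROH on chromosome(s) absent from the length table: ",
         paste(miss, collapse = ", "))
  chroms <- as.integer(names(l_bta))
  grid <- expand.grid(sample_id = samples$sample_id, chrom = chroms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$population <- samples$population[match(grid$sample_id,
                                              samples$sample_id)]
  key <- paste(grid$sample_id, grid$chrom)
  lr <- setNames(numeric(nrow(grid)), key)
  if (nrow(roh_set)) {
    agg <- tapply(roh_set$length_bp,
                  paste(roh_set$sample_id, roh_set$chrom), sum)
    lr[names(agg)] <- agg
  }
  grid$l_roh_bp <- as.numeric(lr)
  grid$l_bta_bp <- l_bta[as.character(grid$chrom)]
  grid$froh_bta <- grid$l_roh_bp / grid$l_bta_bp
  grid[, c("sample_id", "population", "chrom", "l_roh_bp", "l_bta_bp",
           "froh_bta")]
}

#' Coefficient of variation, in percent
#' @param x numeric vector, or a mean when `sd_x` is given.
#' @param sd_x optional standard deviation accompanying a scalar mean.
#' @return `100 * sd / mean`.
#' @export
cv_pct <- function(x, sd_x = NULL) {
  if (is.null(sd_x)) 100 * stats::sd(x) / mean(x) else 100 * sd_x / x
}

#' Per-population, per-class ROH summary
#'
#' Counts, class frequency percentages, and mean / SD / CV / normal 95%
#' confidence interval of the segment lengths in Mb, per population and
#' size class.
#'
#' @param roh_set a classified `roh_set`.
#' @return Data frame with columns `population`, `size_class`, `n_roh`,
#'   `freq_pct`, `mn_roh_mb`, `sd_mb`, `cv_pct`, `ci95_low`, `ci95_high`.
#'   Empty classes keep `n_roh = 0` with the remaining fields `NA`.
#' @export
class_summary <- function(roh_set) {
  pops <- sort(unique(roh_set$population))
  classes <- levels(roh_set$size_class)
  rows <- list()
  for (pop in pops) {
    sel <- roh_set$population == pop
    n_tot <- sum(sel)
    for (cl in classes) {
      len <- roh_set$length_bp[sel & roh_set$size_class == cl] / 1e6
      n <- length(len)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          population = pop, size_class = cl, n_roh = 0L, freq_pct = 0,
          mn_roh_mb = NA_real_, sd_mb = NA_real_, cv_pct = NA_real_,
          ci95_low = NA_real_, ci95_high = NA_real_)
        next
      }
      m <- mean(len)
      s <- if (n > 1L) stats::sd(len) else NA_real_
      half <- if (n > 1L) 1.96 * s / sqrt(n) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, size_class = cl, n_roh = n,
        freq_pct = 100 * n / n_tot, mn_roh_mb = m, sd_mb = s,
        cv_pct = if (n > 1L) 100 * s / m else NA_real_,
        ci95_low = m - half, ci95_high = m + half)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population means of cumulative F_ROH
#'
#' Means over individuals, per population, of the threshold-cumulative
#' genomic inbreeding values from [froh_individual()].
#'
#' @param records output of [froh_individual()].
#' @return Data frame: `population`, `n_samples`, mean and SD of
#'   `froh_ge_4`, `froh_ge_8`, `froh_gt_16`, and the CV (%) of
#'   `froh_ge_4`.
#' @export
froh_population_summary <- function(records) {
  pops <- sort(unique(records$population))
  do.call(rbind, lapply(pops, function(pop) {
    r <- records[records$population == pop, , drop = FALSE]
    data.frame(population = pop, n_samples = nrow(r),
               froh_ge_4_mean = mean(r$froh_ge_4),
               froh_ge_4_sd = stats::sd(r$froh_ge_4),
               froh_ge_8_mean = mean(r$froh_ge_8),
               froh_ge_8_sd = stats::sd(r$froh_ge_8),
               froh_gt_16_mean = mean(r$froh_gt_16),
               froh_gt_16_sd = stats::sd(r$froh_gt_16),
               froh_cv_pct = 100 * stats::sd(r$froh_ge_4) / mean(r$froh_ge_4))
  }))
}

#' Write the F_ROH report files
#'
#' Deterministic tab-separated outputs: per-individual records, the
#' per-class summary, per-chromosome boxplot data (quartiles and
#' maximum of `froh_bta` per population x chromosome) and per-sample
#' scatter data (`n_roh` vs `s_roh_bp`).
#'
#' @param records output of [froh_individual()].
#' @param summaries output of [class_summary()].
#' @param by_chrom optional output of [froh_per_chromosome()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
froh_report <- function(records, summaries, by_chrom = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(individual = file.path(dir, "froh_individual.tsv"),
             class = file.path(dir, "froh_class_summary.tsv"),
             scatter = file.path(dir, "froh_scatter.tsv"))
  wt <- function(df, path)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(records, paths["individual"])
  wt(summaries, paths["class"])
  wt(records[, c("sample_id", "population", "n_roh", "s_roh_bp")],
     paths["scatter"])
  if (!is.null(by_chrom)) {
    paths["boxplot"] <- file.path(dir, "froh_by_chromosome.tsv")
    agg <- do.call(rbind, lapply(
      split(by_chrom, list(by_chrom$population, by_chrom$chrom),
            drop = TRUE),
      function(d) {
        q <- stats::quantile(d$froh_bta, c(0.25, 0.5, 0.75))
        data.frame(population = d$population[1L], chrom = d$chrom[1L],
                   q1 = q[[1L]], median = q[[2L]], q3 = q[[3L]],
                   max = max(d$froh_bta))
      }))
    agg <- agg[order(agg$population, agg$chrom), , drop = FALSE]
    rownames(agg) <- NULL
    wt(agg, paths["boxplot"])
  }
  invisible(paths)
}
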