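#' Configuration for LD-based Ne estimation
#'
#' Defaults match the standard medium-density-array analysis: MAF
#' filter 0.05, physical-to-genetic mapping at 1 cM/Mb, mutation
#' correction alpha = 2.2, unphased (composite) LD with the sample-size
#' correction 1/(2n), pairs between 1.4 and 50 Mb (covering roughly
#' generations 1-35 at 1 cM/Mb), and distance bins targeting integer
#' generations with at least 50 pairs each.
#'
#' @param maf_min minimum minor allele frequency.
#' @param mindist_bp,maxdist_bp distance window for SNP pairs, in bp.
#' @param alpha mutation correction in the drift expectation
#'   `E[r2] = 1/(alpha + 4Nc)`; conventional values are 1, 2 or 2.2.
#' @param recomb_rate_per_bp Morgans per bp (default 1e-8 = 1 cM/Mb).
#' @param mapping physical-to-genetic mapping: `"linear"` (c = d * rate),
#'   `"haldane"` or `"sved_feldman"` (second-order in d * rate).
#' @param phase_known `FALSE` for genotype-based composite LD (sample
#'   correction `1/(2n)`), `TRUE` for phased data (`1/n`).
#' @param t_min,t_max generation targets of the distance bins; defaults
#'   derived from the distance window.
#' @param min_pairs minimum SNP pairs per reported bin.
#' @return An object of class `ne_config`.
#' @export
ne_config <- function(maf_min = 0.05, mindist_bp = 1.4e6, maxdist_bp = 5e7,
                      alpha = 2.2, recomb_rate_per_bp = 1e-8,
                      mapping = c("linear", "haldane", "sved_feldman"),
                      phase_known = FALSE, t_min = NULL, t_max = NULL,
                      min_pairs = 50L) {
  mapping <- match.arg(mapping)
  if (mindist_bp <= 0 || maxdist_bp <= mindist_bp)
    stop("need 0 < mindist_bp < maxdist_bp")
  if (alpha < 1) stop("alpha must be >= 1")
  if (recomb_rate_per_bp <= 0) stop("recombination rate must be positive")
  r <- recomb_rate_per_bp
  if (is.null(t_min)) t_min <- max(1L, ceiling(1 / (2 * maxdist_bp * r)))
  if (is.null(t_max)) t_max <- max(t_min, floor(1 / (2 * mindist_bp * r)))
  structure(list(maf_min = maf_min, mindist_bp = mindist_bp,
                 maxdist_bp = maxdist_bp, alpha = alpha,
                 recomb_rate_per_bp = r, mapping = mapping,
                 phase_known = phase_known, t_min = as.integer(t_min),
                 t_max = as.integer(t_max),
                 min_pairs = as.integer(min_pairs)),
            class = "ne_config")
}

#' Composite LD between two genotype columns
#'
#' Squared Pearson correlation of the 0/1/2 dosage vectors over
#' pairwise-complete samples — the standard composite measure of LD for
#' unphased genotypes.  Returns `NA` when fewer than two complete
#' observations remain or either column is monomorphic among them.
#'
#' @param g1,g2 integer genotype codes (0/1/2/NA).
#' @return r-squared, or `NA`.
#' @export
r2_composite <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Collect intra-chromosomal SNP pairs with their LD
#'
#' Applies the MAF filter, then gathers all within-chromosome marker
#' pairs whose physical distance lies in the configured window.
#' Inter-chromosomal pairs are never used.
#'
#' @param ds a [genotype_dataset()].
#' @param config an [ne_config()] object.
#' @return Data frame `chrom`, `d_bp`, `r2` (one row per pair; pairs
#'   with undefined LD are dropped).  Empty, with a warning, when no
#'   pair falls in the window.
#' @export
collect_pairs <- function(ds, config = ne_config()) {
  keep <- !is.nan(marker_maf(ds)) & marker_maf(ds) >= config$maf_min
  ds <- subset_markers(ds, keep)
  out <- list()
  for (ch in unique(ds$map$chrom)) {
    idx <- which(ds$map$chrom == ch)
    if (length(idx) < 2L) next
    pos <- ds$map$pos_bp[idx]
    r2 <- r2_matrix(ds$geno[, idx, drop = FALSE])
    d <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(d)
    sel <- ut & d >= config$mindist_bp & d <= config$maxdist_bp & !is.na(r2)
    if (!any(sel)) next
    out[[length(out) + 1L]] <-
      data.frame(chrom = ch, d_bp = d[sel], r2 = r2[sel])
  }
  if (!length(out)) {
    warning("no SNP pairs in the distance window")
    return(data.frame(chrom = integer(0), d_bp = numeric(0),
                      r2 = numeric(0)))
  }
  do.call(rbind, out)
}

#' Sample-size adjustment of LD
#'
#' `r2_adj = r2 - 1/(beta * n)` with `beta = 2` for unphased
#' genotype-based LD and `beta = 1` for phased data; negative results
#' are floored at zero (a floored bin is excluded downstream).
#'
#' @param r2 raw r-squared value(s).
#' @param n number of samples (>= 2).
#' @param phase_known logical; see [ne_config()].
#' @return Adjusted r-squared.
#' @export
adjust_sample_size <- function(r2, n, phase_known = FALSE) {
  if (n < 2) stop("sample size must be >= 2")
  beta <- if (phase_known) 1 else 2
  pmax(0, r2 - 1 / (beta * n))
}

#' Physical distance to recombination fraction
#'
#' Default linear mapping `c = d * rate`; Haldane
#' `c = 0.5 (1 - exp(-2 d rate))`; Sved-Feldman second-order
#' `c = m (1 - m/2)` with `m = d * rate`.  All mappings are capped at
#' 0.5.
#'
#' @param d_bp physical distance(s) in bp.
#' @param config an [ne_config()] (uses its rate and mapping).
#' @return Recombination fraction(s) in Morgans, in (0, 0.5].
#' @export
bp_to_c <- function(d_bp, config = ne_config()) {
  m <- d_bp * config$recomb_rate_per_bp
  c_t <- switch(config$mapping,
                linear = m,
                haldane = 0.5 * (1 - exp(-2 * m)),
                sved_feldman = m * (1 - m / 2))
  pmin(0.5, pmax(0, c_t))
}

#' Effective size from one LD bin
#'
#' Inverts the drift expectation `E[r2_adj] = 1/(alpha + 4 N c)`:
#' `N_T = (1/r2_adj - alpha) / (4 c)`, the effective size roughly
#' `t = 1/(2c)` generations ago.  Bins whose adjusted LD is zero or
#' implies a negative size are invalid (`NA`).
#'
#' @param mean_r2_adj mean adjusted r-squared of the bin.
#' @param c_t recombination fraction of the bin.
#' @param alpha mutation correction.
#' @return Estimated effective size, or `NA` for invalid bins.
#' @export
ne_from_bin <- function(mean_r2_adj, c_t, alpha = 2.2) {
  n_t <- (1 / mean_r2_adj - alpha) / (4 * c_t)
  n_t[!is.finite(n_t) | mean_r2_adj <= 0 | n_t < 0] <- NA_real_
  n_t
}

#' Expected r-squared under constant effective size
#'
#' The closed-form drift expectation used as the independent oracle in
#' tests: `E[r2] = 1/(alpha + 4 N c) + 1/(beta n)` (no sampling term
#' when `n = Inf`).
#'
#' @param N effective population size.
#' @param c_t recombination fraction.
#' @param n number of sampled diploids (`Inf` for none).
#' @param alpha mutation correction.
#' @param phase_known logical, selects `beta` as in
#'   [adjust_sample_size()].
#' @return Expected r-squared.
#' @export
expected_r2_constant <- function(N, c_t, n = Inf, alpha = 1,
                                 phase_known = FALSE) {
  beta <- if (phase_known) 1 else 2
  1 / (alpha + 4 * N * c_t) + if (is.finite(n)) 1 / (beta * n) else 0
}

#' Estimate the effective-population-size trajectory
#'
#' Collects SNP pairs, bins them by the generation each distance probes
#' (`t = 1/(2c)`, bin `t` covering `d` in
#' `[1/(2 (t + 0.5) rate), 1/(2 (t - 0.5) rate))`), adjusts the mean
#' r-squared for sample size, and inverts the drift expectation per bin.
#' Bins with fewer than `min_pairs` pairs are suppressed.
#'
#' @param ds a [genotype_dataset()] (one population).
#' @param config an [ne_config()] object.
#' @param population label stored in the result; defaults to the
#'   dataset's (single) population label.
#' @return An `ne_trajectory`: data frame `population`, `t`, `d_low`,
#'   `d_high`, `n_pairs`, `mean_r2`, `mean_r2_adj`, `c`, `n_t`, ordered
#'   by increasing `t`, with the config as attribute.  Invalid bins have
#'   `n_t = NA`.
#' @export
estimate_ne <- function(ds, config = ne_config(), population = NULL) {
  if (n_samples(ds) < 2L) stop("need at least two samples")
  if (is.null(population)) {
    pops <- unique(ds$samples$population)
    population <- if (length(pops) == 1L) pops else "pooled"
  }
  pairs <- collect_pairs(ds, config)
  if (!nrow(pairs)) stop("no SNP pairs available for Ne estimation")
  r <- config$recomb_rate_per_bp
  n <- n_samples(ds)
  rows <- list()
  for (t in config$t_min:config$t_max) {
    d_hi <- 1 / (2 * (t - 0.5) * r)
    d_lo <- 1 / (2 * (t + 0.5) * r)
    d_hi <- min(d_hi, config$maxdist_bp)
    d_lo <- max(d_lo, config$mindist_bp)
    if (d_lo >= d_hi) next
    sel <- pairs$d_bp >= d_lo & pairs$d_bp < d_hi
    np <- sum(sel)
    if (np < config$min_pairs) next
    mean_r2 <- mean(pairs$r2[sel])
    r2_adj <- adjust_sample_size(mean_r2, n, config$phase_known)
    c_t <- bp_to_c(1 / (2 * t * r), config)
    n_t <- if (r2_adj <= 0) NA_real_ else
      ne_from_bin(r2_adj, c_t, config$alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      population = population, t = t, d_low = d_lo, d_high = d_hi,
      n_pairs = np, mean_r2 = mean_r2, mean_r2_adj = r2_adj, c = c_t,
      n_t = n_t)
  }
  if (!length(rows)) stop("all distance bins are empty")
  out <- do.call(rbind, rows)
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ne_trajectory", "data.frame"), config = config)
}

#' Write an Ne trajectory as tab-separated text
#' @param traj an `ne_trajectory`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ne_tsv <- function(traj, path) {
  write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
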