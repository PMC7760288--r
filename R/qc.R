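#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: all heterozygote counts compatible with the
#' observed allele counts are enumerated and the probabilities of
#' configurations no more likely than the observed one are summed
#' (no mid-p correction).
#'
#' @param n_aa,n_ab,n_bb observed counts of the three genotype classes.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("HWE test undefined: all genotype counts are zero")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  hmax <- min(n_a, n_b)
  h <- seq.int(hmax %% 2L, hmax, by = 2L)   # feasible het counts (parity)
  logp <- lfactorial(n) - lfactorial((n_a - h) / 2) - lfactorial(h) -
    lfactorial((n_b - h) / 2) + h * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  p <- exp(logp)
  p_obs <- p[match(n_ab, h)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Marker quality control
#'
#' Removes markers failing, in order: missing-call fraction
#' (`> geno_max`), minor allele frequency (`< maf_min`), and the exact
#' Hardy-Weinberg test (`p < hwe_p_min`).  Each removed marker is
#' attributed to the first filter that fails it.
#'
#' @param ds a [genotype_dataset()].
#' @param geno_max maximum tolerated missing-call fraction per marker.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum HWE exact p-value.
#' @return A list with elements `dataset` (the filtered data) and
#'   `report` (a `qc_report`: input/output counts, per-filter removal
#'   counts and the thresholds used).
#' @export
apply_marker_qc <- function(ds, geno_max = 0.1, maf_min = 0.01,
                            hwe_p_min = 0.01) {
  thr <- c(geno_max = geno_max, maf_min = maf_min, hwe_p_min = hwe_p_min)
  if (any(thr < 0 | thr > 1))
    stop("QC thresholds must lie in [0, 1]")
  g <- ds$geno
  n_in <- ncol(g)
  miss <- colMeans(is.na(g))
  fail_geno <- miss > geno_max
  maf <- marker_maf(ds)
  fail_maf <- !fail_geno & (is.nan(maf) | maf < maf_min)
  cnt <- genotype_counts(ds)
  todo <- which(!fail_geno & !fail_maf)
  p_hwe <- rep(1, n_in)
  p_hwe[todo] <- vapply(todo, function(j)
    hwe_exact_test(cnt[1L, j], cnt[2L, j], cnt[3L, j]), numeric(1))
  fail_hwe <- !fail_geno & !fail_maf & p_hwe < hwe_p_min
  keep <- !(fail_geno | fail_maf | fail_hwe)
  report <- structure(list(
    n_markers_in = n_in,
    n_markers_out = sum(keep),
    n_removed_geno = sum(fail_geno),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_removed_prune = 0L,
    geno_max = geno_max, maf_min = maf_min, hwe_p_min = hwe_p_min),
    class = "qc_report")
  list(dataset = subset_markers(ds, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("marker QC: ", x$n_markers_in, " -> ", x$n_markers_out,
      " (geno>", x$geno_max, ": ", x$n_removed_geno,
      ", MAF<", x$maf_min, ": ", x$n_removed_maf,
      ", HWE p<", x$hwe_p_min, ": ", x$n_removed_hwe,
      ", pruned: ", x$n_removed_prune, ")\n", sep = "")
  invisible(x)
}

#' Serialize a QC report as tab-separated text
#' @param report a `qc_report`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(field = names(unclass(report)),
                   value = unlist(unclass(report), use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# squared composite (dosage) correlation matrix for a genotype submatrix;
# monomorphic columns yield NA without warnings
r2_matrix <- function(g) {
  suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window_snps` markers (step `step_snps`) along each
#' chromosome.  Within a window, while any retained pair has composite
#' r-squared above `r2_max`, the member of the currently worst pair with
#' the lower MAF is removed (tie: the later map position).  The result
#' is deterministic for a fixed dataset.
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param window_snps window size in markers (>= 2).
#' @param step_snps step between window starts, in markers.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @return The pruned [genotype_dataset()]; the number of markers removed
#'   is available as `attr(x, "n_removed_prune")`.
#' @export
ld_prune <- function(ds, window_snps = 50L, step_snps = 5L, r2_max = 0.5) {
  if (window_snps < 2L) stop("window_snps must be >= 2")
  if (step_snps < 1L) stop("step_snps must be >= 1")
  maf <- marker_maf(ds)
  keep <- rep(TRUE, n_markers(ds))
  for (ch in unique(ds$map$chrom)) {
    idx <- which(ds$map$chrom == ch)
    S <- length(idx)
    starts <- if (S <= window_snps) 1L else
      unique(c(seq.int(1L, S - window_snps + 1L, by = step_snps),
               S - window_snps + 1L))
    for (s in starts) {
      w <- idx[s:min(S, s + window_snps - 1L)]
      repeat {
        act <- w[keep[w]]
        if (length(act) < 2L) break
        r2 <- r2_matrix(ds$geno[, act, drop = FALSE])
        diag(r2) <- NA
        if (all(is.na(r2)) || max(r2, na.rm = TRUE) <= r2_max) break
        worst <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1L, ]
        pair <- act[worst]
        # drop the lower-MAF member; tie -> later map position
        m <- maf[pair]
        drop <- if (m[1L] < m[2L]) pair[1L]
        else if (m[2L] < m[1L]) pair[2L]
        else pair[which.max(ds$map$pos_bp[pair])]
        keep[drop] <- FALSE
      }
    }
  }
  out <- subset_markers(ds, keep)
  attr(out, "n_removed_prune") <- sum(!keep)
  out
}
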