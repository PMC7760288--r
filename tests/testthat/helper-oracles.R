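# Independent reference implementations (naive loops / normalized
# enumeration) used to validate the package's vectorized code paths.

# HWE exact test by normalized enumeration of all genotype
# configurations compatible with the observed allele counts.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  hs <- 0:min(n_a, n_b)
  hs <- hs[(n_a - hs) %% 2 == 0]
  w <- vapply(hs, function(h) {
    aa <- (n_a - h) / 2
    bb <- (n_b - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2))
  }, numeric(1))
  p <- w / sum(w)
  min(1, sum(p[p <= p[hs == n_ab] * (1 + 1e-9)]))
}

# per-SNP window support fractions by looping over every window
oracle_scan <- function(row, pos, params) {
  S <- length(row)
  w <- params$window_snps
  W <- S - w + 1
  ok <- logical(W)
  for (j in seq_len(W)) {
    win <- row[j:(j + w - 1)]
    ok[j] <- sum(win == 1, na.rm = TRUE) <= params$max_het_per_window &&
      sum(is.na(win)) <= params$max_miss_per_window
  }
  frac <- numeric(S)
  for (i in seq_len(S)) {
    js <- max(1, i - w + 1):min(i, W)
    frac[i] <- mean(ok[js])
  }
  frac
}

# full ROH reference for a single sample x chromosome: explicit window
# enumeration, candidate stretches, gap splitting and filters
oracle_call_roh_row <- function(row, pos, params) {
  S <- length(row)
  if (S < params$window_snps) return(NULL)
  frac <- oracle_scan(row, pos, params)
  cand <- frac >= params$window_threshold
  res <- list()
  i <- 1
  while (i <= S) {
    if (!cand[i]) { i <- i + 1; next }
    j <- i
    while (j < S && cand[j + 1]) j <- j + 1
    # split at large gaps
    s <- i
    for (k in i:j) {
      gap_next <- if (k < j) pos[k + 1] - pos[k] else Inf
      if (k == j || gap_next > params$max_gap_bp) {
        len <- pos[k] - pos[s] + 1
        nsnp <- k - s + 1
        if (len >= params$min_length_bp &&
            nsnp >= params$min_snps_in_run &&
            nsnp / len >= 1 / params$min_density_bp)
          res[[length(res) + 1]] <-
            data.frame(start_bp = pos[s], end_bp = pos[k], n_snps = nsnp)
        s <- k + 1
      }
    }
    i <- j + 1
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# random single-chromosome genotype row for oracle-equivalence sweeps:
# heterozygous-rich background with an occasional homozygous block
random_roh_row <- function(seed) {
  set.seed(seed)
  S <- sample(30:200, 1)
  pos <- cumsum(round(runif(S, 2e4, 1.5e5)))
  het <- runif(1, 0.2, 0.5)
  row <- sample(c(0L, 1L, 2L), S, replace = TRUE,
                prob = c((1 - het) / 2, het, (1 - het) / 2))
  row[runif(S) < 0.02] <- NA_integer_
  if (runif(1) < 0.7) {
    blk <- sample(20:min(60, S - 1), 1)
    a <- sample(S - blk + 1, 1)
    row[a:(a + blk - 1)] <- 0L
  }
  list(row = row, pos = pos)
}

make_single_row_dataset <- function(row, pos) {
  map <- data.frame(marker_id = paste0("m", seq_along(pos)), chrom = 1L,
                    pos_bp = pos, allele_a = "A", allele_b = "B")
  genotype_dataset(matrix(row, nrow = 1), map,
                   data.frame(sample_id = "s1", population = "P"))
}
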