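# Fixtures built in code at test time.

# Bovine autosome length covered by the 50K array (bp), used as the
# F_ROH denominator throughout.
L_AUTOSOME_BP <- 2504168970

# Segment-count and mean-length summaries of the three Charolais
# populations (per size class), used to rebuild population-shaped ROH
# sets for the worked-example checks.
charolais_classes <- list(
  CHF  = list(n_samples = 20, counts = c(158, 47, 16),
              mean_mb = c(5.35, 11.072, 22.195)),
  CHCU = list(n_samples = 40, counts = c(354, 182, 72),
              mean_mb = c(5.549, 11.24, 23.634)),
  CHUK = list(n_samples = 26, counts = c(193, 73, 28),
              mean_mb = c(5.598, 10.633, 27.377)))

# Build an roh_set whose per-class counts and mean lengths match a
# population summary; segments are laid out non-overlapping per sample.
make_summary_roh <- function(pop, n_samples, counts, mean_mb) {
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", pop, seq_len(n_samples)),
    population = pop, stringsAsFactors = FALSE)
  lens <- rep(round(mean_mb * 1e6), counts)
  n <- length(lens)
  if (n == 0L) {
    df <- data.frame(sample_id = character(0), population = character(0),
                     chrom = integer(0), start_bp = numeric(0),
                     end_bp = numeric(0), n_snps = integer(0),
                     length_bp = numeric(0))
    return(classify_roh(structure(df,
                                  class = c("roh_set", "data.frame"),
                                  params = roh_params(),
                                  samples = samples)))
  }
  sample_idx <- rep_len(seq_len(n_samples), n)
  ids <- sprintf("%s_%02d", pop, sample_idx)
  df <- data.frame(sample_id = ids, population = pop, chrom = 1L,
                   length_bp = lens, stringsAsFactors = FALSE)
  df <- df[order(df$sample_id), , drop = FALSE]
  start <- unlist(lapply(split(df$length_bp, df$sample_id), function(l)
    cumsum(c(1, head(l, -1) + 1e6))), use.names = FALSE)
  df$start_bp <- start
  df$end_bp <- df$start_bp + df$length_bp - 1
  df$n_snps <- pmax(20L, as.integer(df$length_bp / 85000))
  df <- df[, c("sample_id", "population", "chrom", "start_bp", "end_bp",
               "n_snps", "length_bp")]
  rownames(df) <- NULL
  out <- structure(df, class = c("roh_set", "data.frame"),
                   params = roh_params(), samples = samples)
  classify_roh(out)
}

# reassign segments to globally disjoint coordinate slots across the 29
# autosomes (1 Mb apart), so a region built from one segment's span
# cannot touch any other segment
relocate_roh <- function(roh) {
  roh$chrom <- rep(1:29, length.out = nrow(roh))
  roh$start_bp <- ave(roh$length_bp, roh$chrom,
                      FUN = function(l) cumsum(c(1, head(l, -1) + 1e6)))
  roh$end_bp <- roh$start_bp + roh$length_bp - 1
  roh
}

make_charolais_roh <- function(pop) {
  cc <- charolais_classes[[pop]]
  make_summary_roh(pop, cc$n_samples, cc$counts, cc$mean_mb)
}

# concatenate roh_sets, merging their sample tables
bind_roh <- function(...) {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, as.data.frame))
  structure(df, class = c("roh_set", "data.frame"),
            params = attr(parts[[1]], "params"),
            samples = do.call(rbind, lapply(parts, attr, "samples")))
}

# small deterministic dataset in canonical allele orientation (first
# observed genotype not homozygous-b), for PLINK round-trip tests
make_toy_dataset <- function(n = 3, m = 5, seed = 7) {
  set.seed(seed)
  geno <- matrix(sample(c(0L, 1L, 2L, NA), n * m, replace = TRUE,
                        prob = c(0.4, 0.3, 0.2, 0.1)), n, m)
  geno[1, ] <- 0L   # canonical orientation
  map <- data.frame(marker_id = paste0("snp", 1:m),
                    chrom = rep(1:2, length.out = m),
                    pos_bp = rep(seq(1e5, by = 9e4, length.out = m), 2)[1:m],
                    allele_a = "A", allele_b = "G")
  genotype_dataset(geno, map,
                   data.frame(sample_id = paste0("ind", 1:n),
                              population = rep(c("P1", "P2"),
                                               length.out = n)))
}
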