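test_that("HWE exact test matches the enumeration oracle on key cases", {
  # monomorphic: a single possible configuration
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  # balanced intermediate case
  expect_equal(hwe_exact_test(25, 50, 25), oracle_hwe(25, 50, 25),
               tolerance = 1e-12)
  # everything heterozygous: grossly out of equilibrium
  p <- hwe_exact_test(0, 100, 0)
  expect_equal(p, oracle_hwe(0, 100, 0), tolerance = 1e-12)
  expect_lt(p, 0.01)
  expect_error(hwe_exact_test(0, 0, 0), "undefined")
  expect_error(hwe_exact_test(-1, 2, 0), ">= 0")
})

test_that("HWE exact test equals the oracle for every n <= 50", {
  for (n in c(1:12, 20, 33, 50)) {
    for (n_aa in 0:n) for (n_ab in 0:(n - n_aa)) {
      n_bb <- n - n_aa - n_ab
      expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                   oracle_hwe(n_aa, n_ab, n_bb), tolerance = 1e-9,
                   label = sprintf("hwe(%d,%d,%d)", n_aa, n_ab, n_bb))
    }
  }
})

make_qc_fixture <- function() {
  set.seed(11)
  n <- 20; m <- 100
  geno <- matrix(rep(c(0L, 1L, 1L, 2L), length.out = n * m), n, m)
  # columns in exact HWE-friendly proportions (5/10/5)
  base <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))
  for (j in 1:m) geno[, j] <- sample(base)
  fail_geno <- 1:10        # 3/20 = 0.15 missing
  fail_maf <- 11:20        # monomorphic, MAF 0
  fail_hwe <- 21:30        # all heterozygous
  for (j in fail_geno) geno[1:3, j] <- NA
  for (j in fail_maf) geno[, j] <- 0L
  for (j in fail_hwe) geno[, j] <- 1L
  map <- data.frame(marker_id = paste0("m", 1:m), chrom = 1L,
                    pos_bp = seq(1e5, by = 9e4, length.out = m),
                    allele_a = "A", allele_b = "G")
  genotype_dataset(geno, map,
                   data.frame(sample_id = paste0("i", 1:n),
                              population = "P"))
}

test_that("marker QC removes and attributes failures in filter order", {
  ds <- make_qc_fixture()
  res <- apply_marker_qc(ds)
  r <- res$report
  expect_equal(r$n_markers_in, 100L)
  expect_equal(r$n_removed_geno, 10L)
  expect_equal(r$n_removed_maf, 10L)
  expect_equal(r$n_removed_hwe, 10L)
  expect_equal(r$n_markers_out, 70L)
  expect_equal(r$n_markers_out,
               r$n_markers_in - r$n_removed_geno - r$n_removed_maf -
                 r$n_removed_hwe)
  expect_equal(n_markers(res$dataset), 70L)
  # a marker failing two filters is counted once, at the first
  ds2 <- ds
  ds2$geno[1:3, 15] <- NA   # marker 15 already fails MAF; add missingness
  res2 <- apply_marker_qc(ds2)
  expect_equal(res2$report$n_removed_geno, 11L)
  expect_equal(res2$report$n_removed_maf, 9L)
})

test_that("marker QC is idempotent and validates thresholds", {
  ds <- make_qc_fixture()
  once <- apply_marker_qc(ds)
  twice <- apply_marker_qc(once$dataset)
  expect_true(datasets_equal(once$dataset, twice$dataset))
  expect_equal(twice$report$n_markers_out, twice$report$n_markers_in)
  expect_error(apply_marker_qc(ds, geno_max = 1.5), "\\[0, 1\\]")
  expect_error(apply_marker_qc(ds, maf_min = -0.1), "\\[0, 1\\]")
})

test_that("QC thresholds follow the strict/loose boundary conventions", {
  # 3 of 20 missing (0.15) removed at geno_max 0.1; 2 of 20 (0.1) kept
  ds <- make_qc_fixture()
  miss2 <- ds
  miss2$geno[1:2, 31] <- NA
  res <- apply_marker_qc(miss2)
  expect_true("m31" %in% res$dataset$map$marker_id)
  # single minor-allele copy in 86 diploids: MAF ~ 0.0058 < 0.01
  set.seed(12)
  g <- matrix(0L, 86, 21)
  g[1, 1] <- 1L
  g[, 2:21] <- matrix(sample(c(rep(0L, 25), rep(1L, 40), rep(2L, 21))),
                      86, 20)
  map <- data.frame(marker_id = paste0("w", 1:21), chrom = 1L,
                    pos_bp = seq(1e5, by = 1e5, length.out = 21))
  ds86 <- genotype_dataset(g, map,
                           data.frame(sample_id = paste0("s", 1:86),
                                      population = "P"))
  res86 <- apply_marker_qc(ds86, hwe_p_min = 0)
  expect_false("w1" %in% res86$dataset$map$marker_id)
  expect_gte(res86$report$n_removed_maf, 1L)
})

test_that("write_qc_report serializes all counts", {
  ds <- make_qc_fixture()
  res <- apply_marker_qc(ds)
  path <- tempfile(fileext = ".tsv")
  write_qc_report(res$report, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(tab$value[tab$field == "n_markers_out"], 70)
})

test_that("LD pruning keeps one of a duplicated marker pair", {
  ds <- make_toy_dataset(n = 12, m = 8, seed = 3)
  i <- match(c("snp1", "snp3"), ds$map$marker_id)  # both on chrom 1
  ds$geno[, i[2]] <- ds$geno[, i[1]]               # exact duplicate, r2 = 1
  pruned <- ld_prune(ds, window_snps = 8, step_snps = 2, r2_max = 0.99)
  kept <- pruned$map$marker_id
  expect_equal(sum(c("snp1", "snp3") %in% kept), 1L)
  expect_equal(attr(pruned, "n_removed_prune"), 1L)
})

test_that("LD pruning leaves independent markers untouched", {
  set.seed(21)
  g <- matrix(sample(c(0L, 1L, 2L), 50 * 10, replace = TRUE), 50, 10)
  map <- data.frame(marker_id = paste0("m", 1:10), chrom = 1L,
                    pos_bp = seq(1e5, by = 1e5, length.out = 10))
  ds <- genotype_dataset(g, map,
                         data.frame(sample_id = paste0("s", 1:50),
                                    population = "P"))
  r2 <- suppressWarnings(cor(g)^2); diag(r2) <- 0
  expect_lt(max(r2), 0.5)   # fixture precondition (fixed seed)
  pruned <- ld_prune(ds)
  expect_equal(n_markers(pruned), 10L)
  expect_error(ld_prune(ds, window_snps = 1), "window_snps")
})

test_that("LD pruning matches a brute-force application of its rule", {
  set.seed(5)
  n <- 40
  base <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(.3, .4, .3))
  g <- matrix(sample(c(0L, 1L, 2L), n * 10, replace = TRUE), n, 10)
  # correlated triple at markers 4, 5, 6
  g[, 5] <- base
  g[, 6] <- base; flip <- sample(n, 3); g[flip, 6] <- 2L - g[flip, 6]
  g[, 4] <- base; flip <- sample(n, 5); g[flip, 4] <- 2L - g[flip, 4]
  map <- data.frame(marker_id = paste0("m", 1:10), chrom = 1L,
                    pos_bp = seq(1e5, by = 1e5, length.out = 10))
  ds <- genotype_dataset(g, map,
                         data.frame(sample_id = paste0("s", 1:n),
                                    population = "P"))
  # independent greedy oracle over the full marker set
  maf <- marker_maf(ds)
  alive <- rep(TRUE, 10)
  repeat {
    idx <- which(alive)
    r2 <- suppressWarnings(cor(g[, idx, drop = FALSE])^2)
    diag(r2) <- NA
    if (all(is.na(r2)) || max(r2, na.rm = TRUE) <= 0.5) break
    w <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- idx[w]
    drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1] else
      if (maf[pair[2]] < maf[pair[1]]) pair[2] else max(pair)
    alive[drop] <- FALSE
  }
  pruned <- ld_prune(ds, window_snps = 10, step_snps = 5, r2_max = 0.5)
  expect_equal(pruned$map$marker_id, map$marker_id[alive])
})
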