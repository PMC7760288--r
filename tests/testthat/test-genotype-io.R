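test_that("PED parsing assigns codes from the first observed allele", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200", "1\tsnp3\t0\t300"),
             map)
  writeLines("FAM1 ID1 0 0 0 -9 A A A G 0 0", ped)
  ds <- read_plink_text(ped, map)
  expect_equal(as.vector(ds$geno), c(0L, 1L, NA))
  expect_equal(ds$map$allele_a, c("A", "A", NA))
  expect_equal(ds$samples$population, "FAM1")
  # het-first marker: lexicographic tie-break for allele_a
  writeLines(c("F I1 0 0 0 -9 G A T T C C",
               "F I2 0 0 0 -9 G G T T C C"), ped)
  ds2 <- read_plink_text(ped, map)
  expect_equal(ds2$map$allele_a, c("A", "T", "C"))
  expect_equal(ds2$geno[, 1], c(I1 = 1L, I2 = 2L))
})

test_that("PED/MAP format errors name the offending line", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200"), map)
  writeLines(c("F I1 0 0 0 -9 A A G G", "F I2 0 0 0 -9 A A"), ped)
  expect_error(read_plink_text(ped, map), "line 2")
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\tx200"), map)
  expect_error(read_plink_text(ped, map), "position")
})

test_that("write -> read round-trips a dataset exactly", {
  ds <- make_toy_dataset()
  prefix <- tempfile()
  write_plink_text(ds, prefix)
  ds2 <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_true(datasets_equal(ds, ds2))
  # missing genotypes written as "0 0"
  ped <- readLines(paste0(prefix, ".ped"))
  expect_true(any(grepl("0 0", ped, fixed = TRUE)))
  # a second round trip is byte-stable
  prefix2 <- tempfile()
  write_plink_text(ds2, prefix2)
  expect_identical(readLines(paste0(prefix, ".ped")),
                   readLines(paste0(prefix2, ".ped")))
})

test_that("an empty (0-sample) dataset writes a valid empty PED", {
  ds <- make_toy_dataset()
  empty <- subset_samples(ds, integer(0))
  prefix <- tempfile()
  write_plink_text(empty, prefix)
  expect_identical(readLines(paste0(prefix, ".ped")), character(0))
  back <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_equal(n_samples(back), 0L)
  expect_equal(n_markers(back), n_markers(ds))
})

test_that("markers outside autosomes 1-29 are dropped with a warning", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines(c("1\tsnp1\t0\t100", "30\tsnpX\t0\t200"), map)
  writeLines("F I1 0 0 0 -9 A A G G", ped)
  expect_warning(ds <- read_plink_text(ped, map), "outside 1-29")
  expect_equal(ds$map$marker_id, "snp1")
})

test_that("PLINK binary (BED) input matches the text reader", {
  ds <- make_toy_dataset()
  prefix <- tempfile()
  # write a SNP-major BED/BIM/FAM triple by hand (independent packer)
  m <- ds$map
  writeLines(paste(m$chrom, m$marker_id, 0, m$pos_bp,
                   ifelse(is.na(m$allele_a), "A", m$allele_a),
                   ifelse(is.na(m$allele_b), "G", m$allele_b),
                   sep = "\t"),
             paste0(prefix, ".bim"))
  writeLines(paste(ds$samples$population, ds$samples$sample_id,
                   0, 0, 0, -9), paste0(prefix, ".fam"))
  two_bit <- function(g) if (is.na(g)) 1L else c(0L, 2L, 3L)[g + 1L]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(n_markers(ds))) {
    codes <- vapply(ds$geno[, j], two_bit, integer(1))
    codes <- c(codes, rep(0L, (-length(codes)) %% 4))
    bytes <- vapply(seq(1, length(codes), 4), function(k)
      sum(codes[k:(k + 3)] * c(1L, 4L, 16L, 64L)), numeric(1))
    writeBin(as.raw(bytes), con)
  }
  close(con)
  ds2 <- read_plink_bed(prefix)
  expect_identical(is.na(ds$geno), is.na(ds2$geno))
  expect_true(all(ds$geno == ds2$geno, na.rm = TRUE))
})

test_that("merge keeps the marker intersection and sample union", {
  ds <- make_toy_dataset(n = 4)
  a <- subset_samples(ds, 1:2)
  b <- subset_samples(ds, 3:4)
  m <- merge_populations(a, b)
  expect_equal(n_markers(m), n_markers(ds))
  expect_equal(m$samples$sample_id, ds$samples$sample_id)
  expect_true(all(m$geno == ds$geno, na.rm = TRUE))
  # marker private to one dataset is dropped
  b2 <- subset_markers(b, b$map$marker_id != "snp2")
  m2 <- merge_populations(a, b2)
  expect_setequal(m2$map$marker_id, setdiff(ds$map$marker_id, "snp2"))
})

test_that("merge flips swapped allele orientations", {
  map1 <- data.frame(marker_id = c("s1", "s2"), chrom = 1L,
                     pos_bp = c(100, 200), allele_a = c("A", "C"),
                     allele_b = c("G", "T"))
  g1 <- matrix(c(0L, 2L, 1L, 0L), 2, 2)
  d1 <- genotype_dataset(g1, map1,
                         data.frame(sample_id = c("x1", "x2"),
                                    population = "P1"))
  # same individuals, alleles swapped at s1 -> codes flipped on input
  map2 <- map1
  map2$allele_a[1] <- "G"; map2$allele_b[1] <- "A"
  g2 <- g1; g2[, 1] <- 2L - g2[, 1]
  d2 <- genotype_dataset(g2, map2,
                         data.frame(sample_id = c("y1", "y2"),
                                    population = "P2"))
  m <- merge_populations(d1, d2)
  # duplicated individuals must have identical dosages -> r2 = 1
  expect_equal(unname(m$geno[1:2, ]), unname(m$geno[3:4, ]))
  expect_equal(r2_composite(m$geno[, 1], m$geno[, 1]), 1)
  # incompatible alleles raise an error naming the marker
  map3 <- map1; map3$allele_b[2] <- "G"
  d3 <- genotype_dataset(g1, map3,
                         data.frame(sample_id = c("z1", "z2"),
                                    population = "P3"))
  expect_error(merge_populations(d1, d3), "s2")
})

test_that("merge marker intersection is order-independent", {
  ds <- make_toy_dataset(n = 4)
  a <- subset_samples(ds, 1:2); b <- subset_samples(ds, 3:4)
  m1 <- merge_populations(a, b)
  m2 <- merge_populations(b, a)
  expect_equal(m1$map$marker_id, m2$map$marker_id)
  expect_equal(sort(m1$samples$sample_id), sort(m2$samples$sample_id))
  ia <- match(m1$samples$sample_id, m2$samples$sample_id)
  expect_true(all(m1$geno == m2$geno[ia, ], na.rm = TRUE))
})
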