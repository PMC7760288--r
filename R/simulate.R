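#' Generate a dataset with implanted homozygous tracts
#'
#' Background genotypes are drawn heterozygous with probability
#' `het_prob` (the remainder split evenly between the two homozygotes,
#' emulating array markers near MAF 0.5); the listed spans are then
#' forced homozygous (code 0).  Truth records carry the exact SNP
#' boundaries of each implant.  Marker spacing is uniform on
#' `(0.5, 1.5) * mean_spacing_bp`; the default 85 kb mirrors 50K-chip
#' density.
#'
#' @param n_samples,n_chrom,snps_per_chrom dataset dimensions.
#' @param mean_spacing_bp mean inter-marker distance in bp.
#' @param het_prob background heterozygosity.
#' @param implants data frame `sample` (index), `chrom`, `start_bp`,
#'   `length_bp`; may be `NULL` for none.
#' @param miss_prob per-genotype missing probability.
#' @param population population label for all samples.
#' @param seed mandatory RNG seed.
#' @return List with `dataset` (a [genotype_dataset()]) and `truth`
#'   (data frame `sample_id`, `chrom`, `start_bp`, `end_bp`, `n_snps` of
#'   the implanted tracts at SNP resolution).
#' @export
implant_roh_dataset <- function(n_samples = 10L, n_chrom = 2L,
                                snps_per_chrom = 600L,
                                mean_spacing_bp = 85000,
                                het_prob = 0.35, implants = NULL,
                                miss_prob = 0, population = "SIM",
                                seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  maps <- lapply(seq_len(n_chrom), function(ch) {
    gaps <- runif(snps_per_chrom, 0.5, 1.5) * mean_spacing_bp
    data.frame(marker_id = sprintf("c%d_s%d", ch, seq_len(snps_per_chrom)),
               chrom = ch, pos_bp = round(cumsum(gaps)),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map$allele_a <- "A"; map$allele_b <- "B"; map$cm <- map$pos_bp / 1e6
  n_mark <- nrow(map)
  geno <- matrix(sample(c(0L, 1L, 2L), n_samples * n_mark, replace = TRUE,
                        prob = c((1 - het_prob) / 2, het_prob,
                                 (1 - het_prob) / 2)),
                 n_samples, n_mark)
  if (miss_prob > 0)
    geno[runif(length(geno)) < miss_prob] <- NA_integer_
  truth <- NULL
  if (!is.null(implants) && nrow(implants)) {
    for (k in split(seq_len(nrow(implants)), implants$sample)) {
      spans <- implants[k, , drop = FALSE]
      for (ch in unique(spans$chrom)) {
        s <- spans[spans$chrom == ch, , drop = FALSE]
        if (nrow(s) > 1L) {
          o <- order(s$start_bp)
          e <- s$start_bp + s$length_bp - 1
          if (any(s$start_bp[o][-1L] <= e[o][-nrow(s)]))
            stop("overlapping implants on sample ", s$sample[1L],
                 " chromosome ", ch)
        }
      }
    }
    rows <- list()
    for (i in seq_len(nrow(implants))) {
      sm <- implants$sample[i]; ch <- implants$chrom[i]
      a <- implants$start_bp[i]; b <- a + implants$length_bp[i] - 1
      j <- which(map$chrom == ch & map$pos_bp >= a & map$pos_bp <= b)
      if (!length(j))
        stop("implant ", i, " covers no markers")
      geno[sm, j] <- 0L
      rows[[i]] <- data.frame(sample_id = sprintf("%s_%d", population, sm),
                              chrom = ch, start_bp = map$pos_bp[min(j)],
                              end_bp = map$pos_bp[max(j)],
                              n_snps = length(j))
    }
    truth <- do.call(rbind, rows)
  }
  samples <- data.frame(sample_id = sprintf("%s_%d", population,
                                            seq_len(n_samples)),
                        population = population, stringsAsFactors = FALSE)
  list(dataset = genotype_dataset(geno, map, samples),
       truth = if (is.null(truth))
         data.frame(sample_id = character(0), chrom = integer(0),
                    start_bp = numeric(0), end_bp = numeric(0),
                    n_snps = integer(0)) else truth)
}

#' Linear effective-size decline helper
#'
#' Builds a per-generation N vector: `burn_in` generations at `from`,
#' then a linear decline `from -> to` over `gens` generations (the
#' shape of a century-scale bottleneck such as 140 -> 20 in 20
#' generations).
#'
#' @param from,to effective sizes at the start and end of the decline.
#' @param gens generations of decline.
#' @param burn_in constant-size generations prepended.
#' @return Integer vector of per-generation sizes, oldest first.
#' @export
ne_decline <- function(from = 140L, to = 20L, gens = 20L, burn_in = 20L) {
  c(rep(from, burn_in), round(seq(from, to, length.out = gens)))
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Discrete generations; each offspring draws two parents uniformly
#' (selfing allowed) from the previous generation; gametes recombine as
#' a Poisson process at 1 crossover/Morgan (Haldane, no interference).
#' Founders carry maximally diverse haplotypes (a private label per
#' founder haplotype at every locus); at sampling each locus is resolved
#' to a biallelic SNP by randomly splitting founder labels into two
#' allelic classes, and loci with MAF below `maf_min` are dropped.
#' Pedigree inbreeding of the sampled individuals is computed from the
#' recorded pedigree by the standard kinship recursion.
#'
#' @param ne vector of per-generation population sizes, oldest first
#'   (e.g. from [ne_decline()]); the first entry is the founder count.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_m chromosome length in Morgans.
#' @param loci_per_chrom candidate loci per chromosome (equally spaced).
#' @param n_sample diploids sampled (without replacement) from the final
#'   generation.
#' @param maf_min minimum minor allele frequency of retained loci; 0
#'   keeps every locus, including fixed ones.
#' @param recomb_rate_per_bp Morgans per bp used to place loci on the
#'   physical map (default 1e-8, i.e. 1 cM/Mb).
#' @param population population label.
#' @param seed mandatory RNG seed.
#' @return List with `dataset` (a [genotype_dataset()]), `trajectory`
#'   (data frame `generations_ago`, `n` — the truth the LD estimator
#'   should recover), and `f_ped` (named pedigree-inbreeding vector of
#'   the sampled individuals).
#' @export
simulate_wf <- function(ne, n_chrom = 10L, chrom_length_m = 1,
                        loci_per_chrom = 500L, n_sample = 40L,
                        maf_min = 0.05, recomb_rate_per_bp = 1e-8,
                        population = "WF", seed) {
  if (missing(seed)) stop("a seed is required")
  ne <- as.integer(round(ne))
  if (any(ne < 2L)) stop("every generation must have N >= 2")
  G <- length(ne)
  if (n_sample > ne[G]) stop("cannot sample ", n_sample, " from final N = ",
                             ne[G])
  set.seed(seed)
  pos_m <- lapply(seq_len(n_chrom), function(ch)
    seq(0, chrom_length_m, length.out = loci_per_chrom))
  # founder haplotypes: label = haplotype index at every locus
  haps <- lapply(seq_len(n_chrom), function(ch)
    matrix(rep(seq_len(2L * ne[1L]), loci_per_chrom), 2L * ne[1L],
           loci_per_chrom))
  # kinship of the current generation with itself; founders unrelated
  phi <- diag(0.5, ne[1L])
  f_ind <- rep(0, ne[1L])
  if (G > 1L) for (g in 2:G) {
    Np <- ne[g - 1L]; Nn <- ne[g]
    sire <- sample.int(Np, Nn, replace = TRUE)
    dam <- sample.int(Np, Nn, replace = TRUE)
    parent <- as.integer(rbind(sire, dam))  # gametes 2i-1, 2i
    haps <- lapply(seq_len(n_chrom), function(ch)
      meiosis_cpp(haps[[ch]], parent, pos_m[[ch]]))
    f_ind <- phi[cbind(sire, dam)]          # F = kinship of the parents
    phi_new <- 0.25 * (phi[sire, sire, drop = FALSE] +
                       phi[sire, dam, drop = FALSE] +
                       phi[dam, sire, drop = FALSE] +
                       phi[dam, dam, drop = FALSE])
    diag(phi_new) <- 0.5 * (1 + f_ind)
    phi <- phi_new
  }
  pick <- sort(sample.int(ne[G], n_sample))
  hap_rows <- as.integer(rbind(2L * pick - 1L, 2L * pick))
  # resolve founder labels to biallelic SNPs: random binary split per locus
  maps <- list(); genos <- list()
  for (ch in seq_len(n_chrom)) {
    h <- haps[[ch]][hap_rows, , drop = FALSE]
    split_b <- matrix(rbinom(2L * ne[1L] * loci_per_chrom, 1L, 0.5),
                      2L * ne[1L], loci_per_chrom)
    b <- matrix(split_b[cbind(as.vector(h),
                              rep(seq_len(loci_per_chrom),
                                  each = nrow(h)))],
                nrow(h), loci_per_chrom)
    g <- b[seq(1L, nrow(b), 2L), , drop = FALSE] +
         b[seq(2L, nrow(b), 2L), , drop = FALSE]
    p <- colMeans(g) / 2
    keep <- pmin(p, 1 - p) >= maf_min
    if (!any(keep)) next
    pos_bp <- round(pos_m[[ch]] / recomb_rate_per_bp) + 1
    maps[[length(maps) + 1L]] <- data.frame(
      marker_id = sprintf("c%d_s%d", ch, which(keep)),
      chrom = ch, pos_bp = pos_bp[keep], cm = 100 * pos_m[[ch]][keep],
      allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
    genos[[length(maps)]] <- g[, keep, drop = FALSE]
  }
  if (!length(maps)) stop("no polymorphic loci retained")
  map <- do.call(rbind, maps)
  geno <- do.call(cbind, genos)
  storage.mode(geno) <- "integer"
  ids <- sprintf("%s_%d", population, seq_len(n_sample))
  samples <- data.frame(sample_id = ids, population = population,
                        stringsAsFactors = FALSE)
  list(dataset = genotype_dataset(geno, map, samples),
       trajectory = data.frame(generations_ago = (G - 1):0, n = ne),
       f_ped = setNames(f_ind[pick], ids))
}

#' Random non-overlapping candidate regions
#'
#' Draws `n_regions` non-overlapping intervals over the genome spanned
#' by a marker map, together covering about `genome_fraction` of it —
#' a stand-in for externally reported selection-signature intervals.
#'
#' @param map a marker map (`chrom`, `pos_bp`).
#' @param n_regions number of intervals.
#' @param genome_fraction total fraction of the covered genome to span.
#' @param seed mandatory RNG seed.
#' @return A [genomic_intervals()] object.
#' @export
make_candidate_regions <- function(map, n_regions, genome_fraction = 0.05,
                                   seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_regions == 0L)
    return(genomic_intervals(integer(0), numeric(0), numeric(0)))
  set.seed(seed)
  spans <- covered_chromosome_lengths(map)
  chroms <- as.integer(names(spans))
  total <- sum(spans)
  target <- genome_fraction * total
  if (target > 0.8 * total)
    stop("requested span exceeds the genome")
  len <- target / n_regions
  if (len >= min(spans))
    stop("regions too long for the shortest chromosome")
  out <- vector("list", n_regions)
  placed <- lapply(chroms, function(ch) cbind(numeric(0), numeric(0)))
  names(placed) <- as.character(chroms)
  for (k in seq_len(n_regions)) {
    for (try in 1:1000) {
      ch <- sample(chroms, 1L, prob = spans)
      lo <- min(map$pos_bp[map$chrom == ch])
      hi <- max(map$pos_bp[map$chrom == ch]) - len
      if (hi <= lo) next
      a <- lo + floor(runif(1) * (hi - lo))
      b <- a + ceiling(len) - 1
      p <- placed[[as.character(ch)]]
      if (nrow(p) && any(a <= p[, 2L] & b >= p[, 1L])) next
      placed[[as.character(ch)]] <- rbind(p, c(a, b))
      out[[k]] <- data.frame(chrom = ch, start_bp = a, end_bp = b)
      break
    }
    if (is.null(out[[k]])) stop("could not place non-overlapping regions")
  }
  df <- do.call(rbind, out)
  o <- order(df$chrom, df$start_bp)
  genomic_intervals(df$chrom[o], df$start_bp[o], df$end_bp[o],
                    sprintf("region_%d", seq_len(n_regions)))
}
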