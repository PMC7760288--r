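---
title: "ROH detection, genomic inbreeding and LD-based Ne: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROH detection, genomic inbreeding and LD-based Ne: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohne)
```

## Scope and model

`rohne` analyses diploid SNP-array genotypes (typically a bovine 50K
panel: ~30–40k autosomal markers on 29 autosomes, a few dozen animals
per population) for three linked questions about small, closed
populations:

1. **Where is the genome autozygous?** Runs of homozygosity (ROH) —
   long stretches where every genotyped marker is effectively
   homozygous — mark segments inherited identical-by-descent from a
   common ancestor. Long ROH (> 8–16 Mb) reflect recent inbreeding,
   shorter ones older inbreeding, because recombination breaks segments
   at ~1 crossover per Morgan per meiosis.
2. **How inbred is each animal?** The genomic inbreeding coefficient
   `F_ROH = S_ROH / L_AUTOSOME`, the summed ROH length over the
   autosomal length covered by markers, globally, cumulatively by
   minimum segment length, and per chromosome
   (`F_ROH_BTA = sum(L_ROH_BTA) / L_BTA`).
3. **How fast is the population losing diversity?** Linkage
   disequilibrium at recombination distance `c` reflects the effective
   population size roughly `t = 1/(2c)` generations ago through the
   drift expectation `E[r2] = 1/(alpha + 4 N c)`. Inverting it per
   distance bin yields an Ne trajectory:
   `N_T = (4 f(c_t))^-1 (E[r2_adj]^-1 - alpha)`.

## Marker QC

Filters run in a fixed order — call rate (`geno > 0.1` removed), minor
allele frequency (`MAF < 0.01` removed), exact Hardy–Weinberg test
(`p < 0.01` removed) — and each removed marker is attributed to the
first filter that fails it, so the report's counts reconcile exactly.
The HWE test enumerates all heterozygote counts compatible with the
observed allele counts and sums the probabilities of configurations no
more likely than the observed one (the conventional two-sided exact
test, no mid-p).

LD pruning follows: within 50-SNP windows stepping by 5, while any
retained pair has composite r² above 0.5, the lower-MAF member of the
worst pair is dropped (tie: later position). The window/step/threshold
triple is not dictated by the analysis the package mirrors (only the
before/after marker counts were reported), so the defaults are the
common PLINK-style ones and all three are arguments.

The pipeline's `all` command applies the pruned set to ROH/F_ROH and
the unpruned QC'd set (with MAF ≥ 0.05 applied internally) to Ne
estimation. The underlying study is ambiguous about which set fed
which analysis; this split follows the stated marker counts (38,789
for Ne, 33,038 after pruning for the ROH statistics) and both sets are
always written to disk so the other choice costs one flag.

## ROH calling

Detection is PLINK-style, window-based: 20-SNP sliding windows with at
most one heterozygous and one missing call are "homozygous-compatible";
each SNP's support is the fraction of windows containing it that are
compatible (edge SNPs are spanned by fewer windows); SNPs at support ≥
0.05 are candidates; maximal candidate stretches are split at inter-SNP
gaps > 1 Mb and kept when ≥ 4 Mb long, ≥ 20 SNPs, and ≥ 1 SNP/100 kb
dense. Segments below 4 Mb are deliberately out of scope: at 50K
density they are unreliable.

Design points a maintainer should know:

* Run length is `pos_last - pos_first + 1` (1-based inclusive): the
  coordinates of observed SNPs, with no extrapolation into the
  flanking intervals.
* Heterozygous calls *can* sit inside a reported run — the window
  definition governs, as with PLINK's `--homozyg`; a strict per-run het
  cap is intentionally not applied.
* Density is evaluated on the run's own SNP count and length, after
  the length test.
* Chromosomes with fewer SNPs than one window are skipped with a
  warning.
* Size classes (4–8, 8–16, > 16 Mb) are left-closed/right-open, so 16.0
  Mb is "> 16"; the three classes partition [4 Mb, ∞).
* The caller is validated against an exhaustive window-enumeration
  oracle on hundreds of random small chromosomes, and against implant
  fixtures with known tract boundaries.

## F_ROH statistics

`froh_individual()` reports, per animal, the total and the cumulative
fractions for segments ≥ 4, ≥ 8 and ≥ 16 Mb. Cumulative (not
per-class) values are what the package mirrors in its
population-summary output: the published per-interval table this
design reproduces only reconciles as threshold-cumulative sums of the
per-class contributions, and the package's worked-example test
reproduces those cells from per-class counts and means alone.
Per-class descriptives (`class_summary()`) report counts, within-class
frequency percentages, mean/SD/CV of segment length in Mb, and a
normal-approximation 95% CI (`mean ± 1.96 SD/√n`) — the CI method is
unstated in the mirrored work; the normal approximation reproduces its
printed intervals to the reported precision. Reports round F_ROH to 3
decimals and percentages to 1, matching the field's convention.

`L_AUTOSOME` defaults to 2,504,168,970 bp (the 50K-covered bovine
autosome) and is configurable; per-chromosome denominators always come
from the actual map span (`max(pos) - min(pos) + 1`), never from a
reference genome, so the conservation identity
`sum_chrom(F_ROH_BTA * L_BTA) = S_ROH` holds exactly.

## Ne estimation

For each population: markers at MAF ≥ 0.05, all intra-chromosomal
pairs with physical distance in `[mindist, maxdist]` (defaults 1.4–50
Mb, probing roughly generations 1–35 at 1 cM/Mb), composite r² from
0/1/2 dosages over pairwise-complete samples. Pairs are binned by the
generation their distance probes (`t = 1/(2c)`), each bin's mean r² is
adjusted by `1/(2n)` for unphased genotype LD (`1/n` if phased), and
the drift expectation is inverted per bin. Bins with < 50 pairs, a
floored adjusted r², or a negative implied size are suppressed or
flagged `NA` rather than reported.

Numerical/design choices:

* **The inversion formula.** The source text's equation is
  typographically corrupted; the package implements the SNeP/Corbin
  form `N_T = (4 f(c_t))^-1 (E[r2_adj]^-1 - alpha)` and unit-tests the
  exact inversion identity against the closed-form expectation on an
  (N, c) grid.
* **alpha** defaults to 2.2 (mutation-inclusive correction); 1 and 2
  are the other conventional values, exposed as a flag. At the
  distances probed here the alpha choice shifts `N_T` by
  `Δalpha/(4c)` — about 10 animals at c = 0.024 — which the CLI test
  verifies analytically.
* **Mapping** from bp to Morgans is linear at 1 cM/Mb by default (no
  bovine recombination map is shipped); Haldane and a second-order
  Sved–Feldman mapping are selectable, all capped at c = 0.5.
* **Binning by integer target generations** (not equal-width distance
  bins) makes the output directly a (t, N_T) series with strictly
  increasing t.
* Sample-size adjustment is applied to the bin mean; being linear this
  equals per-pair adjustment, and a floored (≤ 0) mean invalidates the
  bin.

## The synthetic-data generators

Real genotypes for the motivating study are not deposited anywhere, so
the package ships two generators that are first-class, tested code:

* `implant_roh_dataset()` draws background genotypes heterozygous with
  probability 0.35 (the remainder split between the homozygotes) at
  ~85 kb spacing — 50K-chip-like — and forces listed spans to
  homozygosity, recording exact SNP boundaries. It emulates marker
  density and known tract positions; it does **not** emulate LD,
  allele-frequency spectra or relatedness, so a green implant test
  establishes boundary accuracy and filter behaviour, not population
  realism.
* `simulate_wf()` is a forward Wright–Fisher simulation: discrete
  generations of arbitrary size `N(g)`, uniform parent choice with
  selfing, gametes recombined as a Poisson process at 1
  crossover/Morgan (Haldane, no interference; the hot loop is a small
  Rcpp kernel using R's RNG, so results are seed-reproducible).
  Founders carry a private label per haplotype at every locus; at
  sampling each locus is resolved to a biallelic SNP by an independent
  random binary split of founder labels (approximate linkage
  equilibrium at founding — drift alone then builds LD), and loci
  below the MAF floor are dropped. The recorded pedigree yields exact
  pedigree inbreeding for every sampled animal, which is what lets the
  suite check that F_ROH ranks animals like pedigree F does. A
  forward (rather than coalescent) simulator was chosen precisely for
  that pedigree. There is no mutation, selection, migration or
  realistic recombination map; consequences: the drift expectation
  with alpha = 1 fits the simulated LD (the mutation-inclusive 2.2 is
  still the analysis default), and very long constant-size runs slowly
  lose polymorphism.
* Default scenario: a census declining 140 → 20 over 20 generations
  after a 20-generation burn-in — the bottleneck shape the package's
  motivating populations show. The CLI floors the census at the
  requested sample size, since one cannot sample 40 diploids from a
  census of 20; the published n = 40 against Ne ≈ 23 is an effective,
  not census, size.

## Degenerate inputs and tie-breaks

* Monomorphic marker pairs have undefined r² and are dropped from LD
  collection; `r2_composite()` returns `NA` for them and for < 2
  complete observations.
* `hwe_exact_test(0, 0, 0)` is an error (undefined), not a p-value.
* Merging datasets intersects markers by id and reconciles swapped
  allele orientation by letter matching (never by frequency);
  irreconcilable allele sets are an error listing the marker ids.
* PED reading defines `allele_a` as the first allele observed
  (lexicographic tie-break on a heterozygous first observation).
  Consequently write-then-read is the identity on read-produced
  datasets; a hand-built dataset whose first non-missing genotype is
  homozygous-b re-reads with flipped codes. Every analysis in the
  package is orientation-invariant, so this canonicalization is
  harmless.
* LD-pruning ties (equal MAF) drop the later map position,
  deterministically.

## Known limitations

* ROH below 4 Mb are not called, by design; the package says nothing
  about ancient (> ~12 generations) inbreeding.
* Ne estimates inherit the usual LD-method caveats: sensitivity to
  alpha at small c, to the sample-size correction, and to the phase
  assumption; no confidence intervals (jackknife) are provided.
* The acceptance-grade simulation checks recover a constant N = 100
  within ±25% and a decline's direction, not absolute trajectories of
  real data.
* Per-sample QC, imputation, phasing, sex chromosomes, gene annotation
  and enrichment analysis are out of scope.
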