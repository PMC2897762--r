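---
title: "Methods: comparative nucleosome architecture from mononucleosome reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative nucleosome architecture from mononucleosome reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucarch)
library(dplyr)
```

# Scope and model

nucarch reconstructs promoter and terminator chromatin organisation in small
eukaryotic (yeast-like) genomes from mononucleosome sequencing read
alignments, and asks how three determinants — transcription, intrinsic
anti-nucleosomal sequence, and general regulatory factor (GRF) binding —
shape nucleosome-free regions (NFRs). The pipeline is:

1. **Occupancy landscape.** Reads are extended to 100 bp from their 5' end
   and summed per base. Bases that a 36 bp read cannot uniquely place
   (k-mer seen more than once, counting both strands) are masked, as are
   bases whose raw coverage exceeds 10 times the median (rDNA-like pileups).
   The remaining values are divided by their mean, so unmasked occupancy
   averages 1 and tracks are comparable across sequencing depths.
2. **Fragment length.** Plus-strand read starts and minus-strand read ends
   flank each protected fragment symmetrically, so the Pearson
   cross-correlation between the two per-base start profiles peaks at the
   fragment length. The peak's second moment is reported as its spread.
3. **Nucleosome calls.** Each read start is shifted by half the fragment
   length toward the dyad it represents, a Gaussian kernel (sd 30 bp,
   truncated at 4 sd) is summed at the shifted centers (a Parzen-window
   density), and local maxima become candidate dyads. Candidates are
   accepted tallest first; a candidate whose 147 bp footprint would overlap
   an accepted call by more than 20 bp is discarded, so accepted dyads are
   at least 127 bp apart. Per call we report occupancy (footprint mean of
   the normalized track), fuzziness (sd of contributing shifted centers
   within ±73 bp) and width (full width at half maximum clipped at flanking
   minima). Fuzziness and width are our stated interpretations of feature
   names whose exact formulas are not public.
4. **NFRs.** Calls with occupancy below 40% of the mean call occupancy are
   removed; the linkers (gaps between remaining 147 bp footprints) within
   1,000 bp upstream/downstream of each gene — truncated at neighboring
   ORFs — are examined, and the linker longer than 60 bp nearest the gene
   end is the NFR (falling back to the first linker, flagged, when none
   qualifies). The NFR edge nearest the ATG is the TSS prediction. A
   26-feature vector per gene summarises both NFRs and their bounding
   nucleosomes (Nuc+1, Nuc-1, the last genic nucleosome, the first
   downstream one): lengths, occupancies, occupancy contrasts, fuzziness,
   widths, and median adjacent spacings.
5. **Enrichment.** For any per-gene quantity and gene set, the two-sample
   Kolmogorov–Smirnov statistic (set versus all other genes) is converted
   to a signed score `S = ±log10(P)`, positive when the set's values are
   high. P-values use the asymptotic Smirnov distribution with effective
   sample size n1·n2/(n1+n2) and the small-sample correction of Stephens;
   Benjamini–Hochberg controls the FDR at 5% per feature across sets. Gene
   sets travel between species through orthogroup projection (union of
   orthologs, sets under 10 members skipped).
6. **Variance partitioning.** A robust Lowess fit whose smoothing window is
   10% of the *span of the predictor* (not a nearest-neighbour fraction of
   n — see Numerical choices) explains each chromatin feature from a
   determinant; percent variance explained is `(1 − var(resid)/var(y))·100`.
   Determinants are fit successively on residuals (expression, then
   Poly(dA:dT) strength, then GRF motif affinity), each step referenced to
   the original variance so steps sum to the cumulative total.
7. **Sequence depletion.** On the log2, z-normalized track, every n-mer
   class (n-mer merged with its reverse complement) is scored by the mean
   negative z over all its instances; Poly(dA:dT) tracts (maximal A or T
   runs of ≥5 bp with up to k = 0..20 mismatches, endpoints matching) are
   scored per (length, k) class, with a count-weighted line fit of score
   versus length substituting for classes with fewer than 100 occurrences.
   Folds (2^score) are quantized to the highest of 2/4/8/16/32 exceeded,
   and tracts are aggregated over increasing k, a higher-k tract replacing
   overlapped lower-k tracts only on a strictly higher quantized level.
8. **Motifs.** Promoters (≤1,000 bp upstream, truncated at neighbor ORFs)
   are scanned with PWMs against an order-3 Markov background estimated
   from the full promoter set; per-site p-values are exact
   (score-distribution enumeration) for motifs up to 10 bp and fixed-seed
   Monte Carlo beyond. Sites are binned by center into Nuc+1, 5'NFR, Nuc-1,
   Nuc-2 and NFR2 (the Nuc-1/Nuc-2 linker); Linkers-vs-Nucs contrasts in
   inherited gene expression classify motifs as activator- or
   repressor-like, and a paired Wilcoxon signed-rank test measures each
   motif's preference for locally depleted sequence. NFR affinity is the
   summed PWM-to-background likelihood ratio over all window positions and
   both strands.

# The synthetic data generator

Every stage is exercised on generated data with exported ground truth. One
"species" is a single chromosome of i.i.d. uniform A/C/G/T sequence carrying
non-overlapping gene cassettes: two upstream nucleosomes, a 5' NFR, a genic
nucleosome array, and a 3' NFR. The defaults are the package's reference
study conditions, chosen once to resemble budding-yeast promoter
architecture at desk scale:

* 60 genes (in tests: exactly 20 each of the growth/stress/neutral classes),
  ~1.8 kb cassette, chromosome ~95 kb;
* inter-dyad spacing 165 bp; 6 genic nucleosomes; 3' NFR 80 bp;
* 5' NFR width by class: growth 150, stress 80, neutral 110 bp — growth
  promoters are wide and deep, stress promoters narrow and partially
  occupied (NFR "fill" fragments at rates 0 / 0.4 / 0.15 of per-dyad
  coverage);
* expression class means +2 / −2 / 0 log2 with Gaussian noise (sd 0.5);
* growth 5' NFRs carry a centered Poly(dA:dT) tract (probability 0.8,
  length 8–20 bp) and GRF motif sites; stress genes carry a motif under
  their Nuc-1 nucleosome. An activator-like motif is planted in growth NFRs
  *and* under stress genes' Nuc-1 (functional high-expression context
  versus non-functional low-expression context), and a repressor-like motif
  mirrored, so the Linkers/Nucs expression contrast has sites in both
  classes;
* reads: 30 fragments per dyad, fragment length 147 ± 8 bp, center jitter
  sd 10 bp, 36 bp reads from both fragment ends. An "in vitro"-like mode
  places fragments uniformly except for rejection over planted tracts, so
  the in vivo/intrinsic contrast can be emulated without GRF effects.

What the generator does *not* emulate: sequence divergence between species
(orthologous genes share classes and, across species, differ only in the
configured spacing/width/rate overrides), codon structure, overlapping or
divergent transcription beyond ORF truncation, MNase sequence bias, and PCR
duplicates. Passing recovery tests therefore demonstrates the estimators'
correctness under the stated noise model, not performance on real MNase
libraries.

# Numerical choices

* **Coordinates** are 0-based half-open internally; writers convert.
* **Minus-strand reads** are stored by genomic start plus strand; the
  cross-correlation indexes them by their half-open end, so the recovered
  shift equals the fragment length exactly in the noise-free case.
* **Kernel truncation** at 4 sd bounds cost with error <1e-4 of peak;
  greedy ties break to the leftmost dyad for determinism.
* **Odd fragment lengths** shift by floor(L/2).
* **Outlier masking** is a single pass, and the median is taken over all
  unmasked bases including zeros (zeros are real absence of signal).
* **The z-track pseudocount** (default 0.01 on the normalized scale) keeps
  log2 of zero-occupancy bases finite.
* **Lowess bandwidth**: most library implementations take a fraction of the
  number of points; here the window is a fraction of the predictor *range*
  (half-width = window_frac·span/2) with tricube weights, which is what a
  fixed "10% of the span of expression values" means. Degenerate windows
  fall back to the nearest weighted points; outliers are detected once from
  a non-robust first pass (residual > 6 sd) and zero-weighted in a single
  refit.
* **Per-step partition percentages** are referenced to the original
  response variance (so they sum to the cumulative); the per-step-local
  variant is emitted alongside because either reading of the procedure is
  defensible.
* **K-S ties** are handled by right-continuous ECDFs evaluated at pooled
  points; at K = 0 the asymptotic series is replaced by P = 1. FDR is
  stratified per feature across gene sets within a species.
* **The 40% occupancy floor** is relative to mean *call* occupancy (the
  floor filters calls, so the natural reference is the call population).
* **n-mer instance value** is the mean −z over the n bases themselves — the
  smallest unbiased footprint. Rankings are reported among classes with at
  least 10 genomic instances: on a ~100 kb toy genome a class with one or
  two instances can top the table by landing in a single depleted spot,
  which is sampling noise of exactly the kind the <100-occurrence line-fit
  rule addresses for tracts.
* **NFR Poly(dA:dT) strength** sums quantized levels of tracts whose
  midpoint falls in the NFR; the max-level variant is emitted alongside
  since the aggregation is not otherwise pinned down.
* **Motif p-value enumeration** is exact to motif length 10 (4^10 weighted
  sequences); beyond that a fixed-seed Monte Carlo null is used. In
  property tests on the toy genome, architectural contrasts (GRF versus
  stress-factor NFR fractions) are evaluated at a stringent per-site
  threshold (2e-5) because at genome sizes of ~10^5 bp a 5% per-window
  threshold is dominated by chance near-matches; the expression-contrast
  tests use 1e-4.
* **Divergent promoters**: an instance in a promoter shared by two genes is
  assigned to each gene's frame separately.

# Design decisions that were genuinely open

* Linkers are measured between call *footprints* (dyad ± 73), not between
  dyads — linker DNA is the inter-nucleosomal sequence.
* Neighbor truncation of search regions uses annotated CDS intervals of any
  gene on either strand.
* `plus1_minus_nfr5_ocup` and its relatives are signed differences of mean
  occupancies.
* Genes whose searched region is fully masked keep all-NA feature vectors
  rather than being dropped; downstream statistics drop NAs explicitly.
* The greedy caller, the signed K-S score, the span-based robust Lowess and
  the tract machinery are implemented in the package itself; standard steps
  (BH adjustment, hypergeometric tails, Wilcoxon tests, linear fits) call
  base R.

# Problem sizes

The test-suite and acceptance computations run on the reference conditions
above: one ~95 kb chromosome, 60 genes, ~30k reads; 2,000 replicates for
K-S calibration; 20 replicates of n = 5,000 for variance recovery;
exhaustive enumeration for the permutation, hypergeometric, greedy and
tract oracles at small n. These sizes were chosen so each property is
measured with comfortable statistical margin on a single CPU.

# Known limitations

* Fuzziness/width are interpretations; real pipelines differ in detail.
* The asymptotic K-S p-value is approximate below ~10 observations per
  sample (the permutation oracle shows rank agreement, not equality).
* The caller is greedy; no HMM or template alternatives are provided.
* Paired-end logic, duplicate collapsing and alignment itself are out of
  scope: inputs are pre-aligned single-end-style records.
* Real-data headline figures from the literature (e.g. TSS prediction
  rates, cross-species variance-explained ranges) require the original
  twelve-species data and are treated as plausibility context only; nothing
  in this package asserts them.

# A worked mini-example

```{r example, eval = FALSE}
truth <- simulate_species(species_config(), seed = 1)
reads <- simulate_reads(truth, seed = 2)
glen <- c(chr1 = nchar(truth$genome[["chr1"]]))
track <- occupancy_track(reads, glen)
fl <- estimate_fragment_length(reads, glen)
calls <- call_nucleosomes(reads, glen, frag_len = fl$shift_bp) |>
  attach_occupancy(track)
nfrs <- find_nfrs(calls, track, truth$genes)
feats <- compute_features(calls, nfrs, track, truth$genes)
plot_average_profile(
  average_profile(track, truth$genes, anchor = "Nuc+1",
                  calls = calls, nfrs = nfrs),
  anchor_label = "Nuc+1")
```
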