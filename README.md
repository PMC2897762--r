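# nucarch

Comparative nucleosome-architecture analysis for small eukaryotic genomes,
from mononucleosome (MNase-seq) read alignments and gene annotations to
nucleosome calls, nucleosome-free regions (NFRs), per-gene chromatin
features, gene-set enrichments, determinant variance partitioning,
anti-nucleosomal sequence scores, and motif/nucleosome positioning
analyses. It is written for researchers studying how promoter chromatin
organisation — the depth and width of the 5' NFR, the placement of the
flanking Nuc+1/Nuc−1 nucleosomes, Poly(dA:dT) tracts and general
regulatory factor (GRF) sites — varies across genes and across related
yeast-like species.

## What it computes

* **Normalized occupancy tracks**: reads extended to 100 bp, summed per
  base, mappability- and outlier-masked (10× median), and scaled to mean 1.
* **Fragment length** by strand cross-correlation: the shift *s*
  maximizing cor(plus-starts, minus-ends shifted by *s*).
* **Nucleosome calls** by a Parzen-window density: Gaussian kernels
  (σ = 30 bp) at half-fragment-shifted read starts; local maxima accepted
  greedily, tallest first, with ≤ 20 bp footprint overlap (dyads ≥ 127 bp
  apart).
* **NFRs**: after dropping calls with occupancy < 40% of the mean call
  occupancy, the linker > 60 bp nearest each gene end within 1 kb
  (truncated at neighbor ORFs); the ATG-proximal NFR edge predicts the TSS.
* **Signed K-S enrichment** of any per-gene quantity in any gene set:
  *K* = max |ΔCDF| between set and background,
  *S* = ±log₁₀(*P*), positive when the set is shifted high; BH-FDR at 5%.
* **Percent variance explained**, (1 − σ²_R/σ²_D)·100, by robust Lowess
  fits whose smoothing window is 10% of the predictor span, applied
  successively over expression → Poly(dA:dT) → GRF affinity.
* **Anti-nucleosomal scores**: mean −z-normalized log2 occupancy over all
  instances of each n-mer class (reverse-complement merged, n = 5..8) and
  over Poly(dA:dT) tracts (maximal A/T runs ≥ 5 bp, k = 0..20 mismatches),
  with count-weighted line-fit fallback for rare lengths, 2/4/8/16/32-fold
  quantization, and non-overlapping aggregation across k.
* **Motif analysis**: PWM promoter scanning against an order-3 Markov
  background with exact per-site p-values, NFR affinity scores
  A(P,S) = Σₖ Πⱼ p(S,j)/b(S), binning of sites into
  Nuc+1 / 5'NFR / Nuc−1 / Nuc−2 / NFR2, activator/repressor calls from the
  Linkers-vs-Nucs expression contrast, and paired Wilcoxon tests of local
  depletion.
* A **synthetic multi-species generator** with exported ground truth
  (planted dyads, NFRs, tracts, motif sites, orthology, gene sets), so the
  whole pipeline is testable without any download.

## Worked example

```r
library(nucarch)
library(dplyr)

truth <- simulate_species(species_config(), seed = 1)   # ~95 kb, 60 genes
reads <- simulate_reads(truth, seed = 2)                # ~30k 36 bp reads
glen  <- c(chr1 = nchar(truth$genome[["chr1"]]))
track <- occupancy_track(reads, glen)

(fl <- estimate_fragment_length(reads, glen))
#> Fragment length estimate: 148 bp (peak sd 13.9 bp)

calls <- call_nucleosomes(reads, glen, frag_len = fl$shift_bp) |>
  attach_occupancy(track)
nrow(calls)        # 486 calls for 480 planted nucleosomes
nfrs  <- find_nfrs(calls, track, truth$genes)
feats <- compute_features(calls, nfrs, track, truth$genes)
expr  <- simulate_expression(truth, seed = 3)

d <- feats |> select(gene_id, nfr5_ocup, nfr5_len) |>
  left_join(select(expr, gene_id, expression), by = "gene_id")
growth <- tibble(set_id = "growth",
                 gene_id = truth$genes$gene_id[truth$genes$gene_class == "growth"])
ks_enrichment_table(d, growth)
#>   feature_id set_id  K_KS     P_KS  S_KS significant
#> 1  nfr5_ocup growth 0.925 3.63e-11 -10.4        TRUE
#> 2   nfr5_len growth 0.925 3.63e-11  10.4        TRUE
#> 3 expression growth 1.000 5.60e-13  12.3        TRUE
```

The fragment-length estimate (148 bp) recovers the simulated 147 ± 8 bp
fragments; the call count matches the planted nucleosomes to within a
handful of spurious peaks. The signed K-S scores read: growth genes have
*low* 5' NFR occupancy (S = −10.4: deep NFRs), *long* NFRs (S = +10.4) and
*high* expression (S = +12.3), all surviving FDR — the planted
growth/stress promoter dichotomy, recovered end to end from reads.

`successive_partition()`, `nmer_depletion_scores()`, `find_polya_tracts()`
/ `quantize_and_aggregate()`, and `scan_promoters()` /
`linker_vs_nuc_expression()` continue the analysis; see the methods
vignette (`vignettes/nucleosome-architecture.Rmd`) for the full model and
every numerical convention.

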