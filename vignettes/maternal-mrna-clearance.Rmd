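---
title: "Quantifying small-RNA-guided clearance of maternal mRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying small-RNA-guided clearance of maternal mRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztclear)
```

## The biological question and the measurements

During the maternal-to-zygotic transition (MZT), *C. elegans* embryos must
clear thousands of maternally deposited mRNAs from their somatic blastomeres
while zygotic transcription starts up. One clearance route runs through
antisense 22G-RNAs loaded into the catalytically active Argonaute CSR-1:
transcripts densely covered by CSR-1-bound 22G-RNAs are sliced and removed
faster than the bulk of cleared maternal mRNAs, in a dose- and
slicer-dependent way, and preferentially when they are no longer engaged by
ribosomes.

`mztclear` implements the quantitative side of that analysis as a reusable
pipeline. It begins where alignment ends — at per-gene count tables,
strand-aware nucleotide coverage, gene models and coding sequences — and
provides:

* **IP target calling**: a gene is a CSR-1 22G-RNA target when the ratio of
  normalized 22G abundance in the immunoprecipitate over the input is at
  least 2 and its IP abundance exceeds 1 RPM; targets are tiered by 22G
  density as (1, 50], (50, 150] and (150, Inf) RPM (`call_targets()`).
* **Staged classification**: maternal detection (1-cell TPM > 1, strict) and
  the four MZT classes plus early/late decay timing from (1-cell, early,
  late) mean TPM (`classify_mzt()`, `classify_decay_timing()`).
* **Per-gene statistics**: degradation rate (early/1-cell TPM ratio),
  degradation efficiency (log2 degradome/RNA), translational efficiency
  (log2 (RPF+1)/(RNA+1)), pseudocounted log2 fold changes and the
  observed/predicted enrichment factor over 20,447 protein-coding genes
  (`decay_metrics` functions).
* **Metaprofiles**: scaled TSS-to-TTS per-bin mean RPM of antisense 22G
  coverage over declared gene sets (`metaprofile()`), and the CDS vs 3'UTR
  partition of that coverage (`partition_cds_utr3()`).
* **Codon usage**: pooled relative synonymous codon usage per gene set
  (`rscu()`).
* **smFISH quantification**: two-step Gaussian enhancement, local-maximum
  spot detection and ROI counting (`detect_spots()`, `count_in_roi()`).
* **Statistics**: two-tailed Mann-Whitney-Wilcoxon comparisons, bootstrap
  median confidence intervals, type-7 box summaries and a per-gene
  rate-ratio test with Benjamini-Hochberg adjustment (`stats` functions).
* **A synthetic-data generator** that plants all of the structure above with
  known ground truth (`sim_config()`, `simulate_dataset()`), so the whole
  pipeline is testable end to end without any sequencing download.

`analyse_dataset()` runs everything on a dataset directory and
`run_report()` writes the derived tables and a summary annotated with group
sizes and p-values.

## Normalization conventions

TPM is computed by first normalizing counts by the transcript union exon
length in kilobases (RPK) and then by the per-sample total RPK in millions,
so every non-empty sample column sums to exactly 1e6. RPM divides by the
total counted reads of the library (column sums by default; an explicit
library-size vector can be supplied). Replicates are averaged in normalized
space — mean TPM/RPM — never on raw counts. No pseudocounts are applied at
normalization time; the pseudocount of 1 enters only where a ratio is
formed from possibly-zero abundances (translational efficiency, generic
fold changes). Nascent-transcription (GRO) counts flow through the same TPM
path as RNA-seq.

## Classification rules and their precedence

The class definitions use two declared thresholds: detection at TPM > 1
(strict; "undetectable" is TPM < 1, so a gene at exactly 1 is unclassified)
and a twofold change. Twofold is printed only for the early/late-degraded
definitions; we adopt the same factor for "diminished", "stable" and
"increase" in the four MZT classes for coherence, and both thresholds are
arguments. Profiles satisfying several descriptions are resolved by a fixed
precedence — maternal-and-zygotic (a twofold rise in either stage) is tested
first, because zygotic accumulation is its distinguishing feature, then
cleared, stable, newly zygotic, else unclassified. The rules are total and
mutually exclusive: every profile receives exactly one class and one decay
timing (property-tested over an exhaustive grid). Whether the published
classes were disjoint is not stated; exclusivity is our declared choice.

## What the generator emulates — and what it does not

The generator is the package's study system; its defaults are fixed
conditions, not tuning knobs:

* 5,000 genes, 500 planted targets, 3 replicates per library, negative
  binomial counts with dispersion 0.05 (the standard RNA-seq noise model),
  library sizes of 10-30 million reads.
* Class composition (19% cleared, 15% stable, 10% newly zygotic, 28%
  maternal+zygotic of genes, the rest background) loosely mirroring the
  published proportions without claiming their exact counts.
* Cleared kinetics with a fast archetype (early multiplier 0.3, late 0.1;
  30% of cleared genes) and a slow archetype (0.75, 0.2); stable genes flat;
  maternal+zygotic genes deposited at 0.3x the maternal baseline and rising
  threefold by the late stage; per-gene log-normal jitter (SD 0.08) spreads
  the kinetics.
* Targets are drawn mostly (75%) from cleared genes with uniformly assigned
  density tiers and tier-specific slicing boosts (1.5x/2.5x/4x extra decay
  under an active slicer); the remainder are low-density (T1) targets on
  translated stable mRNAs carrying 3'UTR-only 22G coverage — the reporter
  logic in which a 3'UTR from a stable transcript protects the fused coding
  sequence. Targets are deposited at twice the baseline, matching the
  observation that high-density targets are inherited at higher levels.
* IP/input enrichment effects of 4-8x for targets and 1x for non-targets;
  planted per-sample RPMs are rescaled to sum to 1e6 so the column-sum RPM
  estimator is consistent with the planted values.
* Antisense coverage densities per region: 2.0 RPM/nt on the 3'UTR for all
  targets, 1.0 on the CDS for the early archetype versus 0.05 for the late
  archetype, 0.1 on the 5'UTR. Coverage amplitude is deliberately uniform
  across targets (not scaled by each gene's IP RPM) so the planted
  early/late body-density ratio is exact.
* Degradome expectation proportional to RNA level times slicing flux (boost
  under an active slicer, baseline 0.05 otherwise); ribosome-protected
  fragments proportional to RNA level times a planted translation level that
  is low (0.05-0.3) for early-degraded targets and high (0.5-1) for
  late-degraded ones.
* smFISH images: 128x128 pixels, Gaussian background noise (SD 10 over a
  level of 100), planted Gaussian spots (sigma 1.5 px, amplitude 50 = 5x the
  noise SD, minimum separation 8 px), a somatic ROI covering the left two
  thirds, and three times as many ROI spots under depletion (30 vs 10) with
  a few germline-region spots under both conditions.

Two structural choices deserve emphasis. First, **mass conservation**: TPM
is compositional, so the planted per-stage totals are balanced — newly
zygotic transcripts absorb exactly the mass the cleared transcripts lose,
struck under the active-slicer condition and shared across conditions
(zygotic output does not depend on the slicer). Without this, the estimator
rescales every stage ratio by a global factor and entire classes drift onto
classification boundaries; real embryos avoid the same artifact by actually
replacing degraded maternal mass with zygotic transcripts. Second,
**self-consistent truth**: the planted class labels are obtained by applying
the classifier's own rules to the noise-free expected stage TPM of the
control condition. Slicing reshapes target kinetics, so labels fixed before
the boost would disagree with what the data actually encode; deriving them
from the realized expectation makes label recovery a pure measurement of
noise, which is what the recovery tests are meant to quantify.

What the generator does *not* emulate: multi-mapping ambiguity, positional
coverage biases, between-sample composition artifacts beyond the planted
classes, sequence-dependent 22G biogenesis, germ-granule spatial structure,
or read-level data. Passing tests on this generator therefore demonstrate
that the pipeline's inference is correct when its assumptions hold — not
that those assumptions hold in any particular sequencing run.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; coverage lives on the
  spliced transcript, 5' to 3' in transcript orientation, which matches the
  union-exon-length accounting. Genomic-space (flank) metaprofiles are out
  of scope, so `flank_bins` must be 0.
* Binning splits a transcript into maximally equal spans with longer spans
  first; transcripts shorter than the bin count are rejected rather than
  padded. Metaprofile averaging is unweighted per gene (each gene counts
  once); a coverage-weighted mode exists behind a flag.
* Ratio conventions: IP/input with a zero input and positive IP is +Inf and
  still a target (absence from the input cannot disqualify an enriched
  gene); 0/0 is no call. Zero-RNA genes are excluded from degradation
  efficiency, and zero-degradome genes are reported missing rather than
  -Inf so medians stay defined. Degradation rate is reported as a plain
  ratio, not a log.
* The Mann-Whitney test uses the exact null for combined n <= 16 without
  ties and a tie-corrected normal approximation with continuity correction
  otherwise. Median confidence intervals use the percentile bootstrap
  (seed-pinned; no particular interval construction is standard for these
  figures, so the choice is declared). Quantiles are type 7.
  The per-gene "adjusted p" test is a declared stand-in — an exact binomial
  rate-ratio test against the library-proportion expectation with BH
  adjustment — since the published method behind that cutoff is unnamed and
  dispersion-modelled differential testing is out of scope.
* Spot detection enhances with a large-kernel background subtraction
  (clamped at zero) followed by a small matched kernel, both with mirror
  padding. Because the clamp leaves a positive noise floor, the automatic
  threshold is a robust z-score — median plus k times the MAD-based SD of
  the enhanced image — rather than a bare multiple of the noise SD; with a
  bare multiple the threshold sits inside the noise floor and precision
  collapses. The default k = 5 reflects that a 2-D image tests ~16,000
  pixels at once: at 3 robust SDs dozens of noise maxima per image survive,
  while 5 SDs keeps false positives near zero yet detects amplitude-5x-noise
  spots, whose matched-filter response sits far above the cut. Maxima
  within one spot-sigma of the border are discarded as unreliable; exact
  plateaus resolve to the lexicographically smallest coordinate, and a
  plateau adjacent to a higher pixel is a shoulder, not a spot. Only the
  2-D central-plane mode is implemented — the quantified images are single
  central planes; a 3-D array errors clearly.
* RSCU is computed on pooled codon counts per gene set ("aggregate then
  compute"); per-gene averaging was the other defensible reading and is not
  the default. Stop codons are excluded from families; a terminal stop is
  tolerated and dropped, an internal one is an error.
* All simulation randomness descends from one root seed through fixed
  per-component offsets, every artifact is plain text (TIFF aside) and two
  runs with the same seed are byte-identical; reports contain no timestamps.

## Problem sizes used in the tests

The test suite exercises the default 5,000-gene simulation once (shared
across the acceptance-style checks) and smaller instances (120-400 genes,
2 replicates) elsewhere; the bootstrap coverage check uses 1,000 replications
of n = 200 with 2,000 resamples; spot detection is validated on 50 images of
10 spots plus the 2x10-image condition contrast. These sizes keep the full
suite and the acceptance script to a few minutes on a single core while
leaving every estimate's Monte-Carlo error well below the asserted margins.

## Known limitations

* The depletion condition makes tier groups statistically exchangeable, so
  "no pairwise difference" assertions are themselves noisy: with six
  pairwise 5%-level tests, a fully equalized simulation still shows at least
  one nominally significant pair about a quarter of the time. The stable
  summary of slicer dependence is the collapse of the median spread, which
  is what the acceptance script reports.
* Target calling uses replicate-mean RPM; per-replicate calling (and the
  choice of overlap denominator for set comparisons) are exposed as options
  because the published conventions are not stated.
* The pipeline starts from counts and coverage; nothing upstream of
  alignment (trimming, mapping, multi-mapper policy) is modelled, and bigWig
  binaries are not read — coverage I/O is bedGraph.
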