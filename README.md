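# mztclear

Quantitative analysis of small-RNA-guided clearance of maternal mRNAs during
the *C. elegans* maternal-to-zygotic transition (MZT).

Early embryos inherit both maternal mRNAs and a complementary pool of
antisense 22G-RNAs loaded into the catalytically active Argonaute CSR-1.
Transcripts densely covered by CSR-1-bound 22G-RNAs are cleaved and cleared
faster than other maternal mRNAs, in a dose- and slicer-dependent manner,
and preferentially when they are no longer translated. `mztclear` implements
the statistics by which that model is tested, for anyone analysing staged
embryo RNA-seq together with Argonaute-IP small-RNA-seq, degradome-seq,
Ribo-seq and smFISH — and ships a ground-truthed synthetic-data generator so
the whole pipeline is verifiable end to end without any sequencing download.

## The quantities it computes

With per-gene counts normalized as TPM (RPK by union-exon kilobase, then per
million total RPK) or RPM (per million counted reads), mean over replicates:

* **Target calling** — gene *g* is a CSR-1 target iff
  `IP_RPM(g) / input_RPM(g) >= 2` and `IP_RPM(g) > 1`; targets are tiered by
  22G density: T1 (1, 50], T2 (50, 150], T3 (150, Inf) RPM.
* **MZT classes** — from the staged profile (TPM_1cell, TPM_early, TPM_late)
  with detection at TPM > 1 and a twofold rule: maternal cleared / maternal
  stable / newly zygotic / maternal and zygotic; decay timing: early-degraded
  (>= 2-fold down by the early stage) vs late-degraded (stable early, >=
  2-fold down late).
* **Decay statistics** — degradation rate `TPM_early / TPM_1cell`;
  degradation efficiency `log2(TPM_degradome / TPM_RNA)`; translational
  efficiency `log2((TPM_RPF + 1) / (TPM_RNA + 1))`; pseudocounted
  `log2((a + 1) / (b + 1))` fold changes; enrichment factor
  `observed / (T x C / 20447)` over the protein-coding gene universe.
* **Coverage views** — scaled TSS-to-TTS metaprofiles (per-bin mean RPM,
  unweighted across genes) and the CDS vs 3'UTR partition of antisense 22G
  coverage.
* **Codon usage** — pooled RSCU per gene set,
  `RSCU_ij = x_ij / mean_family(x_i)`.
* **smFISH** — spot enhancement `G(sigma_spot) * max(I - G(sigma_bg) * I, 0)`,
  strict local-maximum detection above a robust threshold, and ROI counts.
* **Statistics** — two-tailed Mann-Whitney-Wilcoxon tests (exact for small
  tie-free samples), percentile-bootstrap median CIs, type-7 quantile box
  summaries, binomial rate-ratio tests with Benjamini-Hochberg adjustment.

See the methods vignette (`vignettes/maternal-mrna-clearance.Rmd`) for the
modelling choices, generator design and numerical conventions.

## Worked example

Simulate a small ground-truthed dataset, run the pipeline, and reproduce the
dose-dependent degradation of cleared maternal target mRNAs:

```r
library(mztclear)

cfg <- sim_config(seed = 42, n_genes = 1000, n_targets = 100)
dir <- file.path(tempdir(), "mzt_demo")
simulate_dataset(cfg, dir, what = c("genes", "expression", "srna"))
analysis <- analyse_dataset(dir)

head(subset(analysis$targets, is_target), 3)
#>     gene_id   ip_rpm input_rpm enrichment_ratio is_target tier
#> 4  gene0004 57.15685  7.895026         7.239603      TRUE   T2
#> 19 gene0019 60.76152 11.510923         5.278597      TRUE   T2
#> 28 gene0028 28.72261  5.802792         4.949792      TRUE   T1

table(analysis$classification$mzt_class)
#>     maternal_cleared      maternal_stable        newly_zygotic
#>                  187                  135                  119
#> maternal_and_zygotic         unclassified
#>                  277                  282

d <- analysis$degradation
cleared <- d$mzt_class == "maternal_cleared"
grp <- as.character(d$tier); grp[grp == "none"] <- "non_target"
round(tapply(d$rate_control[cleared], grp[cleared], median), 3)
#> non_target         T1         T2         T3
#>      0.667      0.405      0.276      0.179
mann_whitney(d$rate_control[cleared & grp == "T3"],
             d$rate_control[cleared & grp == "non_target"])[c("U", "p")]
#> $U
#> [1] 39
#> $p
#> [1] 5.224323e-15
```

Reading the output: all 100 planted IP-enriched genes are recovered as
targets with their density tiers; the staged classifier assigns the five
transcript classes; and among cleared maternal mRNAs the median degradation
rate (early/1-cell TPM) falls monotonically with 22G density — the
highest-density targets retain only ~18% of their 1-cell level by the early
stage versus ~67% for cleared non-targets, a difference the rank-sum test
calls at p ~ 5e-15. `run_report(analysis, "report/")` writes the full table
bundle plus a summary annotated with group sizes and p-values.

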