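# isoratio

Quantification of an intronic-start transcript variant from exon-level
RNA-seq read counts, with the cohort analyses that surround it.

Some genes express, alongside the full-length mRNA, a shorter variant
transcribed from an internal (intronic) start site that shares only the 3'
exons. A well-studied example is an acyl-CoA oxidase 2 (ACOX2) variant that
starts in intron 9 of the 15-exon gene and comprises exons 10–15; it is
essentially absent from normal breast tissue, enriched in ER-positive
breast tumors, and its presence associates with better relapse-free
survival. Standard transcript quantifiers are not needed to measure such a
variant: because the two isoforms partition the exons into an *exclusive*
5' block and a *shared* 3' block, their abundance ratio has a closed form
in raw exon counts. This package implements that estimator and the cohort
statistics built on it, for anyone studying an alternate-start (or
3'-shared) two-isoform system from exon-level counts or alignments.

## The estimator

Let the gene have `n` exons, the variant starting at exon `k`. Write `L0`
for the summed length of all exons, `L1` for the summed length of exons
`k..n`, `r0` for the raw reads on exons `1..k-1`, and `r1` for the raw
reads on exons `k..n`. Assuming uniform per-nucleotide coverage along each
isoform, and that these two isoforms are the only ones present, the reads
assignable to the full-length and variant transcripts are

    F0 = r0 * L0 / (L0 - L1)
    F1 = r1 - F0 * L1 / L0

and the variant-to-full-length mRNA abundance ratio is

    R = (F1 / L1) / (F0 / L0)

`log2 R` is reported with a configurable pseudocount (`epsilon = 1e-6`).
Sampling noise can drive raw `F1` below zero (clipped to 0 and flagged);
`r0 = 0` with reads in the shared block means pure variant signal
(sentinel `R = Inf`, flagged, counted positive). A threshold on `R`
(default 0.1) gives a binary positivity call, the sequencing analogue of a
PCR-band assay.

Around the estimator the package provides exon read counting from SAM/BAM
(primary mapped reads, maximal-overlap assignment), per-exon RPKM
profiles, paired tumor/normal `log2 R` differences, Wilcoxon rank-sum
subgroup comparisons, Fisher exact association with clinical factors,
Kaplan–Meier/log-rank survival by positivity, and a fully seeded
synthetic-data generator (gene models, counts, SAM reads, and paired
clinical cohorts).

## Worked example

```r
library(isoratio)
m <- gene_model("ACOX2", "chr3", starts = (0:14) * 150,
                ends = (0:14) * 150 + 100,
                strand = "+", variant_start_exon = 10)
m
#> gene_model: ACOX2 (chr3, + strand)
#>   15 exons, variant starts at exon 10
#>   L0 = 1500 bp, L1 = 600 bp

est <- estimate_isoform_ratio(
  exon_counts("tumor_1", c(rep(100, 9), rep(300, 6))), m)
est
#> ratio_estimate: tumor_1  R = 2 (log2R = 1.000)
call_positivity(est)
#> [1] "positive"
```

Reading the numbers: 900 reads on the nine exclusive exons imply
`F0 = 900 * 1500/900 = 1500` full-length reads, of which
`1500 * 600/1500 = 600` fall in the shared block, leaving
`F1 = 1800 - 600 = 1200` variant reads; per-nucleotide, the variant is
`(1200/600)/(1500/1500) = 2` times as abundant as the full-length mRNA.

## The analysis workflow

The `analysis/` scripts run the full cohort study on synthetic data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1   # 87 tumor/normal pairs, seed 1
Rscript analysis/02_quantify.R     # per-sample R, per-exon log2 RPKM
Rscript analysis/03_cohort.R       # paired, subgroup, Fisher, survival
```

Stage 3 prints, for seed 1:

```
paired: 87 pairs analysed, 0 excluded, 83 with delta > 1
wilcoxon 'ER+/Her2- vs ER-/Her2-': n = 42 vs 33, p = 9.64e-09
wilcoxon 'ER-/Her2+ vs ER-/Her2-': n = 4 vs 33, p = 0.007683
fisher positivity x grade: n = 87, p = 0.4147
fisher positivity x er: n = 87, p = 3.683e-07
fisher positivity x pr: n = 87, p = 9.956e-05
fisher positivity x tp53: n = 87, p = 0.03844
survival 'overall': n = 43/44, log-rank p = 0.02738
survival 'ER+': n = 13/37, log-rank p = 0.08424
survival 'ER-': n = 30/7, log-rank p = 0.0264
```

i.e. the variant is higher in tumor than matched normal in 83 of 87 pairs,
strongly ER-associated, and positivity stratifies relapse-free survival.

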