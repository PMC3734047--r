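# phaseq

Phase-resolved bacterial RNA-seq quantification and ¹³C-incorporation
analysis for heterotrophic PHA production.

`phaseq` is for microbiologists and bioinformaticians studying
polyhydroxyalkanoate (PHA) metabolism in bacteria such as *Ralstonia
eutropha* H16, where two questions arise together: *how does the
transcriptome change across growth, PHA-production and stationary
phases?* and *does the transcriptionally induced Calvin–Benson–Bassham
(CBB) cycle actually fix CO₂ into the polymer?* The package implements
both analyses as tested, pipe-friendly tibble workflows, plus a
deterministic synthetic-data generator so every stage is validated
without any external download.

## What it computes

**RNA-seq quantification** (from SAM alignments + GFF3 annotation + rRNA
exclusion intervals):

* alignments with mismatches (`NM > 0`) or overlapping rRNA regions are
  discarded; reads left without loci are removed (and tallied as rRNA
  reads where appropriate) — essential when incomplete rRNA depletion
  leaves 70–90% of reads on rrn operons;
* a multimapped read with *k* surviving loci contributes 1/*k* per locus,
  split 1/*m* among *m* overlapping CDS features;
* RPKM = count / (length·10⁻³) / (library·10⁻⁶), with library size the
  counted-on-CDS total, so Σ RPKM·length_kb = 10⁶ per sample;
* per-gene one-way ANOVA across conditions over replicate RPKM values
  (gate: raw *p* < 0.05), expression categories (RPKM < 250 silent/weak,
  > 20,000 high), between-phase ratio tables, log2 matrices and
  average-linkage sample clustering on 1 − Pearson *r*.

**Isotopomer analysis** (from GC-MS fragment mass-isotopomer
distributions of 3HB methyl ester, fragments *m/z* 45/87/103 with
2/4/4 carbons): the ¹³C atom fraction of a fragment is Σᵢ i·Mᵢ / n; the
polymer abundance is the fragment mean (%); the newly fixed carbon is

increase = Δ × n̄_C / M × 1000  (mmol ¹³C / g polymer),

with Δ the labeled-minus-control atom-fraction difference, n̄_C = 10/3
the mean fragment carbon count and M = 86.09 g/mol the C₄H₆O₂ repeat
unit.

## Worked example

Simulate a two-phase experiment with a programmed 4× induction, quantify
it, and gate/cluster the result:

```r
library(phaseq)
library(dplyr)

cfg  <- synth_config(n_genes = 30, conditions = c("F16", "F26"),
                     reads_per_sample = 50000, seed = 42)
ann  <- generate_annotation(cfg)
prof <- expression_profile(ann, conditions = cfg$conditions, seed = 42,
                           fold_changes = list(gene010 = c(F26 = 4)))
design <- tidyr::crossing(condition = cfg$conditions, replicate = 1:2) |>
  mutate(sample_id = paste0(condition, "_r", replicate))

sams <- setNames(file.path(tempdir(), paste0(design$sample_id, ".sam")),
                 design$sample_id)
for (i in seq_len(nrow(design)))
  write_sam(simulate_alignments(ann, prof, cfg, design$condition[i],
                                design$replicate[i]), sams[i])

rs <- quantify_samples(sams, ann, design)
glance(rs)
#>   condition replicate sample_id library_size n_reads_input n_reads_rrna
#> 1 F16               1 F16_r1            7443         50000        40113
#> 2 F16               2 F16_r2            7583         50000        39932
#> 3 F26               1 F26_r1            7502         50000        40086
#> 4 F26               2 F26_r2            7356         50000        40168
```

Each sample keeps ~7.4k of 50k reads: ~80% were rRNA, ~5% mismatched,
~5% of the remainder fell between genes — the filter statistics above
make that loss auditable.

```r
head(expression_ratios(rs, "F26", "F16"), 3)
#>   gene_id mean_num mean_den ratio log2_ratio direction
#> 1 gene010   11341.    3145.  3.61      1.85  up
#> 2 gene026    3781.    2537.  1.49      0.576 up
#> 3 gene017    2866.    2163.  1.32      0.406 up

cluster_samples(log2_matrix(rs))
#> <sample_clustering> ((F16_r1:0.006,F16_r2:0.006):0.0068,(F26_r1:0.0078,F26_r2:0.0078):0.005);
#>   nearest pair: F16_r1 + F16_r2 (height 0.01207)
```

The programmed 4× gene tops the ratio table (3.61 observed — RPKM ratios
slightly attenuate large folds through the library-size shift they
cause), and technical replicates pair before conditions join.

The isotope module converts measured ¹³C abundances into incorporated
carbon; with the bundled Rubisco-disruptant table:

```r
tab <- phb_labeling()
inc <- incorporation_increase(tab$abundance_13c, tab$abundance_12c,
                              strain = tab$strain)
mutate(inc, increase = round(increase, 2))
#>   strain       abundance_labeled abundance_control   delta increase
#> 1 H16                       2.22              1.13 0.0109      0.42
#> 2 H16_dcbbLS_c              1.81              1.10 0.0071      0.27
#> 3 H16_dcbbLS_p              2.11              1.13 0.0098      0.38
#> 4 H16_ddcbbLS               1.25              1.11 0.0014      0.05
fold_ratio(inc[1, ], inc[4, ])
#> [1] 8.4
```

The wild type fixes 0.42 mmol ¹³C per gram of P(3HB) — 8.4-fold more
than the Rubisco double disruptant — showing the CBB cycle is active
during heterotrophic PHA synthesis.

See `vignette("phase-resolved-expression")` for the full methods
account: model assumptions, parameter defaults, what the synthetic data
do and do not emulate, and numerical choices.

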