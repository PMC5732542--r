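# rnaiscreen

In silico off-target screening for pesticidal RNAi.

Pesticidal double-stranded RNAs (dsRNAs) are diced in vivo into ~21-nt small
interfering RNAs (siRNAs) that silence genes by sequence complementarity. In
a non-target organism — a pollinator such as the honey bee, say — a
pesticidal RNA can silence the homolog of its intended target (*non-target
binding*) or an unrelated gene with sufficient similarity (*off-target
binding*). `rnaiscreen` is a first-tier, sequence-only screen for both: it
is aimed at ecotoxicologists and risk assessors who need to rank pesticidal
RNA candidates against a non-target gene set before committing to in vivo
work.

## What it computes

Given a registry of pesticidal RNAs and an annotated non-target gene set
(FASTA + annotation table), the pipeline:

1. enumerates every 21-nt window of each RNA, sense and antisense, step 1
   (molecules under 21 nt are matched full length);
2. finds **every** gene-set position matching a window with at most 2
   substitutions — an exhaustive Hamming scan classed as 19/21, 20/21 or
   21/21 matched nucleotides, with a perfect-seed flag (guide positions
   2–8); genes flagged low-quality or of unknown function are excluded;
3. collapses hits to one tally per (RNA, gene) pair — a gene counts once per
   RNA no matter how many locations match — labelled `off_target` or
   `non_target` (the latter iff the gene is the declared ortholog of the
   RNA's target);
4. runs the statistical layer:
   * log–log least-squares regression of off-target count on dsRNA length,
     `y = log10(count + 1)`, `x = log10(length)`, with the F test
     `F = (SSR/1)/(SSE/(n-2))`;
   * the companion raw-scale slope expressed as extra hits per 100 nt with
     its 95% CI;
   * Pearson chi-square tests of independence for target taxon × non-target
     binding incidence and gene functional group × pesticidal target
     category;
   * descriptive mean ± SE of off-target homologies per dsRNA.

A synthetic-data generator (`generate_synthetic()`) produces gene sets,
registries and planted homologies with known ground truth — location,
orientation, substitution count — so every stage is testable without genome
downloads.

## Worked example

```r
library(rnaiscreen)

cfg <- synthetic_config(seed = 7, n_genes = 150,
                        gene_length_range = c(400, 900),
                        n_dsrna = 20, dsrna_length_range = c(100, 1200),
                        dsrna_length_dist = "uniform", n_sirna = 5,
                        n_target_genes = 12)
sim <- generate_synthetic(cfg)          # registry + gene set + ground truth
scr <- screen_offtargets(sim$registry, sim$genes)
summary(scr)
```

```
In silico RNAi off-target screen
  20 dsRNAs, 5 siRNAs scanned; 3376 hits, 789 per-(RNA, gene) tallies
  dsRNAs with >= 1 off-target similarity: 20 of 20; siRNAs: 0 of 5
  off-target homologies per dsRNA: 39.2 +/- 4.00 SE
  length regression (log-log): F(1, 18) = 259, p = 4e-12
  raw-scale rate: 5.88 hits per 100 nt (95% CI 5.01-6.75)
  taxon x non-target binding: X-squared = 6.84, df = 7, p = 0.445
  gene group x target category: X-squared = 0.917, df = 4, p = 0.922

Developmental-gene exposure:
  100.0% of dsRNAs share off-target similarity with developmental genes
  of those, 85.0% also hit homeobox genes
```

Reading this: every dsRNA matched at least one non-target gene while no
siRNA did (short molecules are far more specific); off-target potential
rises steeply with length — the raw-scale fit recovers ≈ 5.9 extra hits per
100 nt against the 6.0/100 nt actually planted, with the truth inside the
CI; the taxon test is null (non-target binding was planted at equal
probability across taxa); and the gene-group test is null (plants landed on
genes uniformly). `scr$hits`, `scr$tallies` and `scr$summaries` hold the
underlying tables; `write_results()` writes them as TSV/JSON with a fixed
schema and deterministic ordering, and `plot(scr)` draws the log–log
length-response.

Real data enter through `read_registry()` (TSV: one row per RNA with
sequence, molecule class and target metadata) and `read_gene_set()`
(FASTA + annotation TSV with functional group, quality flag and ortholog
links); `database_stats()` applies the statistical layer directly to a
per-RNA summary table when the scan has already been done elsewhere. A thin
command-line front end lives in `inst/scripts/rnaiscreen.R`
(`simulate`, `scan`, `screen`).

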