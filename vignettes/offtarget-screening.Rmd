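---
title: "In silico off-target screening for pesticidal RNAi: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico off-target screening for pesticidal RNAi: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaiscreen)
```

## The screening problem

Pesticidal double-stranded RNAs (dsRNAs) are diced in vivo into small
interfering RNAs (siRNAs) of roughly 19-25 nt, which guide degradation of
complementary mRNA. In a non-target organism, a pesticidal RNA can cause
unintended silencing in two ways: *non-target binding* (similarity to the
homolog of the intended target gene) and *off-target binding* (similarity to
an unrelated gene). `rnaiscreen` implements a first-tier, sequence-only
screen for both, over an annotated non-target gene set, and the statistical
analyses that summarize the result: does off-target potential grow with
dsRNA length, does target-taxon relatedness predict non-target binding, and
are particular gene functional groups over-represented among off-target
matches.

Sequence similarity alone does not imply silencing in vivo; the screen is
designed to rank and focus risk assessment, not to predict phenotypes.

## Matching model

The scoring unit is a 21-nt window. Every offset of each RNA contributes one
sense window and one antisense window (the reverse complement of the same
stretch, since either strand of a dsRNA can be loaded as a guide), stepped
one nucleotide at a time. A window matches a gene position when it aligns
with at most `max_mismatches` substitutions - a Hamming model with no gaps,
because the x/21 identity-class scheme (19/21, 20/21, 21/21 matched
nucleotides) has no gap semantics. The search is exhaustive: every window is
compared against every position of every eligible gene sequence, so unlike a
seeded heuristic aligner it cannot miss a 19/21 match with awkward mismatch
spacing. Internally a pigeonhole filter (one of `max_mismatches + 1`
contiguous window parts must match exactly) prunes the comparison without
changing its result; tests compare the scan against a literal brute-force
double loop.

Conventions worth stating precisely:

* **Identity class** is `k - mismatches` for full windows (`k = 21`).
  Molecules shorter than 21 nt are matched full length and scored on the
  same over-21 scale: a perfect 19-nt siRNA match counts as 19/21, and a
  19-mer with one substitution (18/21) falls below the lowest class and is
  not reported.
* **Strand**: a hit's strand is `+` for sense windows and `-` for antisense
  windows; all matching is performed against the gene's forward sequence.
  Scanning an RNA and scanning its reverse complement therefore give
  mirrored hit sets, which is tested as an invariant.
* **Ambiguity policy**: under the default `strict` policy any non-ACGT code
  on either side is a mismatch (even `N` against `N`) - conservative for Ns
  in assemblies. An `iupac` policy (bases match when their IUPAC sets
  intersect) is available but not the default.
* **Seed region**: positions 2-8 of the guide (1-based, 7 nt). Each hit
  carries a `seed_perfect` flag - perfect seed complementarity matters most
  for mRNA recognition - but the flag does not change tallying.
* **Exclusions**: genes flagged `low_quality`, `unknown_function` or
  `unannotated` are never searched, mirroring conservative database
  filtering; the searchable space is gene-attributed sequence only.
* **Coordinates** are 0-based half-open everywhere, including output files.

A planted or real homology is typically reported several times: windows
overlapping it by 19+ nt also clear the identity threshold, producing a
short ladder of hits at neighbouring offsets. This is expected and is the
reason tallies deduplicate.

## Tallies and binding classes

Each gene is tallied **once per RNA**, however many windows or locations
match it; the tally records the best identity class, the number of distinct
matching windows and whether any hit had a perfect seed. A tally is
`non_target` when the gene's declared `ortholog_of` set contains the RNA's
target gene name, else `off_target`. Orthology is declared in the
annotation, never inferred. Per-RNA summaries count off-target tallies only
(`n_offtarget_genes`) and flag non-target binding separately, since a
non-target homolog is by definition not a *different* gene.

## Statistical layer

* **Length regression.** Off-target counts are `log10(x + 1)` transformed
  (zeros are legitimate) and lengths `log10` transformed, then fitted by
  closed-form two-variable least squares with the usual F test,
  `F = (SSR/1)/(SSE/(n-2))` on (1, n-2) df. The log base is recorded in the
  result; the log-log slope is base-invariant. A numerically perfect fit
  reports `F = Inf, p = 0`; a constant response reports `F = 0`.
* **Hits per 100 nt.** The interpretable "extra hits per 100 nt" figure
  cannot come from the log-log fit (it has no constant raw-scale slope), so
  it is computed as a companion untransformed least-squares slope times
  100, with its 95% confidence interval, and reported alongside - never
  instead of - the transformed regression.
* **Chi-square tests.** Pearson's test of independence with expected counts
  `row x col / N`, no continuity correction by default (the tables are
  r x c, not 2x2-specific); Yates' correction is available for 2x2. All-zero
  rows/columns are dropped with a warning because their expected counts are
  undefined; a `low_expected_warning` flags expected cells below 5, which
  is common at these sample sizes (74 RNAs over 8 taxa). The taxon test
  treats non-target binding as a **binary per-RNA incidence** (any
  non-target tally at the minimum identity class or better), giving the
  familiar df = taxa - 1 structure.
* **Gene-group test.** Rows are five configurable functional groups
  (`homeobox`, `other_developmental`, `housekeeping`, `neural_muscular`,
  `other` - a documented reconstruction, since only the developmental and
  homeobox groups are fixed by the analysis this reproduces), columns the
  pesticidal target category (`vATPase` vs `other`), counted over off-target
  tallies; df = 4 at the defaults.
* **Regression sample.** Whether the length regression should include
  siRNAs is genuinely ambiguous in the analysis this package reproduces
  (the printed df implies more points than there are dsRNAs), so the
  molecule filter is exposed as `regression_molecules` (default dsRNA-only)
  rather than hard-coded; likewise `taxon_molecules` for the taxon test.
  `database_stats()` applies the same layer to an external per-RNA table
  without re-running the scan.

P-values are upper-tail probabilities of the F and chi-square distributions
(`stats::pf`, `stats::pchisq`).

## What the synthetic generator emulates

`generate_synthetic()` produces a gene set (FASTA + annotation), a
pesticidal-RNA registry and a ground-truth record, with this structure:

* 74 dsRNAs spanning 19-2500 nt and 21 siRNAs of 19-23 nt (the scale of the
  published pesticidal-RNA literature). dsRNA lengths are **log-uniform** by
  default: published lengths span two orders of magnitude, and under the
  6 hits/100 nt planted rate a log-uniform draw reproduces the observed
  scale of ~29 off-target homologies per dsRNA; a uniform option exists.
* Off-target homologies planted at `planted_rate_per_100nt = 6` per 100 nt:
  the count for a dsRNA of length L is Poisson(L/100 x 6), the generative
  analogue of the observed linear length-response. Each homology lands on a
  **distinct** normal-quality gene, so deduplicated tallies recover the
  planted count exactly. Plants copy a window of the dsRNA - or its reverse
  complement, probability 0.5 each, exercising strand handling - into a
  free stretch of the gene, then apply exactly the drawn number of
  substitutions (mix 0.25/0.35/0.40 over 0/1/2 by default). Copying into
  the gene side rather than the dsRNA side matters: a 2500-nt dsRNA is
  expected to carry ~150 distinct-gene homologies but could host at most
  119 non-overlapping 21-mers, so planting into genes avoids truncating the
  planted length-response. dsRNAs shorter than 21 nt receive no plants
  (recorded as absent), so at desk scale they legitimately finish with zero
  tallies, unlike a whole-genome search where chance matches are plentiful.
* Non-target binding planted into the target gene's declared ortholog with
  per-taxon probability 0.3, flat across all eight taxa - the null taxon
  effect, matching the non-significant published taxon result; the
  probabilities are configurable to create an effect when one is wanted.
* Eight target taxa cycled over 57 target genes; ~30% of targets in the
  `vATPase` category; 15% of genes declared orthologs; 8% low-quality and
  5% unknown-function genes to exercise exclusion filtering. Gene groups
  drawn as 5/15/25/15/40% over
  homeobox/other-developmental/housekeeping/neural-muscular/other.
* Background sequence is i.i.d. uniform ACGT - adequate for exercising
  matching and statistics, but deliberately non-biological: no codon
  structure, GC bias, repeats or paralogy. Passing tests on synthetic data
  therefore demonstrate algorithmic correctness and statistical recovery,
  not performance on real genomes, where repeat families and conserved
  domains will concentrate hits.

`expected_spurious_rate()` gives the analytic expected number of chance
matches at or above 19/21 between the configuration's windows and its
random background (`n_windows x positions x 2 x P(Hamming <= 2)`, with
`P = (1 + 63 + 1890)/4^21 ~ 4.4e-10`). Test fixtures are sized so this rate
is well below 0.01 when exact truth recovery is asserted; at full study
scale a few chance 19/21 matches are expected and tolerated, just as they
would be against a real genome.

```{r spurious}
cfg <- synthetic_config(seed = 1)
expected_spurious_rate(cfg)
```

## Numerical and interface choices

* Identical seed and configuration give byte-identical output files; the
  pipeline itself is deterministic, so screens of the same dataset are
  identical.
* All result tables are written with a fixed column schema and
  deterministic row ordering (rna_id, gene_id, sequence index, position).
* Registry sequences are uppercased and U-normalized to T at ingest so
  matching is alphabet-uniform; parsers validate every row and never
  silently drop one.
* Duplicate hits from sense and antisense windows at the same locus are
  both retained at hit level; deduplication happens only at tally level.
* The minimum identity class for tallying is configurable
  (`min_identity_class`, default 19) for users who want to restrict "high
  similarity" to 20/21 or 21/21.

## Problem sizes used by the test suite

The packaged tests run the matcher-versus-oracle comparison on 200 random
instances of 2-4 genes x 130-280 nt against RNAs of 25-110 nt, end-to-end
truth recovery on 8-10 dsRNA instances sized for a spurious rate below
0.01, and the study-scale regression recovery on 60 dsRNAs of 100-2500 nt
against 200 genes of 500-3000 nt. These sizes were chosen to make the
statistical assertions sharp at desk scale; the pipeline itself has no
size-dependent switches.

## Limitations

* No G-U wobble pairing, no silencing thresholds below 19/21, no
  thermodynamic or RISC-loading model, no expression weighting: matches are
  counted, not ranked by biochemical plausibility.
* Secondary (replicated) RNAs, which need not match the primary molecule,
  are out of scope; only the primary pesticidal sequence is screened.
* Orthology is taken from the annotation as given.
* The searchable space is gene-attributed sequence; hits in regions with no
  gene attribution are undefined here (a conservative choice).
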