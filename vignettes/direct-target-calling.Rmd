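---
title: "Calling direct transcriptional targets from paired ChIP-seq and knockdown RNA-seq"
author: "cotarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling direct transcriptional targets from paired ChIP-seq and knockdown RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotarget)
```

## The problem

A transcription factor binds thousands of genomic sites, but only a small
fraction of that binding is functional: knocking the factor down changes
the expression of far fewer genes than it binds.  `cotarget` implements
the standard two-evidence definition of a *direct target*: a gene whose
expression depends on the factor (RNA-seq under knockdown) **and** that
carries at least one binding peak near it (ChIP-seq).  The motivating use
case is a factor pair such as RUNX2 and its non-DNA-binding partner CBFB
in osteosarcoma cells, where co-occupancy of the two factors and the
downstream target set (e.g. MYC) are the biological read-outs, but every
stage is generic.

The pipeline has four stages, each usable on its own:

1. **Peak intensity and co-occupancy.**  Each peak is scored by summing
   the per-nucleotide tag count across the peak (`peak_intensity()`), the
   binding-strength statistic.  Two peak sets are compared by a
   peak-centric, one-sided Venn decomposition (`venn_decompose()`): how
   many A peaks overlap at least one B peak, and vice versa.  Overlapping
   peaks are paired one-to-one by maximal shared bases
   (`match_overlapping_peaks()`) and their intensities correlated with
   Spearman's rank correlation (`spearman_correlation()`).
2. **Peak-to-gene assignment** (`assign_peaks()`), strand-aware, with
   three windows per transcript: *promoter* (TSS ± 5 kb), *gene body*
   (the rest of the transcript span), and *distal* (closer than 25 kb to
   the nearest transcript edge).  Precedence is promoter > gene body >
   distal.  A gene with at least one assigned peak is *bound*.
3. **Concordant knockdown filter** (`concordant_dependent_genes()`).
   With a control and two independent shRNA hairpins (three replicates
   each), a gene is *dependent* when both hairpins move it in the same
   direction with linear fold change > 1.5 and p < 0.05.  Requiring two
   hairpins to agree is the guard against shRNA off-target effects.
4. **Direct-target calling** (`call_direct_targets()`): dependent ∩
   bound.  A target whose expression *falls* upon knockdown was
   *activated* by the factor; one that *rises* was *repressed*.  The
   resulting list can be tested for gene-set enrichment with an
   upper-tail hypergeometric test (`hypergeometric_enrichment()`).

`run_pipeline()` chains the stages from a config of file paths and writes
result tables plus a machine-readable summary.

## Coordinate conventions

Internally everything is a `GRanges` in the Bioconductor 1-based closed
convention; `rtracklayer` performs all disk conversions (BED and bedGraph
are 0-based half-open, GFF3 is 1-based closed).  Overlap means at least
one shared base — no minimum-fraction rule anywhere — and the gap
distance between intervals is the number of bases strictly between them,
so `gap == 0` exactly when two intervals touch or overlap.  Keeping a
single convention with all conversion at the I/O boundary is what makes
the write/read round trips in the test suite exact.

Two boundary choices deserve a note:

* The promoter window covers `2 * promoter_flank` bases centred on the
  strand-aware TSS (for a minus-strand transcript "upstream" means larger
  coordinates).  Because the window is symmetric in genomic coordinates,
  only the TSS anchor, not the window shape, depends on strand.
* "Closer than 25 kb" is implemented strictly: a peak whose gap to the
  transcript is exactly 25,000 bases is **not** assigned.  Distal
  distances are measured from the nearest transcript edge, not the TSS or
  the midpoint, since the window is anchored to the transcript.

A peak may be assigned to several genes (both are reported; distal ties at
identical distance are flagged), and per gene the best assignment across
its transcripts is kept: category precedence first, then smallest
distance, then transcript id as a deterministic tie-break.

## Statistical choices

**Peak intensity** is computed by segment arithmetic against the bedGraph
step function (overlap length × segment value), which is exact and fast;
the naive per-base loop is kept in the test suite as an oracle and the two
agree exactly on random fixtures.

**Spearman correlation** is the product-moment correlation of
average-tied ranks.  For n > 10 the p-value uses the classical
t approximation `t = rho * sqrt((n-2)/(1-rho^2))`; for n ≤ 10 it is an
exact two-sided permutation p, enumerating every distinct permutation of
the rank vector in compiled code (ties are handled by permuting the
tied-average ranks themselves).  Constant input is an error — the
correlation is undefined, and silently returning `NA` hides upstream
bugs.  P-values below 2.2e-16 are displayed with the conventional
"< 2.2e-16" floor (`format_pvalue()`); the numeric value is preserved in
all outputs.

**The replicate-level test** behind the dependency calls is a two-sided
Welch (unequal-variance) t-test on `log2(RPKM + 1)`.  RPKM is
approximately log-normal, so testing on the log scale with a pseudocount
is the transparent choice at n = 3 per group; the test is pluggable
(`test_fun`) for anyone preferring a count-based model, which is out of
scope here.  Two degenerate cases are pinned down: zero spread and equal
means gives p = 1; zero spread and different means gives the smallest
positive double.  **No multiple-testing correction is applied** — the
two-hairpin concordance requirement is the multiplicity guard, mirroring
the raw p < 0.05 convention of the experimental design this emulates.
This is a deliberate caveat: with a single hairpin the raw threshold
would not be defensible.

**Fold changes** are computed on pseudocounted linear means,
`log2((mean_kd + 1)/(mean_ctrl + 1))`, and the threshold is applied on the
linear scale (> 1.5 or < 1/1.5).  The pseudocount bounds the fold change
of barely-expressed genes, which is why the synthetic generator plants
its regulated genes in the clearly-expressed range (see below).

**Enrichment** uses the upper-tail hypergeometric `P[X >= k]`, summed
from log-scale density terms; Benjamini–Hochberg q-values are appended as
an extra column while raw p-values are preserved.  The default universe
is all annotated genes, configurable, since enrichment p-values are only
meaningful relative to an explicit background.

## What the synthetic generators emulate

`simulate_bundle()` writes a complete, seeded input bundle: a GFF3
annotation, two BED peak sets, two bedGraph coverage tracks, an RPKM
matrix with its sample sheet, and a planted-truth ledger.  The defaults
are the package's reference study conditions: 500 genes, 1,000 factor-A
peaks (1,250 for B), a 0.61 one-sided overlap fraction, Spearman 0.84
between paired intensities, 200 bound genes, 60 planted direct targets
(30 activated + 30 repressed) plus 20 dependent-but-unbound genes,
3-fold knockdown effects, 20% replicate CV, three replicates — sizes that
keep the full pipeline and test suite fast while leaving headroom on the
statistical gates.

Design points worth knowing:

* **Layout.**  Transcripts alternate strands and every inter-transcript
  gap exceeds `2 * (promoter_flank + distal_limit)`, so no peak can fall
  within the windows of two genes unless planted there.  Bound genes get
  one peak centred on their TSS; all other peaks go to intergenic slots
  farther than 25 kb from every transcript.  Re-deriving bound genes with
  `assign_peaks()` therefore reproduces the planted list *exactly*, which
  the tests assert.
* **Pairing.**  `round(fraction * n_peaks_a)` A peaks receive an
  overlapping B partner, so the realised overlap fraction is exact to
  1/(2n) rather than binomially noisy.
* **Correlated intensities** come from a Gaussian copula over log-normal
  margins.  For a bivariate normal the Spearman correlation is
  `(6/pi) * asin(r/2)`, so the copula uses
  `r = 2 * sin(pi * rho_target / 6)`; rank correlations survive the
  monotone log-normal transform.  Intensities are rounded to integers.
* **Exact coverage.**  Each coverage track is a rectangular pileup built
  so that `peak_intensity()` returns every planted intensity exactly:
  height `intensity %/% width` across the peak with the remainder stacked
  one tag higher on the peak's first bases.  Intensity tests are
  therefore exact, not approximate.
* **Expression.**  Control RPKM is log-normal (meanlog log 30, sdlog 1);
  planted regulated genes are drawn from a clearly-expressed distribution
  (meanlog log 60, sdlog 0.5) because silent genes are undetectable at
  RPKM level and the pseudocount would otherwise swallow the planted
  fold change.  Replicate noise is multiplicative log-normal with the
  configured CV, mean-preserving.  `effect_fold = 1` produces the null
  case.

All randomness flows from the single config seed (each generator uses a
fixed small offset from it), there is no hidden global state — the
caller's RNG is saved and restored — and identical configs produce
byte-identical files (variable GFF3 comment headers are stripped on
write).

What the generator deliberately does **not** emulate: read-level data
(FASTQ), fragment-size effects, background noise peaks and other ChIP
artifacts, overlapping genes and multi-transcript loci, correlated
replicate structure or batch effects, and count-level mean–variance
relationships.  Passing the planted-truth tests shows the integration
logic is correct under the stated statistical structure; it does not
validate peak calling, RPKM estimation, or robustness to real-data
artifacts, all of which are upstream of this package's inputs.

## Small assay calculators

Two deterministic Methods-style calculators ship alongside the pipeline.
`percent_input()` implements dilution-adjusted ΔCt ChIP-qPCR enrichment:
the input Ct is first shifted by `log_E(1/input_fraction)` cycles to
represent 100% of chromatin, then enrichment is
`100 * E^(adjusted_input_ct - ct_ip)`; the amplification efficiency E
defaults to 2 (perfect doubling) and is exposed because real assays
rarely achieve it.  The default input fraction of 1% is a conventional
placeholder — use the assay's actual value.  The qPCR primer pair for the
MYC promoter amplicon ships as a named fixture (`myc_chip_primers()`).
`cumulative_cell_numbers()` corrects counted cells by the running product
of splitting ratios, `C_i = count_i * prod(r_j, j < i)` — the only
reading of a "cumulative" split-corrected count that yields a growing
curve for a growing culture.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
bundle <- simulate_bundle(cfg, "fixtures")
res <- run_pipeline(bundle$config)

res$venn                    # one-sided overlap counts and display percent
res$spearman$rho            # intensity correlation of matched pairs
res$target_calls            # direct targets by class
head(res$enrichment)        # if a GMT was configured

# compare with the planted truth
mean(bundle$truth$direct$gene_id %in%
       res$target_calls$calls$gene_id[res$target_calls$calls$target_class != "none"])
```

## Known limitations

* Gene-level only: transcript matrices are collapsed by summing RPKM
  (`collapse_to_genes()`); isoform-specific regulation is invisible.
* The dependency filter uses raw per-hairpin p-values by design (see
  above); the package does not implement count-based DE models.
* Assignment is window-based; enhancer–promoter looping or
  nearest-gene-only modes are out of scope.
* The Venn decomposition is peak-centric, not merged-region based, so the
  two one-sided counts need not agree and neither is a "number of shared
  regions".
* The exact-permutation Spearman p is limited to n ≤ 10 by factorial
  growth; beyond that the t approximation is used, which is slightly
  liberal at n just above 10.
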