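---
title: "Joint 5mC/5hmC methylome analysis from paired BS/oxBS RRBS"
author: "hmcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint 5mC/5hmC methylome analysis from paired BS/oxBS RRBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcall)
```

## The measurement problem

Bisulfite sequencing converts unmodified cytosine to uracil but leaves both
5-methylcytosine (5mC) and 5-hydroxymethylcytosine (5hmC) protected, so a
standard bisulfite (BS) library reports the *sum* of the two marks at every
CpG. Oxidative bisulfite (oxBS) sequencing first oxidises 5hmC to
5-formylcytosine, which then converts like unmodified C; an oxBS library
therefore reports 5mC alone. Sequencing each sample both ways — here as
reduced representation bisulfite sequencing (RRBS), which enriches the
CpG-dense genome fraction — lets the two marks be separated per cytosine.

`hmcall` implements the complete desk-side analysis of such paired
libraries: per-CpG 5hmC inference by subtraction, per-cytosine differential
methylation (DM) testing between sample groups, annotation-class enrichment
of DM sites, and a calibrated simulator that provides ground truth for
validating every stage.

## The subtraction estimator

True 5mC is taken directly from the oxBS record. 5hmC is inferred per
paired site from full-precision percentages (recomputed from raw counts, so
file-level percent rounding never contaminates the signal):

$$\mathrm{Count}_{5hmC} = \mathrm{Count}_{BS\,meth} - \mathrm{Count}_{oxBS\,meth},
\qquad \%_{5hmC} = \%_{BS\,meth} - \%_{oxBS\,meth}$$

and the unmodified-read complement is reconstructed from
$\%_{5hmC} = 100\,\mathrm{Count}_{5hmC}/(\mathrm{Count}_{5hmC}+\mathrm{Count}_{No5hmC})$,
rounded to the closest integer. Rounding is half-away-from-zero, fixed for
reproducibility (half-to-even would serve equally; the choice is arbitrary
but must be stable). Re-deriving the percentage from the reconstructed
integers agrees with the subtracted percentage to within
$50/(\mathrm{Count}_{5hmC}+\mathrm{Count}_{No5hmC})$, the bound induced by
integer rounding; the test suite asserts it on tens of thousands of random
pairs.

**Fringe rule.** When the oxBS signal exceeds the BS signal the subtraction
is negative; such sites are set to zero 5hmC with
$\mathrm{Count}_{No5hmC} = \mathrm{Count}_{BS\,unmeth}$. Because the two
libraries may differ in depth, the count difference and the percent
difference can also disagree in sign; these inconsistent cases are routed
to the same zero path and flagged (`fringe`) so users can distinguish them.

```{r}
pair <- data.frame(chrom = "chr1", pos = 100L,
                   bs_count_mod = 8L, bs_count_unmod = 2L,
                   ox_count_mod = 5L, ox_count_unmod = 5L)
infer_5hmc(pair)
```

### Properties and limitations of the estimator

With oxidation efficiency $e$, the oxBS library reports $m + h(1-e)$, so
the subtraction recovers $h\,e$, not $h$: a 95%-efficient oxidation
understates 5hmC by 5% of its true level. The parameter-recovery tests
measure exactly this ($h = 0.2$: mean inferred 0.20 at $e = 1$, 0.18 at
$e = 0.9$).

The zero-truncation of the fringe rule makes the estimator biased at low
depth and, more importantly, sensitive to *depth asymmetry*: when BS and
oxBS coverage are drawn independently (separate library preps), the sign
of the count difference flips on depth alone at a substantial fraction of
sites — at mean depth 50, roughly 10% — and zeroing those sites biases the
mean inferred 5hmC downward by about one percentage point at these
settings. With depth-matched libraries the analytic expectation $h\,e$
holds to within a few tenths of a point. The recovery experiments in the
test suite therefore use the simulator's `depth_matched` mode; analyses of
real unequal-depth pairs should expect the subtraction estimator (as
defined, without depth matching or downsampling) to be slightly
conservative for 5hmC. No maximum-likelihood or shrinkage correction is
attempted; the plain subtraction is the method under study.

## Differential methylation testing

Both channels (5mC, 5hmC) are tested per cytosine between two groups of
replicates. Sites must be covered at `min_coverage` (default 10; a
conventional per-library threshold, configurable) in *every* replicate of
both groups. The methylation difference is computed from replicate-pooled,
coverage-weighted fractions, as group B minus group A — "hyper" means
higher in the mutant/aged group.

Two per-site tests are provided:

* **Pooled exact conditional test** (used when either group has a single
  replicate): a two-sided exact test on the pooled 2×2 table, summing
  hypergeometric probabilities of all tables at fixed margins no more
  probable than the observed one (a $1+10^{-7}$ relative tolerance absorbs
  floating-point ties, matching common practice).
* **Binomial likelihood-ratio test** (two or more replicates per group):
  group-wise MLE proportions are the pooled group fractions, so
  $G = 2[\ell(\hat p_A,\hat p_B) - \ell(\hat p_{pooled})]$ in closed form,
  with $p$ from $\chi^2_1$.

These are deliberate, documented substitutes for logistic-regression-based
per-site machinery in established DM callers; q-values are plain
Benjamini–Hochberg across all tested sites of a channel (not SLIM), so
numeric results will differ from analyses built on those tools. The LRT
carries the usual caveat of the $\chi^2$ approximation: at extreme tail
quantiles on discrete counts it is mildly anticonservative relative to the
exact conditional test, which matters only for borderline discoveries at
stringent thresholds. Neither test models replicate-level overdispersion;
the simulator draws replicates from a common truth, matching that
assumption.

Candidate DM sites then pass the study's joint filter: absolute pooled
difference of at least `min_diff_pct` (default 25 percentage points) *and*
BH $q$ below `q_threshold` (0.05 by default; 0.01 is the stricter variant
used for single-replicate designs). The filter is applied per channel.

## Annotation enrichment

For each annotation class, with $D$ DM sites among $C$ tested cytosines,
of which $D_{ov}$ and $N_{ov}$ overlap the class:

$$\mathrm{OR} = \frac{D_{ov}/(D-D_{ov})}{N_{ov}/(C-D-N_{ov})},\qquad
P = P(X \ge D_{ov}),\; X \sim \mathrm{Hypergeom}(C,\, D_{ov}+N_{ov},\, D)$$

The upper tail is summed directly from log-binomial-coefficient terms and
is exact (verified against exhaustive enumeration for every table with
$C \le 30$). $C$ is interpreted as the number of cytosines that entered
the DM test — the population from which DM sites were drawn. A site
overlaps a class by membership (once, however many intervals contain it);
nested classes such as ERVK within all LTRs are tested independently.
Degenerate odds-ratio denominators yield `Inf` rather than a Haldane 0.5
correction — the raw counts are kept in the output so users can apply
their own. BH adjustment spans the annotation classes tested in one call;
enrichment is run separately per channel and per direction (hyper/hypo).

Coordinates follow one internal convention: coverage positions are 1-based
inclusive, BED intervals 0-based half-open, and all interval arithmetic
maps cytosine $p$ to $[p-1, p)$. Chromosome names are matched exactly; no
"chr" normalisation is attempted. CpG dyads are never merged across
strands, matching the granularity of the coverage files.

## The simulator

The simulator exists so that every downstream stage is testable against
known truth without external data. It emulates the statistical structure
of a paired BS/oxBS RRBS study of HP1-deficient mouse hippocampus:

* **Landscape** — `n_sites` CpGs at distinct positions over a configurable
  chromosome layout; each site assigned to one annotation class (CpG
  island, exon, intron, LINE, SINE, ERV1, ERVL_MaLR, ERVK, other LTR,
  ICR-like, clustered-protocadherin) or background, with per-class true
  (5mC, 5hmC) baselines.
* **Effects** — additive deltas on the fraction scale per (condition,
  class, mark), clamped to $[0,1]$ with $m+h \le 1$ enforced by
  proportional rescaling; the simplest structure able to reproduce the
  qualitative biology: marked ERVK/LTR 5mC loss plus protocadherin and
  ICR hypomethylation in the double knockout, de novo CpG-island
  hypermethylation under HP1β loss, and a broad 5hmC gain over introns,
  LINEs, SINEs and LTRs in single mutants and normal aging.
* **Sequencing** — per-library negative-binomial coverage (RRBS depth is
  overdispersed; default mean 30, size 5), independent between BS and oxBS
  since they are separate preps (`depth_matched = TRUE` shares the draw,
  emulating downsampled pairs); binomial modified-read counts with three
  error scalars: conversion failure 0.005 (unmodified read as modified),
  non-conversion of modified bases 0.01, oxidation efficiency 0.95. These
  defaults are synthetic choices — the emulated study reports no numeric
  error rates — of plausible magnitude for bisulfite protocols.
* **Calibration** — per-class baselines are likewise invented (the study
  prints no per-class levels) and were chosen so the coverage-weighted
  global modified fraction is ≈35–36%, the study's reported global level.
  Sites drawing zero coverage are omitted, matching the file-format
  invariant that every record carries at least one read.

What the simulator does *not* model: read-level artefacts (MspI digest
geometry, PCR duplicates, mappability), strand structure, replicate-level
biological overdispersion, and spatial autocorrelation of methylation
along the genome. Passing tests therefore demonstrate correctness of the
inference, testing and enrichment machinery under the stated sampling
model — not robustness to every artefact of real RRBS libraries.

Determinism: every random draw is seeded from the single top-level seed
through labelled sub-streams (`derive_seed`), so a rerun with the same
configuration is byte-identical, per library and per stage.

## End-to-end pipeline

```{r, eval = FALSE}
cfg <- pipeline_config(
  simulation = default_sim_config(n_sites = 10000, n_replicates = 3),
  contrasts = list(list(name = "DKO_aged_vs_WT_aged",
                        group_a = "WT_aged", group_b = "DKO_aged",
                        channels = c("5mC", "5hmC"))),
  seed = 1)
res <- run_pipeline(cfg, outdir = "hmcall_run")
head(res$dm$DKO_aged_vs_WT_aged_5mC)
res$enrichment$DKO_aged_vs_WT_aged_5mC_hypo
```

`run_pipeline()` writes simulated coverage and BED files, inferred
5mC/5hmC coverage per sample, per-replicate global summaries, DM and
enrichment TSVs per contrast/channel/direction, and a JSON manifest
(seed, thresholds, version, file list) from which the run can be
reproduced exactly. A failed stage aborts with the stage name and leaves
the manifest marked incomplete. Real coverage files can replace the
simulation (`coverage_files`/`annotations` in the config) without code
changes; nothing is downloaded.

The shipped YAML (`inst/extdata/default_config.yaml`) and the `hmcall`
script (`inst/scripts/hmcall`, subcommands `simulate`, `infer`,
`diffmeth`, `enrich`, `run`, `validate`) expose the same functionality
from the shell.

## Numerical and design choices

* Percentages are recomputed from counts at full precision before
  subtraction; stored file percents (which may be rounded to 0.5) are
  never used in arithmetic.
* The coverage validator allows a stored percent to deviate from the
  count ratio by $\max(0.5,\ 50/\mathrm{coverage})$: the first term covers
  file rounding, the second the reconstruction bound of 5hmC records,
  whose stored percent is the subtracted percent rather than the count
  ratio.
* A fringe site with zero unmethylated BS reads would reconstruct to a
  zero-read record; such records are dropped from 5hmC coverage output
  rather than emitted invalid.
* The minimum-coverage filter applies per library at pairing and per
  replicate at DM testing; whether to filter before or after pairing is a
  genuine free choice and is applied at pairing here.
* Degenerate enrichment tables ($D_{ov}=0$ with $N_{ov}=0$) return `NaN`
  odds ratios; a zero numerator returns 0.
* Validation sizes: reconstruction consistency on 10,000 random pairs;
  recovery on 10,000 sites at depth-matched mean coverage 50; null
  calibration and ERVK effect recovery on 5,000 sites, 3v3 replicates at
  mean coverage 30, 20 seeds each; the hypergeometric oracle on every
  table with $C \le 30$. These sizes give stable statistics while keeping
  the full suite fast.

## Known limitations

* The subtraction estimator is the method under study; it is noisier than
  joint-likelihood (m, h) estimators and biased toward zero 5hmC at
  unmatched depths, as quantified above.
* With 3v3 replicates the LRT, not the exact test, is in force; at the
  global-null BH boundary its tail anticonservatism admits occasional
  borderline false calls that the exact test would withhold.
* Enrichment treats sites as exchangeable; clustering of DM sites within
  elements (true of real repeats) would overstate significance. The
  simulator places class sites independently, so its tests do not probe
  that failure mode.
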