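---
title: "Methods and design of the breakome hotspot pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the breakome hotspot pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(breakome)
```

## The data model

A breakome sample is a deduplicated set of strand-specific single-nucleotide
records `(chrom, pos, strand, depth)`. Coordinates are 0-based half-open
internally and BED on disk. `pos` marks the base immediately 5′ of the nick
in strand orientation — the base carrying the 3′-OH terminus that the capture
chemistry ligates to. Two consequences of that convention run through the
package: the `C|G` / `|CG` context tests read, in strand orientation, the
base at `pos` and the following one or two bases; and in ±5 bp motif windows
the centre column holds the base at `pos`, with the nick between the centre
column and the next. This is a choice, not something the upstream data
dialect fixes: if your break files mark the base 3′ of the nick instead,
shift by one before import.

All statistics are restricted to *mappable* space: the non-repeat mask minus
positions adjacent to endogenous polyA stretches, where poly(dT)-primed
capture cannot anchor reads. The polyA exclusion rule (a position within K
bases downstream, in strand orientation, of a run of ≥ A_min adenines;
defaults A_min = 8, K = 1) is a parameter because "adjacent" has no standard
definition; the synthetic generator derives the mask from its own sequence
with the same rule.

## Hotspot definitions and the null

Three stringencies: sample-level (within-sample depth ≥ 2, unioned over a
tissue's samples), sample-shared at depth ≥ 1 in ≥ 2 samples, and
sample-shared at depth ≥ 2. Raising either threshold can only shrink the
set, which the tests assert as a property. Hotspot *fractions* are reported
against the pooled distinct break positions of the tissue — positions, not
reads, so that real and simulated data are commensurable (the null
regenerates positions). The denominator choice is recorded in output
metadata because figure-level fraction definitions vary between studies.

The null re-places each sample's position count uniformly (without
replacement) over mappable space × 2 strands, re-calls hotspots with the
identical definition, and repeats (default 100 iterations). Simulated depths
are resampled from the real sample's empirical depth distribution, so
depth-thresholded definitions are genuinely exercised — a uniform null says
nothing about how simulated records acquire depth ≥ 2, and constant-depth
filling would make sample-level calling vacuous. The comparison is a
two-sided one-sample t test of the simulated fraction vector against the
observed fraction, summarised as `ratio = real / mean(simulated)`.

## TSS statistics

Every position is assigned to its nearest TSS (only the shortest distance
is kept); equidistant ties go to the smaller genomic coordinate, and among
transcripts sharing a coordinate the lexicographically first
(gene_id, transcript_id) row represents the TSS — all deterministic.
Template means the break strand is opposite the gene strand.

The enrichment ratio `R = (M200/M5000)/(L200/L5000)` counts unique
positions in the *merged* ±200 bp and ±5 kb windows over all TSSs, with
effective lengths from the same merge; merging prevents double counting
where gene TSSs crowd together. The six bins (±5, ±6–20, ±21–50, ±51–100,
±101–150, ±151–200 bp; closed on both ends, the ±5 bin containing d = 0 and
hence 11 positions) exactly partition the ±200 core.

Per-bin odds ratios use `OR_i = (M_i/T)/(L_i/LG)`. Two geometric details
matter and were both validated against uniform data:

* **L_i must be nearest-TSS-consistent.** The bin-i region is
  `union(±hi windows) \ union(±(lo−1) windows)` — the set of bases whose
  nearest-TSS distance lies in the bin — not the union of per-TSS annuli.
  Where a gene's transcript TSSs sit within a few hundred bp of each other
  the naive union overstates outer-bin length substantially (we measured
  ~45% OR deflation in the ±151–200 bin on uniform data before the fix).
* **Strand-split counts need a halved length term.** The OR formula is
  exactly calibrated (uniform ⇒ 1) when M_i counts both strands. For a
  template-only or nontemplate-only count, each base offers one qualifying
  strand out of the two genome-wide slots, so those rows use
  `(M/T)/(L_i/2LG)`. The class-agnostic `"both"` rows keep the plain
  formula. Without the correction, uniform data yields class ORs of ~0.5
  against a "no enrichment" reference line of 1.

Density profiles split ±5 kb into 500 × 20 bp bins; `f_j` is the mean
mappable fraction of bin j over all TSSs (computed exactly from prefix sums
of the mappable indicator) and `D_j = (n_j/N)/f_j` per strand class, NA
where `f_j = 0`. A position at exactly +5 kb is clamped into the last bin.

Tissue-level contrasts (template vs nontemplate, hotspot set vs background)
use exact paired one-sided Wilcoxon signed-rank tests with zero differences
excluded.

Three template:nontemplate estimators coexist and are deliberately kept
apart. Position-level count ratios per bin mirror figure-style summaries
but are attenuated where positions saturate (the denser strand collapses
more); hotspot-set ratios are inflated toward the squared odds because
recurrence probability scales with the squared per-strand rate; the
depth-weighted event ratio (`template_bias_estimate()`) counts break
events directly and is the unbiased estimator of the underlying strand
odds — it is what parameter-recovery checks use.

## SSB–AP overlap and CG context

Base-excision repair predicts two nick positions with fixed offsets from an
AP site: the APE1 incision immediately 5′ of it, and the post-fill-in nick
immediately following it. The overlap analysis therefore runs in two modes:
direct intersection, and "AP − 1", where AP coordinates are first shifted
one base upstream in strand orientation. `OOR = (O/T)/(M/LG)`. Overlap is
strand-matched by default (the BER nick inherits the AP site's strand); a
strand-agnostic flag exists for sensitivity analysis. The companion
significance test is a one-sided Fisher exact test on the 2×2 table
`(O, T−O, M−O, LG−T−M+O)`, i.e. treating the LG effective base pairs as the
candidate universe — consistent with OOR's own use of LG rather than 2·LG.

CG context asks whether the nick falls in `C|G` or `|CG` on its own strand.
Positions whose test would read past a contig end are excluded from the
denominator and counted. The background is not a formula but an exhaustive
enumeration: the same rule applied to every stranded position of the masked
space (optionally restricted to TSS windows), so observed and expected
fractions are computed by the identical test.

## Expression association

Gene-level hotspot presence considers *any* annotated TSS of the gene.
Per tissue and strand a gene sits in the most TSS-proximal bin containing a
hotspot; pooled groups are the union over tissues, each gene contributing
the mean TPM of the tissue in which it qualified (a strict
most-proximal-across-tissues mode is available — the pooling rule is
genuinely ambiguous, and both readings are implemented with the union as
default). All displays and tests use `log2(TPM + 1)` with two-sided
rank-sum tests; fully tied comparisons report p = 1 rather than NaN.
A `representative_transcript()` helper makes the one-transcript-per-gene
choice reproducible under a seed when transcript-level quantifications are
collapsed upstream.

## The synthetic generator

The generator emulates exactly the statistical structure the pipeline
measures, and nothing else — no chromatin, replication timing, or real
mutation spectra. Defaults describe the study scale the package is tested
at: one 2 Mb chromosome, GC 0.42, 40% repeat tiles of 1 kb, 20 planted
polyA/polyT runs, 200 genes (1–3 transcripts each, extra TSSs 0–300 bp
downstream), 3 tissues × 4 samples × 20,000 break events.

Break events are drawn from an explicit per-slot probability law over
(mappable position × strand):

* TSS enrichment: in-window weight `1 + (e − 1)·shape(bin)` with shape
  increasing toward ±5 and normalised to window mean 1, so the mean ±200 bp
  enrichment is exactly `e` (default 5) and `e = 1` is exactly flat — the
  null construction used for calibration tests.
* Template bias: within ±200 bp the strand follows template odds β
  (default 2); elsewhere strands are even.
* Upstream-C bias: a mixture component restricted to positions whose
  strand-oriented base is C, mixed so the marginal C fraction at `pos` hits
  the target (default 0.5).
* Shared structure: with probability h (default 0.3) an event comes from a
  hot-position pool (default 2,000 slots) drawn once from the same law.
  Weighted distinct-slot draws use Efraimidis–Spirakis sampling with
  log-scale keys `log(u)/p`; the textbook `u^(1/p)` form underflows at
  genome-scale slot probabilities and silently degenerates to index order.
* Depth: `1 + Geometric(p = 0.8)` per event, events collapsed by position
  with depths summed — so sample-level (depth ≥ 2) calling has organic
  positives and hot slots pile up depth naturally.

AP samples use a flat law with a purine bias at the site (default 0.7) and
an AP pool coupled to the SSB pool at rate c (default 0.5), either at the
identical position ("direct") or one base downstream so that the AP − 1
shift recovers it ("offset") — the two modes let tests verify that overlap
signal appears only in the matching mode. Expression is log-normal per gene
(meanlog 1, sdlog 1), multiplied by γ (default 2) for genes with a planted
hot position within ±200 bp of any TSS — or by per-bin multipliers for the
distance-graded scenario — with per-sample log-normal noise (sdlog 0.5).

`expected_enrichment_ratio()` is the generator's own oracle for R: it sums
the realised per-slot probabilities over the merged windows, optionally as
`1 − (1 − q_s)^n` to account for unique-position saturation at hot slots —
a numerical expectation, independent of the pipeline's counting path. At
default scale saturation attenuates R by ~15%, which is real measurement
behaviour, not generator error; recovery tests compare against the
saturation-aware expectation.

What passing tests do and do not show: calibration and recovery on this
generator demonstrate the statistics are computed correctly and are
sensitive to planted structure at realistic effect sizes. They do not show
that real breakomes satisfy the generator's assumptions (uniform
background, piecewise-constant enrichment, independent samples), and
absolute values from real tissues will differ.

## Problem sizes and numerical choices

The test suite runs the full default 2 Mb scenario once for parameter
recovery, a 1 Mb × 300-gene scenario for the distance-graded expression
trend, and smaller instances elsewhere: null-ratio stability uses 100 seeds
of 2 × 1,500 uniform breaks over 60 kb with 25 iterations each (the ratio
statistic depends on the mean of simulated fractions, so fewer iterations
widen but do not bias it), and expression type-I calibration uses 200 seeds
of 150 + 150 genes. These sizes were chosen as the smallest at which the
binomial/collision expectations quoted in the tests are sharp.

Other conventions, for completeness: strict inequality at the 5% motif
display threshold; windows truncated by contig ends are excluded from motif
matrices with a logged count; ambiguous bases drop out of the affected
column's denominator; `simulate_breaks` draws without replacement via
uniform slot indices; every run directory carries a manifest with the
config, seeds and output digests, and a fixed seed reproduces all outputs
byte-identically.

## Known limitations

* Nearest-TSS assignment gives each position one gene; antisense or
  bidirectional promoters sharing a TSS coordinate resolve by a
  deterministic but arbitrary tie-break.
* The OR/OOR significance machinery treats positions as independent;
  clustered damage (e.g. a single lesion detected on both strands) would
  overstate significance.
* `LG` treats the genome as one candidate slot per base in the Fisher
  table, mirroring the OOR definition; a fully stranded universe would use
  2·LG and roughly halve the odds ratios.
* The expression analysis consumes a gene × sample TPM matrix as given; no
  normalisation or batch handling is attempted.
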