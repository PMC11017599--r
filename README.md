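# breakome

Nucleotide-resolution hotspot analysis of DNA single-strand breaks (SSBs)
and abasic (AP) sites.

Techniques that capture 3′-OH break termini (and, with an extra chemistry
step, AP sites) yield strand-specific, single-nucleotide "breakome" maps:
per sample, a set of `(chromosome, position, strand)` records with a read
depth. Two questions follow immediately. Do breaks recur at the *same
nucleotide* more often than chance — i.e. do hotspots exist? And if so,
where do the hotspots sit relative to gene regulatory anatomy, what
sequence do they prefer, and do they track gene expression? `breakome`
implements that analysis end-to-end for anyone working with such maps,
and ships a synthetic-data generator with known planted structure so the
whole pipeline can be validated without any external data.

## What it computes

**Hotspot calling** at three stringencies, per tissue and strand:
sample-level (within-sample depth ≥ 2), sample-shared (≥ 1 read in ≥ 2
independent samples), and sample-shared at depth ≥ 2. Calling is
restricted to the non-repeat, non-polyA-adjacent portion of the genome.

**Randomised null.** Each sample's break count is re-placed uniformly over
mappable space, hotspots are re-called identically across (by default) 100
iterations, and the observed hotspot fraction is compared with the
simulated fractions via a two-sided one-sample t test and the ratio
`real / mean(simulated)`.

**TSS proximity.** With nearest-TSS assignment (template strand = opposite
of the gene strand), the package computes aggregate density profiles
(500 × 20 bp bins over ±5 kb, normalised per bin by mean mappable
fraction, `D_j = (n_j/N)/f_j`), the TSS enrichment ratio

```
R = (M200 / M5000) / (L200 / L5000)
```

(unique positions within ±200 bp vs ±5 kb of TSSs, normalised by the
effective window lengths), and per-distance-bin odds ratios over the six
bins ±5, ±6–20, ±21–50, ±51–100, ±101–150, ±151–200 bp:

```
OR_i = (M_i / T) / (L_i / LG)
```

with `T` the genome-wide position total and `LG` the effective non-repeat
genome length (for template/nontemplate-split counts the length term is
`L_i / 2LG`, so "no enrichment" is 1 in every row). Template:nontemplate
count ratios per bin quantify strand bias; paired one-sided Wilcoxon
signed-rank tests compare tissues.

**BER provenance.** SSB–AP overlap odds ratios
`OOR = (O/T) / (M/LG)` in two modes — direct (post-fill-in nick of
short-patch BER) and "AP − 1" (the APE1 nick, detected by shifting AP
coordinates one base upstream in strand orientation) — plus
CG-dinucleotide context fractions of hotspots (`C|G` or `|CG`, `|` = the
nick) against exhaustively enumerated background fractions.

**Motifs.** Strand-oriented ±5 bp base-composition matrices around breaks
and TSSs, signed difference profiles with a strict 5% display threshold,
and a test for cytosine enrichment immediately upstream of the nick.

**Expression.** Two-sided rank-sum comparisons of `log2(TPM+1)` between
genes with and without TSS-proximal hotspots, and the hierarchical
distance-bin analysis (each gene in its most TSS-proximal bin per strand,
pooled across tissues).

## Worked example

```r
library(breakome)

cfg <- synthetic_config(genome_length = 5e5L, n_genes = 50L,
                        breaks_per_sample = 5000L, n_tissues = 2L,
                        samples_per_tissue = 4L, rng_seed = 7L)
sim <- simulate_breakome(cfg)
mappable <- mappable_mask(sim$bundle$non_repeat, sim$bundle$polyA_excluded)
ssb <- lapply(sim$ssb$samples, mask_filter, mask = mappable)
liver <- ssb[1:4]                                   # one tissue

hs <- call_sample_shared(liver, min_depth = 1, min_samples = 2)
nrow(hs)                                            # 1728 hotspots
nrow(breaks_universe(liver))                        # of 15479 positions

run_null(liver, hotspot_definition("sample_shared", 1), mappable,
         n_iter = 20, rng_seed = 1)
#> <null_result sample_shared(depth>=1, samples>=2):
#>   real=0.112 mean(sim)=0.0111 ratio=10.1 p=1.95e-44 (20 iter)>

er <- enrichment_ratio(breaks_universe(liver), sim$bundle$tss,
                       sim$bundle$non_repeat, sim$bundle$polyA_excluded,
                       sim$bundle$bounds)
er$R                                                # 4.18
```

The generator planted 30% of break events on a shared hot-position pool
and a 5× mean enrichment over ±200 bp of TSSs: the observed hotspot
fraction is ~10× the uniform-null expectation (ratio 10.1, p ≈ 2e-44) and
the enrichment ratio R = 4.18 reflects the planted 5× factor after the
±5 kb normalising window (which is itself partly enriched) and
unique-position saturation are accounted for. The ±5 bp bin shows
`OR(template) = 7.8` and a template:nontemplate ratio of 1.63, recovering
the planted template odds β = 2 up to the same saturation.

A full run with every stage and TSV/JSON outputs:

```r
run_breakome(synthetic_config(), out_dir = "run1")
summarize_breakome("run1")
```

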