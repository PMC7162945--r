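# rhythmod

Module-level detection and phasing of diel transcriptional rhythms in
multi-organ expression time courses.

## The problem

In a diel (day/night) time-course experiment several organs are profiled in
parallel — the motivating design is three organs of a field-grown grass
(source leaf, growing internodes, storage internode) sampled every 2 h for
26 h: 14 time points starting 2 h before dawn, dawn at 5:45, dusk at 19:00
(13.25 h photoperiod). The questions: which transcripts cycle, when do they
peak, and how do peak times compare across organs?

With ~10⁴ transcripts and only 14 samples, per-transcript testing is noisy.
`rhythmod` implements a module-level strategy aimed at exactly this setting:

1. **Expression call** — a transcript is expressed when detected above local
   background in ≥ 8 of 14 time points ("more than 7").
2. **Coexpression modules** — Z-scored series form an unsigned weighted
   network, *a<sub>ij</sub>* = |cor(*x<sub>i</sub>*, *x<sub>j</sub>*)|^β with
   β = 18; average-linkage clustering on topological-overlap dissimilarity,
   sign splitting of each cluster, pointwise-median *representative* series,
   merging of modules with representative dissimilarity ≤ 0.25, and a 0.175
   adjacency threshold for final modules.
3. **Exact rhythm test** — each representative is scored against cosine
   reference rank patterns over a (period × lag) grid with the Kendall-type
   statistic *S* = Σ<sub>i&lt;j</sub> sign(*x<sub>j</sub>* −
   *x<sub>i</sub>*) · sign(*r<sub>j</sub>* − *r<sub>i</sub>*); the
   per-combination P comes from the exact permutation null (a
   Jonckheere–Terpstra distribution conditioned on the reference tie
   pattern, built by q-multinomial convolution), and the minimum P is
   Bonferroni-adjusted over the grid. Modules with adjusted P < 0.75 are
   rhythmic.
4. **Member filter and phase** — members with Spearman ρ < 0.3 against their
   representative are dropped; module phases (the best-fitting lag, i.e.
   hours between dawn and the peak) are harmonised across organs against a
   dendrogram of all representatives; every retained member of a rhythmic
   module inherits the corrected phase.
5. **Comparative statistics** — Euler region counts across organs,
   hypergeometric over/under-representation of functional categories
   (upper-tail P < 0.05 → over, > 0.95 → under), chi-square comparisons of
   categorical distributions, phase histograms, day/night fractions.

A synthetic multi-organ generator with exact planted ground truth (rhythmic
fraction, dawn/dusk-concentrated phases, amplitudes, noise, detection
dropout, cross-organ sharing and phase shifts) makes every stage testable
offline. See the vignette in `vignettes/diel-rhythm-detection.Rmd` for the
model, parameter meanings, and design decisions.

## Worked example

```r
library(rhythmod)

design <- diel_design()          # 14 points, ZT-2..ZT24, dawn 5:45, dusk 19:00
spec <- list(n_transcripts = 500, rhythmic_fraction = 0.3,
             amplitude_range = c(1, 1), noise_sd = 0.25)
data <- simulate_multi_organ(design, list(L1 = spec, I1 = spec),
                             sharing_spec(n_shared = 375, n_rhythmic_shared = 75),
                             seed = 1)
analysis <- run_full_pipeline(lapply(data[c("L1", "I1")], `[[`, "matrix"))
analysis
#> rhythm_analysis
#>   L1: 500 expressed, 153 rhythmic (30.6%)
#>   I1: 500 expressed, 152 rhythmic (30.4%)
```

Each organ planted 150 rhythmic transcripts (30%); the pipeline recovers
153 and 152 calls. Per-transcript calls carry module, phase, 2-h bin and a
day/night flag:

```r
head(subset(analysis$calls$L1, rhythmic), 3)
#>    transcript_id organ expressed module_id sign rhythmic phase_zt phase_bin day_peak
#> 13        t00013    L1      TRUE      M01-    -     TRUE       12      ZT12     TRUE
#> 14        t00014    L1      TRUE      M01+    +     TRUE        0      ZT00     TRUE
#> 20        t00020    L1      TRUE      M01+    +     TRUE        0      ZT00     TRUE

h <- phase_histogram(na.omit(analysis$calls$L1$phase_zt))
h[h > 0]
#> ZT00 ZT12
#>   91   62
```

The recovered phases sit in the two planted peak-time bins (dawn, ZT0, and
ZT12), and both fall inside the 13.25-h photoperiod, so all peaks here are
day peaks. Cross-organ phase agreement for transcripts rhythmic in both
organs:

```r
a <- analysis$calls$L1; b <- analysis$calls$I1
both <- intersect(a$transcript_id[a$rhythmic], b$transcript_id[b$rhythmic])
table(classify_phase_relation(a$phase_zt[match(both, a$transcript_id)],
                              b$phase_zt[match(both, b$transcript_id)]))
#> same
#>   75
```

All 75 transcripts of the shared rhythmic pool have the same phase (± 2 h)
in both organs, as planted.

A command-line interface wraps the same functions
(`inst/cli/rhythmod simulate|run|enrich|report`); see `?cli_main`.

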