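---
title: "Integrative copy-number and expression analysis of paired tumor/normal arrays"
author: "cnvIntegrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative copy-number and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvIntegrate)
```

## Scope and model

`cnvIntegrate` analyses paired tumor/normal cohorts assayed with array-CGH
(probe-level log2 tumor/normal ratios) and gene-level expression arrays
(log2 signals with one tumor and one normal column per sample). The
pipeline has five stages:

1. **Per-sample aberration calling.** Each sample's ratio track is
   centralized (mode subtraction), its probe noise $\hat\sigma$ is
   estimated, and aberrant intervals are found by recursive
   maximal-scoring-interval search with score
   $$S(I) = \frac{|\bar r_I|\,\sqrt{|I|}}{\hat\sigma},$$
   the interval mean in noise-s.d. units scaled by the square root of the
   probe count. Intervals with $S \ge 4$ are called, then filtered:
   at least 2 probes, $|\bar r_I| \ge 0.5$ (a 1.4-fold amplitude floor
   that suppresses shallow calls), at most 10,000 calls per sample, and
   chromosome Y excluded.
2. **Recurrence.** Calls are rasterized onto the probe grid; a probe run
   altered in at least $\lceil 0.25\,n\rceil$ samples (7 of 27) is a
   recurrent region, and the locally maximal carrier-count plateaus
   inside it are the minimal common regions (MCRs) — the smallest
   intervals shared by the most samples. Gains and losses are processed
   independently; sizes are reported in Mb (half-up, two decimals) and
   frequencies as `count (percent)` with nearest-integer percents.
3. **Subtype comparison.** For each region and each clinical contrast
   (PD vs MD histology, T1-2 vs T3-4, N0 vs N1-3), samples are classified
   gain/neutral/loss (a call must cover at least half the region) and the
   resulting 2 × 3 table is tested with a conditional exact Fisher test
   computed by full enumeration of margin-preserving tables. Samples with
   partial signet-ring histology are excluded throughout, mixed (M-PD)
   histology is excluded from the histology contrast, regions on X/Y are
   skipped, and a region is only tested when at least 25% of at least one
   group carries a classifying gain or loss. Significance is the raw
   $p < 0.05$, with Benjamini–Hochberg FDR reported alongside.
4. **Dosage integration.** For genes inside recurrent regions and above
   the expression signal cutoff: the gene copy ratio is the mean log2
   ratio of overlapping probes per sample; samples with
   $|\log_2| \ge 0.585$ (1.5-fold) in the region's direction are CNV+;
   the dosage fold change is
   $$\mathrm{FC} = \frac{\mathrm{median}\,2^{x_T,\ \mathrm{CNV+}}}
                        {\mathrm{median}\,2^{x_T,\ \mathrm{CNV-}}},$$
   selected at 1.3-fold (2-fold for region "target genes"), with the
   reciprocal rule for losses; and the Pearson correlation between gene
   copy ratio and tumor-minus-normal expression log2 ratio is tested via
   $t = r\sqrt{n-2}/\sqrt{1-r^2}$.
5. **Clustering and validation.** Dosage-selected genes are clustered
   two-way (genes and T/N sample columns) by average linkage on
   1 − Pearson distances; cutting the sample tree into two clusters gives
   a tumor/normal separation purity. qRT-PCR validation data are reduced
   with the $2^{-\Delta\Delta C_t}$ method (ACTB-normalized triplicates,
   matched normal as calibrator) and correlated with the gene copy
   ratios by the same machinery.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `admThreshold` | 4 | noise s.d. | minimum interval score $S$ |
| `minProbes` | 2 | probes | minimum call length |
| `minAbsMean` | 0.5 | log2 | amplitude floor (1.4-fold) |
| `maxRegions` | 10,000 | calls | per-sample call cap (top by score) |
| `recurrenceFraction` | 0.25 | — | recurrence rule |
| `cnvCallLog2` | 0.585 | log2 | CNV+ classification (1.5-fold) |
| `fcCutoff` / `targetFcCutoff` | 1.3 / 2.0 | fold | dosage / target-gene selection |
| `exprSignalCutoff` | 3.9 | log2 signal | expressed-gene filter (strict >) |
| `alpha` | 0.05 | — | scan and correlation significance |
| `classifyingFraction` | 0.25 | — | per-group gate before a region is tested |

All are bundled in `cnvConfig()`, and every writer stamps the full
configuration and seed into `#` header lines so outputs identify their
run.

## The synthetic cohort and what it does (not) emulate

`simulateCohort()` generates the benchmark conditions used throughout the
tests: 27 sample pairs, four chromosomes of 2,000 uniformly spaced probes
(10 kb spacing, so 20 Mb chromosomes), 500 evenly spaced genes, and eight
injected segments with log2 shifts ±0.8 whose carrier fractions span
0.15–0.70 — a high-frequency large gain (70%), a second frequent gain
(63%), mid-frequency gains and losses, one non-recurrent gain, and one
gain carried by 80% of the MD-histology samples only, to exercise the
subtype scan. Probe ratios are Normal(shift, 0.2) inside carried
segments, Normal(0, 0.2) elsewhere, all offset by +0.1 so centralization
has work to do. Within each segment, alternating genes respond to dosage
(tumor expression = baseline + coefficient × true copy ratio + noise,
coefficient 1 by default); the others are copy-altered bystanders, which
gives the selection benchmarks genuine negatives. Clinical labels mirror
the cohort composition (12 PD of which 2 SRCC-flagged, 11 MD, 4 M-PD).
All randomness flows from one seed with a fixed draw order, so cohorts
are exactly reproducible.

Deliberately not modelled: tumor purity and capture efficiency, probe GC
bias and probe-quality weights (probes are homoscedastic), RMA
summarization (expression is simulated at gene level), and any
tumor-intrinsic expression change beyond gene dosage. The last point
matters when interpreting the clustering benchmark: a synthetic tumor
that happens to carry few injected segments has a genuinely normal-like
expression profile, so two-cluster purity can dip for some seeds; real
cohorts carry a denser genome-wide aberration burden. Passing tests
demonstrate correct recovery of the injected structure, not performance
on real arrays — in particular the score threshold's behaviour on real
data depends on the vendor's probe-error model, which is not reproduced.

## Numerical choices

- **Centralization** subtracts the histogram mode (bin width 0.01) with
  parabolic refinement over the modal bin and neighbours; constant input
  returns itself as the offset. The mode of a broad Gaussian peak is
  intrinsically coarse (a few hundredths at $\sigma = 0.2$), which is
  immaterial against the 0.5 amplitude floor.
- **Noise** is the median absolute adjacent-probe difference within
  chromosomes divided by $0.6745\sqrt 2$ — robust to true copy steps —
  floored at $10^{-8}$ so constant tracks stay finite and yield no calls.
- **Tie-breaking**: equal-scoring intervals resolve leftmost-then-
  shortest; equal agglomeration distances resolve to the lowest index
  pair. Both make results platform-deterministic.
- **Fuzzy-zero approximation**: the vendor's long-aberration correction
  is unspecified, so shallow-call suppression is implemented as the
  post-hoc $|\bar r| \ge 0.5$ floor.
- **Degenerate inputs**: Fisher tables with an empty row/column margin
  return $p = 1$; zero-variance correlation inputs are flagged NA rather
  than guessed; constant clustering columns get unit distance with a
  warning; genes without probe coverage are excluded and flagged (as a
  real cohort's *GRINA* would be).

## Open design points, resolved

- **MCR semantics** are not algorithmically defined in copy-number
  reports; the locally-maximal-plateau rule is standard MCR semantics
  and reproduces the finer-than-region partitioning seen in published
  tables (e.g. a broad 20q-like gain splitting into adjacent MCRs).
  Probe bounds (not midpoints) define region ends.
- **Fold change scale**: "median expression" is computed on the linear
  scale of tumor signals ($2^{\log_2}$), because fold change is a
  linear-scale concept and published FC ranges (1.3–9.8) are
  linear-style. The loss-side selection uses the reciprocal
  $\mathrm{FC} \le 1/1.3$.
- **Region-level sample call**: a call must cover ≥ 50% of the region;
  published methods state no overlap rule.
- **Scan units** are the recurrent regions by default (any region set,
  e.g. fixed bins, can be passed to `scanRegions()`).
- **Clustering distance** is 1 − Pearson on gene-centered log2 signals
  (the log-ratio scale such heatmaps display); Euclidean is available.
  Gene centering matters: on absolute signals, per-gene baselines
  dominate every between-column correlation and mask the tumor/normal
  structure.
- **Scan calibration null**: an aberration-free cohort produces
  all-neutral tables ($p = 1$ everywhere), which calibrates nothing, so
  the type-I benchmark draws per-sample region states i.i.d.
  (gain/neutral/loss at 0.35/0.50/0.15, mirroring recurrent-region
  carrier frequencies) independently of group labels.

## Problem sizes used by the test suite

Unit tests run on 50–500-probe fixtures with exhaustive oracles
(interval scoring, Fisher enumeration vs. the reference network
algorithm, a brute-force average-linkage agglomerator, definitional
Pearson). Calibration tests use 200 null segmentation tracks of 500
probes, 5,000 label-free Fisher replicates, and 1,000 null correlation
replicates. The end-to-end benchmark runs the full default cohort
(27 × 8,000 probes, 500 genes) once per seed.

## Worked example

```{r example, eval = FALSE}
sim <- simulateCohort(seed = 1)
res <- runCohortAnalysis(sim$probes, sim$expression, sim$metadata,
                         sim$annotation, cnvConfig(seed = 1))
res$regions                      # recurrent regions with count (percent)
res$mcrs                         # MCRs with target genes
head(res$dosage)                 # per-gene FC, r, p, FDR, flags
res$scans$PD.MD                  # Fisher scan of the histology contrast
res$cluster                      # two-way clustering, separation purity
segmentRecovery(sim$truth, res$regions)
```

## Known limitations

Segmentation uses equal probe weights and no GC correction; absolute
call counts on real vendor arrays will differ even at the same
threshold. The exact conditional Fisher test is discrete and therefore
conservative at small group sizes (empirical size below the nominal
0.05). MCRs are reported by coordinates; cytoband naming requires an
external cytoband table and is out of scope. The qPCR module assumes
perfect doubling per cycle (no efficiency correction).
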