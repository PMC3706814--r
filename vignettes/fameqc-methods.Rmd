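---
title: "Quantification and internal QC for high-throughput FAME profiling"
author: "fameqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification and internal QC for high-throughput FAME profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fameqc)
```

## The measurement problem

Plasma phospholipid fatty acid composition is a dietary biomarker used in
large epidemiological studies. The assay behind this package profiles
fatty acid methyl esters (FAMEs) by gas chromatography with flame
ionization detection (GC-FID): phospholipids are isolated, hydrolysed and
methylated, and the FAMEs separated on a polar capillary column. The FID
response is close to proportional to analyte mass, so each fatty acid is
reported as its share of the total fatty acid signal — *area percent* —
rather than as an absolute concentration. Batches of 32 vials (up to 29
samples, one process blank, and two quality-control plasmas: QC1 pooled
human, QC2 pooled horse) run for months across parallel instruments, so
the scientific problem is as much statistical quality control as it is
quantification.

`fameqc` implements the data-analysis layer of such a workflow, starting
from integrated peak tables (retention time, area, height per peak). The
physical workflow — extraction, solid-phase cleanup, derivatization,
instrument control, and peak integration — is out of scope.

## The quantification model

For one injection with peaks $p_1, \dots, p_m$ and a panel of analytes
with expected retention times $r_1 < \dots < r_n$:

1. **Identification.** Peaks are matched to analytes by retention time.
   A pair is eligible when $|rt_{peak} - r_i| \le \tau$ (default
   $\tau = 0.1$ min). Among eligible matchings that use each peak and
   each analyte at most once, the package maximises the number of
   matched analytes and then minimises $\sum |\Delta rt|$; remaining
   ties go to the earlier-eluting peak. Because both sequences are
   sorted and the cost is an absolute difference, the optimum is
   order-preserving and is found by an $O(nm)$ dynamic program (the
   uncrossing argument: swapping a crossed pair never increases either
   the match count or the total deviation). The suite checks this
   program against exhaustive enumeration on small instances.
2. **Co-elution.** Analyte pairs the column cannot resolve are summed
   under a single reported code; the default panel reports
   C20:3n3 + C20:4n6 as C20:4n6, C20:3n3 being negligible in human
   plasma. One merge plus the two solvent-peak exclusions (C4:0, C6:0)
   takes the 37-component mix plus 3 added standards to exactly 37
   quantifiable analytes.
3. **Blank correction.** The process blank of the same batch measures
   contamination (typically trace C14:0, C16:0, C18:0); its areas are
   subtracted per analyte, clipped at zero, *before* percentages are
   formed. Per-batch (rather than long-run average) subtraction is the
   default because contamination tracks reagent lots batch by batch.
4. **Relative quantification.** $pct_i = 100 \, a_i / \sum_j a_j$ over
   the corrected areas; closure to 100 within $10^{-9}$ is an invariant
   of every profile.
5. **BLOQ flagging.** Any analyte whose final percent is strictly below
   0.15% of total signal is flagged below the limit of quantification —
   at such levels long-term reproducibility degrades beyond a 20% CV.
   Flagged values are retained, not zeroed, so closure holds and
   downstream stages can decide what to exclude.

The area-percent definition follows the method's own convention; no
molar response-factor correction is applied (a non-goal here), so
"percent" throughout means percent of detector signal.

## Calibration and detection-limit diagnostics

Calibration uses a 5-level dilution series of the standards (relative
volumes 0.01, 0.05, 0.1, 0.5, 1.0). Per analyte the package fits
ordinary least squares of area on amount and reports $R^2 = 1 -
SS_{res}/SS_{tot}$; the published instrument showed $R^2$ between 0.991
and 1.00 over a dynamic range of 0.15–40% of total signal, and the
simulated default series reproduces that bound. The limit of detection
follows the 3:1 signal-to-noise convention, $LOD = 3\,\sigma_{noise} /
slope$. Raw baseline-noise measurements are not part of a peak table, so
by default $\sigma_{noise}$ is taken as the residual SD of the
calibration fit — a conservative, always-available proxy; callers with a
measured noise floor can pass it directly.

The plasma-equivalent LOQ scales the on-column limit by the volumetric
chain of the preparation: plasma volume × 0.8 (1600/2000 µl of the
chloroform layer recovered) × 0.6 (600/1000 µl of the hexane layer) ×
injection/reconstitution × 1/21 (20:1 split, on-column fraction taken as
$1/(split+1)$; instrument conventions vary, so this is configurable).
The identity LOQ(125 µl, 2 µl) = LOQ(250 µl, 1 µl) falls out of the
arithmetic and is asserted in the tests. Spike recovery is computed per
replicate as $100 (measured_{spiked} - measured_{unspiked}) / spike$ and
summarised as mean and CV; the operation is unit-agnostic but
unit-consistent.

## Internal QC: Shewhart charts and long-term precision

Routine monitoring inserts QC1 and QC2 into every batch. After a
baseline period — 60 successive batches in the published program — the
per-analyte mean and between-batch SD (always the $n-1$ sample SD)
define an individuals Shewhart chart: centre line Avg and control limits
Avg ± k·SD. The sigma multiplier is not stated in the source program;
k = 3 is the standard individuals-chart choice and the default, with k
exposed as a parameter. Only the one-point-beyond-limit rule is applied,
with boundary values counting as in control; for i.i.d. normal data this
gives the textbook ≈0.27% false-alarm rate, which the suite verifies on
10,000 simulated points within three binomial standard errors. Baseline
points are plotted and flagged as baseline rather than excluded from the
chart.

Long-term precision is the percent CV, $100\,s/\bar{x}$, over the full
series. For stability reporting the series is split into monthly-sized
groups and summarised as (n, mean, SD); the package recombines such
summaries without access to raw data:

* weighted grand mean $\sum n_i \bar{x}_i / \sum n_i$;
* pooled overall CV from the total sum of squares
  $\sum (n_i - 1) s_i^2 + \sum n_i (\bar{x}_i - \bar{x})^2$, which
  equals the CV of the concatenated raw series exactly whenever the
  groups partition it (tested as an identity);
* single-factor ANOVA from summaries:
  $F = MS_{between}/MS_{within}$ with
  $MS_{between} = \sum n_i(\bar{x}_i - \bar{x})^2/(k-1)$ and
  $MS_{within} = \sum (n_i - 1) s_i^2/(N-k)$.

The summary-statistics ANOVA is validated against an *expansion oracle*:
raw pseudo-data constructed to match each (n, mean, SD) exactly must
give the identical F and p through `stats::aov`. This matters because
published stability tables print rounded means and SDs: recomputing the
ANOVA from a rounded table does not reproduce a p-value computed from
the unrounded raw data (for the reference DHA table, rounded inputs give
F ≈ 1.40, p ≈ 0.19), and the table's own monthly CV column is likewise
inconsistent with its rounded mean/SD entries. Equivalence to the
oracle — not agreement with an unreproducible printed p — is therefore
the correctness criterion, and monthly CVs are not used as targets.

## Method comparison

To compare two preparation methods on aliquots of one material, the
package summarises each group per analyte (mean, SD, CV), restricts to
"major" analytes (group mean ≥ 0.1% by default, matching the 19-analyte
selection used for horse plasma), and reports: Pearson correlation of
the paired per-analyte means; Bland–Altman agreement (mean difference
and 1.96·SD limits — the limits are reported for completeness even where
a source quotes only the average difference); a precision table of
per-method SDs with the sign of their difference; and optional Welch
t-tests per analyte (unequal variances assumed, since pooling is rarely
defensible across preparation methods).

## The synthetic generator

Every stage is testable without instruments through a seeded generator.
Its defaults are the study conditions of the reference program:

| parameter | default | meaning |
|---|---|---|
| `total_area` | 1e6 | total signal of a nominal injection |
| `area_noise_cv` | 0.02 | multiplicative detector noise CV |
| `rt_jitter_sd` | 0.02 min | Gaussian retention-time jitter |
| `blank_trace` | C14:0 0.02, C16:0 0.10, C18:0 0.05 | percent-equivalent contamination |
| `drift_per_batch` | 0 | per-analyte multiplicative drift |
| QC compositions | long-term Table of means/SDs | per-analyte normal draws |

Design choices a user should know:

* **Two emulation modes.** QC series can be drawn directly as measured
  percentages (`simulateQcMeasurements`) — matching how long-term
  statistics are tabulated, marginal per analyte, with no closure
  imposed — or as full peak tables that the quantification stage
  renormalises. Forcing closure inside the generator would bias the
  marginal CVs the tables report, so closure is applied only where the
  pipeline itself applies it.
* **Contamination model.** The trace the process blank measures is real
  contamination of every preparation, so `simulateStudy` adds it to
  every vial; per-batch blank subtraction then removes it. This is what
  makes the zero-noise round trip exact: simulate → quantify returns
  the configured composition to within floating-point error.
* **Floors at zero.** Negative draws of areas or percents are floored
  at zero; these are physical nonnegative quantities and the floor only
  binds for near-zero analytes.
* **Drift** is multiplicative per analyte, $(1+d)^{batch}$, reflecting
  proportional detector-response change, and is recovered in tests by
  log-linear regression on a drifting analyte's QC series.
* **Unpublished dispersions.** Analytes whose long-term SD was reported
  only as "BLOQ" are simulated with SD = 30% of their mean (the source
  reports CV > 20% for such levels); analytes marked not-detected are
  omitted. The retention ladder spaces analytes evenly over 2.5–29.5
  min of a 30-min run in carbon-number/unsaturation order, since true
  retention times are column- and program-specific; only ordering and
  separability matter downstream. Between- and within-batch variance
  are not decomposed — a single SD per analyte — because the source
  tables report only the marginal SD.

What the generator does **not** emulate: raw chromatogram traces,
co-elution shoulders, injection carryover, heteroscedastic noise at the
detection floor, or non-normal batch effects. Passing tests therefore
demonstrate the correctness of the analysis layer on data satisfying its
assumptions, not the behaviour of any physical instrument.

## Problem sizes and numerical conventions

The test suite runs studies of 12–100 batches with 0–29 samples per
batch and 10,000-point chart simulations; these sizes give standard
errors small enough for three-sigma parameter-recovery checks while
keeping the suite quick. Statistical checks on stochastic output use
three-standard-error bounds at a fixed seed. Reported percents are
rounded half-away-from-zero to 2 decimals and CVs to 1–2 decimals only
at the reporting edge; all internal computation is full precision.
Degenerate inputs fail loudly and early: empty chromatograms, all-zero
areas, missing or duplicated process blanks, zero-variance baselines
(warning, degenerate limits), and zero within-group ANOVA variance with
unequal means (p = 0 with a warning).

## Known limitations

* Area percent is not molar percent; no FID response-factor correction.
* One co-elution merge is modelled; no peak deconvolution.
* LOD from calibration residuals overestimates the true instrument
  noise floor when calibration error is dominated by volumetric error.
* Shewhart run rules beyond point-beyond-limit (Westgard multirules,
  CUSUM/EWMA) are not implemented.
* The chart treats instruments as pooled, as the reference program did;
  per-instrument charts require splitting profiles upstream.
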