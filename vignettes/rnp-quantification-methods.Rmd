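---
title: "Quantifying RNP transport: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNP transport: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpquant)
```

`rnpquant` implements the quantitative layer of single-molecule studies of
mRNA transport in the *Drosophila* egg chamber: converting fluorescent spot
intensities into RNA copy numbers, measuring the association of RNPs with
fluorescently tagged proteins against a chance baseline, describing where
RNA sits along the oocyte's anteroposterior (AP) axis, and characterizing
the motility of RNP particles both in ooplasmic extracts and in
reconstituted in vitro assays. Spot detection, tracking, and region-of-interest
drawing happen upstream; the package's contract inputs are tables of
detections, trajectories, kymograph traces, and ROI polygons.

This vignette explains each model, the parameters that matter, the numerical
choices made where the methods literature leaves the design open, and what
the synthetic-data generators do and do not emulate.

## Intensity calibration: from photons to copy numbers

A diffraction-limited smFISH or MS2/MCP-GFP spot containing $k$ mRNA copies
has expected intensity $k \mu_1$, where $\mu_1$ is the intensity of a single
labeled molecule. `fit_mixture()` fits a one-dimensional Gaussian mixture to
the raw intensity distribution (via mclust's EM, unequal component
variances), choosing the number of components $K \in \{1,\dots,8\}$ by BIC
over ten differently initialized fits (initialization subsamples the data,
so restarts are meaningful for large samples; the best-BIC restart wins).

Two unit-selection policies reflect two experimental regimes:

* **`smallest_mean`** — the smallest fitted $\mu_k$ is one RNA unit. Used
  for ex vivo time-lapse series, where calibration is refitted for each
  series individually (`stratify_by_rna()`).
* **`dominant_component`** — the $\mu_k$ of the heaviest-weight component is
  one unit. Used for fixed tissue, where single-copy RNPs dominate the
  nurse-cell population and the dominant component is in practice almost
  the lowest-mean one.

**Component consolidation.** BIC occasionally prefers to split the
single-copy population into two heavily overlapping Gaussians (in our
synthetic benchmarks this happens in roughly half of replicates at
$n = 5000$, $\mathrm{cv} = 0.15$), which would corrupt the unit by ~10%.
Because genuine copy-number populations sit at integer multiples of the
unit, no two resolvable populations below five copies can have a mean ratio
under $5/4$; `fit_mixture()` therefore merges adjacent components whose
mean ratio falls below `merge_ratio = 1.25` (weight-averaged moments) before
selecting the unit. We also evaluated ICL as the model-selection criterion;
it does not discriminate against the split solutions, whereas consolidation
recovers the unit in 100% of benchmark replicates.

Normalized intensities (`normalize_intensity()`, intensity divided by the
unit) are stratified into power-of-two copy-number bins
$[2^i, 2^{i+1})$, labeled `1`, `2:3`, `4:7`, `8:15`, ... up to exponent 8
(`assign_bin()`). Values in $[0.5, 1)$ round up into bin `1`; values below
0.5 are flagged `sub_unit` and excluded downstream (dim outliers below half
a unit cannot be a whole molecule); values at or beyond $2^9$ clamp into the
top bin with a flag. Ex vivo track stratification instead rounds half-up
into the coarser strata `1`, `2`, `>2` used for motility statistics.

## Colocalization with a randomization null

`nearest_neighbor_pairs()` maps every RNP to its nearest reporter object
(Euclidean distance; 2D by default, 3D available when detections carry z —
the choice defaults to 2D because the upstream analyses operate on
deconvolved optical sections). A pair within `coloc_radius` counts as
colocalized. The default radius of 0.25 µm approximates the lateral
resolution of the imaging; it is a configuration field reported in outputs,
not a constant of the method.

Observed per-bin frequencies overstate association wherever reporter density
is high, so `expected_frequency()` estimates the chance baseline by
repeatedly redrawing the reporter positions uniformly inside the compartment
polygon (minus nuclear masks), keeping reporter counts and all RNP positions
fixed — the statistic conditions on the RNP pattern and matches the
density of the reporter channel. The corrected frequency is observed minus
expected and may legitimately be negative (depletion). With 100
randomizations the Monte Carlo standard error is reported so users can
raise the count when needed.

Confidence intervals follow the grouped scheme: RNPs of a bin are randomly
partitioned into groups of 50 (remainder dropped), each group yields one
corrected frequency, and the group values give a t-based 95% CI and a
one-sample t test against zero; bins with $p > 0.01$ are flagged "not
different from zero". Normality of group means is assumed by construction
of the random grouping and not separately tested.

Reporter intensity scaling (`fit_scaling()`) is ordinary least squares of
normalized reporter intensity on copy number; comparing two conditions uses
a shared model with a group-by-copies interaction, whose p-value reports
whether the slopes differ.

## AP-axis distribution statistics

`build_matrix()` redistributes a weighted signal point cloud into a
100 × 100 matrix: column $j$ holds the fraction of total signal under the
$j$-th percent of the AP axis (anterior = column 1), and the row coordinate
is the point's fractional position along the chord of the outline
perpendicular to the AP axis at that AP position. The paper-level
definition fixes only the columns; making rows chord-normalized renders
both axes shape-invariant, so oocytes of different sizes and aspect ratios
average meaningfully (`average_cohort()`, entrywise mean and population SD
— n divisor, declared in outputs). The AP axis is the straight
anterior-to-posterior segment; axis curvature is not modeled.

The center of mass (`center_of_mass()`) is the signal-weighted mean AP
position in percent of axis length, minus the AP position of the outline's
geometric centroid: 0 means the signal is balanced around the geometric
center and positive values point posterior. Distributions are compared with
a Kruskal–Wallis omnibus test followed by pairwise Mann–Whitney U tests
against the control (`compare_com()`); the stage-progression analysis
(`fit_com_vs_size()`) regresses CoM on oocyte outline area (µm²), the
package's declared proxy for developmental stage.

## Compartment enrichment

`compartment_means()` measures signal per unit area inside manually drawn
follicle-cell, nurse-cell, and oocyte polygons; `enrichment_ratio()`
normalizes to the nurse-cell value, with the follicle-cell ratio serving as
an internal control. Group comparisons use unpaired t tests — Welch by
default, since equality of variances across genotypes is not guaranteed;
the classic pooled-variance form is available by flag and the choice is
recorded in the output metadata.

## Ex vivo run analytics

Trajectories from ooplasmic-extract TIRF imaging (20 frames/s, ~30 s) are
projected onto each track's microtubule polarity axis (derived upstream
from EB1 comet directions). A **run** is an inclusion-maximal frame window
that starts and ends with a step in the run direction, never contains more
than `max_reversal_tolerance = 1` consecutive counter-steps, spans at least
`min_run_frames = 3` intervals, and displaces at least
`min_run_length = 0.5` µm. These thresholds are declared defaults — the
source methodology for run calling is external and unspecified — and all
three are configuration fields reported in outputs. Speed is net
displacement over duration. The implementation is verified against a
brute-force enumeration of all valid windows on every test track.

Polarity distributions (plus/minus counts and percentages per RNA stratum)
are compared across conditions with Fisher's exact test; speeds and run
lengths with Mann–Whitney U tests, alongside the percent difference of mean
travel distance relative to the control. Cells with fewer than three runs
are flagged and left untested.

## In vitro event analytics

Kymograph traces from reconstitution assays are classified per candidate
event (a contiguous frame stretch): **binding** requires at least 3
continuous frames; **processive** additionally requires unidirectional
movement of at least 5 pixels (default pixel size 0.107 µm, so ~0.54 µm)
at any time during the event. "Unidirectional" is read strictly — a
sub-window whose per-frame steps never change sign (zero steps allowed,
zero backsteps tolerated) totaling the threshold — because that is the
tightest reading of an event moving "at least 5 pixels during this time";
a net-displacement mode over the whole event is available by flag. The
classifier is validated against exhaustive window enumeration.

Per-microtubule tallies are normalized to events per µm per minute so
microtubules of different lengths are comparable (raw counts are emitted
alongside). Non-specific surface binding is corrected by subtracting the
mean binding frequency observed in microtubule-free regions sized to the
median microtubule length; corrected values are floored at zero with a
flag. Condition contrasts divide per-microtubule values by the matching
reference-condition mean and use Mann–Whitney tests; multi-condition
contrasts use Welch's ANOVA with a Brown–Forsythe variance check.

## Synthetic data and what passing tests mean

Every pipeline input can be generated with recorded ground truth:

* `gen_rnp_field()` — two-channel point fields. Copy numbers are drawn from
  a configurable distribution defaulting to `{1: 0.5, 2: 0.35, 4: 0.15}`
  (most RNPs in nurse cells carry one or two copies); intensities are
  `copies × unit × (1 + N(0, cv))` with `cv = 0.15`, multiplicative because
  spot intensities are shot-noise dominated. Truly colocalized reporters
  are placed within half the detection radius so truth sits strictly inside
  the cutoff, avoiding boundary ambiguity in recovery tests.
* `gen_oocyte_signal()` — point clouds with arbitrary AP density profiles.
* `gen_tracks()` — one constant-velocity run per track at 20 frames/s with
  additive Gaussian localization noise (0.02 µm), a plus-end fraction
  defaulting to 0.65, and per-track random microtubule orientations.
* `gen_invitro()` — Poisson landing events on microtubules (geometric
  dwell, mean 8 frames), a configurable processive fraction, and
  non-specific surface landings that appear both in background regions and,
  scaled by length, on the microtubules themselves — which is precisely
  what the background correction is meant to remove.

The generators reproduce the *statistical structure* of the assays, not
their physics: no photobleaching, blinking, stage drift, pixelation, or
segmentation errors, and intensity noise is exactly Gaussian. Passing
recovery tests therefore demonstrates that the estimators are correct and
calibrated on data matching their model assumptions; they do not certify
performance on real images, where upstream detection quality dominates.

Recovery tests for the colocalization machinery stratify RNPs by their
ground-truth copy number rather than by measured intensity: generator copy
classes sit exactly at bin lower edges (1, 2, 4), so intensity noise sends
about half of each class into the adjacent bin and measured-bin frequencies
are mixtures of the per-bin truth for any correct implementation.
Calibration accuracy is tested separately.

## Validation problem sizes

The package's validation suite exercises, per replicate: mixtures of 5,000
intensities over 50 seeds (calibration); 2,500–3,000 RNPs with 100
reporter randomizations over 50–100 seeds (colocalization null and
recovery); Poisson fields at 0.1–10 reporters/µm² against the closed form
$1 - e^{-\lambda \pi r^2}$; 500 tracks over 50 seeds (polarity recovery);
1,000 random traces against the event-classification oracle; 100
twenty-microtubule replicates for background-correction bias; and all 2×2
contingency tables with total count up to 30 against hypergeometric
enumeration. These sizes were chosen to make distributional oracles tight
(binomial/Poisson 3σ, CI coverage) at desk-scale runtimes.

## Interfaces and limitations

The package is driven from R: the exported functions compose the pipeline
(simulate → calibrate → pair → correct → summarize), and
`scripts/acceptance.R` reproduces the full validation from the shell. No
separate command-line binary is shipped — the analysis is interactive and
per-study, which in our experience is better served by scripted R than by a
fixed CLI.

Known limitations: 3D distribution matrices are not implemented (the AP
matrix is 2D by design); microscope image formats are out of scope
(detections and traces are the contract); ex vivo and fixed-tissue
calibrations are kept on separate scales, as nothing guarantees a shared
unit between live MCP-GFP and smFISH intensities; and the empirical
AP-asymmetry of real oocyte outlines (the posterior pole sitting beyond
50% of the axis from the geometric center) is a property of specimens, not
a constant of the method — nothing in the package hard-codes it.
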