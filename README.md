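# rnpquant

Quantitative analysis of mRNA transport and ribonucleoprotein (RNP)
motility from single-molecule fluorescence microscopy.

During *Drosophila* oogenesis, mRNAs such as *oskar* are packaged into RNPs
and moved along microtubules by dynein (toward minus ends) and kinesin-1
(toward plus ends); which motor dominates is regulated by RNA-binding
proteins on the particle. Measuring that regulation requires a chain of
quantitative steps that recur across such studies, and `rnpquant`
implements them as a tested, reusable pipeline:

* **Copy-number calibration** — a Gaussian mixture fitted to spot
  intensity distributions; one component's mean µ defines the intensity of
  a single mRNA, every spot is normalized to it, and RNPs are stratified
  into power-of-two copy bins (2^i : 2^(i+1)), i.e. `1`, `2:3`, `4:7`, ...
* **Object-based colocalization** — per-bin nearest-neighbor frequencies
  between RNPs and fluorescent reporters, corrected by the chance
  frequency estimated from randomized reporter positions
  (f_corr = f_obs − f_exp; negative values mean depletion), with grouped
  (n = 50) 95% CIs and one-sample t tests against zero, plus
  reporter-intensity-vs-copy-number regressions with slope comparison.
* **AP-axis distribution statistics** — 100 × 100 shape-normalized signal
  matrices per oocyte (column = 1% of the anteroposterior axis), cohort
  mean/SD maps, and the signed center-of-mass relative to the oocyte's
  geometric center, compared by Kruskal–Wallis and Mann–Whitney tests.
* **Compartment enrichment** — signal density ratios of oocyte and
  follicle cells to the nurse cells, with Welch/Student t tests.
* **Motility analytics** — directed-run segmentation of ex vivo
  trajectories with EB1-derived microtubule polarity (run speed, length,
  plus/minus shares per RNA stratum; Fisher exact and Mann–Whitney
  tests), and in vitro kymograph event classification (binding = ≥ 3
  continuous frames; processive = unidirectional movement ≥ 5 pixels),
  with background-corrected per-microtubule frequencies and relative
  metrics across conditions.
* **Synthetic data** — generators for every input (intensity mixtures,
  two-channel point fields, AP signal profiles, bidirectional tracks,
  per-microtubule event streams) with recorded ground truth, so every
  stage is testable without any imaging data.

See the vignette (`vignettes/rnp-quantification-methods.Rmd`) for the
models, parameter defaults, and design choices.

## Worked example

Simulate a two-channel field with known per-bin colocalization
probabilities (10% / 30% / 60%), calibrate spot intensities, and measure
corrected colocalization:

```r
library(rnpquant)

geom <- oocyte_geometry(
  outline = rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
  anterior = c(0, 50), posterior = c(100, 50))

sim <- gen_rnp_field(
  n_rna = 2000, geometry = geom, unit = 100, cv = 0.15,
  coloc_prob = c("1" = 0.1, "2:3" = 0.3, "4:7" = 0.6),
  reporter_slope = 50, background_reporters = 100, seed = 1)

cfg <- rnp_config(rng_seed = 2)
cal <- calibrate_detections(sim$detections, channel = "rna", config = cfg,
                            policy = "smallest_mean")
cal$model
#> <calibration_model> K = 3, unit = 100 (policy: smallest_mean)
#>    mean    sd weight
#> 1 100.0 15.08 0.5042
#> 2 198.2 30.09 0.3406
#> 3 399.0 62.67 0.1552

rnps      <- cal$detections[cal$detections$channel == "rna", ]
reporters <- sim$detections[sim$detections$channel == "reporter", ]
res <- coloc_analysis(rnps, reporters, geom, cfg)
res[, c("bin", "n_rnp", "f_obs", "f_exp", "f_corr",
        "ci_lo", "ci_hi", "zero_flag")]
#>  bin n_rnp f_obs f_exp f_corr ci_lo ci_hi zero_flag
#>    1  1360  17.1  1.18   15.9  13.9  18.1     FALSE
#>  2:3   496  41.7  1.09   40.6  36.8  44.1     FALSE
#>  4:7   144  60.4  1.38   59.0  46.9  72.3      TRUE
```

The fitted unit lands on the true single-copy intensity (100 a.u.) and the
three copy-number populations are recovered with their simulated weights.
Corrected frequencies rise with copy number as injected; they exceed the
per-bin truth here because intensity noise mixes neighboring copy classes
across measured bins (copies sit at bin lower edges), e.g. half of the
two-copy RNPs (30% colocalized) are measured into bin `1`. The `zero_flag`
column marks bins whose grouped one-sample t test cannot distinguish the
corrected frequency from zero at p > 0.01: bin `4:7` holds 144 RNPs, i.e.
only two complete groups of 50, so the test has a single degree of freedom
and stays above the 0.01 threshold (p = 0.0107) despite the clearly
positive interval.

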