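# hepaclear

Quantification of hepatic excretory function and nanocarrier
pharmacokinetics from dynamic optical and optoacoustic imaging.

Excretory liver failure — clinically visible as jaundice — is a hallmark of
severe infection and portends poor outcomes. Its functional readout is how
fast the liver removes test dyes from circulation. `hepaclear` implements
three such quantitative readouts, for researchers analyzing dynamic
contrast imaging of liver function (and for validating such analyses on
simulated data):

* **ICG clearance from multispectral optoacoustic tomography (MSOT) time
  series.** From a two-channel stack (800 nm indocyanine-green channel,
  900 nm anatomy channel) and an animal-contour ROI, the pipeline performs
  translation-only rigid registration (subpixel phase correlation with
  Gauss–Newton intensity refinement, estimated on the anatomy channel,
  applied to the ICG channel), first-frame z-normalization
  $Z_{x,y,z} = (X_{x,y,z} - \mu)/\sigma$, temporal down-sampling by 4
  (block means), per-pixel signal change-rate vectors, k-means extraction
  ($k = 4$) of characteristic kinetic curves per treatment group, nearest
  centroid pixel assignment, restriction to net-increase curves,
  abundance-weighted curve averaging, and the trapezoidal area under the
  curve's linear tail (from down-sampled frame 8). Larger tail AUC = more
  retained ICG = worse excretory function. Groups are compared by
  Kruskal–Wallis and pairwise Wilcoxon tests with Benjamini–Hochberg FDR
  control.
* **Plasma-disappearance half-life** from intravital fluorescence traces:
  baseline subtraction, qualitative-criteria QC (initial rise, Z-drift),
  OLS of $\log F$ on $t$ over the 15–40 min decay window,
  $t_{1/2} = \ln 2/|\mathrm{slope}|$, and mean ± SEM aggregation across
  vein ROIs.
* **Competitive-uptake IC50**: background-subtracted, protein-normalized
  well data fitted with the four-parameter log-logistic
  $y(c) = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom})/(1 +
  (c/\mathrm{IC}_{50})^{\mathrm{hill}})$, plus a 37 °C vs 4 °C temperature
  contrast isolating active transporter-mediated uptake.

A synthetic-data module (`simulate_msot_pair()`, `simulate_cohort()`,
`simulate_decay_trace()`, `simulate_dose_response()`) generates every input
the pipeline consumes — per-pixel kinetic classes, breathing/drift motion,
Gaussian noise, mono-exponential decay traces, 4PL plates — with complete
ground truth, so every stage is testable without animal data. See the
methods vignette (`vignettes/hepaclear-methods.Rmd`) for the models,
assumptions, and design decisions.

## Worked example

```r
library(hepaclear)

## 1. plasma half-life from one noisy synthetic ear-vein trace
tr  <- simulate_decay_trace(t_half = 55.9, baseline = 10, amplitude = 100,
                            injection_time = 1, noise_sd = 5, seed = 42)
fit <- fit_half_life(subtract_baseline(tr, 10), window = c(15, 40))
fit
#> Half-life fit (15-40 min window, 51 points): t1/2 = 62.34 min, slope = -0.01112 /min, R^2 = 0.5867
```

A single trace at 5% amplitude noise is scattered around the 55.9 min truth
(here 62.3 min); averaging the per-vein estimates with
`aggregate_half_life()` recovers the truth — the acceptance script below
does exactly that.

```r
## 2. IC50 from a simulated inhibition plate (8 concentrations x 4 replicates)
conc  <- 344 * 10^seq(-1.5, 1.5, length.out = 8)
plate <- simulate_dose_response(344, hill = 1, top = 1, bottom = 0,
                                concentrations = conc, n_replicates = 4,
                                noise_sd = 0.05, seed = 7)
fit_ic50(plate)
#> IC50 fit: IC50 = 401.3 nmol/l, hill = 1.2, top = 0.9738, bottom = 0.02648 (SSE 0.0832)

## 3. end-to-end clearance pipeline on two small simulated cohorts
cohort <- c(simulate_cohort(3, "control",  elimination_rate = 0.12,
                            size = 48, n_frames = 40, seed = 100),
            simulate_cohort(3, "impaired", elimination_rate = 0.03,
                            size = 48, n_frames = 40, seed = 200))
run_clearance(cohort, pipeline_config(seed = 11))
#> <clearance_run> 6 animals, 2 group(s), k = 4, seed 11
#>    animal_id    group        auc undefined
#>   control_01  control -0.4290033     FALSE
#>   control_02  control -0.4290033     FALSE
#>   control_03  control -0.4290033     FALSE
#>  impaired_01 impaired -0.3239255     FALSE
#>  impaired_02 impaired -0.3230838     FALSE
#>  impaired_03 impaired -0.3235046     FALSE
#>
#> Kruskal-Wallis omnibus: chi-squared = 4.355 df = 1 p = 0.0369
#> Group summaries:
#>     group n median_auc
#>   control 3 -0.4290033
#>  impaired 3 -0.3235046
#> Pairwise Wilcoxon (BH-adjusted):
#>   group1   group2 W          p          q
#>  control impaired 0 0.06360257 0.06360257
```

The 4-fold reduced elimination rate of the "impaired" group yields a larger
(less negative) linear-tail AUC in every animal: the dye's late change
rates stay closer to zero because ICG is retained. (Control AUCs coincide
to print precision because group-level characteristic curves are shared and
per-animal abundances barely differ at this noise level.) File-based runs
use `run_pipeline(config, manifest, out_dir)` with multi-page float32 TIFF
stacks and a CSV manifest, and write AUC tables, curves, and a
comparison/summary JSON.

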