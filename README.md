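# amblyosim

Amblyopia ("lazy eye") does not just blur vision — it distorts it. When an
amblyopic observer views a sinusoidal grating through the affected eye, the
percept can contain wavy or zigzag lines, interference patterns, bars of
uneven thickness, or irregular blind patches. `amblyosim` is an R package
for researchers in visual psychophysics and computational neuroscience that
models, fits, and quantifies these distortions, and links them to
contrast-sensitivity deficits and to the predicted spread of cortical
activation.

## The model

A distorted percept is a saturated weighted sum of rectified sinusoidal
gratings ("cortical filters"):

    P~ = Sat( Σᵢ Wᵢ · Fᵢ ),    Fᵢ = Sat_T( Gᵢ + Kᵢ )

Each filter has six parameters: orientation θ (degrees), spatial frequency
f (cycles/degree), phase φ, a dark/light duty-cycle constant K ∈ [−1, 1]
(negative K thickens dark bars; K = 0 in fellow eyes), a saturation
threshold T ∈ [0, 2], and a weight W (scaled by the amblyopia constant
A ∈ [0, 1]). The package:

* renders gratings, filters and percepts on circular-aperture contrast
  fields (`make_grating`, `make_filter`, `synthesize_percept`);
* scores image similarity with a normalized Laplacian pyramid distance
  (`nlpd`), cross-validated against an independent NumPy implementation;
* fits the model to a drawing by iterative filter addition with
  Nelder–Mead, seeding each round by matching pursuit on the residual
  (`fit_percept`);
* quantifies distortion magnitude as |Wn − Wm| × K̄ — the mismatched-vs-
  matched mean-weight difference times the mean absolute duty constant
  (`distortion_magnitude`);
* fits Gaussian contrast sensitivity functions and computes the deficit as
  the fellow/amblyopic peak ratio minus one (`fit_csf`, `cs_deficit`);
* simulates monocular cortical response maps on orientation-preference
  maps and the amblyopic/fellow activation spread ratio
  (`fellow_response`, `amblyopic_response`, `spread_ratio`,
  `map_metrics`);
* analyzes spatial-frequency tuning of thalamic neurons at multiple
  contrasts and maps receptive fields by spike-triggered averaging
  (`fit_tuning`, `lsf_hsf_difference`, `reverse_correlate`);
* generates all the synthetic data needed to exercise the pipeline end to
  end — drawings with hand-jitter and pixel noise, CSF tables, orientation
  maps with pinwheels, and whole subject cohorts (`gen_drawing`,
  `gen_csf_pair`, `gen_orientation_map`, `gen_cohort`,
  `run_cohort_pipeline`).

## Worked example

Simulate a distorted drawing from two known filters, fit it blind, and
quantify the distortion:

```r
library(amblyosim)

truth <- filter_set(
  list(grating_params(0, 5, 0,   K = -0.3, T_sat = 1, A = 0.8),
       grating_params(30, 5, 120, K = -0.3, T_sat = 1, A = 0.4)),
  weights = c(0.8, 0.4))
syn  <- gen_drawing(synthetic_drawing_spec(truth, rng_seed = 2), n_pixels = 64)
stim <- make_grating(grating_params(0, 5), n_pixels = 64)

nlpd(stim$values, syn$drawing$values)
#> [1] 0.04154697

fit <- fit_percept(syn$drawing, stim, grating_params(0, 5),
                   fit_config(nlpd_threshold = 1e-6, nlpd_tolerance = 1e-4,
                              max_filters = 4, rng_seed = 1))
fit
#> <fit_result> 2 filter(s), final NLPD 0.003583 (threshold 1e-06), converged
#> <filter_set> 2 filter(s)
#>   [1] W=+0.899 theta=0.0 f=5 phi=15.7 K=-0.365 T=1.164 A=0.899
#>   [2] W=+0.296 theta=30.1 f=4.96 phi=138.0 K=-0.077 T=1.019 A=0.296
```

The fit recovers both generating orientations (0° and 30°, truth 0°/30°)
and brings the perceptual distance from 0.0415 (stimulus vs drawing) down
to 0.0036. The distortion score and the predicted cortical spread of the
fitted percept:

```r
distortion_magnitude(fit)
#> raw = 0.1334  (Wm = 0.899, Wn = 0.296, Kbar = 0.221)

map <- gen_orientation_map(rng_seed = 1)   # 57 x 57 synthetic map
spread_ratio(fellow_response(map, 0),
             amblyopic_response(map, fit$filter_set, 0))
#> fellow 882 px, amblyopic 999 px, ratio 1.133
```

The mismatched 30° component recruits cortical territory outside the
stimulus-matched orientation columns: the amblyopic activation spread is
13% larger than the fellow-eye spread.

A full synthetic-cohort analysis (seven subjects, drawings fitted blind,
CSFs fitted, distortion and spread correlated with the deficit) is one
call:

```r
report <- run_cohort_pipeline(rng_seed = 1, outdir = "cohort_out")
report$deficit_distortion   # Pearson r and p across subjects
```

A thin command line interface wraps the same functions
(`exec/amblyosim`): `amblyosim fit`, `spread`, `csf`, `distort-metric`,
`synth`, `run`.

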