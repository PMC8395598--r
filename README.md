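# lungreg

Deformable registration of longitudinal thoracic CT in the presence of
radiation-induced lung damage (RILD), for imaging scientists who need to
align a pre-radiotherapy scan with follow-up scans in which consolidation,
fibrosis or collapse has changed how the tissue *looks* without a
one-to-one intensity correspondence surviving.

Instead of raw Hounsfield units, the method registers a multichannel stack
of anatomical features that remain recognisable across timepoints:

* a compressed signed distance transform of the lung boundary,
  `f(d) = ±(1 − 1/(1 + min(d, 12)))` in voxel units, saturating (zero
  gradient) twelve voxels from the boundary;
* the same transform of the main-airway segmentation;
* a multiscale Frangi vesselness map of the CT.

The stack is registered with a symmetric diffeomorphic model: a cubic
B-spline **stationary velocity field** `v` (final control spacing 5 mm)
whose exponentials `exp(±v)` are the mutually inverse forward/backward
maps. The objective is the weighted per-channel similarity sum — SSD
(weight 1) on the distance channels, NMI (weight 2.5) on vesselness — in
both directions, minus a bending-energy penalty (weight 0.001), maximised
by conjugate-gradient ascent over a 3-level pyramid with a positivity guard
on the full-resolution Jacobian determinant. An intensity-only baseline
(single NMI channel on HU, same engine) is included for comparison, along
with block-matching rigid initialisation, the landmark evaluation protocol
(`D_pre`, bidirectionally averaged `D_reg`), and a synthetic thoracic
phantom with analytic vessel-bifurcation landmarks and a ground-truth SVF,
so the whole pipeline runs and is tested without any patient data.

## Worked example

```r
library(lungreg)

# a complete synthetic case: baseline + follow-up CT, lung/airway masks,
# a 15 mm ground-truth deformation, 59 bifurcation landmarks
case <- phantom_case(shape = 96, spacing = 2, seed = 1,
                     max_displacement_mm = 15, rild_fraction = 0)

# feature stacks for both timepoints
mc_b <- feature_stack(case$baseline, case$lung_mask_b, case$airway_mask_b)
mc_f <- feature_stack(case$followup, case$lung_mask_f, case$airway_mask_f)

# symmetric multichannel diffeomorphic registration (a few minutes, 1 CPU)
fit <- register_multichannel(mc_b, mc_f, reg_config(),
                             case$lung_mask_b, case$lung_mask_f)
summary(fit)

# landmark evaluation against the analytic ground truth
ev <- evaluate_registration(fit, case$landmarks_b, case$landmarks_f)
ev$summary
```

On this case the evaluation prints (seed 1):

```
  case n_landmarks mean_d_pre median_d_pre sd_d_pre mean_d_reg median_d_reg
1 case          59       9.67        10.03     1.81       1.20         1.02
```

so the mean landmark distance falls from 9.67 mm before deformable
registration to about 1.2 mm (sub-voxel at 2 mm) afterwards, with the
minimum Jacobian determinant of the forward map ≈ 0.43 — no folding. The
fitted object behaves like an R model: `print()`, `summary()`, `coef()`
(the velocity coefficients), `predict()` (warp landmarks or images),
`plot()` (convergence and Jacobian diagnostics).

A thin command-line interface over the same functions ships in
`inst/cli/lungreg.R` (`phantom`, `features`, `register`,
`register-intensity`, `evaluate`, `pipeline`, `compare` subcommands).

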