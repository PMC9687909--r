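# angioflow

Velocity estimation from projective contrast images, with optical flow
and machine-learning correction.

## The problem

Angiography-style imaging projects a 3-D contrast-agent flow onto a 2-D
detector. Velocity fields estimated from such projections with
intensity-based optical flow are systematically biased — the image
integrates attenuation along the whole beam path, while the quantity of
interest is the velocity on the vessel's center plane. `angioflow`
reproduces this situation end to end in a controlled synthetic setting
and corrects the biased optical-flow estimate with supervised
regression, for researchers studying image-based hemodynamics and
surrogate models for flow estimation.

The package:

1. **simulates dye perfusion** in a 1-inch square duct: a passive
   scalar φ is advected (semi-Lagrangian advection–diffusion,
   D = 10⁻⁹ m²/s) through the analytic fully developed laminar duct
   profile, under four injection patterns (constant with radius ramp
   0.37 → 2.0 mm; intermittent 0.1 s on / 0.25 s off; radial cosine
   φ = φ₀ cos(ωr) with ω = 500 rad/m; temporal cosine φ = cos(4π/3·t));
2. **renders 8-bit projection images** (161 × 306 px) by discretized
   Beer–Lambert attenuation, `I_j = I_{j-1} exp(-μ_j Δz)` with
   μ = μ_ref·φ;
3. **estimates per-pixel velocity** from image pairs (Δt = 0.02 s) by
   minimizing the extended brightness-transport residual
   `Qt + V·∇Q + Q ∇·V − D∇²Q` plus a Horn–Schunck smoothness term
   λ(|∇u|² + |∇v|²), solved by conjugate gradients;
4. **builds a supervised dataset** from dye-dominant pixels
   (gray ≤ 80): features (u_ofm, v_ofm, Ix, Iy) against center-plane
   ground truth (u, v), split by the duplicate-coordinate rule (per
   pixel key, one random record to test, the rest to train);
5. **trains four multi-output regressors** — LASSO (grouped L1, the
   baseline), an MLP (4 → 10 ReLU → 2, dropout 0.02), a 1-D CNN (three
   conv layers + max-pool + linear head) and an LSTM (standard
   sigmoid/tanh gate equations) — with mini-batch Adam, batch 32,
   MAE/MSE losses, and 10-fold × 3-repeat cross-validation;
6. **evaluates** MAE/MSE and per-station percentage error of the
   v-velocity at nine downstream stations.

See the methods vignette (`vignettes/velocity-correction.Rmd`) for the
model details, parameter choices, and limitations.

## Worked example

A complete run of the default configuration (four cases, 106 snapshots,
53 image pairs, ~59,000 samples; roughly 15 minutes on one CPU core):

```r
library(angioflow)

res <- run_pipeline(default_pipeline_config(seed = 1))
#> case 1: 14 pairs [87.3s]
#> case 2: 13 pairs [86.6s]
#> case 3: 13 pairs [84.9s]
#> case 4: 13 pairs [80.5s]
#> samples: 59109 records (53531 train / 5578 test) from 53 pairs, 106 snapshots
#> model lasso: cv mean MAE 1.41e-05 [1.7s]
#> model mlp: cv mean MAE 9.43e-06 [4.8s]
#> model cnn: cv mean MAE 7.88e-06 [179.3s]
#> model lstm: cv mean MAE 6.08e-06 [281.7s]
#> avg v-error: OFM 65.3%, MLP 0.2%
```

What the numbers mean: each `cv mean MAE` is a model's mean absolute
error (m/s, pooled over both velocity components) averaged over the 30
cross-validation folds — all four models sit far below the 3 × 10⁻³ m/s
working criterion. The final line is the station-averaged percentage
error of the v-velocity against ground truth: raw optical flow on the
projections is off by ~65% on average (it cannot distinguish
center-plane motion from the integrated column, and the centerline
pattern moves ~2.5 px between frames, beyond optical flow's ~1 px
comfort zone), while the MLP correction brings the same pixels to ~0.2%
— a several-hundred-fold error reduction on this synthetic scene.

Per-station profiles and the model grid:

```r
res$profiles$ofm      # station-wise OFM v-error (%), 55-86% downstream
res$profiles$mlp      # station-wise corrected v-error (%), ~0.2%
res$summary           # model x loss grid with CV means/sds and paired tests
```

Individual stages are exported too (`run_case`, `render_projection`,
`estimate_flow`, `assemble_samples`, `split_by_duplicates`,
`fit_mlp`, `cross_validate`, …), as are file-based drivers
(`af_simulate` … `af_run_all`) and a CLI:

```sh
Rscript inst/cli/angioflow.R all --config my_config.yml --outdir out/
```

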