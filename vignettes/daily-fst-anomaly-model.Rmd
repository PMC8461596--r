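---
title: "Modelling daily facial skin temperature for anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily facial skin temperature for anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Facial skin temperature (FST), measured by infrared thermography, tracks
autonomic state: fever, acute stress and breath-holding all perturb its
spatial distribution. A practical screening system only needs to recognise
*normal*; anything sufficiently unlike normal is flagged. The catch is that
normal is not one image: FST drifts through the day with the circadian
rhythm, so a model of "normal for this person" must be trained on data that
spans the diurnal cycle. thermovae implements that idea as a three-stage
pipeline:

1. **An individual normal model.** A convolutional variational autoencoder
   (VAE) is trained on 8×8-pixel patches cut from min–max normalized facial
   thermal images (FTIs) collected hourly across a day. Patches at this
   scale capture the fine vascular texture of the skin; per-image min–max
   normalization removes absolute temperature (and with it most of the
   diurnal and room-temperature bias), leaving relative spatial pattern.
2. **A two-dimensional test statistic.** At test time each image is reduced
   to the log-scale mean and variance of its patch-wise *unregularized
   anomaly score* — the reconstruction-error half of the VAE objective,
   \(L(x) = \sum_i (\mu_{xi} - x_i)^2 / (2\sigma^2_{xi})\), evaluated
   deterministically at the latent mean \(z = \mu_z\).
3. **A parametric threshold.** The statistic vectors of normal images are
   modelled as bivariate Gaussian (Hotelling theory). The squared
   Mahalanobis distance \(a(x') = (x'-\hat\mu)^\top \Sigma^{-1} (x'-\hat\mu)\)
   is referred to a \(\chi^2\) distribution, so a desired detection
   probability \(P\) back-calculates to the threshold
   \(a_{th} = Q_{\chi^2_d}(1-P)\) — no labelled anomalies are needed to set
   it.

## The VAE and how the architecture is read

The encoder is Conv(16 filters, 2×2, stride 2) → BatchNorm → ReLU →
Conv(32, 2×2, stride 2) → BatchNorm → ReLU → a fully connected layer
producing the 6-dimensional latent mean and log-variance; spatial
resolution falls 8→4→2. The decoder mirrors it: FC → BatchNorm → ReLU →
reshape to 2×2×32 → ConvTranspose(32, 2×2, stride 2) → BatchNorm → ReLU →
ConvTranspose(16, 2×2, stride 2) → BatchNorm → ReLU → two *parallel*
ConvTranspose(1, 4×4, stride 1, same padding) heads.

Two design decisions deserve a note. The decoder ends in two
single-filter 4×4 layers; we use them as parallel output heads for the
per-pixel reconstruction mean and log-variance, and we do *not* apply
BatchNorm or ReLU to either output: a ReLU would forbid negative log-variances and clip
reconstruction means at zero, and the anomaly score needs both \(\mu_x\)
and \(\sigma^2_x\) per pixel. Second, the decoder's variance is handled in
log space and clamped below at a floor (`variance_floor`, default 1e-4):
reconstruction errors are divided by \(\sigma^2_{xi}\), and on
well-reconstructed texture the fitted variances become small enough that
scores would otherwise diverge.

Training minimizes the negative evidence lower bound — the Gaussian
reconstruction term plus the closed-form KL divergence pulling the
posterior towards the standard normal — with Adam, 15 epochs, batch size
128. The learning rate is a free parameter; the package defaults to the
conventional 1e-3, which trains stably at this scale. Networks this small are cheap, so everything is implemented directly
in R as dense linear algebra: convolutions gather kernel neighbourhoods
through precomputed index maps and multiply by weight matrices; transposed
convolutions are their exact adjoints. Analytic gradients for every layer
are verified against central-difference differentiation in the test suite.

Small VAEs are optimization-noisy: at this scale roughly one training in
seven lands in an optimum whose reconstruction statistics barely separate
anomalies, and its final loss is slightly *worse* than the good optima.
`select_best_vae()` therefore trains a small seed grid (default 3) and
keeps the model with the lowest final training loss; `run_pipeline()` uses
that selection by default (`n_restarts = 3`), with `n_restarts = 1` as the
cheap single-training option used by most unit tests.

## The score statistic

The population over which the "mean and variance of the score" are taken is
a modelling choice; the package draws `n_patches` (default 100) random 8×8
patches per test image, scores each, and uses the natural logarithm of the
sample mean and of the unbiased (n−1) sample variance. One hundred patches
cover a 90×83 image about two-thirds over while keeping scoring cost
trivial; the log transform tames the heavy upper tail of reconstruction
errors, which is what makes the Gaussian model defensible. The Shapiro–Wilk
gate (`normality_gate()`) tests exactly that assumption on the normal
statistics and warns — it does not abort — when either coordinate fails at
α = 0.05, since a failed gate undermines the χ² calibration but not the
ranking.

## The Hotelling detector

The null model is fitted by maximum likelihood (covariance divided by *n*,
no small-sample T² correction, matching the χ²-approximation regime) on
*normal* statistics only — held-out normal images never seen in training —
because the whole method is framed as normal-only learning; fitting on a
mixed test set is available behind `fit_on_all = TRUE` for comparison. The
degrees of freedom default to 2: Hotelling theory for a d-dimensional
Gaussian statistic gives \(\chi^2_d\), and the statistic here is
two-dimensional. Practitioner write-ups sometimes quote one degree of
freedom for this statistic; `dof = 1` is accepted as an option,
and since the ROC sweeps the threshold the choice does not affect AUC, only
the calibration of a fixed detection probability. Decisions use strict
inequality (`a_value > threshold`); ties are measure-zero and resolve to
Normal. Probability contours are exact ellipses computed from the
eigendecomposition of \(\Sigma\) rather than a raster level-set: semi-axes
\(\sqrt{\lambda_k\, a_{th}}\) along the eigenvectors.

## What the synthetic generator emulates

No radiometric face data can ship with the package, so
`simulate_protocol()` reproduces the *measurement protocol* on a synthetic
face and the generator's defaults are the study conditions:

* 16 hourly sessions, 8:00–23:00; 120 s rest at 1 Hz per session → 1920
  normal frames; a 60 s breath-hold task per session whose last 20 s are
  anomaly frames; 90 % of normals train the model, 60 held-out normals and
  the 20 anomaly frames of one session form the 80-sample test set.
* The face is an ellipse (~34 °C) on a 22.1 °C background, textured with
  8 random smooth "vessel" curves of Gaussian cross-section, amplitudes
  0.3–0.6 °C and widths 1–3 px — sub-patch-scale structure for the VAE to
  learn, since the patch model exists precisely to capture vascular
  texture.
* Diurnal drift is a single sinusoid, amplitude 0.3 °C, peaking at 17:00.
  Circadian FST variation has no agreed functional form; a sinusoid of a
  few tenths of a degree is the simplest realistic stand-in.
* The breath-hold response is a smooth monotone ramp (cubic smoothstep
  after a 10 s onset) reaching `delta_temp_c` — default 0.8 °C, a free
  parameter of the simulation, not a measured value — concentrated in two
  periorbital Gaussian blobs. The periorbital default matters: a spatially
  *uniform* warm shift inside the face is almost entirely cancelled by
  per-image min–max normalization, whereas real acute responses are
  spatially structured; a `global_shift` profile is kept as an option
  precisely to demonstrate that near-invariance.
* Sensor noise is i.i.d. Gaussian with σ = 0.05 °C, the stated resolution
  bound of the instrument class; quantization is not modelled.

Everything flows from one seed: the frame stack is a pure function of
`(face_model, protocol_config, anomaly_model)`.

One consequence of per-image min–max normalization is worth knowing when
reading score plots: a smooth warm blob raises the image *maximum*, which
compresses the normalized contrast of the vascular texture everywhere else.
Anomalous images therefore tend to shift the log-mean score *downward*
rather than upward. This is not a defect — the Hotelling detector measures
distance from the normal cloud in the 2-D statistic plane, so displacement
in any direction is flagged — but it means one-sided intuitions about
"higher reconstruction error under anomaly" do not transfer to normalized
images with smooth thermal responses.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: head pose and registration error, facial
expression and blood-pressure-driven texture change, emissivity and
atmospheric correction, camera fixed-pattern noise, and between-day
non-stationarity of the diurnal profile. The synthetic task is cleaner than
a real one; synthetic AUCs certify the pipeline's mechanics, not clinical
performance.

## Numerical choices and degenerate inputs

* Min–max normalization rejects constant images (`max = min`) rather than
  guessing; patch extraction requires at least one valid 8×8 position.
* Scoring an image whose patch scores have zero variance (possible only for
  degenerate constant inputs) is an error, not a silent −∞.
* BatchNorm uses ε = 1e-5 and momentum 0.1 running statistics; inference
  passes are deterministic functions of the weights.
* The Hotelling fit refuses a covariance with reciprocal condition number
  below 1e-12.
* AUC uses the Mann–Whitney rank formulation with half-credit ties, which
  the tests verify equals the trapezoidal ROC integral to 1e-12 and an
  independent implementation (pROC) exactly.
* All sub-seeds (per-image patch draws, pipeline stages) are derived from
  the master seed via a seeded `sample.int`, keeping every value in 32-bit
  integer range.

## Problem sizes in the test suite

The default-scale pipeline (1920 normal frames, 10,000 learning patches,
15 epochs) runs in about a minute and is exercised by the acceptance tests
and the acceptance script, aggregated over three seeds. Unit tests use a
reduced protocol — typically 2–3 sessions, 8–40 s segments, ~1200 patches
and 3–4 epochs — chosen as the smallest sizes at which training still
visibly converges and the end-to-end properties (determinism, separation,
calibration) are meaningful.

## Known limitations

* The VAE runs on CPU in plain R; it is sized for 8×8 patches and the
  fixed two-level architecture, not for larger inputs.
* Per-individual modelling only: no cross-subject pooling or transfer.
* The χ² calibration inherits the Gaussianity of the log-scale statistics;
  the gate warns but the package does not offer a nonparametric fallback.
* The 20-frame anomaly test window is small; AUC on 60×20 pairs has
  visible seed-to-seed variance, which is why headline numbers are medians
  over seeds.
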