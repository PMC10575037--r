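---
title: "Maximizing stimulus-response correlation: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximizing stimulus-response correlation: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimcorr)
```

## The problem

When a person listens to continuous natural speech, the slow amplitude
modulation of the speech signal — its *envelope* — is tracked by cortical
activity measurable in scalp EEG. Quantifying that tracking as a Pearson
correlation between the envelope and the EEG is hard: any single channel
correlates with the stimulus at perhaps 0.02–0.05, because scalp recordings
are dominated by non-stimulus brain activity and artifacts. `stimcorr`
implements a pipeline that concentrates the stimulus-related part of the EEG
into one component and then learns, with a small neural network, a stimulus
representation of the response whose correlation with the stimulus is
maximal.

The pipeline has four stages, each exposed as ordinary functions:

1. **CCA as dimensionality reduction** (`fit_cca`, `project_eeg`). With a
   one-dimensional stimulus, canonical correlation analysis degenerates to a
   single EEG spatial filter `b ∝ (C_yy + λI)^{-1} c_yx`, the unit-norm
   channel combination whose time course is maximally correlated with the
   envelope. The envelope itself passes through unchanged (the stimulus-side
   canonical transform is an affine map, which Pearson correlation ignores).
2. **Overlapping rectangular windows** (`segment`): window *n* (0-based)
   covers samples `(w−o)n … (w−o)n + w − 1`. This turns two long
   1-D signals into many fixed-size realizations.
3. **Truncated discrete Karhunen–Loève transform** (`fit_klt`,
   `klt_project`): the SVD of the (mean-centered) window matrix provides an
   orthonormal basis; only the leading `p` components are kept, which
   suppresses noise directions and fixes the network's input/output width.
4. **A single MLP trained with a correlation loss** (`build_mlp`,
   `fit_mlp`): the network maps envelope features to predicted EEG features
   and is trained to minimize `J = ρ(x, y) − ρ(x, ŷ)`, i.e. to drive the
   correlation between input and predicted output up to (and past) the
   correlation between input and true output. Only the `ρ(x, ŷ)` term
   depends on the parameters.

Evaluation (`run_fold`, `cross_test`) is leave-one-trial-out per subject:
the CCA, both KLT bases and the network are fit on the training trials only;
the held-out trial is pushed through the trained pipeline, the predicted
feature windows are reconstructed through the output basis and overlap-added
back to a time series, and the reported `rho_proposed` is the Pearson
correlation between the held-out envelope and that predicted signal.
`rho_lcca`, the linear baseline, is the correlation between the held-out
envelope and the CCA-projected raw EEG of the same trial.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `window` (`w`) | 256 samples (2 s at 128 Hz) | window length; must exceed the slowest envelope fluctuation of interest |
| `overlap` (`o`) | 128 samples (50%) | window overlap; higher overlap = more (correlated) training rows |
| `n_components` (`p`) | 50 | retained KLT components; `scree()` suggests a value from the singular-value energy profile, but the configured `p` always wins |
| `hidden` | 1000, 550 | hidden-layer widths of the MLP |
| `dropout_rate` | 0.2 | dropout after each hidden activation |
| `lambda` | `1e-6 · tr(C_yy)/C` | CCA ridge; makes rank-deficient channel covariances (e.g. noiseless simulations) solvable |
| `train$learning_rate`, `batch_size`, `max_epochs`, `patience` | 1e-3, 64, 200, 20 | Adam optimization with early stopping on the validation loss |

Training hyperparameters are not prescribed by the method itself; the
defaults above are conventional Adam settings. The validation split is the
*last* 10% of the training windows (window order preserved), a deliberate
choice that keeps the split deterministic and respects the serial
correlation of overlapping windows.

## What the synthetic generator emulates — and what it does not

`make_dataset()` produces envelope/EEG pairs with a *known* coupling so that
every stage is testable without external recordings:

* the envelope is rectified 1–8 Hz band-limited Gaussian noise, smoothed
  with a 50 ms moving average and scaled to unit standard deviation —
  matching the band and nonnegativity of a speech envelope without modeling
  speech acoustics;
* each channel is `a_c · g(s(t − τ))` plus equicorrelated Gaussian noise and
  sparse 0.25 s raised-cosine artifact bursts; `g` is linear, `tanh` or
  quadratic;
* for the linear, lag-0, artifact-free case `oracle_correlation()` returns
  the exact maximal achievable envelope/EEG correlation
  `ρ* = sqrt(SNR/(1+SNR))`, `SNR = aᵀΣ⁻¹a` (Sherman–Morrison closed form
  for the equicorrelated Σ). Because the envelope is normalized per
  realization, the closed form is exact for the realized data, not just
  asymptotically.

The generator does **not** simulate cortical dynamics, volume conduction,
1/f background spectra, eye blinks with realistic topographies, or actual
speech audio. Tests that pass on this generator therefore demonstrate the
*mechanics* of the pipeline (recovery of known couplings, correct
bookkeeping, no leakage) — they do not certify performance on real EEG,
where noise is structured and nonstationary.

Default study conditions used by the test suite and the acceptance script,
chosen once as desk-scale analogues of a listening experiment: 8 channels
with gains `(1, 0.5, 0, …)`; unit white noise for the linear recovery study
(`ρ* ≈ 0.745`); `tanh` coupling with noise σ = 2, spatial correlation 0.2
and 2 artifact bursts/min of amplitude 8σ for the nonlinear study; trials of
50 000 samples (linear) or 120 s (nonlinear); hidden widths reduced to
128/64 and 60 training epochs so a ten-seed study runs in well under a
minute.

## Numerical design choices

**Centering.** The truncation is PCA-style: windows are centered by the
training-window mean before the SVD (`center = TRUE`). The uncentered
transform is available (`center = FALSE`) for exact correspondence with the
plain `X = USVᵀ`, `X* = XV` formulation.

**Sign convention.** Each singular vector's largest-magnitude element is
made positive, so repeated fits are bit-identical.

**Basis gauge alignment (`align_klt`).** This is the one place where the
package goes beyond the obvious dataflow, and it is worth understanding.
The window matrix of a *stationary* signal has an almost-Toeplitz
covariance, whose eigenbasis is quasi-Fourier: singular values arrive in
near-degenerate sine/cosine pairs. Within such a pair the SVD's choice of
vectors is numerically arbitrary — an O(1) rotation of the fitted basis is
produced by an O(noise) perturbation of the data. The input (envelope) and
output (projected EEG) bases are fitted on different noisy views of the same
underlying signal, so their components disagree by exactly such rotations,
and a prediction that is perfect in feature coordinates decorrelates when
reconstructed through the output basis (measured on synthetic data: feature
correlation 1.0 reconstructs to time-domain correlation 0.16 without
alignment, 0.99 with a consistent basis). The correlation loss cannot repair
this: its gradient involves only `ρ(x, ŷ)`, never `y`, so the network has no
signal from which to learn the rotation. `align_klt` therefore rotates the
output basis onto the input basis by orthogonal Procrustes *within blocks of
components whose relative singular-value gaps are below the sampling-error
scale* `sqrt(2/N)`. Rotations act inside blocks only, so the retained
subspace — and hence the output reconstruction error — is exactly unchanged;
the transform is still the output windows' own truncated KLT, merely with
its rotational gauge fixed deterministically. The step is on by default
(`align_output_basis = TRUE`) and restores continuity with the noiseless
case, where the two bases coincide exactly.

**Loss sign.** The loss is implemented as `J = ρ(x, y) − ρ(x, ŷ)`, so
minimizing `J` maximizes the input–prediction correlation; `J = 0` when the
prediction reproduces the true input–output correlation and `|J| ≤ 2`
always. Because Pearson correlation is scale-free, training cannot and does
not fix the output scale — evaluation must therefore use correlation, never
mean-squared error. The batch correlation is computed over the flattened
batch (one scalar per batch); a per-row-mean alternative is available via
`loss_mode = "rowmean"`.

**Degenerate inputs.** Zero-variance signals are errors, not `NA`s, at every
correlation; CCA refuses `T ≤ C` and advises `λ > 0` on singular
covariances; windowing refuses signals shorter than one window, naming both
lengths.

## What the held-out correlation does and does not estimate

A point that matters when reading results: `rho_proposed` correlates the
stimulus with a *deterministic function of the stimulus* (the network sees
only envelope features). It is therefore not an estimator of the
stimulus–response canonical correlation and is not bounded by the linear
ceiling `ρ*`: on linear synthetic data with `ρ* = 0.745` the pipeline
reaches ≈ 0.81 at desk scale and ≈ 0.93 with the full-width network. That
exceedance is the method's point — the prediction is free of the noise and
artifacts that cap the baseline — and it mirrors the published behavior on
real recordings, where the network column exceeds the linear-CCA column by
an order of magnitude. The honest interpretation of `rho_proposed` is "how
much stimulus-locked structure the trained pipeline can reproduce in the
response representation", with `rho_lcca` as the accompanying measurement of
the raw stimulus–response correlation.

## Open choices resolved by this package

* **CCA fitting scope**: per subject, on the concatenation of the training
  trials of each fold, never including the held-out trial. Whether the
  reference analysis excluded the test trial from the CCA is unstated; we
  exclude it to avoid leakage (verified by a checksum test: corrupting the
  held-out trial leaves every fitted parameter bit-identical).
* **Lags**: lag-0 CCA only; temporal structure is left to the window/KLT
  stages. The generator's `lag_samples` exists precisely to probe the cost
  of this choice.
* **Per-subject training**: one model per subject per fold. Pooling windows
  across subjects is possible in principle but conflicts with the
  per-subject cross-testing protocol, so it is not the default path.
* **Mastoid channels**: the portable data layout carries already-referenced
  channels; no mastoid handling is done at load time.
* **Reporting convention**: stored values are full precision; tables are
  displayed at 3 decimals (correlations) and 2 decimals (percent), and the
  relative-improvement line is computed from the displayed overall values,
  matching the convention of the published tables it mirrors.

## Known limitations

* The public speech-EEG corpora distribute MATLAB container files; no reader
  for those containers is bundled (no such parser is among this package's
  dependencies). Convert external data to the portable layout documented in
  `?save_subject`.
* The MLP is plain R with BLAS matrix products: comfortable at desk scale
  (tens of thousands of windows, widths in the hundreds), not tuned for the
  full 1000/550 architecture on hours of 128-channel data.
* `oracle_correlation` covers the linear, lag-0, artifact-free case only;
  for nonlinear couplings the only available truth is the Monte-Carlo
  superiority comparison against the linear baseline.
* Quadratic coupling with a symmetric envelope distribution is nearly
  uncorrelated with any *linear* readout; the CCA projection step can then
  fail to concentrate stimulus information, and the pipeline inherits that
  failure. The envelope's skewness makes the default generator avoid the
  fully pathological case.
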