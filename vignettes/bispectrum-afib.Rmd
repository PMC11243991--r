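---
title: "Bispectrum images for atrial fibrillation detection: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bispectrum images for atrial fibrillation detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgbispec)
```

## The method in one paragraph

Atrial fibrillation (AFIB) disrupts three things a normal ECG has: regular
RR intervals, a P wave before every QRS complex, and a quiet baseline.  The
package detects AFIB in 5-second single-channel ECG segments by estimating
each segment's bispectrum — the two-dimensional Fourier transform of the
third-order cumulant sequence — cropping the 0.5–12 Hz bifrequency square,
normalizing it into a 24 × 24 gray image, and classifying the images with a
compact serial CNN (AFIB-NET).  The bispectrum is the right summary because
it is zero in expectation for Gaussian processes (so additive Gaussian noise
is suppressed), it preserves phase relations between harmonic components,
and it reacts differently to the phase-locked harmonic comb of a regular
rhythm than to the smeared, fibrillatory structure of AFIB.

## Cumulants and the bispectrum

For zero-mean stationary $x(t)$ the second- and third-order cumulant
sequences are $C_2(\tau) = E[x(t)x(t+\tau)]$ and
$C_3(\tau_1,\tau_2) = E[x(t)x(t+\tau_1)x(t+\tau_2)]$.  For general (not
mean-subtracted) samples the joint cumulants follow the partition
(Leonov–Shiryaev) expansion; `joint_cumulant2()` and `joint_cumulant3()`
implement the two- and three-variable cases with expectations as arithmetic
means, and `third_order_cumulant_sequence()` the lag grid with **biased**
$1/N$ normalization.  Biased normalization was chosen because it guarantees
a stable, positive-semidefinite-like spectral estimate at large lags where
few products are averaged; the variance cost is negligible at the record
lengths used.  The bispectrum is
$B(f_1,f_2) = \sum_{\tau_1}\sum_{\tau_2} C_3(\tau_1,\tau_2)
e^{-j2\pi(f_1\tau_1 + f_2\tau_2)}$, and its symmetries make the triangle
$k_2 \ge 0,\ k_1 \ge k_2,\ k_1 + k_2 \le N_{\text{fft}}/2$ (on FFT bins) the
non-redundant region, computed by `nonredundant_mask()`.  We store the full
non-negative quadrant $[0, N_{\text{fft}}/2]^2$ rather than only the
triangle because the classifier consumes *square* image crops; the exchange
symmetry $B(f_1,f_2)=B(f_2,f_1)$ fills the second half exactly.

## Estimators and their defaults

Two conventional non-parametric estimators are provided
(`estimator_config()`):

* **direct** — sub-records of `record_len` samples (default 512, the FFT
  length), 50% overlap, per-record mean subtraction and a Hann taper;
  per record the triple products $X(k_1)X(k_2)X^*(k_1+k_2)$ are accumulated
  and averaged over records.
* **indirect** — per-record $C_3$ lag grids (default `max_lag` 64) are
  averaged, multiplied by a 2-D lag window, and transformed by a 2-D DFT.
  The `"parzen"` window is applied in the product form
  $w(\tau_1)w(\tau_2)w(\tau_1-\tau_2)$, which preserves all bispectral
  symmetries; `"none"` keeps the raw truncated lags.

Only the FFT length (512) is fixed by the method definition; sub-record
length, overlap, taper and lag parameters are the conventional defaults of
higher-order-spectra toolboxes, and all are exposed in the config.  For a
1250-sample segment the default splits into 3 half-overlapping records; a
single-record mode (`record_len` < 512 with zero padding, or
`overlap_fraction = 0`) is available where the averaging behaviour itself is
under study.

The direct estimator also accepts a `smoothing` half-width $M$: the averaged
estimate is taken to the lag domain, multiplied by the Parzen product window
of half-width $M$, and transformed back (Blackman–Tukey-style frequency
smoothing).  This is the resolution-matched counterpart of an indirect
estimate with `max_lag = M`: the two estimators then agree closely
(rank correlation > 0.9 on the quadratically phase-coupled test signal),
whereas at full resolution their off-peak sidelobe fields are dominated by
estimator-specific leakage patterns and rank-correlate weakly.  That
comparison is exactly how the estimator cross-check in the test suite is
performed.

Numerical conventions: bin $k$ maps to $k \cdot f_s / N_{\text{fft}}$ Hz
with bin 0 = DC; sample intervals are 0-based and half-open; every record is
mean-subtracted before tapering because the cumulant formulas assume zero
mean and ECG has baseline offset.

## From bispectrum to network input

`band_bins()` maps a band to FFT bins as $k \in [1, \lfloor f_{hi}
N_{\text{fft}} / f_s \rfloor]$: the DC bin is excluded, and at
$f_s = 250$ Hz, $N_{\text{fft}} = 512$ the 0.5–12 Hz band gives bins 1–24
(a 24 × 24 crop, ~0.49–11.72 Hz) and 0.5–14 Hz gives bins 1–28.  This is the
unique bin rule consistent with both crop sizes.  The crop is the square
sub-matrix over the same bin range on both axes — not the non-redundant
triangle — because CNN inputs are square; the redundant half carries no
extra information but costs nothing.  Min–max normalization to $[0,1]$ is
**per image** over the cropped area only, so each image uses its full
dynamic range; a constant crop maps to all zeros (the neutral gray — the
degenerate case is not otherwise defined).  Pixels are kept real-valued by
default; `gray_levels = 256` snaps them to an 8-bit grid for workflows that
store images as PNG (the difference is below half a gray level and did not
change any test outcome, so continuous is the default).  `tile_for_gnn()`
replicates a 28 × 28 crop 8 × 8 and copies it to three channels for
ImageNet-sized inputs.

## AFIB-NET

`build_afibnet()` returns the 23-layer table: five 3 × 3 convolution blocks
(8, 16, 32, 64, 128 filters, stride 1, same padding), each followed by batch
normalization and ReLU, 2 × 2 max pooling after the first four blocks, then
a fully connected layer to 2 classes, softmax and the classification output.
The pooling strides are 1, 1, 2, 2, giving the spatial trajectory
24 → 23 → 22 → 11 → 5.  The published layer table prints stride values that
contradict its own activation shapes (a stride [1 1] against a 22 → 11
halving, and [2 2] against size-preserving convolutions); we follow the
activation column because it is self-consistent and pins the fully
connected fan-in ($5 \cdot 5 \cdot 128 \cdot 2 + 2 = 6402$ learnables).
Total learnables: 105,138, recomputed layer-by-layer by
`count_learnables()` from the structural formulas
($k^2 C_{in} C_{out} + C_{out}$, $2C$, $\text{fan}\cdot c + c$).

Training (`afibnet_train()`) is mini-batch SGD with momentum 0.9 and
cross-entropy loss.  The initial learning rate follows the stated scaling
rule $0.1 \cdot \text{batch}/128$, i.e. 0.025 at the default batch of 32;
the alternative transcription 0.25 that appears alongside the formula is an
order of magnitude hotter and is not the formula's value, so 0.025 is the
default and the argument is overridable.  The optimizer is not otherwise
specified in the source material; plain SGD+momentum is the customary
default for this training style and is what we ship.  Batch normalization
uses mini-batch moments in training and exponentially averaged running
moments (decay 0.9, $\varepsilon = 10^{-5}$) at prediction.  Weights use He
initialization; all randomness (init, shuffling) is drawn from the R RNG
under the supplied seed, so a fit is reproducible bit-for-bit on a fixed
BLAS thread count.  The convolution engine (im2col + GEMM, C++/Armadillo)
is deterministic.

The 70/10/20 split is segment-level by default, which mirrors the published
protocol; `split_dataset(mode = "record")` keeps all segments of one
recording in one part, the stricter protocol for leakage control, and is
recommended whenever record provenance exists.

## The synthetic generator

The generator (`rhythm_model()`, `generate_segment()`) emulates exactly the
three diagnostic features, with defaults fixed once:

| parameter | N rhythm | AFIB | unit |
|---|---|---|---|
| RR distribution | Normal(0.8, 0.03), truncated [0.5, 1.2] | Uniform(0.35, 1.1) | s |
| P wave | present | absent | — |
| f-waves | none | 3 sinusoids, frequencies U(4, 9) Hz, 0.05 mV each | — |
| noise | Gaussian, sd 0.02 | same | mV |

Beats are Gaussian-bump P-QRS-T complexes (R amplitude 1 mV); units are
millivolts and seconds throughout, matching the ±10 mV/12-bit calibration
of ambulatory recorders.  The N-rhythm RR spread (sd 0.03 s ≈ 4% of the
mean) is ordinary sinus variability; the AFIB RR range spans the
irregularly-irregular 55–170 bpm band; 0.05 mV f-waves are small relative
to the 1 mV R wave, as on real tracings.  The generator logs ground-truth
beat onsets and RR draws next to the samples, so rhythm statistics can be
verified without a QRS detector, and segments round-trip through a
plain-text fixture format and through WFDB-compatible record files.

What the generator does **not** emulate: morphology variability between and
within subjects, baseline wander, motion artifacts, ectopy, atrial flutter,
or conduction abnormalities.  Synthetic AFIB and N are therefore *much*
easier to separate than database rhythms — the desk-scale run reaches AUC
≈ 1.0, where the published full-scale result on real recordings is 0.983
with sensitivity 0.953 and specificity 0.937.  Passing the synthetic
end-to-end test shows the pipeline is wired correctly and the classifier
can exploit the intended signal; it says nothing about clinical
performance.

## Evaluation measures

`metrics_report()` computes sensitivity, specificity, PPV, NPV, prevalence,
accuracy (the count form and the prevalence-weighted form
$\text{sens}\cdot PV + \text{spec}\cdot(1-PV)$ are cross-checked to
$10^{-12}$), LR+ $= \text{sens}/(1-\text{spec})$, LR− $=
(1-\text{sens})/\text{spec}$, and F-scores.  $F1_{AFIB}$ is the harmonic
mean of PPV and sensitivity.  For the N class the default is the harmonic
mean of **NPV and the AFIB sensitivity** — the convention under which the
published measure column is internally consistent (it reproduces both
printed N-class values); the statistically standard per-class alternative
(NPV with specificity) is available via `f1_n = "per_class"`.  Zero
denominators yield `Inf` where the ratio diverges (e.g. LR+ at perfect
specificity) and `NA` with a warning where the measure is genuinely
undefined; presentation rounding is half-up to 3 decimals
(`round_report()`), with raw values retained.  `roc_curve()` sweeps unique
scores (ties enter together), integrates AUC by the trapezoidal rule —
identical to the Mann–Whitney pair-count statistic, which the tests verify
exhaustively — and records the threshold-0.5 operating point.

## Segmentation and database accounting

Rhythm annotations are parsed from MIT-format files; each rhythm marker
opens an episode that runs to the next marker or the record end (0-based,
half-open).  Kept-label episodes are cut into consecutive non-overlapping
5-s windows starting at the episode's exact annotation sample — no beat
alignment, matching plain time division — **independently on each of the
two ECG channels**, and the two channels' segments are pooled.  The
two-channel rule is inferred from count arithmetic (the published segment
and omission totals equal twice the per-channel quantities), not from an
explicit statement.  A trailing remainder shorter than one window, or an
episode shorter than 5 s, contributes one omitted fragment per (episode,
channel).  Records whose signal files are absent are skipped and reported,
as with the two unavailable recordings of the reference database.

## Problem sizes and budgets

The package's own tests and the acceptance script run at desk scale,
chosen so the full suite completes in a few minutes on one CPU: the
end-to-end check uses 500 synthetic segments per class, 10 training epochs
and a fixed seed (held-out AUC ≥ 0.90 required); estimator property checks
use 4–64 records of 512 samples; the full-scale profile
(`pipeline_profile("paper")`: 18,000 images, 40 epochs, a WFDB database
directory) reproduces the published protocol when the database is
available locally.

## Known limitations

* The CNN engine is single-purpose (this architecture family, CPU only);
  it is not a general deep-learning framework.
* Bicoherence normalization, parametric (AR) bispectrum estimation and
  higher polyspectra are out of scope.
* GoogLeNet fine-tuning requires externally pretrained weights; only its
  input-image preparation (`tile_for_gnn()`) is provided.
* Reproduction of the published database totals requires the database
  itself; offline, the accounting and segmentation rules are verified on
  WFDB databases synthesized in code.
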