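---
title: "Models and methods behind cardiopatch"
author: "cardiopatch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiopatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cardiopatch is a self-contained analytics stack for single-lead wearable ECG:
a synthetic-data generator with exact ground truth, a preprocessing chain,
Pan-Tompkins vitals, signal-quality metrics, an interpretable attention
transformer (IAT) for 4-class disease classification, and an adversarially
trained network that assesses how the patch is worn. This vignette records
the models, the tunable parameters and the design decisions, in enough
detail that a reader can judge what the package's tests do and do not
demonstrate.

## The synthetic ECG generator

No public dataset covers the combination this package targets — four disease
classes crossed with three wear orientations of a 120°-symmetric triangular
patch, with per-sample ground truth. The generator therefore *is* the study
population, and everything downstream is evaluated against its ground truth.

Each beat is a sum of five Gaussian deflections (P, Q, R, S, T) on a beat
phase $\phi \in (-\pi, \pi]$ with the R peak at phase zero:

$$x(\phi) = \sum_{w} a_w \exp\!\left(-\frac{(\phi - \theta_w)^2}{2 b_w^2}\right).$$

This phase-domain construction (in the spirit of classical dynamical ECG
models) gives analytic fiducials: P-wave, QRS, ST-segment and T-wave spans
follow from $\theta_w \pm k\, b_w$ and are emitted as 0-based half-open
sample spans. R-peak ground truth is exact: consecutive R peaks are
separated by exactly the drawn RR intervals, and each R-peak index coincides
with the argmax of its beat's clean waveform to within one sample.

Default morphology approximates an upright lead-II trace (R = 1.0 mV,
P = 0.12 mV, T = 0.30 mV, PR interval about 160 ms, ST span about 90 ms at
60 bpm). RR intervals are drawn i.i.d. normal with mean $60/\mathrm{HR}$ s
and the bpm-equivalent spread mapped into the RR domain; an optional
respiratory modulation exists but defaults to off so that a zero-variance
rhythm is exactly periodic.

Pathology is imprinted as the textbook waveform signatures:

* **MI** — every ST-segment span offset by `st_shift` (default +0.2 mV);
* **AR** — the RR sequence re-drawn with its standard deviation multiplied
  by `rr_irregularity_factor` (default 4) plus premature ectopic beats with
  per-beat probability `ectopic_prob` (default 0.1). Ectopic beats carry the
  textbook morphology of a premature contraction: absent P wave, QRS
  widened 1.6x, damped T, a 0.6x shortened RR followed by a 1.4x
  compensatory pause;
* **AH** — P-wave amplitude scaled 2x and width 1.5x.

The magnitudes are unstated in the motivating application, so they were
fixed once at values giving clear but non-trivial separation: with default
profiles at 30 s the per-class summary statistic (mean ST level for MI, RR
standard deviation for AR, P/R amplitude ratio for AH) sits at least 5
pooled standard deviations away from normal. Mean heart rate varies across
records, uniform on 55–95 bpm, so rhythm rate itself is not a class cue.

Misplacement of the triangular patch admits three stable orientations.
`O120` and `O240` distort the trace as

$$x' = p \cdot s\,[(1-m)\,x + m\,\mathrm{warp}(x)] + o,$$

with polarity $p$, amplitude scale $s$, baseline offset $o$ and a morphology
mix $m$ toward a warp signal re-synthesized with fixed per-wave amplitude
re-weighting (P 1.5x, Q 0.5x, R 0.8x, S 2x, T 0.6x). This reproduces the
three misplacement signatures of interest — baseline shift, amplitude
change, waveform shape alteration — and is exactly invertible, which the
position module exploits when it verifies its own adjustment suggestions.
Orientation labels compose as the cyclic group of order 3. The transform
values (O120: 0.6, −1, +0.1 mV, 0.3; O240: 0.7, +1, −0.1 mV, 0.5) are
synthetic stand-ins, fixed in configuration.

Noise is additive: a baseline-wander sinusoid (0.3 Hz, 0.15 mV), mains
interference (50 Hz, 0.05 mV), white broadband noise (0.03 mV), and
Poisson-timed motion bursts (1/min, 0.2 mV, 50 ms Gaussian envelope). These
defaults describe a decent ambulatory recording; `noise_for_snr()` instead
constructs a pure broadband mixture at an exact expected power ratio, which
is what the signal-to-noise acceptance checks use.

What the generator does **not** emulate: inter-subject morphology variation
beyond wave-parameter settings, non-stationary noise (electrode pops,
motion correlated with the cardiac cycle), atrial-fibrillation-like
waveform chaos, conduction-block morphologies, or any multi-lead structure.
Passing tests therefore demonstrate that the algorithms recover structure
*of this model family*; they do not certify clinical performance.

## Preprocessing

Fixed order: 50 Hz notch → band-pass → baseline correction → segmentation →
per-window z-normalization.

* The notch is a second-order Butterworth band-stop of width
  $f_0/Q$ (Q = 30) applied forward–backward, so the effective magnitude is
  $|H|^2$ and the phase is zero: ≥ 30 dB attenuation at 50 Hz with < 1 dB
  passband deviation over 1–40 Hz.
* The diagnostic band-pass is a cascade of second-order high-pass (0.5 Hz)
  and low-pass (40 Hz) Butterworth filters, each zero-phase; the cascade
  avoids the numerical fragility of a direct band-pass design with a 0.004
  relative lower edge.
* Baseline correction subtracts a two-stage running-median estimate (200 ms
  then 600 ms windows). A median baseline is used instead of a sharper
  high-pass because it preserves ST-segment levels, on which the MI label
  depends.
* Segmentation drops trailing partial windows rather than padding, keeping
  all model inputs the same length; constant windows normalize to zeros and
  carry a flag.

The zero-phase contract is tested: the chain moves R-peak locations by at
most one sample.

## Pan-Tompkins vitals

The QRS detector is the classic adaptive-threshold formulation: 5–15 Hz
band-pass, five-point derivative, squaring, 150 ms moving-window
integration, dual signal/noise peak trackers with 0.125/0.875 and
0.25/0.75 update coefficients, a 200 ms refractory period, a T-wave slope
check inside 360 ms, and search-back at 1.66x the running mean RR with a
halved threshold. Because the package runs offline, every stage is
zero-phase and accepted detections are refined to the raw-signal maximum
within ±50 ms. One practical detail: candidate maxima of the integrated
signal are first pruned to a minimum separation of one refractory period —
integration ripple otherwise yields rising-edge sub-peaks that fire the
threshold early.

Heart rate in a 6-s window is $60/\overline{RR}$ over the RR intervals
whose midpoint falls in the window (stabler than peak counting at this
window length); windows without any RR midpoint are flagged missing rather
than interpolated. HRV statistics use the population convention for SDNN;
RMSSD and pNN50 are standard. No ectopic-beat rejection is applied before
HRV (configurable upstream by regenerating without ectopics). The streaming
interface emits one update per window and is batch-backed: detection runs
on the full record so that streamed windows are identical to batch
segmentation, which makes stream-equals-batch an exact identity rather than
an approximation — it reproduces the app-style cadence, not a true causal
detector.

## Quality metrics

* **Template SNR.** Beats are aligned on R peaks over a window of half the
  shortest RR per side (≤ 0.6 s), with an integer-lag realignment pass
  against the ensemble average (detector jitter of one sample on the steep
  QRS slope would otherwise dominate the residual). The ensemble average is
  the signal estimate, per-beat residuals are noise, and
  $\mathrm{SNR} = 10\log_{10}(n\sum \text{template}^2 / \sum \text{residual}^2)$.
  The wide window makes the estimate commensurate with a record-wide power
  ratio: a mixture constructed at 20 dB reads back within 1 dB. The
  definition is a package convention — reported values are comparable
  across runs of this package, not to any particular hardware's figures.
* **Drift amplitude.** The baseline is the 0.5 Hz FFT low-pass component;
  the reported drift is its peak-to-peak amplitude divided by the
  peak-to-peak amplitude of the detrended signal. The normalization makes
  the metric scale-invariant; "total amplitude" of drift is thus measured
  in units of the normalized ECG amplitude.
* **Instantaneous frequency.** Spectrogram (1 s Hanning window, 75%
  overlap) with the spectral first-moment ridge
  $\mathrm{IF}(t) = \sum f P(f,t) / \sum P(f,t)$, chosen over an
  analytic-signal phase derivative because the ECG is multi-component.
* **Cross-correlation.** Pearson correlation maximized in magnitude over
  lags up to ±0.5 s, reported with its sign and lag.

## The interpretable attention transformer

The classifier follows the slice-embed/CLS/self-attention design. One
normalized diagnostic window per record (default 8 s of the 10-s record) is
processed as:

1. a 1-D convolution over the raw window (8 channels in two kernel groups,
   ReLU) extracts local features — because it runs *before* slicing, each
   token sees context beyond its own slice. The kernel length is the
   decisive receptive-field parameter: the default 127 samples (≈ 0.5 s)
   lets every token see both QRS complexes flanking it, which is what makes
   R-R-interval structure a first-order token feature. A second kernel
   group (`conv_kernel_local`) can be made narrow to keep morphology
   features strictly local (see the saliency discussion below); by default
   both groups use the wide kernel;
2. non-overlapping slices of 25 samples (0.1 s) are flattened and linearly
   projected to a 64-d embedding; a learned positional encoding is added
   and a learned CLS token is prepended (a single global CLS, the reading
   consistent with its role as the global representation);
3. two pre-norm transformer encoder layers (4 heads, 128-d MLP, GELU,
   dropout 0.1) return final representations and the full per-layer
   attention tensor;
4. a linear head on the CLS representation produces the 4-class softmax.

Saliency maps the attention score matrix back to the signal: the final
layer's CLS row, averaged over heads, with the CLS self-score removed
(otherwise it is a degenerate attractor) and renormalized, spread uniformly
over each token's sample span. An attention-rollout variant (head-averaged
attention mixed with the identity and multiplied across layers) is
available behind `saliency = "rollout"`; the single-layer CLS reading is
the default.

Training minimizes cross-entropy with Adam (learning rate $10^{-3}$, batch
32) for 80 epochs with a linear warmup over the first tenth of the budget
and cosine decay to a tenth of the peak rate; parameters are averaged over
the final quarter of the epochs (stochastic weight averaging), which
reduces run-to-run variance of the finally selected weights. One data
augmentation is on by default: the 8-s window is cropped at a random
position of the 10-s record during training (centred at prediction time),
teaching translation-invariant rhythm features. A time-rescaling
augmentation and dropout on the attention probabilities exist but default
to off (the former blurs the QRS-width signature of ectopic beats, the
latter spreads attention off the waveform regions it should highlight).
Training is fully deterministic given the configuration seed (dropout uses
a counter-based generator keyed on epoch and batch).

The slice length (0.1 s) was set so that R-R dispersion — the arrhythmia
cue, with a scale of 0.05–0.2 s — is resolvable on the token grid; with
0.2-s slices the irregularity signal is sub-token. The wide conv kernel is
what makes the arrhythmia class *robustly* learnable: with kernels at or
below ~0.2 s the pure rate-dispersion cue (arrhythmic records whose 8-s
window happens to contain no ectopic beat, about a quarter of them) is
learned only on some optimization trajectories, and held-out recall for
the class varies widely across seeds; with the 0.5-s kernel every seed
tried learns it.

### Attention alignment is a trade-off, not a free property

The attention saliency is faithful to the model — it is exactly the CLS
attention mass — but whether that mass coincides with the clinically
diagnostic waveform regions depends on the tokenizer's receptive field.
With strictly narrow kernels (≈ 0.1 s or less), class evidence exists only
in the tokens covering the diagnostic deflection, and the trained model's
saliency concentrates sharply on ST segments for MI (enrichment far above
the uniform baseline on every test record in our runs). With the wide
kernel that rhythm classification needs, the same evidence is smeared into
every token within half a second of the deflection, the classifier is free
to read it from anywhere, and the saliency no longer localizes reliably —
the package's own acceptance checks measure and report exactly this. The
defaults favour diagnostic robustness (wide kernels); users who want
localized saliency maps can set `conv_kernel_local` to ~25 samples and
accept a less reliable arrhythmia class. This mirrors a well-known caution
in the interpretability literature: attention maps explain *where the
model looked*, which aligns with *where the evidence is* only under
architectural constraints that force the two together.

## Wear-position network

The assessment network maps each frame of 50 samples through a fully
connected embedding (32-d, ReLU), a 1-D convolution across the embedded
frame sequence (32 channels, kernel 3 frames), and a GRU (32 hidden units)
whose final state is the summary vector. Two heads share this summary: a
3-class orientation softmax, and a discriminator — a small MLP on the
summary concatenated with its difference from the encoded
standard-position reference — that scores, in (0, 1), whether the window
comes from a correctly placed patch. The reference vector is tracked as an
exponential moving average of standard-position summaries during training
and frozen to their mean afterwards.

Training is joint: orientation cross-entropy plus the discriminator's
binary cross-entropy (real = standard position), weighted equally. The
discriminator acts as a *verifier* — there is no generator being fooled and
no gradient reversal; adversarial pressure simply shapes a summary space in
which misplacement is visible. Placement is "within tolerance" when the
discriminator score reaches the configured threshold (default 0.5 — the
underlying tolerance criterion is not quantified anywhere, so the neutral
probability is used). The suggested adjustment is the rotation (0, −120 or
+120 degrees) returning the predicted orientation to standard; the patch
geometry admits only these three stable placements, so a classification
head rather than a continuous regression is used.

One augmentation is essential: training windows receive white noise with a
relative standard deviation drawn uniformly from [0, 0.5]. Undoing a
misplacement transform numerically amplifies the additive noise by the
inverse gain (about 2.4–2.9x), and without noise augmentation the
discriminator keys on the noise floor instead of the morphology, rejecting
corrected windows it should accept. With it, applying the suggested
inverse transform raises the discriminator score on the large majority of
misplaced held-out records. After per-window normalization the `O240`
orientation differs from standard only through its morphology mix, which
makes it the hardest of the three and dominates the remaining confusion.

The network input is the ECG window itself; the application's "position
data" is not otherwise specified, and the waveform is the information the
deep-learning placement classification demonstrably uses.

## Pipeline and reporting

`run_report()` composes the modules in a fixed order with the position
check first: a misplaced patch flags the diagnosis as
position-compromised, but the diagnosis is still emitted — suppressing it
would hide information from the user, flagging it preserves both signals.
Reports carry a provenance block (seeds, window length, filter settings)
from which every numeric field reproduces byte-identically. A pluggable
text-advice backend stands where an external conversational service would
sit; the built-in backend is an offline template keyed on the predicted
class and the position flag. The diagnostic window fed to the classifier is
the model's 8-s window; vitals update on 6-s windows.

## Numerical choices and degenerate inputs

* Zero-phase filtering throughout; filter edge effects are avoided in tests
  by measuring away from record boundaries.
* Flat or constant signals: the QRS detector returns an empty peak set;
  normalization maps constant windows to zeros with a warning flag;
  cross-correlation on constant input is an error (undefined metric).
* Fewer than 3 R peaks is insufficient data for HRV; fewer than 5 beats for
  template SNR.
* Sample indices are 0-based and fiducial spans half-open, matching the
  generator's ground-truth convention everywhere.
* R-peak times are quantized half-up to the sample grid, so a 120-bpm
  zero-variance rhythm yields exactly 125-sample spacing at 250 Hz.
* All stochastic components (generation, training order, dropout,
  augmentation) derive from named integer seeds; datasets and fitted
  models are byte-reproducible given those seeds.

## Problem sizes used by the packaged experiments

The packaged evaluation trains the IAT on 1000 synthetic records (balanced
classes, 80/20 stratified split, 10-s records at 250 Hz) and the position
network on 600 records balanced over the three orientations; the
shuffled-label control reuses the 1000-record dataset with permuted labels
and a shortened (30-epoch) budget, since its claim — held-out accuracy at
chance — is about information, not optimization. Signal-level checks use
30–60 s single records. These sizes make the full suite reproducible on a
single CPU in well under half an hour.

## Known limitations

* All performance statements are within the generator's model family; no
  claim transfers to human recordings without revalidation.
* The streaming interface is batch-backed (see above), not a causal
  real-time detector.
* WFDB support is a minimal native subset (format 16, single signal,
  beat-annotation round-trip) written for this package; interoperability
  with the full format ecosystem is untested beyond that subset.
* The positive-polarity refinement step of the QRS detector assumes upright
  R peaks; strongly inverted leads should be corrected (position module)
  before vitals are trusted.
* Orientation misplacement is modelled as three discrete placements;
  continuous rotation is out of scope.
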