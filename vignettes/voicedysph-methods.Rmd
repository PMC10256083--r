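---
title: "Multicepstral multiprojection detection of dysphonia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicepstral multiprojection detection of dysphonia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented by **voicedysph**, the
choices made where the design was genuinely open, and what the bundled
synthetic corpus can and cannot show about real clinical audio.

## 1. Signal model and representation

A sustained vowel is modelled as a quasi-periodic glottal excitation
filtered by vocal-tract resonances, plus aperiodic noise. Dysphonia
manifests acoustically as elevated cycle-to-cycle perturbation of periods
(jitter) and peak amplitudes (shimmer) and as a reduced
harmonic-to-noise ratio (HNR). The package represents a recording by two
complementary blocks.

### Cepstral block

Eight extractors produce a `20 x nframes` coefficient matrix each:

* six filterbank families sharing one spectral front end — 25 ms Hamming
  windows, 10 ms hop, pre-emphasis 0.97, FFT size the next power of two at
  or above the window, 26 filters, log floor `1e-10`, orthonormal type-II
  DCT. The scales are mel, inverse mel (the mel bank mirrored along the
  frequency axis), linear, bark (Traunmüller warp
  `z = 26.81 f/(1960+f) − 0.53`), and 4th-order gammatone / gammachirp
  magnitude responses at ERB-spaced centres (chirp factor fixed at −1,
  gammachirp rows scaled to unit maximum). These framing constants are the
  de-facto defaults of the cited feature families; none is tuned.
* LPCC: autocorrelation-method LPC of order 16 per frame via
  Levinson–Durbin, converted by the standard cepstral recursion with
  `c0 = ln G²`; zero-energy frames degrade to `(ln ε, 0, …, 0)`.
* CQCC: a constant-Q transform with 96 bins/octave over the 9 octaves
  below Nyquist, implemented with sparse frequency-domain kernels; kernel
  windows are capped at 2^16 samples (truncating the lowest-frequency
  filters is equivalent to zero-padding 1–2 s signals, which is what
  reference implementations do), ~100 frames/s, log power, spline
  resampling of the log spectrum onto a uniform linear-frequency axis,
  orthonormal DCT.

First- and second-order regression dynamics (half-window `N = 2`, edge
replication) are computed from the raw static matrix; cepstral
mean–variance normalization (CMVN) is then applied to each of the three
matrices independently. An important structural consequence, verified by
the test suite: because CMVN standardizes every coefficient trajectory,
the SUM projection of a CMVN'd matrix is identically 0 and the STD
projection identically 1 — under this processing order only the SKEW and
PCA mappings carry cepstral information. The order (dynamics first, CMVN
afterwards, projection last) is the package's reading of the stated
design; it is kept because it makes each of the three matrices exactly
standardized, and the degenerate blocks are harmless downstream (constant
coordinates are zeroed by normalization).

### Multiprojection

Each mapping in the ordered set `M` sends a coefficient trajectory to one
scalar: row sums (SUM), population standard deviation (STD), uncorrected
`g1` skewness (SKEW, 0 when the row variance is below `1e-12`), and the
row's score on the first principal axis of the centred matrix (PCA; rows
are the samples, the axis sign is fixed so its largest-magnitude loading
is positive, making the mapping deterministic). Population rather than
sample statistics are used throughout because no bias correction is
prescribed anywhere in the design. Single-frame matrices return zeros
(SUM returns the single column). The fused cepstral vector concatenates
`m(C), m(Δ), m(ΔΔ)` per mapping, then per technique:
`length = n_P · 3 · 20 · n_M`.

### Noncepstral block (28 coordinates)

F0 statistics, jitter and shimmer families, HNR, and formant measures, in
a fixed documented order (`NONCEPSTRAL_LAYOUT`).

* **F0**: framewise normalized autocorrelation (40 ms frames, 10 ms hop),
  search range 60–500 Hz, voicing threshold 0.45, parabolic lag
  refinement. The autocorrelation uses the normalized cross-correlation
  form (segment-energy denominators), which is bounded by 1 and nearly
  unbiased at the pitch lag; among near-maximal peaks the shortest lag is
  preferred, suppressing octave errors.
* **Pulse marks**: peak walking one expected period at a time from the
  strongest voiced-region peak, searching ±25 % of the local period; the
  expected period comes from a 5-point running median of the voiced F0
  track; cycles outside `[0.5, 2]×` the median period are discarded
  (longest valid run kept).
* **Jitter**: local (`mean|ΔT|/mean T`, %), local absolute (s), RAP
  (3-point average perturbation, %). **Shimmer**: local dB
  (`mean|20 log10(A_{i+1}/A_i)|`), APQ3/5/11 (centred-window average
  perturbation quotients, %), DDA = 3·APQ3 (the conventional identity).
  The consecutive-difference / K-point forms are the standard
  perturbation definitions; the prose descriptions in the source material
  are not operational.
* **HNR**: per voiced frame `10 log10(r'/(1−r'))` from the normalized
  autocorrelation at the pitch lag, clamped to [−20, 60] dB, averaged.
* **Formants**: resample to 10 kHz (Fourier method), pre-emphasis 0.97,
  25 ms Gaussian-tapered frames, autocorrelation LPC, polynomial roots →
  (frequency, bandwidth) candidates, kept if 90–4800 Hz with bandwidth
  < 400 Hz; the lowest four per frame fill F1..F4 slots, each slot
  reported (mean and median) over the frames where it is filled, needing
  at least 5 frames. The LPC order default is 16: order 12 proved too
  small to resolve F3/F4 against the high-frequency band of broadband
  excitation, and 16 recovers all four /a/ formant medians within ±60 Hz
  on the synthetic corpus.
* **Derived vocal-tract measures** with speed of sound `c = 350 m/s` (a
  representative warm-air value; the underlying definitions leave it
  open): dispersion `(F4−F1)/3`; `ΔF` as the least-squares slope of `F_i`
  against `(2i−1)/2`; tract lengths `c/(2ΔF)` and `c/(2·dispersion)` in
  cm; `MFF = (F1F2F3F4)^{1/4}`; formant position as the mean of the four
  medians z-scored against training-corpus statistics (0 when none are
  available).
* The jitter-PCA and shimmer-PCA coordinates are scores on
  one-dimensional principal axes fitted (centred, unscaled) on the
  training corpus's jitter and shimmer blocks; fitting is per training
  partition — inside each CV fold — to avoid leakage. Measures undefined
  for a signal (unvoiced input, too few cycles, missing formants) are
  imputed with training-corpus medians so fusion never sees missing
  values.

## 2. Detection pipeline

Training follows balance → reduce → normalize → classify, all fitted on
the training partition only:

1. **SMOTE** (k = 5 neighbours): the minority class is oversampled to the
   majority count with points `x + u(x_nn − x)`, `u ~ U[0,1]`; originals
   retained; deterministic given the seed.
2. **Truncated SVD** of the *uncentered* training matrix (pure SVD, not
   PCA); `m = round(fraction · d)` (half away from zero, at least 1)
   leading right singular vectors; at fraction 1.0 the basis is a full
   orthonormal rotation, hence an isometry. The inferred rounding matches
   the published reduction arithmetic (10 % of 240 → 24, 50 % of 60 → 30).
3. **Normalization**: Min–Max, Standard (population sd), Robust (median
   and IQR with linear-interpolation quantiles), or identity; zero-range
   coordinates map to 0.
4. **Classifier**, each with class weights inversely proportional to
   class frequencies (active even with SMOTE off):
   * SVM, RBF kernel, C = 1. The kernel width uses the classic median
     heuristic `γ = 1/(2·median‖x−x'‖²)` on the training set. The
     sklearn-style default `γ = 1/(m·var)` was evaluated first and
     rejected: with CMVN making most cepstral coordinates uninformative,
     that width concentrates the kernel on noise coordinates and
     end-to-end accuracy collapses, while the median heuristic is
     data-driven, standard, and not tied to any particular configuration.
   * Random forest, 100 trees (seeded, hence reproducible).
   * L2-regularized logistic regression (`glmnet`, `alpha = 0`,
     `lambda = 1/n`).

Metrics: EH, EP, EER = (EH+EP)/2 (an exact identity, asserted on every
evaluation), ACC, and F1 with dysphonic as the positive class — F1 is
implemented as the harmonic mean of precision and recall; the
sensitivity/accuracy phrasing found in some descriptions is treated as a
wording slip. KFCV is a stratified 5-fold cross-validation in which
SMOTE, the reducer, the normalizer and the noncepstral auxiliaries are
all refitted inside each fold.

`run_grid()` evaluates the Cartesian product of technique sets (P1–P15),
mapping sets (M1–M9), noncepstral on/off, normalizations, reduction
fractions, classifiers and balancing, against one stratified 75/25 split,
and emits per-metric best-configuration descriptor strings
(`value|techniques|normalization|dim|classifier|balancing|mappings`).
Signal-level features are computed once per corpus and shared across
folds and grid rows; this is sound because they depend only on the
signal, never on the partition.

## 3. The synthetic corpus: what it emulates, and what not

`synthesize_vowel()` is a source–filter generator: Rosenberg-style smooth
glottal pulses (open quotient 0.6), one per cycle; cycle periods
`T_i = T0(t)(1+ε_i)` and log-amplitudes perturbed by independent Gaussian
deviates rescaled so the realized local jitter and local shimmer of the
cycle sequence equal the targets exactly; cascaded second-order
resonators at the four vowel formants (classic presets — /a/
730-1090-2440-3400 Hz, /i/ 270-2290-3010-3700, /u/ 300-870-2240-3400,
bandwidths 60-100-120-150 Hz) plus a fixed fifth resonance at 4.5 kHz
(real vocal tracts have one; without it the 3.5–5 kHz band is
unrealistically flat and LPC formant estimation degrades); a
lip-radiation first difference; white noise scaled to the requested HNR;
peak normalization to 0.9. The pulse shape follows the *nominal* local
period so that period perturbation moves waveform landmarks one-to-one —
otherwise measured jitter is structurally attenuated. Pitch regimes scale
the base f0 by 1.25/0.8/1.0 (high/low/normal); "low-high-low" ramps f0 up
20 % mid-utterance and back (raised-sine contour).

Default class conditions (1 s at 50 kHz, 16-bit-equivalent amplitudes):
healthy jitter 0.2–0.5 %, shimmer 0.1–0.3 dB, HNR 25–35 dB; dysphonic
jitter 2–5 %, shimmer 1–2 dB, HNR 5–15 dB; f0 uniform on 100–220 Hz;
vowels and pitch regimes sampled uniformly. These ranges are engineering
choices informed by clinical perturbation norms (healthy local jitter is
typically below ~1 %, pathological voices well above), not estimates of
any particular population.

Limitations to keep in mind when reading green tests: the generator has
no aspiration-modulated noise (noise is stationary white), no diplophonia
or subharmonics, no vocal tremor, no gender-specific tract scaling, no
recording-channel variation; cycle starts are quantized to samples, which
caps measurable HNR near 30–35 dB for non-integer periods; and the two
classes differ *only* in perturbation/noise parameters, so a pipeline
that separates them perfectly has demonstrated correct plumbing and
sensitivity to perturbation cues — not clinical validity. Back vowels
(/u/-like spectra) recover F3/F4 less accurately than /a/ and /i/.

## 4. Numerical choices and degenerate inputs

* Log floor `ε = 1e-10` everywhere a log is taken; zero-variance rows,
  zero-range normalizer coordinates and zero-energy LPC frames have
  explicit documented degenerate rules (zeros / identity / `(ln ε, 0…)`).
* Resampling uses the Fourier method (spectrum zero-pad/truncate): it is
  exactly band-limited, handles arbitrary rate ratios, preserves
  sub-Nyquist sinusoid amplitude within 1 %, and is deterministic; a
  polyphase FIR design would trade exactness for edge behaviour and a
  filter-length parameter.
* All randomness (synthesis, SMOTE, fold shuffling, random forest) flows
  from explicit integer seeds through one guarded RNG scope, so every
  fitted model, grid row and corpus is bit-reproducible; library calls
  never perturb the caller's RNG state.
* Test and acceptance problem sizes — 200-signal default corpus, 20 seeds
  per parameter-recovery estimate, 5 evaluation splits, 10 chance-level
  shuffles — were chosen as the smallest sizes at which the stochastic
  checks are stable, keeping the full suite in the low minutes on one
  core.

## 5. Known limitations

The pipeline operates on sustained vowels only (no connected speech), a
single channel, and a binary healthy/dysphonic contrast. CMVN before
projection discards the SUM/STD cepstral information by construction (see
§1); configurations relying on those mappings alone lean entirely on the
noncepstral block. The grid does not search classifier hyperparameters —
C, tree count and λ are fixed defaults, and only the RBF width adapts via
the median heuristic. Real-data performance claims require a real corpus;
the synthetic acceptance results bound only the implementation, not the
clinical problem.
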