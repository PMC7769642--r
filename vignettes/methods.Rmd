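---
title: "Heart valve ailment detection from phonocardiograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart valve ailment detection from phonocardiograms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlksrn)
```

## The problem

Heart valve ailments — mitral valve prolapse (MVP), aortic stenosis (AS),
mitral regurgitation (MR), mitral stenosis (MS) — alter the heart's acoustic
signature: the S1/S2 valve-closure transients change shape, and turbulent
flow adds murmurs in the systolic or diastolic interval. A phonocardiogram
(PCG) captures these sounds cheaply and non-invasively. This package
implements a complete pipeline that classifies a whole multi-cycle PCG
recording into one of the five classes (normal plus the four ailments)
without segmenting it into cardiac cycles.

The pipeline is: bandpass filtering and amplitude normalization; a
spline-kernel Chirplet transform (SCT) to the time-frequency domain;
per-frequency-atom nonlinear features (L1-norm, sample entropy, permutation
entropy; 1200 dimensions in total); two stacked extreme-learning-machine
(ELM) autoencoders reducing 1200 to 800 to 600 dimensions; and a kernel
sparse representation classifier (KSRC) that assigns the class with the
smallest class-restricted reconstruction residual.

## Preprocessing

Recordings are resampled to a 4 kHz working rate (downsampling only — the
pipeline never fabricates bandwidth), bandpass filtered to 25–900 Hz, and
divided by their maximum absolute amplitude so every recording peaks at
exactly 1:

$$x(n) \leftarrow \frac{x(n)}{\max(|x(1)|, \ldots, |x(N)|)}.$$

Normalization removes device gain, which is why predictions are invariant
to input amplitude scaling. The filter is a fourth-order Butterworth applied
forward–backward (zero phase). The order and the zero-phase application are
this package's choices: low-order Butterworth bandpass with `filtfilt` is
the standard way to clean biosignals without phase distortion, and the
designed response meets −20 dB at 10 Hz and 1.5 kHz while staying above
−1 dB across 100–500 Hz. Filtering precedes normalization so the peak of
the *filtered* signal is what becomes 1.

## The spline-kernel Chirplet transform

The SCT sharpens the time-frequency representation of signals whose
instantaneous frequency (IF) varies nonlinearly — exactly the character of
murmurs. The IF law is modelled as a piecewise polynomial ("spline kernel"):
pieces $i = 1 \ldots I$ with breakpoints $n_i$ and phase-polynomial
coefficients $q_l^i$ ($l = 1 \ldots L$, units cycles/sample$^l$). For an
analysis time $\tilde n$ in piece $i$ the signal is demodulated by two pure
phase factors before Gaussian-windowed Fourier analysis: a *frequency-rotate*
operator

$$\Psi^R(n) = e^{-j 2\pi \left[\sum_l q_l^i (n - n_i)^l + \gamma_i\right]}$$

that flattens the IF law to zero, and a *frequency-shift* operator

$$\Psi^S(n, \tilde n) = e^{+j 2\pi \left[\sum_l l\, q_l^i (\tilde n - n_i)^{l-1}\right] n}$$

that shifts the flattened component back to its true frequency at
$\tilde n$. Because both operators have unit modulus, the demodulated signal
has the same energy as the input. With a zero coefficient matrix both
operators equal 1 and the transform reduces *exactly* to the
Gaussian-windowed STFT — the package's tests exploit this as a machine-
precision cross-check against an independent direct STFT.

Two conventions circulate for the shift operator: with or without the
factor $l$ (the derivative of the rotate phase). Only the derivative form
places the ridge of a matched component at its true frequency, so that is
the default; `convention = "printed"` selects the other reading. For purely
linear pieces the two coincide.

The phase offsets $\gamma_i$ (with $\gamma_1 = 0$) are chained so the rotate
phase is continuous at breakpoints:
$\gamma_{i+1} = \gamma_i + \sum_l q_l^i (n_{i+1} - n_i)^l$. They affect only
the phase of the transform, never the magnitude that the features consume,
but continuity keeps frames phase-coherent.

### Estimating the kernel

The kernel must be estimated from the data; we use the natural estimator in
the Chirplet literature: the maximum-magnitude ridge of a plain Gaussian
spectrogram, median-filtered (window 5) to suppress bin-jumps, then fitted
piecewise by least squares on `I = 10` equal-width pieces with order
`L = 3` polynomials. Within a piece the IF is modelled as a polynomial of
degree $L - 1$; the phase coefficients follow by antidifferentiation,
$q_l = c_{l-1} / l$. The ridge search ignores bins below 25 Hz (the filtered
band's lower edge), and a silent input is flagged `low_confidence` rather
than erroring.

### Analysis parameters

* `sigma = 200` samples (50 ms): comparable to S1/S2 burst duration, a
  standard compromise between resolving the transients in time and the
  murmur bands in frequency.
* `n_fft = 1600` at 4 kHz: 2.5 Hz bin spacing, so frequency atoms 1–400
  span 2.5–1000 Hz — covering the 25–900 Hz passband and the murmur band
  with headroom.
* `hop = 80` samples (20 ms): 2.5× oversampling of the window.
* Window support ±3σ, zero-padded at the recording edges.

These are package choices (the analysis parameters of this kind of
transform are application-set); all are arguments.

## Features

A frequency *atom* is one DFT bin of the magnitude matrix $|T(\tilde n, k)|$,
DC excluded. For each of the first 400 atoms the package computes:

* **L1-norm** $\mathrm{LN}^k = \sum_{\tilde n} |T(\tilde n, k)|$ — the
  total spectral mass of that frequency across the recording;
* **sample entropy** ($m = 2$, $r = 0.2\,\mathrm{SD}$, Chebyshev distance,
  self-matches excluded) — temporal irregularity of the atom's envelope;
* **permutation entropy** (order 3, delay 1, normalized by $\log 3!$,
  ties ranked by occurrence) — ordinal complexity, bounded in $[0, 1]$.

The 1200-dimensional vector is the blockwise concatenation
$[\mathrm{LN}^{1..400} \,\|\, \mathrm{SEN}^{1..400} \,\|\,
\mathrm{PEN}^{1..400}]$. The entropy parameters are the canonical defaults
of their originating definitions. Entropies are computed on the magnitude
(not power, not complex values): magnitudes are what the L1 feature uses
and keep all three blocks on the same footing.

Degenerate series need explicit policy. A silent atom is a constant series:
sample entropy uses an absolute tolerance floor of $10^{-12}$ so all
templates match and the value is 0 (fully regular), and permutation entropy
of a constant series is 0 (a single tie-pattern). When *no* template pair
extends to length $m + 1$ ($A = 0$), sample entropy returns the finite cap
$\ln(B'(B'-1)) + 1$, $B' = \max(B, 2)$ — larger than any attainable value —
instead of infinity. Both policies keep feature vectors finite on any input.

Features are min–max scaled per dimension, fitted on the training portion
only; constant dimensions map to 0, and out-of-range test values are mapped
affinely without clipping (clipping would hide distribution shift from the
classifier).

## The classifier

### ELM-autoencoder stack

Each layer draws fixed random input weights (orthonormalized by QR — the
usual stabilization — plus a random bias, both seeded), forms
$H = f(Z R + b)$ with a logistic sigmoid, and solves the output weights in
closed form by ridge regression:

$$W = \left(H^\top H + I / \gamma_{\mathrm{elm}}\right)^{-1} H^\top Z,$$

with $\gamma_{\mathrm{elm}} = 10^3$. $W$ maps hidden → input, so the layer's
feature map is $f(Z W^\top)$; two layers give
$Z^* = f(f(Z W_1^\top) W_2^\top)$ with sizes 800 and 600. The solved $W$ is
the unique minimizer of the ridge objective; the tests verify the normal
equations directly and by perturbation. Note the deliberate choice of the
ridge closed form: an L1 penalty on $W$ has no closed form and the
closed-form solution is what makes ELM autoencoders attractive (no
gradient training).

### Kernel sparse representation

Training deep features $z_i^*$ form the dictionary. With an RBF kernel
$k(x, y) = \exp(-\|x - y\|^2 / 2\sigma_k^2)$ — bandwidth set by the median
heuristic on the training features — the kernel matrix is $K$, and a
pseudotransformation $S$ ($m \times d$, default KPCA on the centered $K$
with $d = \min(m - 1, 300)$; random projection and kernel LDA are
selectable) reduces the kernel-space dimension. A test point's kernel
vector $k_t$ is sparsely coded by solving the Lagrangian relaxation

$$\min_\gamma \tfrac12 \left\|S^\top k_t - S^\top K \gamma\right\|_2^2
  + \lambda \|\gamma\|_1,$$

$\lambda = 10^{-3}$. The strict equality constraint of sparse coding is
infeasible under noise, so the relaxation is the working form, as is
standard in sparse representation classification. The solver is monotone
FISTA: accelerated iterative shrinkage with step $1/L$ ($L$ the squared
spectral norm of $S^\top K$, precomputed at fit time) and a safeguard that
accepts only objective-decreasing iterates — so the objective trace is
non-increasing by construction; tolerance $10^{-8}$ on the iterate change,
cap $10^4$ iterations with a warning. Each class's residual keeps only its
own atoms' coefficients,

$$\mathrm{rs}_c = \left\|S^\top k_t - S^\top K\, \delta_c(\gamma)\right\|_2,
\qquad \delta_c(\gamma)_i = \gamma_i \,[y_i = c],$$

and the predicted label is $\arg\min_c \mathrm{rs}_c$; exact ties resolve to
the smallest class code with a message. Centering is applied inside KPCA
(standard) but the constraint itself uses the raw $K$.

With KPCA reduction the constraint lives in the centered subspace, so the
recovered code equals the ideal indicator only up to the discarded mean
direction; class residual *ordering* — the decision-relevant quantity — is
unaffected, and with a full-rank reduction the indicator is recovered
exactly (both are tested).

## Synthetic data

Real five-class PCG corpora cannot be bundled, so the generator synthesizes
the phenomenology the classifier must exploit:

* S1 and S2 as Gaussian-enveloped tone bursts (centres drawn from 70–110 Hz
  and 100–150 Hz, widths 18/13 ms, amplitudes 1/0.8) at the cardiac-cycle
  cadence, systole fixed at 37% of the cycle;
* class murmurs as enveloped band-limited Gaussian noise: AS systolic
  crescendo–decrescendo 100–600 Hz, loud (0.75); MR holosystolic
  100–500 Hz (0.45); MVP mid-to-late systolic 150–500 Hz (0.45); MS
  diastolic decrescendo 50–300 Hz (0.45); normal none;
* white noise at a configurable SNR (default 25 dB).

Datasets jitter heart rate (±10 bpm), murmur gain (±20%) and duration
(±15%) per recording so class manifolds have width. Generation is a pure
function of the configuration and seed, and never touches the caller's RNG
stream.

What the generator does *not* emulate: respiratory modulation, sensor and
chest-wall transfer functions, split S2, ejection clicks and opening snaps,
variable murmur pitch within a beat, pediatric/adult differences, or
recording artifacts. Passing the end-to-end test therefore shows the
pipeline recovers class structure from band/timing signatures under noise —
it does not certify clinical performance on real auscultation data, which
must be established on real corpora.

## Evaluation

Hold-out evaluation uses stratified 60/10/30 train/validation/test splits
over repeated random trials (stratification is this package's choice: with
balanced classes it stabilizes small-sample metrics); the validation
portion is reserved for hyperparameter tuning and otherwise untouched.
Stratified k-fold (default 10) is also provided. Metrics are one-vs-rest
per class — precision, sensitivity, specificity, F-score, in percent — plus
overall accuracy; 0/0 ratios report 0 with an `undefined` flag. Every
report carries its confusion matrix, and the metrics are recomputed from it
in the tests.

The packaged end-to-end check runs 40 recordings per class at 25 dB SNR
(2.5 s nominal duration) through a single 60/10/30 hold-out and expects at
least 90% test accuracy, then repeats at 5 dB to confirm accuracy degrades
with noise. Problem sizes here (200 recordings, ~2.5 s each) are desk-scale
choices that keep the full suite quick while leaving the test-set size
(60 recordings) large enough for a meaningful accuracy estimate.

## Numerical notes and limitations

* The resampler uses polyphase rational-ratio resampling; durations are
  preserved within one sample.
* Variable-length recordings are handled natively — the transform hops over
  whatever length is present and the features are length-robust (sums and
  entropies over however many time bins exist). Recordings shorter than
  four analysis frames are rejected.
* All randomness (generator, ELM weights, random projection, splits) is
  seeded; training twice with the same seed yields identical models.
* The whole pipeline is plain R on top of `signal` (filtering, resampling)
  and base linear algebra; a recording of a few seconds featurizes in
  roughly a second on one core.
* The upsampling refusal means recordings sampled below 4 kHz are rejected
  rather than interpolated.
* Hyperparameter tuning (ELM ridge, λ, kernel bandwidth) is deliberately
  off by default so results are reproducible without a search; the
  validation split exists for users who want it.
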