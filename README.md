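# dlksrn

Detection of heart valve ailments from phonocardiogram (PCG) recordings.

Valve disease — mitral valve prolapse (MVP), aortic stenosis (AS), mitral
regurgitation (MR), mitral stenosis (MS) — changes what a stethoscope
hears: the S1/S2 valve-closure sounds are altered and turbulent flow adds
systolic or diastolic murmurs. `dlksrn` classifies a whole multi-cycle PCG
recording into one of the five classes (normal + four ailments), for
researchers and engineers building automated auscultation tools. It is
aimed at offline analysis of WAV recordings; a synthetic five-class PCG
generator makes every stage testable without clinical data.

## Method

The pipeline, end to end:

1. **Preprocess** — resample to 4 kHz, 25–900 Hz zero-phase Butterworth
   bandpass, amplitude normalization
   x(n) ← x(n) / max|x(·)| (every recording peaks at 1).
2. **Spline-kernel Chirplet transform (SCT)** — the instantaneous-frequency
   law of the signal is estimated from the spectrogram ridge and fitted as a
   piecewise polynomial (order L = 3, I = 10 pieces). At each analysis time
   ñ in piece i the signal is demodulated by the frequency-rotate operator
   Ψᴿ(n) = exp(−j2π[Σₗ qₗⁱ(n−nᵢ)ˡ + γᵢ]) and the frequency-shift operator
   Ψˢ(n,ñ) = exp(+j2π[Σₗ l·qₗⁱ(ñ−nᵢ)ˡ⁻¹]n), then Gaussian-windowed and
   Fourier transformed. With a zero kernel this is exactly the Gaussian
   STFT; with a fitted kernel the ridges of frequency-modulated components
   (murmurs) sharpen.
3. **Features** — for each of the first 400 frequency atoms (DFT bins,
   2.5–1000 Hz): L1-norm LNᵏ = Σ_ñ |T(ñ,k)|, sample entropy (m = 2,
   r = 0.2·SD), normalized permutation entropy (order 3). Blockwise
   concatenation gives a 1200-dimensional vector per recording, min–max
   scaled on the training set.
4. **Deep layer kernel sparse representation network (DLKSRN)** — two
   extreme-learning-machine autoencoders with closed-form ridge weights
   W = (HᵀH + I/γ)⁻¹HᵀZ reduce 1200 → 800 → 600
   (Z\* = f(f(ZW₁ᵀ)W₂ᵀ)); a kernel sparse representation classifier (RBF
   kernel, KPCA pseudotransformation S) codes each test point over the
   training atoms by min_γ ½‖Sᵀk_t − SᵀKγ‖² + λ‖γ‖₁ and predicts the class
   with the smallest class-restricted residual
   rs_c = ‖Sᵀk_t − SᵀK δ_c(γ)‖₂.

See `vignettes/methods.Rmd` for assumptions, parameter rationale and
limitations.

## Worked example

```r
library(dlksrn)

# 40 synthetic recordings (8 per class) at 25 dB SNR, deterministic
recs  <- generate_dataset(8, synth_config(snr_db = 25, seed = 42))
feats <- pcg_feature_matrix(recs)      # 40 x 1200 feature matrix

res <- holdout_evaluate(recs, n_trials = 1, seed = 3, features = feats)
print(res$reports[[1]])
#> <eval_report> hold-out 0.6/0.1/0.3 trial 1 (seed 4): OA 90.00%
#>   precision sensitivity specificity f_score
#> 1    100.00         100       100.0  100.00
#> 2    100.00          50       100.0   66.67
#> 3    100.00         100       100.0  100.00
#> 4     66.67         100        87.5   80.00
#> 5    100.00         100       100.0  100.00

model <- dlksrn_train(recs, features = feats)
p <- dlksrn_predict(model, recs[[3]])
cat("predicted:", p$class, " residuals:", round(p$residuals, 3), "\n")
#> predicted: AS  residuals: 0.698 0.698 0.001 0.698 0.698
```

Rows 1–5 of the report are the classes N, MVP, AS, MR, MS; with only
8 recordings per class (2–3 in the held-out test set) single mistakes move
per-class metrics in large steps — here one MVP test recording was taken
for MR, everything else is correct (OA 90%). The prediction's five
residuals are the class-restricted reconstruction errors; the tiny value at
class 3 (AS) is what decides the label.

A command-line interface wrapping the same functions is installed at
`inst/cli/pcg-dlksrn` (subcommands `synth`, `featurize`, `train`,
`predict`, `evaluate`).

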