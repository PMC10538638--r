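# ctenvr

Cortical tracking of the speech envelope (CTenv) from continuous EEG, for
researchers studying speech processing in clinical populations such as
post-stroke aphasia. The package implements the full analysis chain —
EEG preprocessing, stimulus-envelope extraction, forward temporal response
function (TRF) estimation, a permutation null, and a Bayesian association
layer — together with a synthetic-data generator with known ground truth,
so every stage can be validated end to end without access to patient
recordings.

## The model

The forward TRF treats each EEG channel as a lagged linear convolution of
the stimulus amplitude envelope *s(t)*:

```
y_c(t) = sum_tau  w_c(tau) * s(t - tau) + e_c(t),      tau in [-100, 650] ms
```

The kernel `w_c` is estimated by ridge regression on a time-lagged design
matrix, `w = (X'X + lambda * m * I)^{-1} X'y`, where `m` is the mean
eigenvalue of `X'X` (making the `lambda = 2^0 ... 2^20` grid scale-free).
`lambda` is chosen by leave-one-segment-out cross-validation over the
~1-minute speech segments; the CTenv estimate for a channel is the Pearson
correlation between the cross-validated prediction and the observed EEG,
and the participant-level metric averages the five best electrodes (a
lesion-robust alternative to a fixed electrode choice). CTenv is computed
per frequency band — delta (0.75–4 Hz, word/phrase scale), theta (4–8 Hz,
syllable scale), alpha (8–15 Hz, attention-related) — and validated against
a null distribution obtained by deliberately mispairing EEG segments with
non-matching envelopes (derangements, re-running the whole estimation
path). The association layer then links band-wise CTenv to clinical
scores: a robust Student-t Bayesian comparison of observed vs null CTenv,
Gaussian linear models of aphasia severity (WAB-AQ) and rhythm scores on
band-wise CTenv, and hierarchical binomial-logit models of trial-level
treatment response (session x CTenv fixed effects; participant and item
random effects), summarized by posterior means, 90% credible intervals and
posterior tail fractions.

## Worked example

Simulate one participant (9 x 60 s of speech at 128 Hz, EEG at 0 dB SNR
generated from a known kernel), estimate the TRF, and compare the observed
CTenv against the mismatched-pairing null:

```r
library(ctenvr)

env    <- generate_modulated_envelope(duration = 540, rate = 128, seed = 1)
kernel <- generate_trf_kernel(standard_montage(), rate = 128, seed = 1)
eeg    <- synthesize_eeg(env, kernel, snr_db = 0, seed = 42)

idx <- function(i) ((i - 1) * 60 * 128 + 1):(i * 60 * 128)
stim_segs <- lapply(1:9, function(i) speech_envelope(env$samples[idx(i)], 128))
eeg_segs  <- lapply(1:9, function(i) eeg$data[, idx(i)])

fit <- estimate_trf(stim_segs, eeg_segs)
fit$ctenv
#> <ctenv_estimate> top-5 mean r = 0.4672 (channels: P7, Fp1, O1, P3, T8)

nd <- null_distribution(stim_segs, eeg_segs, n_perm = 100, seed = 7,
                        refit_lambda = FALSE, lambda = fit$lambda_best)
nd
#> <null_distribution> 100 permutations; mean = 0.0109, central 95% = [-0.0023, 0.0254]

cmp <- robust_compare(fit$per_electrode_r, nd$values, seed = 1)
cmp$summaries[1, c("coefficient", "mean", "ci_low", "ci_high", "tail_below_zero")]
#>   coefficient      mean    ci_low   ci_high tail_below_zero
#> 1   mean_diff 0.4463842 0.4432299 0.4494417               0
```

The top-5 CTenv of 0.47 far exceeds the null band (|r| < 0.03), and the
robust comparison localizes the observed-minus-null difference at 0.45
with a 90% credible interval excluding zero — the signature of genuine
envelope tracking. `run_pipeline(pipeline_config(...))` chains all stages
(including preprocessing and the association models) and writes CSV result
tables plus a provenance manifest; `inst/cli/ctenv.R` exposes the same
runs from a shell.

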