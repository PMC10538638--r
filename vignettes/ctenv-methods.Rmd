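---
title: "Estimating cortical tracking of the speech envelope: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cortical tracking of the speech envelope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctenvr)
```

## The estimation problem

When a listener attends to continuous speech, low-frequency cortical
activity follows the slow amplitude modulations of the acoustic signal —
the speech envelope, which carries syllabic and prosodic rhythm. `ctenvr`
quantifies this *cortical tracking of the envelope* (CTenv) with a forward
temporal response function (TRF): each EEG channel is modelled as a lagged
linear convolution of the envelope,

$$y_c(t) = \sum_{\tau} w_c(\tau)\, s(t-\tau) + \varepsilon_c(t),
\qquad \tau \in [-100, 650]\ \mathrm{ms},$$

and CTenv is the cross-validated Pearson correlation between the
EEG predicted by the fitted kernel and the observed EEG. The package is
aimed at small clinical cohorts (the motivating application is
post-stroke aphasia, where cortical lesions distort scalp fields), so two
design features run through everything: the participant-level CTenv metric
averages the five best electrodes instead of a fixed site, and every stage
can be exercised on synthetic data with known ground truth.

The linear-convolution assumption is standard for envelope tracking but it
is an approximation: it ignores adaptation, attentional gain changes over
minutes, and any nonlinear envelope coding. The permutation null below is
what protects the analysis against mistaking autocorrelated noise for
tracking.

## Ridge TRFs and cross-validation

The lagged design matrix holds the envelope shifted by every integer lag in
`round(lag_min * rate) : round(lag_max * rate)` (inclusive endpoints; at
128 Hz the −100…650 ms window gives 97 lags). The kernel solves the
penalized normal equations
$w = (X'X + \lambda m I)^{-1} X' y$ with $m$ the mean eigenvalue of
$X'X$. Normalizing by $m$ makes the penalty grid $\lambda = 2^0 \dots
2^{20}$ (integer exponents, 21 values) scale-free: the same grid is
sensible whether the envelope is in arbitrary units or z-scored.

$\lambda$ is selected by leave-one-segment-out cross-validation across the
~1-minute speech segments: for each candidate, TRFs are fitted on all but
one segment and used to predict the held-out one; the $\lambda$ maximizing
the mean held-out correlation over folds and channels wins. Per-electrode
correlations at the winning $\lambda$ are averaged across folds *before*
the top-5 selection, so the electrode choice reflects stable tracking
rather than one lucky fold. $\lambda$ is selected independently per
participant and per band, since each band is a separately filtered
dataset. Intercepts are handled by centering stimulus and response within
each segment, which also removes segment-level offset drift.

Degenerate predictions (zero variance, e.g. after an all-rejected
artifact window) yield `r = 0` with a warning rather than `NaN`, so
top-5 summaries never propagate missing values.

Implementation note: all segment-level fits reduce to cached
cross-products of per-segment centered designs, so the cross-validation
and the permutation null reuse one precomputation; a full 21-point
$\lambda$ search over nine folds costs a few eigendecompositions of a
97×97 matrix.

## The permutation null

The null distribution re-runs the *entire* estimation path after
deliberately mispairing EEG segments with non-matching envelopes. Pairings
are derangements (no segment keeps its own envelope), sampled without
replacement while distinct ones remain. By default $\lambda$ is
re-optimized inside every permutation — the conservative choice, since the
observed CTenv also benefited from the $\lambda$ search; a fixed-$\lambda$
fast mode (`refit_lambda = FALSE`) is available and is visibly
anticonservative in calibration runs, which is why it is not the default
for inference.

With a finite number of permutations, "does the observed value fall in the
null's central 95% band" is a rank question. `null_interval()` therefore
uses type-6 sample quantiles (plotting positions $k/(n+1)$): under
exchangeability an observed value falls inside the resulting interval with
probability 0.95 *exactly in expectation*, whereas the default type-7
quantiles give a visibly narrow band (~91% at 50 permutations).

## Preprocessing

The preprocessing chain mirrors a clinical recording setup: Fourier-domain
downsampling to 128 Hz (spectrum truncation at the new Nyquist — an ideal
anti-alias filter), linear-phase windowed-sinc FIR band-limiting with a
1 Hz high-pass (order 846) and 15 Hz low-pass (order 212), re-referencing
to the mastoid average, epoching −5…70 s around each segment onset, and
band extraction with third-order Butterworth filters: theta 4–8 Hz, alpha
8–15 Hz, and a 4 Hz low-pass for delta applied to data that came through a
0.75 Hz high-pass variant of the sinc filter (an effective 0.75–4 Hz
band). Two numerical choices deserve note:

* **Phase handling.** The sinc FIRs are applied causally and advanced by
  their group delay (they are linear-phase, so this is exact); the
  Butterworth band filters are applied forward-backward (zero-phase),
  because band-dependent group delay would systematically shift TRF
  latencies between bands. Forward-backward application doubles the
  effective order; the stated band edges are the design parameters.
* **Edges.** All filters reflect-pad by 2 s; the −5 s epoch pre-roll
  additionally buffers the analysis window from filter edges.

The alpha band follows the 8–15 Hz filter convention used in the
preprocessing it mirrors (some descriptive traditions say ~8–12 Hz); the
band limits are plain arguments if a user prefers otherwise.

Artifact handling is a deliberate simplification: subspace-reconstruction
and ICA cleaning are replaced by a transparent amplitude rule (any 1-s
window with |amplitude| above a threshold is zeroed and logged, with an
error in strict mode when more than half the data would go). This keeps
the pipeline self-contained and testable; it does not remove ocular or
muscular components the way ICA does, and results on real EEG should be
read with that in mind.

The evoked-average utility (for auditory long-latency responses used as a
recording-quality check) reports the most negative deflection in a
50–250 ms search window. Because that minimum is an extreme-value
selection over ~26 samples, comparing it against 2 baseline SDs would flag
pure noise as "reliable" most of the time; the implemented reliability
threshold is Bonferroni-corrected
(`qnorm(1 - 0.005 / n_search)` ≈ 3.5 SDs), which cleanly separates a
planted 100-ms component from noise in the test suite.

## Envelope extraction

`multiband_envelope()` follows the standard auditory-filterbank recipe:
8 band-pass channels spaced logarithmically from 80 Hz to 8 kHz (capped at
0.9 × Nyquist for low-rate audio), per-band analytic amplitude via the
Hilbert transform, unweighted averaging, a 32 Hz low-pass, and resampling
to the EEG rate. Band count and edges are configuration, not dogma — the
published analyses this mirrors say only "multiband" — and no amplitude
compression is applied by default (a power-law exponent is available).
CTenv's sensitivity to filterbank choices can be probed directly by
re-running `estimate_trf()` under different settings.

## The synthetic-data generator

The generator exists so that every downstream stage has ground truth:

* **Envelope.** Gaussian noise shaped in the frequency domain by a broad
  gamma-like profile peaking at 6.3 Hz — the syllable-rate
  modulation-spectrum peak of the read Spanish narrative the pipeline is
  calibrated for — plus a Gaussian peak component at the same frequency
  that pins the realized spectral maximum. Real speech modulation spectra
  are broadband with a syllabic peak; the broadband tails matter, because
  a narrowband envelope would make the TRF unidentifiable outside its
  band. Modulation depth 0.8 of the mean level, half-wave rectified.
* **Kernel.** A biphasic N1/P2-like shape (negative lobe at 100 ms,
  positive at 220 ms) with a smooth central-maximal scalp gradient and a
  seeded smooth perturbation; tapered so its support stays inside the lag
  window.
* **EEG.** Envelope convolved with the kernel plus 1/f noise, scaled to a
  requested SNR defined on 1–15 Hz band-limited variances (the analysis
  band; a broadband SNR would be dominated by irrelevant low-frequency
  noise power). `snr_db = Inf` and `-Inf` give the noiseless and
  signal-free extremes used in identifiability and calibration tests.
* **Cohort.** Nine-participant-style tables whose severity (WAB-AQ scale,
  0–100) is a linear function of the true band-wise CTenv values plus
  noise, clamped to the scale — the clamp can bias extreme scores
  slightly and is documented rather than corrected. Default coupling
  (+9 per SD of theta, −8 per SD of delta, 0 for alpha, residual SD 10)
  is *illustrative*: no published effect sizes link true CTenv to
  severity, so these defaults are chosen to be detectable but not
  dominant at cohort sizes of interest. Rhythm-perception and
  synchronization scores are generated analogously with zero default
  coupling.
* **Trials.** Binomial word-accuracy counts for 30 sentences × 5
  sessions per condition with logit-linear fixed effects (session
  centered at the treatment midpoint, so main effects read "at
  mid-treatment"), participant intercepts and session slopes, and item
  intercepts.

What the generator does **not** emulate: real lesion topographies and
volume conduction, ocular/muscular artifacts beyond amplitude spikes,
nonstationary attention, or speech-specific envelope structure (word
boundaries, prosodic phrasing). Passing tests therefore demonstrate that
the estimation machinery is correct and calibrated under the stated
generative model — not that any particular clinical effect exists.

## The Bayesian association layer

* `robust_compare()` is a two-group Student-t mean-difference model (the
  "robust Bayesian estimation" tradition): group locations and scales,
  a shared normality parameter with prior
  $\nu - 1 \sim \mathrm{Exponential}(1/29)$, locations
  $\mathcal N(\bar y, 1000\,s_y)$, scales log-uniform across six orders of
  magnitude around the pooled SD. It is sampled by a self-contained
  componentwise random-walk Metropolis sampler (4 chains, adaptive scales
  during warm-up, acceptance rates logged).
* `fit_bayes_lm()` regresses a per-participant score on standardized
  band-wise CTenv with priors $\mathcal N(0, (2.5\,s_y)^2)$ on slopes and
  a vague inverse-gamma on the residual variance. Because this model is
  conditionally conjugate, it is sampled by an *exact Gibbs sampler*
  rather than Metropolis — same posterior, strictly better mixing; the
  reported slopes are per SD of CTenv in that band.
* `fit_hierarchical_logistic()` fits the binomial-logit treatment model
  (session × CTenv fixed effects; participant intercept + session slope
  and item intercept random effects; separate fits per condition; CTenv
  standardized across participants, session centered at the treatment
  midpoint). Two routes are provided, selectable by `method`: the default
  obtains the fixed-effect mode and curvature by Laplace-approximated
  maximum marginal likelihood (via `lme4::glmer`) and draws from the
  Gaussian approximation — fast enough for calibration studies at
  hundreds of replicates; `method = "mcmc"` is a self-contained blockwise
  random-walk Metropolis over the joint posterior (fixed effects, all
  random effects, log random-effect SDs, half-Cauchy(1) priors on SDs,
  independent random-effect distributions). The two routes agree within
  posterior uncertainty in the test suite; the Laplace route ignores
  random-effect-variance uncertainty and is mildly anticonservative for
  between-participant effects, which is visible (and acceptable) in the
  calibration numbers below.
* "Reliable effect" language maps to a 90% credible interval excluding
  zero, and `posterior_tail_fraction()` reports the posterior mass below
  zero, the secondary summary used for borderline effects.

Complete separation (all trials fully correct or fully incorrect) is
rejected with an explicit error suggesting stronger priors, rather than
letting the optimizer diverge.

## Calibration results and problem sizes

The test suite validates, among other things: exact agreement of the ridge
solver with brute-force normal equations; median ground-truth kernel
recovery correlation above 0.9 from nine 60-s segments at 0 dB SNR (20
seeds); monotonicity of median top-5 CTenv in SNR over {−10, 0, +10, ∞}
dB; a 0.91–0.99 rate of the observed CTenv falling inside the null's
central 95% band under zero coupling (200 seeds, 50 permutations each);
and pooled frequentist coverage of the 90% credible intervals from the
linear and hierarchical models within 0.85–0.95 (100 cohort replicates at
n = 9; 50 trial-data replicates at 20 participants × 30 items × 5
sessions). Calibration runs use reduced sizes (64 Hz, 10-s segments, 4–6
channels) chosen so the whole suite completes in minutes on one CPU;
the statistical properties under test do not depend on these sizes.

One caveat worth stating precisely: for *any* calibrated posterior the
standardized error (posterior mean − truth)/posterior SD is approximately
standard normal, so its median absolute value is ~0.674 — a procedure
cannot simultaneously be calibrated and routinely put its posterior mean
within half a posterior SD of the truth. The hierarchical model's
measured median is ~0.6–0.8, consistent with a slightly anticonservative
Laplace approximation.

## Known limitations

* Artifact rejection is amplitude-only; no ICA/ASR equivalents.
* The EDF and WAV codecs are minimal (continuous 16-bit EDF, PCM16/float32
  WAV) — sufficient for round-tripping the package's own objects, not a
  general-purpose clinical reader.
* The permutation null permutes whole segments; within-segment temporal
  structure is preserved, which is the point, but very short segments
  would make the null coarse.
* The Laplace route's fixed-effect intervals slightly undercover for
  between-participant predictors in small cohorts; use `method = "mcmc"`
  when that matters more than runtime.
* Backward (decoding) models, multivariate stimulus features, and
  source-space analysis are out of scope.
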