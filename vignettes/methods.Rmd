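---
title: "Decomposing audiovisual speech entrainment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing audiovisual speech entrainment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avpid)
```

This vignette explains the estimators implemented in `avpid`, the synthetic
cohort they are validated against, and the numerical and design choices a
user should know about before trusting the numbers.

## The estimation problem

Syllable-rate (3–7 Hz) neural activity tracks both the auditory amplitude
envelope and the speaker's lip-area trace during natural audiovisual speech.
Because the two stimulus streams are themselves correlated, per-modality
coupling measures cannot say whether a neural signal represents the two
streams redundantly, uniquely, or synergistically. The package treats this
as a three-variable information problem: a target block M (neural phase) and
predictor blocks A and V (stimulus phases), each two-dimensional (the real
and imaginary unit-circle coordinates of the band-limited analytic signal).

### Gaussian-copula mutual information

`copula_normalise()` maps each margin through its empirical ranks to
standard-normal quantiles (`qnorm(r/(n+1))`, average ranks on ties). The
rank transform preserves the dependence structure while fixing the margins,
so the 6×6 covariance of the transformed blocks describes the full
Gaussian-copula dependence, and entropies take the Gaussian closed form.
`mi_gg()` computes `H(X)+H(Y)−H(X,Y)` from Cholesky log-determinants with a
digamma small-sample bias correction in every entropy term and 1/(n−1)
covariances. Properties to keep in mind:

* The estimate is a **lower bound** on the true MI: dependence that the
  Gaussian copula cannot express (e.g. purely second-order, product-style
  structure) is invisible to it.
* It is bit-exactly invariant to strictly monotone transforms of any input
  column, but only **approximately** invariant to transforms that mix
  columns. A constant phase rotation (a linear mix of the two unit-circle
  coordinates) changes the estimate by well under 0.01 bits at the
  dependence levels typical of stimulus–brain coupling (MI ≲ 0.2 bits), but
  by more near MI ≈ 0.7 bits; the test suite pins the practical regime.
* With bias correction, null estimates are centred near zero and may be
  slightly negative; they are reported as computed, never clipped.
  Downstream surrogate subtraction assumes exactly this behaviour.
* The correction assumes independent samples. Band-limited signals are
  serially correlated, so the null is not exactly zero but a small
  band-dependent floor (fewer effective samples in narrower bands). This is
  precisely what the time-shift surrogates estimate, and why all pipeline
  inferences are made relative to them.

### The decomposition

For bits `mi_a = I(M;A)`, `mi_v = I(M;V)`, `mi_av = I(M;[A,V])`, the
interaction information `mi_av − mi_a − mi_v` equals synergy minus
redundancy; separating the two requires a redundancy measure.
`iccs_redundancy()` implements the pointwise common change in surprisal: a
Monte-Carlo expectation of the local co-information

    c = i(m;a) + i(m;v) − ĩ(m;a,v)

in which the pairwise local terms use the fitted model's densities, while
the joint local term and the integration measure use a **maximum-entropy
surrogate** P̃ that preserves the (M,A) and (M,V) pairwise distributions but
maximises entropy otherwise. In the Gaussian family this surrogate has a
closed form — the model in which A and V are conditionally independent given
M (`Σ_AV ← Σ_AM Σ_MM⁻¹ Σ_MV`; the gradient of the log-determinant with
respect to the free cross block is the corresponding precision block, so the
stationary point is exactly the vanishing conditional dependence). The test
suite verifies the closed form against a numerical constrained
log-determinant maximiser. A sample contributes `c` only when `i(m;a)`,
`i(m;v)`, `ĩ(m;a,v)` and `c` all share one sign — configurations that
unambiguously witness a common change in surprisal — and zero otherwise.
All densities are evaluated in log space; the estimate carries a Monte-Carlo
standard error (`mc_se`).

Two readings of the sign condition's third term are possible (the local
joint information under the surrogate or under the empirical joint); the
package uses the surrogate reading for both the integrand and the sign
condition, consistent with the surrogate-based integration measure.

`pid_decompose()` then sets `uni_a = mi_a − red`, `uni_v = mi_v − red`,
`syn = mi_av − mi_a − mi_v + red`. These identities — and the equality of
`syn − red` with the interaction information — hold to machine precision by
construction; the acceptance suite audits them at 1e−12. All MI terms share
one bias-correction setting so the identities are exact rather than
approximate. Terms may legitimately be negative (the redundancy is not
guaranteed non-negative, and misinformation-like local contributions exist).

### A violated axiom, on purpose

Because P̃ fixes only the (M,A) and (M,V) blocks, the redundancy is
**invariant to the marginal A–V dependence** — the property that makes
values comparable across experimental conditions whose stimulus correlation
differs, and which the test suite asserts directly (perturbing only the A–V
cross block leaves `red` unchanged within Monte-Carlo error). The flip side
is that the measure cannot satisfy the self-redundancy (duplicate-predictor)
axiom for Gaussians: with V an exact copy of A, duplication differs from any
other A–V cross block only in the part of the model the measure is invariant
to, so `red` cannot equal `I(M;A)`. Analytically, under P̃ the local
co-information reduces to the local A–V information under the surrogate, so
for 1-D blocks with `corr(M,A) = corr(M,V) = 0.6` the redundancy is ≈ 0.18
bits while `I(M;A) ≈ 0.32` bits. The acceptance suite contains a test
asserting the idealised identity; it fails by design and documents this
property. Users who need axiom-satisfying redundancy (e.g. minimum-MI
style measures) should be aware of the difference.

## Signal preparation

* **Wideband envelope** (`wideband_envelope()`): 8 sub-bands spaced
  equidistantly on the Greenwood cochlear map between 100 Hz and 10 kHz
  (constants A = 165.4 Hz, a = 2.1, k = 0.88, overridable), fourth-order
  Butterworth band-pass applied forward and reverse, analytic amplitude per
  band, average, polyphase anti-aliased resampling to 250 Hz.
* **Band-pass analytic signal** (`bandpass_analytic()`): default band
  5 ± 2 Hz, zero-phase (forward–reverse) order-4 Butterworth, analytic
  signal by FFT construction of the one-sided spectrum.
* **Phase representation** (`phase_2d()`): the analytic signal normalised by
  its amplitude; zero-amplitude samples are flagged undefined and dropped
  pairwise rather than propagated.
* **Lag alignment** (`lag_align()`): pairs stimulus sample *t* with neural
  sample *t + lag* (positive lag = neural follows stimulus; default 100 ms,
  25 samples at 250 Hz), truncating the overhang.
* **Edge handling**: the first and last second of every filtered signal are
  excluded from estimation windows to avoid filter transients.

`spectral_mi_profile()` sweeps band centers (default 3–20 Hz, ±2 Hz) and
`delayed_mi()` scans lags 0–500 ms in 20 ms steps (26 points), reporting the
across-lag average alongside the profile.

## The synthetic cohort

`gen_cohort()` produces the study conditions the pipeline is validated
under: 44 subjects (configurable), 120 s of 250 Hz signal per subject, a
3–7 Hz shared stimulus band, a 100 ms stimulus-to-brain lag, five neural
nodes per subject (one per planted kind plus a null node), and a behavioral
score. Two minutes per subject keeps a full-cohort run on one core in the
minutes range while leaving ~30k samples per estimate; the study conditions
it emulates used recordings a few times longer.

**Stimuli.** Matched pairs mix a latent narrowband common drive (white noise
band-passed to 3–7 Hz; weight `av_coupling = 0.85` of the in-band variance)
with independent narrowband components and a broadband noise floor
(`stim_noise_sd = 1`), then shift to strict positivity by an affine offset
(magnitudes such as envelopes and areas are positive; rectification would
distort harmonically). The broadband floor is what keeps out-of-band phase
coherence at chance: narrowband filters pass the drive's spectral skirts,
and without an independent floor the phase-MI profile (which is blind to
amplitude attenuation) would not fall off outside the band. Nonmatched
pairs are fully independent realizations. The audio–lip lag of the common
drive is a parameter (`visual_lag_ms`, default 0).

**Nodes.** Drives are built from the band-limited stimulus signals, delayed
by the neural lag, scaled by a per-subject gamma-distributed gain (CV 0.2),
and summed with in-band plus broadband noise:

* *redundant* — couples to the **latent** common drive (gain 4.5). Coupling
  to the latent rather than to the measured sum bounds `I(M;A,V)` (the node
  is conditionally independent of the stimuli given the latent), which keeps
  the node's synergy estimate near zero and almost independent of the
  coupling gain — without this, every PID term of the node tracks the gain
  and no term dissociation is possible.
* *unique_a / unique_v* — a **partial residual** of one modality (70 % of
  the least-squares regression weight on the other; gain 1.5). A complete
  residual lies exactly in the span of the two measured signals, and for any
  drive orthogonal to V the ratio `R²(D|A)/R²(D|A,V)` equals `1 − c²` (c the
  A–V correlation), so at realistic coupling the joint "explaining-away"
  information swamps the unique term; the partial residual keeps the node
  essentially unimodal while the unique term stays dominant.
* *synergistic* — the standardised **difference** of the band-limited modal
  signals (gain 1). Because the two are positively correlated, the
  difference correlates only weakly with each alone yet is determined by the
  pair, reproducing the opposite-sign quadrant structure visible in the
  local information maps. A product-style interaction was considered and
  rejected: the product of two narrowband signals concentrates its energy at
  sum and difference frequencies (outside the analysis band) and is
  second-order, hence invisible to a Gaussian-copula estimator — a generator
  built on it would plant nothing the pipeline could recover.
* *null* — pure noise.

**Behavior.** `comprehension = clip(0.834 + 0.055·(g_red − ḡ_red) + ε, 0, 1)`
with `ε ~ N(0, 0.1)`. The intercept matches the mean comprehension accuracy
typical of the emulated paradigm; the slope places the across-subject
correlation between redundant coupling and comprehension near 0.45, the
scale of published entrainment–behavior correlations. Only the redundant
node's gain enters the score, so the redundancy–behavior link is planted
and the same node's synergy term is not — the dissociation the behavior
regression stage is designed to detect.

**Seeds.** One master seed; per-subject and per-component streams are
derived by a counter-based split, so the cohort is a pure function of the
configuration and any subject can be regenerated alone.

**What the generator does not emulate.** Linear Gaussian mixing only — no
articulatory or vocal-tract structure, no amplitude–phase coupling, no
cross-frequency structure, no volume conduction or sensor noise, no
non-stationarity. Passing tests demonstrate that the estimators recover
known planted structure under these idealised conditions; they do not
certify performance on real recordings, where serial correlation,
non-Gaussian margins and nonlinear mixing are stronger.

## Pipeline statistics

`run_pid_pipeline()` applies the band-pass → Hilbert → lag → phase → copula
→ PID chain per subject and node, and computes a surrogate twin against
circularly time-shifted stimuli (audio 60 s, visual 30 s; circular shifts
preserve length and spectra). Surrogate maps estimate the per-subject
analysis bias; `surrogate_normalise()` subtracts them. `classify_nodes()`
labels nodes by their largest normalised term (null nodes have no dominant
term by construction and are excluded from the accuracy summary).

`group_contrast()` uses paired t statistics with sign-flip permutation
p-values (group-label shuffling when unpaired; default 5000 permutations —
the choice is conventional, balancing p-value granularity against runtime),
two-sided tail-matched conversion to z, and BH/FDR masking.
`behavior_regression_z()` regresses each node × term value on the
behavioral score, obtains permutation p-values by score shuffling, converts
to signed z by two-sided tail matching (the plain quantile reading of a
"Z-transformation"), and thresholds the between-condition z-difference at
P < 0.005, the conventional map threshold. `behavior_correlation()` is
Pearson by default (Spearman behind a flag). Both permutation routines
accept an optional seed; with one, identical inputs give identical output
and the caller's RNG state is untouched.

Monte-Carlo defaults: `n_mc = 1e5` for a standalone `pid_decompose()` call
(mc_se ≈ 1e−3 bits); the examples and tests use 1e4–2e4 where only
orderings matter. Type-I calibration of both permutation procedures is
checked over 200 null cohorts against the binomial confidence interval at
α = 0.05.

## Known limitations

* The redundancy measure violates the self-redundancy axiom for Gaussians
  (see above) — the price of invariance to the stimulus correlation.
* GCMI is a lower bound; purely higher-order dependence is invisible.
* The analytic bias correction assumes independent samples; all inference
  on real, serially correlated signals must be surrogate-relative, as the
  pipeline does by default.
* Node-level analysis only: no source reconstruction, volumetric smoothing
  or spatial cluster statistics.
* The local information maps (`local_pid_map()`) use 1-D band-pass signals
  for interpretability, not the 2-D phase representation of the main
  analysis.
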