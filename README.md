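# avpid

Partial information decomposition (PID) of audiovisual speech entrainment.

During natural speech, low-frequency (3–7 Hz, syllable-rate) neural activity
tracks both the auditory amplitude envelope and the speaker's lip movements.
Because the two speech streams are correlated, showing that a brain signal
carries information about each of them separately says nothing about *how*
the two representations relate: is the information shared (redundant),
carried by one modality only (unique), or available only from observing both
streams together (synergistic)? `avpid` implements the information-theoretic
machinery to answer that question for continuous band-limited phase signals,
together with a synthetic-data generator that plants each kind of coupling
so the whole pipeline can be validated end to end.

The package is aimed at researchers analysing continuous stimulus–brain
coupling (MEG/EEG source time courses, intracranial recordings) who want to
go beyond per-modality entrainment measures.

## The model

For a target signal M (a neural node) and two predictors A (auditory
envelope) and V (lip area), each represented by the unit-circle phase of its
3–7 Hz analytic signal, the joint mutual information splits as

    I(M; A,V) = I_red + I_uni_A + I_uni_V + I_syn

with the interaction information `I(M;A,V) − I(M;A) − I(M;V) = I_syn −
I_red`. All mutual informations are estimated semi-parametrically by
Gaussian-copula MI (GCMI): each margin is rank-normalised to a standard
normal, the 6×6 covariance over the blocks (M, A, V) then fully describes the
copula dependence, and entropies take their Gaussian closed form (with a
digamma small-sample bias correction).

Redundancy is the pointwise common change in surprisal (Iccs): local
information terms `i(m;a)`, `i(m;v)` and the local joint term under a
maximum-entropy surrogate distribution P̃ — the Gaussian with the (M,A) and
(M,V) blocks of the fitted model but A and V conditionally independent given
M (closed form: Σ_AV ← Σ_AM Σ_MM⁻¹ Σ_MV) — are combined into the local
co-information `c = i(m;a) + i(m;v) − ĩ(m;a,v)`, and only samples in which
all four terms share a sign contribute. The expectation over P̃ is taken by
Monte-Carlo integration. Unique and synergistic terms follow from the PID
identities, which hold to machine precision by construction.

The surrounding pipeline reproduces the standard analysis chain:
cochlear-band wideband envelope extraction, zero-phase fourth-order
Butterworth band-pass filtering with Hilbert transform, a 100 ms
stimulus-to-brain lag compensation, time-shifted surrogate stimuli (60 s
audio / 30 s visual) for per-subject bias subtraction, sign-flip permutation
contrasts and score-shuffling behavior regressions with BH/FDR control, and
spectral and delayed-MI profiles.

## Worked example

```r
library(avpid)
library(dplyr)

cfg    <- synth_config(n_subjects = 6, duration = 120, rng_seed = 42)
cohort <- gen_cohort(cfg)

# frequency profile of phase MI between one matched stimulus pair
pair <- gen_stimulus_pair(cfg, matched = TRUE, rng_seed = 42)
prof <- spectral_mi_profile(pair$audio_env, pair$lip_area)
prof$frequency[which.max(prof$mi)]   # 3      <- peak inside the 3-7 Hz band
round(max(prof$mi), 3)               # 0.854  bits

# full PID pipeline with time-shift surrogate normalisation
maps <- run_pid_pipeline(cohort, n_mc = 2e4)
norm <- surrogate_normalise(maps)
norm |> filter(subject == 1, node == "redundant")
#>   node      term     main surrogate   value
#> 1 redundant red    0.634   0.00120   0.633
#> 2 redundant uni_a  0.530   0.00753   0.523
#> 3 redundant uni_v  0.536   0.00275   0.534
#> 4 redundant syn   -0.0926  0.000842 -0.0934

node_recovery_accuracy(norm)         # 0.958
```

The redundant node's decomposition reads: of the ~1.6 bits the two phase
streams jointly carry about this node, 0.63 bits are shared between the
modalities, ~0.5 bits are attributable to each stream uniquely, and the
synergy is at chance — exactly the planted structure. The surrogate column
shows the chance level estimated from time-shifted stimuli (~0.001 bits).
`classify_nodes()` labels each node by its dominant normalised term;
23 of the 24 planted nodes in this small cohort are recovered.

Result tibbles have `tidy()`/`glance()` methods and `autoplot()` figures
(MI profiles, PID bars, cohort maps, local probability-weighted information
maps).

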