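---
title: "Rule-dependent population states: models, simulator, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-dependent population states: models, simulator, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

In a cross-modal sensory selection task, a head-fixed mouse alternates
between two stimulus–response rules in blocks of roughly 60 trials: under
the *respond-to-touch* rule it licks the right port after a tactile
(whisker) stimulus and withholds to a visual flash; under
*respond-to-light* it licks the left port after the flash and withholds to
touch. No cue marks a block switch except a water drop delivered at the
9th trial of every block, so the animal must discover rule changes through
reward feedback. The scientific question is how cortical populations along
the whisker-to-lick pathway (S1, S2, the medial and anterolateral motor
areas MM and ALM) carry and apply the current rule — in particular whether
the *pre-stimulus* population state is configured per rule and shapes the
subsequent sensorimotor transformation.

`xmodal` implements the full analysis chain for this question — behavioral
scoring, single-unit ideal-observer discriminability, population decoding,
population geometry, rule-transition tracking, and hierarchical-bootstrap
inference — together with a synthetic task-and-spiking generator that
stands in for the recorded dataset. Every analysis runs end-to-end on
simulated sessions, and the generator's ground truth (which units are
rule-modulated, when the latent rule switched) lets the analyses be tested
as parameter-recovery problems.

# The task generator

`generate_schedule()` draws block lengths uniformly on 54–66 trials
(mean 60), alternates the two rules from a random start, interleaves
tactile and visual stimuli with at most 4 consecutive same-modality trials
(a rejection-free sequential draw: when the last 4 trials share a
modality, the other is forced), and separates trials by a 3.5 s fixed
interval plus an exponential with mean 4 s. The cue flag is set at
trial 9 of each block. These numbers are the task's stated design and are
the generator's defaults; the acceptance suite verifies them
distributionally.

`simulate_agent()` is a stand-in for behavior the source experiments did
not parameterize: the animal's actual trial-and-error switching policy is
unknown, so the agent is an explicitly flagged model. It holds a latent
rule; licks its rule's port with probability `p_hit = 0.75` after a
stimulus its rule deems relevant and `p_fa = 0.25` after an irrelevant
one (steady-state percent correct is then
$100 \cdot (0.5 \cdot 0.75 + 0.5 \cdot 0.75) = 75\%$, matching the
reported ~75% for both rules). After a block switch it keeps applying the
old rule until its first unrewarded lick — the first informative
feedback — then adopts the new rule with per-trial probability 0.5, and
always at the cue trial. A quarter of trials carry a spontaneous lick in
the second before stimulus onset, matching the ~25% of trials the
pre-stimulus lick filter removes. The latent rule and per-block adoption
trial are recorded so that spiking, decoding, and transition analyses
share one ground truth.

`simulate_spikes()` generates inhomogeneous-Poisson spike trains as a sum
of independent Poisson components (exact for Poisson processes):

* a **baseline** drawn per unit from a log-normal
  (`meanlog = log(8)`, `sdlog = 0.7` spikes/s), multiplied by
  `rule_gain = 2` whenever the *latent* rule matches the unit's preferred
  rule, for a fraction `frac_rule_mod` of units (half prefer each rule).
  Because the gain follows the latent rule, pre-stimulus states track the
  agent's behavioral transitions rather than the nominal block boundary;
* an **evoked transient** — a half-sine bump over the 150 ms stimulus —
  for modality-responsive units, with per-unit amplitudes drawn around
  `evoked_amp = 20` spikes/s, scaled by `relevance_gain = 1.5` when the
  stimulus is relevant under the latent rule. A `rule_rotation` parameter
  in [0, 1] is the fraction of responsive units that express an
  independent amplitude in the irrelevant context, rotating the
  population evoked subspace between rules by recruiting a partly
  different set of units (one of the mechanisms the source work proposes
  for its subspace differences); pattern correlation falls linearly in
  the parameter, which makes recovery sweeps over it well conditioned. A
  continuous mixing formulation was tried first and rejected: near the
  aligned end its pattern correlation is almost flat
  (`cor ≈ (1-θ)/√((1-θ)²+θ²)`), so low grid levels were
  indistinguishable in principle, not merely underpowered. Default 0.5;
* a **choice ramp** from 100 ms before the first answer lick to the lick,
  peak `choice_amp = 10` spikes/s, on lick trials for a 30% subset of
  units.

Area profiles set `frac_rule_mod` to the reported per-area fractions of
pre-stimulus rule-discriminating units (S1 4.5%, S2 2.5%, MM 21.4%,
ALM 10.2%). The rate-model *form* (kernels, gains) is invented plumbing —
the source work reports none — and its parameters were fixed once, before
any acceptance measurement, at values giving single-unit AUC spreads
comparable to the recorded distributions. A 2 ms absolute refractory
period is imposed because the unit-quality filter (correctly) rejects
trains whose inter-spike-interval statistics are un-neuronal: a pure
Poisson train at 10 Hz violates the 0.5% ISI criterion by an order of
magnitude.

**What the generator does not emulate:** cross-unit noise correlations
beyond those induced by shared latent-state and stimulus terms, slow
drifts in excitability, bursting and other non-Poisson ISI structure,
whisker kinematics, and learning across sessions. A green test therefore
establishes that the analysis code measures what it claims on a world
with the stated first-order structure — not that the biological
conclusions reproduce.

# Preprocessing

Rates are computed in half-open bins `[t, t + Δ)` (10 ms for evoked
analyses, smoothed with a 50 ms-σ Gaussian; one unsmoothed 100 ms bin for
pre-stimulus analyses). The smoothing kernel is truncated at ±3σ and each
input bin's mass is renormalized over in-range output bins, so smoothing
conserves every trace's total count and time mean exactly — the
spike-count-conservation invariant the tests assert. Smoothing is applied
per trial before any averaging (the source is silent; per-trial smoothing
commutes with trial averaging for linear summaries).

Soft normalization is per unit: `(rate − mean) / (range + 5)`, with mean
and range taken over all trials and bins entering the specific analysis
and stored so the transform inverts exactly. The +5 spikes/s floor keeps
low-rate units from dominating after normalization and bounds outputs
inside (−1, 1).

Unit QC follows the published thresholds: ISI violations (< 1.5 ms)
≤ 0.5%, presence ratio ≥ 90% (computed over ten equal session segments —
the cited metric's segmentation is unspecified), and supplied L-ratio
≤ 0.1 and cumulative drift ≤ 40 µm as pass-throughs. Trials with licks in
the second before stimulus onset are removed before any pre-stimulus
analysis; censor-window licks censor the trial entirely.

# Analysis choices worth knowing about

**AUC and significance.** Discriminability is the Mann–Whitney AUC
(ties at half weight), with stratified bootstrap percentile CIs.
Bonferroni correction spans bins × units for windowed analyses and units
for single-bin analyses — the published rule corrects "across neurons";
including bins for the three-consecutive-bins rule is the conservative
reading. Percentile (not BCa) intervals are a convention, as is the
add-one permutation p-value `(1 + #{null ≥ obs}) / (n + 1)`, which can
never be zero.

**Decoding.** Features are one window-mean value per unit from
soft-normalized rates; correct trials only; stratified 10-fold CV. LDA
uses a pooled covariance shrunk toward its diagonal with
`λ = min(0.9, max(0.1, p/n))` for small-sample stability. The SVM is a
linear Pegasos implementation and the random forest a bagged CART
ensemble (500 trees, `mtry = √p`) because no reference implementations of
either are available in the target environment; both are exercised by the
same contracts as LDA. The shuffle control permutes trial labels and
reruns the *identical* CV, repeated 100× and averaged. Note that with an
odd number of blocks the two rule classes are imbalanced and the shuffled
accuracy sits slightly above 0.5 (the classifier learns the prior) — the
recorded data's shuffled medians of 0.50–0.55 show the same effect, and
the null-calibration tests therefore use an even block count.

**Transition tracking.** The transition period runs from the first trial
after a block switch through the block's first hit; the first false alarm
closes the "early" part (feedback arrives with that trial's outcome, so
behavior before the next trial is uninformed — this resolves the
ambiguous "separated by"). An LDA trained on 90% of correct
non-transition trials classifies four ordered periods (held-out
pre-switch, early, late, held-out post-first-hit); transition trials
never enter training. The four-period scheme is a declared convention —
the source figure does not enumerate its periods. Kendall's τ (tau-b,
tie-corrected, computed by pair enumeration) summarizes the trend, with a
session-level bootstrap CI; all-tied inputs return τ = 0 with a flag.

**Geometry.** Trajectory PCA treats time points of the trial-averaged
condition trajectories as observations and units as variables, centered
by the fitted data's column means; the same center is reused for
projections. Subspace overlap is the ratio of a dataset's variance
captured by the reference (held-out tactile-hit) top-3 basis to the
variance captured by its own top-3 basis. Variance is computed about each
dataset's *own* time mean in both numerator and denominator: centering
instead on the projected reference center would let a mere mean offset
masquerade as misaligned dynamics, while with own-mean centering
self-overlap is exactly 1 and the measure responds only to subspace
orientation. The reference/control split is a single seeded 50/50 split
per session; sessions under 10 units are excluded (overlap is biased up
at low dimensionality). Coding dimensions follow the published recipes
(equal-weight averages of the modality × response sub-condition means;
misses and correct rejections count as the "no-lick" choice), normalized
to unit length; an empty sub-condition is dropped from its side's average
with a flag, and a zero difference returns a degenerate marker rather
than a vector.

**Hierarchical bootstrap.** Resampling with replacement proceeds
top-down through the declared hierarchy (e.g. mice → sessions → rows),
preserving group sizes at the lowest level, with percentile 95%
intervals. On positively correlated data these intervals are wider than a
pooled bootstrap's — asserted as an invariant. Percentile intervals only
reach nominal coverage with a moderate number of top-level groups:
calibration simulations here use 40 groups (94–95% empirical coverage);
with ~10 groups coverage drops to ~90%, a known small-sample property of
the method, not a bug — a limitation to keep in mind when a dataset has
few mice.

**Permutation floor.** In the top-vs-bottom-half distance test, a random
relabeling occasionally re-draws the observed split, so the smallest
attainable p is slightly above `1/(n_perm + 1)` — the calibration tests
assert a floor consistent with that resolution.

# Degenerate inputs and numerical conventions

Empty condition cells return explicit missing markers, never silent
zeros. Constant units soft-normalize to zero (denominator 5). A single
class makes decoding undefined (`NA`), and fewer trials than folds
reduces the fold count with a warning. Negative kernel amplitudes are
clipped at zero with a warning. All stochastic entry points accept a
seed; a session-level master seed is split into independent per-stage
streams (`derive_seed`), so identical seeds give bit-identical trial
tables and spike sets.

# NWB ingestion

The deposited recordings are NWB/HDF5 files; this build is offline and no
HDF5 reader is available, so ingestion is implemented against an
"NWB-like" plain container (a trials table and a units table with spike
times, JSON-serializable) with a column-alias map and descriptive
ingestion errors. The round trip is exact on synthetic sessions; true
HDF5-NWB support would slot in behind the same `read_nwb_session()`
interface.

# Known limitations

* The agent's switching policy is a geometric-adoption stand-in; real
  mice show richer trial-and-error dynamics.
* The Poisson rate model has no noise correlations or non-stationarity
  beyond the latent rule, so decoding accuracies on synthetic data are
  optimistic relative to recordings at matched unit counts.
* Headline numbers from the recorded dataset (e.g. per-area decoding
  medians, overlap deltas) are not reproducible without the data deposit;
  the acceptance suite therefore checks task-design statistics, printed
  identities, estimator calibration, and parameter recovery instead.
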