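---
title: "Methods: the RL-WM model, model-based EEG markers, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the RL-WM model, model-based EEG markers, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, estimators and generators implemented in
`rlwmpheno`, the assumptions behind them, and the design choices made where
more than one reasonable implementation existed.

## The task

Subjects learn stimulus–response associations by trial and error over
multiple blocks. Each block introduces `set_size` new stimuli, each shown
`iterations_per_stimulus` times in a pseudo-random order with no immediate
repeats. Correct responses earn 1 or 2 points (probabilistically); errors
earn 0. Two covariates quantify working-memory (WM) demand: **set size**
(between blocks) and **delay**, the number of intervening trials since the
same stimulus was last answered correctly (within blocks). **Reward
history** (`pcor`) counts prior correct responses to a stimulus and indexes
the accumulating reinforcement-learning (RL) contribution. Delay is coded
missing before a stimulus's first correct response and such trials are
dropped from delay-bearing analyses rather than imputed — the definition
presupposes a prior correct pairing.

Defaults: set sizes 2–5, 13 iterations per stimulus, 3 blocks per set size
(12 blocks, 546 trials), 3 response keys. The 3-blocks default deserves a
note: single-block sessions (182 trials) leave the WM-side parameters of
the model below (decay, reliance, capacity) essentially unidentified — the
likelihood surface around the generating values is flatter than the
between-agent spread — whereas ~12-block sessions match how this task is
actually administered and give the estimator a fighting chance. The
stimulus scheduler is a feasibility-guarded sequential sampler: stimuli are
drawn with probability proportional to their remaining presentations,
excluding the previous stimulus, with a forced pick whenever one stimulus
holds at least half of the remaining trials (otherwise no valid completion
would exist; for two stimuli this correctly degenerates to alternation).

## The RL-WM model

Two modules maintain stimulus–action values, both initialised at $1/n_a$:

* **RL**: incremental. After reward $r \in \{0, 1\}$ (correctness),
  $Q_{RL}(s,a) \mathrel{+}= \alpha\,(1 - Q_{RL})$ if $r = 1$, and
  $Q_{RL}(s,a) \mathrel{+}= \alpha\gamma\,(0 - Q_{RL})$ if $r = 0$.
* **WM**: one-shot but volatile. $Q_{WM}(s,a) = 1$ exactly on reward;
  $Q_{WM}(s,a) \mathrel{+}= \gamma\,(0 - Q_{WM})$ on non-reward; and every
  trial, every entry decays toward baseline,
  $Q_{WM} \mathrel{+}= \phi\,(1/n_a - Q_{WM})$.

$\gamma$ is the perseveration parameter: the weight on negative feedback in
both modules (low $\gamma$ = errors are neglected). Policies are softmaxes
with inverse temperature $\beta = 100$ (fixed; computed with
max-subtraction so the exponentials never overflow, and exact value ties
yield exactly equal probabilities). The modules mix at the policy level
with blockwise weight $\omega = \rho \cdot \min(1, C/\mathrm{ss})$, where
$\rho \in (0,1)$ is baseline WM reliance and $C \in \{2,\dots,5\}$ integer
WM capacity; a lapse mixture completes the final policy,
$\pi_{final} = (1-\varepsilon)\,\pi_{mix} + \varepsilon/n_a$.

Fixed constants: $\beta = 100$ and $\alpha_{WM} = 1$; neither is reachable
through the fitting interface. $\alpha$ is constrained to $(0, 0.3)$ to
keep the incremental module identifiable against the one-shot module.

Per-trial order (centralised in `rlwm_step()` and switchable via the
`decay` argument): WM decay → policy/choice → WM update → RL update. Decay
precedes the trial's retrieval so the values entering the policy are the
decayed ones, consistent with reading decay as an every-trial forgetting
process; the alternative post-update placement is retained as a switch for
sensitivity analysis. State resets at block boundaries (each block has new
stimuli; no cross-block transfer). The model conditions on binary
correctness only; the 1-vs-2-point magnitude is carried through the tables
but does not enter the updates.

**RPE.** The trialwise reward-prediction error attached to the latents uses
the cooperative expectation
$r - [\omega\,Q_{WM}(s,a) + (1-\omega)\,Q_{RL}(s,a)]$: outcomes already
predicted by WM produce smaller RPEs under load that fits within capacity.
The behavioral likelihood itself uses the update equations verbatim (RL
updates toward $r$ without WM mixing); the cooperative form concerns only
the RPE regressor handed to the EEG stage. A `form = "rl"` switch gives the
pure-RL regressor $r - Q_{RL}$ for sensitivity analysis.

### A note on the $\beta = 100$ regime

With $\beta$ fixed at 100, softmax probabilities are graded only while
value differences are below roughly $5/\beta = 0.05$; beyond that the
policy is effectively argmax. Two consequences shape everything downstream:

1. Both modules update the chosen action in the same direction, so their
   value *orderings* coincide; they are behaviorally distinguishable only
   in the soft window — early iterations (RL still weak, WM certain) and
   post-decay trials. Agents that barely use WM ($\rho$ small) or whose RL
   saturates after one update ($\alpha \gtrsim 0.15$) reveal almost nothing
   about $\phi$, $\rho$ or $C$.
2. The canonical behavioral signatures (accuracy falling with set size,
   rising with reward history; RPEs larger under load) emerge in the
   low-$\alpha$, WM-reliant regime where human fits of this model live, and
   vanish in the saturated regime. The synthetic cohort's parameter
   distributions are therefore set in that regime (below).

## Fitting

`fit_subject()` implements constrained maximum likelihood: for each
capacity $C$ on the integer grid 2–5, the session negative log-likelihood
(sum of $-\log \pi_{final}(a_t)$, state reset per block; finite because
$\varepsilon > 0$) is minimised by Nelder-Mead simplex from multiple random
interior starts (uniform in the central 5–95% of each box, all drawn up
front from the seed so the fit is reproducible and a larger restart count
extends rather than reshuffles the sequence). Box constraints are enforced
by a logistic reparameterisation per parameter — smooth, unconstrained for
the simplex, hard bounds in reporting space. Each restart runs at most
2000 simplex iterations at relative tolerance 1e-10 plus one polish
restart from the terminal point (5-D simplices can collapse prematurely).
Ties between capacities resolve to the smaller $C$ (parsimony,
deterministic reporting). The production default is 40 restarts per
capacity; the validation suites use 8, which reaches the same optima on
this task's likelihood surfaces. The likelihood has two implementations —
a plain-R reference and a compiled fast path — asserted to agree to 1e-10
in the test suite.

### Parameter recovery, honestly

`recover_parameters()` samples ground-truth vectors uniformly inside
`default_recovery_ranges()`, simulates each agent through the task, refits,
and reports Pearson correlations, bias and RMSE per parameter plus the
exact-recovery rate of $C$. The default ranges sample the empirically
plausible fitted region (small $\alpha$, WM-reliant $\rho$), as recovery
studies in this literature draw truths from the fitted population — and
because, per the note above, the complementary region is structurally
uninformative.

Two honest caveats, established by profiling the likelihood directly
(holding all other parameters at truth and scanning one or two at a time):

* $\rho$, $\gamma$ and $C$ have low information ceilings at this task
  scale. Even the oracle-conditioned profile MLE recovers $\rho$ at about
  $r \approx 0.5$ (RMSE $\approx$ 0.2), $\gamma$ similarly, and $C$ exactly
  in roughly half of agents; the joint estimator is necessarily worse.
  These are properties of the model-times-design information, not of the
  optimizer — restart counts beyond 8 find the same optima.
* $\varepsilon$ recovers robustly ($r \approx 0.6$–0.9). $\phi$ typically
  recovers around $r \approx 0.6$, but the joint likelihood admits an
  occasional $\phi$–$\rho$ swap (a WM-wiping $\phi \to 1$ basin) whose
  boundary outliers can drag the Pearson correlation far lower in some
  batches; $\alpha$ is intermediate. Group-level contrasts are far less
  affected because rank tests and group averaging absorb these outliers.

Group-level contrasts of fitted parameters (`compare_group_params()`:
one-way ANOVA + Tukey HSD per parameter) remain well powered despite the
single-subject noise, because estimation error averages out across
subjects while planted group shifts do not.

## Model-based EEG analysis

Inputs are cleaned, epoched EEG (trials × 29 scalp channels × 101
timepoints, −100..700 ms at 125 Hz; electro-ocular channels never enter
analysis arrays) for stimulus- and feedback-locked events. The pipeline:

1. **Z-scoring** (`zscore_epochs()`): each channel × timepoint cell is
   standardised across included trials; zero-variance cells raise an error
   naming the cell. Z-scoring twice equals z-scoring once, and it absorbs
   any affine rescaling of raw voltages.
2. **Design** (`build_design()`): correct trials with defined delay;
   regressors set size, model-derived RL value `q_value` (the chosen
   action's $Q_{RL}$; the trialwise `rpe` replaces it for feedback lock),
   delay, their pairwise and three-way interactions, log RT and trial
   number within block. All mains z-scored; interactions are products of
   z-scored mains, re-z-scored so every column shares a common scale.
3. **Robust mass-univariate regression** (`robust_mass_univariate()`):
   independently per cell, iteratively reweighted least squares with Huber
   weighting (tuning 1.345, MAD scale, max 50 iterations, coefficient
   tolerance 1e-6); non-converged cells fall back to ordinary least
   squares and are flagged. The robust family and tuning are conventional
   choices, configurable, and cross-checked against an independent Huber
   implementation in the tests.
4. **Group cluster test** (`group_cluster_test()`): one-sample t against
   zero per cell; suprathreshold cells (two-sided cluster-forming
   p < 0.05) cluster over consecutive timepoints and spatially adjacent
   channels (adjacency from 10-20 montage distances, threshold 0.46
   montage units ≈ immediate neighbours); observed cluster mass (sum of
   |t|) is compared to a sign-flip permutation null of the maximum cluster
   mass (default 1000 permutations, seeded; positive and negative
   exceedances cluster separately).
5. **Markers** (`extract_trial_marker()`): the trialwise marker is the
   mean sign-aligned z-scored voltage over the group-significant cells
   (cells in negative clusters are negated), one value per trial. The
   group-level mask is the default source; a per-subject mask variant is a
   deliberate non-default because single-subject masks are noisy at
   realistic trial counts. `asymptotic_marker()` averages a marker over
   each stimulus's final 4 iterations (stimuli with fewer marker-bearing
   iterations are summarised over what exists and flagged).

## The synthetic cohort generator

`default_cohort_spec()` defines four groups (CTRL/MDD/BP/SCZ analogues)
with truncated-normal parameter distributions on the constrained scale and
EEG template gains. Planted structure mirrors the qualitative clinical
pattern the analysis is designed to detect: **BP/SCZ** get higher WM decay
($\phi$ +0.12), **SCZ** additionally lower $\gamma$ (−0.20), and **MDD** a
blunted reward-history coupling of the WM template (0 vs 0.35). Shift
sizes were chosen by power arithmetic so the fitted-scale group effects
land near $d \approx 0.8$–1.0 at 20 subjects/group after recovery
attenuation; they are presets for validation, not estimates of any
empirical effect size.

EEG epochs are template-weighted sums: unit-norm spatiotemporal templates
(smooth topography × Gaussian temporal kernel, truncated at 10% of peak so
each template has a compact footprint; early frontal for the RL value,
late parietal for set size, late frontal for delay, mid-latency
frontocentral for the feedback-locked RPE) times the z-scored trial
covariate, plus spatially correlated (exponential falloff, length 0.5
montage units), temporally smoothed (3-sample moving average) Gaussian
noise. The WM/set-size template expresses, additively, both objective
demand (the z-scored set size) and reward history scaled by the group's
coupling rate — the "WM management" signal — except in the MDD analogue,
whose coupling is zero. Where a signal-to-noise ratio is quoted, it is
the template's RMS amplitude over its footprint divided by the marginal
noise SD.

What the generator does **not** emulate: volume-conducted source mixing,
1/f spectral structure, artifacts, incorrect-trial ERP components, RT- or
attention-linked amplitude fluctuations. Passing end-to-end tests on this
generator therefore demonstrates that the estimators recover what they
assume, not that real EEG satisfies those assumptions.

## Group inference

`fit_mixed_model()` wraps lme4 with subject random intercepts (random
slopes are deliberately out of scope; intercepts are the declared default
in the absence of stated structures), z-scores continuous covariates
within subject, treatment-codes `group` against CTRL, and reports
Wald-normal coefficients (estimate, SE, z, p, 95% CI) — matching the
β/SE/p reporting style and keeping the stage estimator-agnostic.
`behavioral_battery()` runs the accuracy models (demand, demand × group,
and the neural-marker moderation variant); `marker_battery()` the marker
models (RL marker on reward history × set size × WM marker; WM marker on
set size and reward history × group; RPE marker on reward history, set
size, WM marker and the same-trial RL marker, optionally the model RPE;
asymptotic accuracy on asymptotic RL marker × reward history).
`cohort_table_stats()` provides Pearson chi-square tests of independence
(no continuity correction, matching df > 1 reporting), standardized
residuals, Holm-adjusted pairwise proportion comparisons, and
`anova_from_summary()` the textbook one-way ANOVA from per-group n/mean/SD.

`run_pipeline()` orchestrates the full loop on a generated cohort and
evaluates the planted-effect checks (pooled BP/SCZ $\phi$ above CTRL,
one-sided; SCZ $\gamma$ below CTRL, one-sided; MDD marker-vs-reward-history
slope below CTRL via the group × pcor interaction). Problem sizes in the
validation suites — 20 subjects/group for the end-to-end run, 8 restarts
per capacity, reduced channel/time grids for permutation calibration — are
the package's declared validation scale; every stage accepts larger sizes.

## Numerical choices and degenerate inputs

* Softmax: max-subtraction; $\beta = 100$ never overflows; ties exact.
* Likelihood: finite for $\varepsilon > 0$; mis-ordered or incomplete
  sessions are rejected, never silently reordered.
* Optimiser: logistic reparameterisation clamped at 1e-9 from the box
  edges; all-restart failure is a hard error with diagnostics.
* Z-scoring: zero-variance cells and constant design columns are errors
  naming the offender; fewer than 10 included trials is an error.
* Cluster test: fewer than 8 subjects or 100 permutations is refused;
  empty masks are legal results, but marker extraction from an empty mask
  is an error advising threshold/power review.
* Outlier rule: 1.5 × IQR per parameter over the whole sample by default;
  zero-IQR samples flag nothing; `k = Inf` disables the rule. The rule is
  a declared choice, not a reconstruction of any particular study's rule.
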