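---
title: "Simulating and analysing conditioned punishment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing conditioned punishment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirateplanets)
```

## The task

Two planets (R1, R2) can be clicked freely throughout 3-minute blocks.
A click on a free planet starts a 2-s trade that pays +100 points with
probability 0.5; the two planets' countdowns are independent, and clicks
on a counting-down planet are recorded but start nothing.  After two such
reward-only blocks, three punishment blocks add the conditioned
contingencies: each click on R1 with no CS pending or on screen triggers,
with probability 0.2, a CS+ that appears 1.5 s later and stays for 6 s,
ending in an attack that removes 20% of the participant's current points;
R2 clicks trigger a CS− under the identical schedule with no consequence.
Only one CS can run at a time.  On a random half of CSs, a shield becomes
available 3 s after onset: activating it costs 50 points, deflects the
attack, and blocks new trades until the CS ends.  Trading is suspended at
180 s but pending trades, CSs and outcomes resolve to completion.

## The engine

`simulate_session()` is an event loop over a small set of timers (per-planet
trade resolutions, CS onset, shield offer, CS end) interleaved with actions
proposed by an agent policy.  Design choices the schedule description leaves
open, and how they are resolved here:

* **Clicks during a countdown** are logged but neither start nor reset the
  trade; the planet becomes available again only when its trade resolves.
* **CS rolls while a CS is pending or active are lost**, not queued: the
  one-CS-at-a-time rule is read literally.
* **The 1.5-s pending window** between trigger and onset is treated as part
  of the inter-trial interval for nothing: the cue is not yet visible, so
  the window is excluded from both the ITI and the CS rate denominators.
* **Attack magnitude** is `-round(0.2 * max(points, 0))`: rounded to an
  integer and clamped so an attack can never *increase* a negative total
  (points can only go negative through shield costs).
* **Ties** between timers are resolved in a fixed order (trades, CS onset,
  shield offer, CS end), and timer events at the same timestamp as a policy
  action are processed first, so logs are deterministic.

Randomness is organised as buffered streams keyed by
`(master seed, participant, block, channel)` where the channels separate
reward rolls, CS rolls, shield availability, policy draws, report noise and
cohort-level assignment.  Identical `(config, policy, seed)` therefore give
byte-identical logs, and a refactoring that changes how one channel consumes
draws leaves the others untouched.

## The generative agent

The analysis pipeline needs cohorts whose ground truth is known.  The agent
model is **not** a cognitive model fitted to human data — it is the simplest
generative policy that produces data with the structure the analyses assume,
and every choice below is recorded in the cohort manifest.

* **Clicking** is a Poisson process at `base_click_rate` (default 60
  clicks/min, a realistic sustained rate for this kind of task), slowed by
  the factor `1 − suppression_gain · V(CS)` while a CS is on screen —
  conditioned suppression proportional to the cue's learned aversive value.
* **Pavlovian learning**: each CS offset updates the CS's value by a delta
  rule, `V ← V + alpha_pav (outcome − V)` with outcome 1 for CS+ (an attack,
  or the deflected-attack feedback when shielded) and 0 for CS−.
  Default `alpha_pav = 0.3`; both archetypes share it.
* **Instrumental learning**: the agent tracks `kappa[R, CS]`, its belief
  that response R triggers that CS.  Every CS-eligible click updates the
  clicked planet's row toward the observed outcome at rate `alpha_instr`.
  The prior is 0.2 for all four pairs — a diffuse "ships may come from
  either planet" belief.  The **sensitive** archetype has
  `alpha_instr = 0.12`; the **insensitive** archetype has
  `alpha_instr = 0`, so its `kappa` never differentiates.  This is the
  *only* parameter the archetypes differ in: failure to avoid is a failure
  to learn one's instrumental control, with Pavlovian learning intact.
* **Choice** is a softmax over
  `Q_R = w_reward·E[reward] − w_punish·loss_nominal·Σ_CS kappa[R,CS]·V(CS)`
  with inverse temperature `softmax_beta = 0.02` per point and
  `loss_nominal = 500` points (the felt stake of an attack; a nominal
  constant rather than the running total so that avoidance saturates
  instead of exploding as points accumulate).  The symmetric reward term
  cancels in the difference, so the insensitive archetype stays at
  indifference exactly in expectation.
* **Shielding**: when offered, the shield is taken with probability
  `plogis(shield_bias + shield_slope · V(CS))` (defaults −2 and 4: ~12%
  for a neutral cue, ~88% for a fully aversive one), after a fixed 0.5-s
  reaction time.  Because `V` is intact in both archetypes, both
  discriminate CS+ from CS− in shield use.
* **Self-reports** are noisy readouts of the agent's own model:
  Response→CS inferences are `100·kappa`, CS→Attack inferences `100·V`,
  and the *direct* Response→Attack inference is the capped chain product
  of the agent's own `kappa` and `V` — so at zero report noise the direct
  and chained estimates coincide exactly, which is the identity the chain
  regression tests exploit.  Rating noise is truncated-normal on
  `[0, 100]` with sd 10 rating points (large enough to be realistic,
  small enough not to pile mass at the bounds); response times are
  truncated-normal on `(0, ∞)` with mean 6 s.

Cohorts jitter each agent's parameters multiplicatively (log-scale sd 0.1)
around the archetype defaults, with a 30% sensitive fraction by default —
a bimodal mixture comparable to human cohorts on this task.

What the generator does **not** emulate: within-session fatigue or drifts
in click rate, trial-by-trial response-time structure, any influence of
trait covariates on behaviour (questionnaire subscales are generated as
independent noise), forgetting, or individual differences in the *shape*
of learning curves beyond rate jitter.  Passing tests therefore show that
the pipeline recovers structure of this specific generative form, not that
human data satisfy the same assumptions.

## Behavioural measures

All rates are time-weighted (clicks per minute of period time), with the
post-trading tail and the CS-pending window excluded from every
denominator, and shield-blocked CS time excluded from the suppression
denominator — shielded portions prevent trading, so counting them would
deflate CS rates artificially.

The **preference ratio** is `R1 ITI rate / (R1 + R2 ITI rate)`;
0.5 = indifference.  The **suppression ratio** is implemented as
`CS rate / (CS rate + ITI rate)`: the plain quotient `CS/ITI` is sometimes
quoted for this measure, but it ranges over `[0, ∞)` and contradicts the
standard anchors (0 = complete suppression, 0.5 = no change, > 0.5 =
facilitation); the ratio form honours them, and the quotient remains
available via `suppression_ratios(formula = "literal")`.  Suppression and
shield use are aggregated across the punishment phase because CSs and
shields are scarce within a block.  Missing values (no unshielded exposure,
no shield offered, no ITI clicks) stay missing and analyses drop them
pairwise — never imputed.

Participants are retained only if every check screen's mean response time
lies in `[1, 30]` s and both catch questions are correct.

## Clustering

Final-block preference ratios are clustered by k-means.  In one dimension
the optimal clusters are contiguous in sorted order, so the global
within-cluster-SS optimum is computed *exactly* by dynamic programming
over contiguous partitions rather than by randomly restarted Lloyd
iterations: restarts were observed to miss the global optimum on flat,
gap-free inputs, whereas the exact solver is deterministic and needs no
seed.  The number of clusters is chosen over k = 2..4 by maximal mean
Euclidean silhouette, ties broken toward smaller k for parsimony.  The cluster with the lower mean final ratio is labelled
*sensitive*.  Degenerate input (all values identical) is an error, since
silhouettes are undefined.

## Chain inferences

Percent-scale component inferences multiply on the probability scale:
`path = a·b/100`, and the overall chained estimate is the sum of the CS+
and CS− paths capped at 100%.  Dividing by 100 is the only scaling under
which two certain links (100% × 100%) give a certain chain, consistent
with the cap.  Direct inferences are regressed on chained estimates by
unweighted OLS with an intercept (reported, since the identity predicts
zero), pooled across blocks for per-block fits and per-subject averaged
for phase-level fits.  The omission analysis regresses direct inferences
on each single-path estimate alone and reports the mean signed error
(`estimate − direct`; negative = underprediction): removing a path can
only remove probability mass, so omission must underpredict whenever the
omitted path carries belief.  Note that restricted predictor range in a
homogeneous group (e.g. near-zero chained estimates for agents that never
differentiated the responses) attenuates r² even when the identity holds —
visible in synthetic cohorts as low insensitive-cluster r² with slopes
near 1.

## Statistical layer

Mixed orthogonal-contrast ANOVAs reduce each single-df within-subject
contrast `c` to per-subject scores `L_i = Σ_j c_j x_ij`: the within effect
tests the unweighted grand mean of `L` against zero with the pooled
within-group error, `F(1, n − g)`; the contrast × group interaction is the
one-way ANOVA on `L`; the between effect is the one-way ANOVA on subject
cell-means.  This reproduces the `F(1, ·)` df pattern of SPSS-style
contrast output; equivalence to any particular SPSS configuration on real
data has not been verified.  Contrast families are validated for zero sums
and mutual orthogonality.

PCA runs on the correlation matrix (items are on heterogeneous scales);
the retained dimensionality is the smallest m for which every item's
m-component communality reaches 0.5, and loadings are varimax-rotated with
Kaiser normalisation (annotated at |loading| > 0.5 and > 0.707).
Communalities are rotation-invariant, which the tests assert.

Stepwise linear regression follows the SPSS convention: forward entry of
the smallest partial-F p-value ≤ 0.05, backward removal at p ≥ 0.1, ties
broken by larger r² increment then input order; candidates with tolerance
below 1e-8 are skipped as collinear.  Stepwise logistic regression uses
likelihood-ratio tests at the same thresholds and reports the Nagelkerke
r² `[1 − (L0/L1)^{2/n}]/[1 − L0^{2/n}]` (exactly 0 for the null model)
and in-sample accuracy at the 0.5 threshold; perfect separation is
flagged rather than silently reported.

## Numerical and scale choices in the test-suite

The suite exercises the pipeline at sizes chosen to make every stochastic
check sharp but quick: schedule calibration accumulates ≥ 5,000 eligible
responses, ≥ 5,000 trades and ≥ 2,000 CS episodes (99% binomial CIs of
±1–3 percentage points); archetype recovery uses ten cohorts of 100
agents at 30% sensitive; oracle comparisons (exhaustive 1-D k-means,
GLM-route contrast ANOVAs, exhaustive stepwise additions) run on vectors
up to n = 200 and designs up to 20 × 6 at tolerance 1e-8.  The analysis
drivers simulate the full 135-agent study scale.

## Known limitations

* The agent model is generative scaffolding, not a fitted cognitive model;
  parameter values are plausibility choices, not estimates.
* The engine models scheduling, not perception: no input latency, no
  visual-attention effects, no inter-click refractory period.
* The contrast-ANOVA error terms follow the per-contrast reduction above;
  other mixed-model conventions (e.g. multivariate or pooled-omnibus error
  terms) would give different denominators for k > 1 df families.
* Silhouette-based model selection is only as meaningful as the 1-D
  feature; it is not a general mixture diagnostic.
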