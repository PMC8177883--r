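# pirateplanets

Simulation and analysis of a free-operant **conditioned-punishment** task,
built for studying individual differences in punishment sensitivity.

## The problem

In conditioned punishment, a response (clicking planet **R1**) does not
produce the aversive outcome directly: it produces a warning stimulus
(**CS+**, a pirate ship on screen for 6 s) which then ends in an attack
removing 20% of the participant's points.  A second response (**R2**)
produces a consequence-free **CS−** under an identical schedule.  Both
responses are equally rewarded throughout (+100 points, 50% per 2-s trade).
On half of CS presentations a **shield** can be bought (−50 points) that
deflects the attack — an active-avoidance response.  Human cohorts on this
task split into a minority that learns to avoid the punished response and a
majority that keeps responding — even though both groups learn the
Pavlovian CS+→Attack relation equally well.  The interesting question is
*why*: the dissociation points at a failure of instrumental
(Response→CS→Attack) contingency learning, not of punishment valuation.

`pirateplanets` provides

* an **event-driven task engine** (`simulate_session()`) that reproduces
  the schedule exactly and emits a validated, tidy event log;
* a **synthetic cohort generator** (`generate_cohort()`) whose two agent
  archetypes differ *only* in the instrumental learning rate
  (`alpha_instr`), so the analysis pipeline can be stress-tested against
  known ground truth;
* the **behavioural measures**: ITI click rates, preference ratio
  `R1/(R1+R2)`, conditioned-suppression ratios `CS/(CS+ITI)`, shield-use
  percentages, pre-block collapsing, engagement exclusions;
* **phenotype clustering**: 1-D k-means on final-block preference ratios
  with silhouette model selection over k = 2..4;
* the **causal chain analysis**: chained Response→Attack estimates
  `min(100, (R→CS⁺·CS⁺→Atk + R→CS⁻·CS⁻→Atk)/100)` regressed against
  directly reported inferences, with component-omission diagnostics;
* the **statistical layer**: one-sample ratio tests, orthogonal-contrast
  mixed ANOVAs, varimax PCA with a 50%-communality retention rule, and
  SPSS-style stepwise linear/logistic regression with the Nagelkerke
  pseudo r².

## Worked example

```r
library(pirateplanets)

coh <- generate_cohort(100, sensitive_fraction = 0.3, seed = 42)
ps  <- participant_summary(coh$events)
fin <- ps[ps$block == 5 & !is.na(ps$preference_ratio), ]
cl  <- cluster_sensitivity(fin$preference_ratio, seed = 1,
                           ids = fin$participant_id)
print(cl)
#> <cluster_result> k = 2 (mean silhouette 0.775, min 0.183)
#>   sensitive    n =  28  mean final ratio 0.065
#>   insensitive  n =  72  mean final ratio 0.492
```

The clustering selects two phenotypes: a punishment-**sensitive** cluster
whose final preference ratio (the R1 share of inter-trial clicking;
0.5 = indifference) has collapsed to 0.065 — they have almost completely
abandoned the punished planet — and an **insensitive** cluster still at
0.492, i.e. indifferent.  Against the generative archetypes recorded in
`coh$manifest`, 98% of the 100 agents receive their true label.

The numbered scripts under `analysis/` run the full study-scale pipeline
(135 agents) and write every stage's tables to `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_behavioural_metrics.R
Rscript analysis/03_clustering.R
Rscript analysis/04_chain_inferences.R
Rscript analysis/05_cohort_statistics.R
```

`run_simulate()` / `run_analyze()` wrap the same stages as two calls for
programmatic use.

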