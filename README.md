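# latentstate

An online latent-state learning model of classical conditioning, with a
Rescorla–Wagner baseline and a programmatic battery of eleven classic
conditioning experiments.

Many conditioning phenomena — rapid return of fear after extinction,
spontaneous recovery, the Hall–Pearce effect, backwards blocking,
post-retrieval memory modification — defeat constant-associability
trial-and-error models. `latentstate` implements an agent that explains
them by *latent-state inference*: it maintains `L` competing cue→reward
association sets ("latent states"), learns each with a Rescorla–Wagner-style
update, and filters a belief distribution over which state is active.
The package is aimed at computational-modeling researchers in learning and
decision-making who want a deterministic, inspectable reference
implementation of the model and of the simulation designs used to probe it.

## The model in brief

Per trial, with feature vector `c` (cue indicators plus pairwise products)
and reward `R` (centered: ±1/2):

* prediction error per state: `E_l = R − c′V_l`
* belief filtering (approximate Bayes, Gaussian kernel, Markov prior):
  `p_l ∝ ((1−γ)p_l + γ/L) · φ(E_l/σ)`, normalizer `l₀`
* change-point statistic (Page-style CUSUM): `q ← max(q + log(φ(0)/l₀) − δ, 0)`;
  if `q > ν`, spawn a new state with `V = R·c/(c′c)`, `B = I`, belief 0
* value update with belief- and effort-dependent associability:
  `V_l ← V_l + α₀ p_l B_l⁻¹ c E_l`
* effort (cue second-moment) update: `B_l ← (1−α₀)B_l + α₀ p_l c c′`
* pooled uncertainty: `σ² ← σ² + β₀(Σ_l p_l E_l² − σ²)`
* between trials, context shifts corrode beliefs toward uniform
  (`p ← w p + (1−w)/L`, `w = (1−γ)^(ITI−1)`; spatial shifts are the
  `ITI = ∞` limit) and temporal shifts replay the value update
  `min(χ, ITI−1)` times ("rumination").

With one state and the effort matrix at its fixed point this reduces
exactly to the Rescorla–Wagner model — a property the test suite checks
against the closed form `V(t) = R(1 − (1−α₀)^t)`.

## Worked example: blocking

```r
library(latentstate)
def  <- build_schedule("blocking")          # A+ (20 trials), then AB+ (20)
traj <- run_schedule(def$conditions$main)   # latent-state learner, defaults
traj[c(20, 21, 40), c("trial", "phase", "strength_A", "strength_B",
                      "prediction", "n_states")]
#>    trial  phase strength_A strength_B prediction n_states
#> 20    20 stage1      0.321     0.0000      0.311        1
#> 21    21 stage2      0.330     0.0250      0.321        1
#> 40    40 stage2      0.346     0.0717      0.489        1

check_effect("blocking", list(main = traj))
#> blocking                 PASS  statistic = +0.2748 (margin 0.01)
```

Strengths are on the centered scale, so 0 means a 50–50 reward expectation
and +0.5 is certainty of reward. After pretraining, cue A alone carries
0.321; during compound training the compound's prediction approaches +0.5
while B only reaches 0.072 — conditioning of A has blocked B, and the
effect statistic (final `strength(A) − strength(B)` = 0.27) clears the 0.01
margin.

The full battery, for this model and the baseline:

```r
run_battery("latent_state")     # reproduces all 12 effect checks
run_battery("rescorla_wagner")  # passes exactly blocking, overexpectation,
                                # conditioned inhibition
```

## Command line

```sh
exec/latentstate run --experiment blocking --out results/
exec/latentstate battery --model latent_state --out results/battery.json
exec/latentstate params --config my_config.yaml
```

Configuration is YAML or JSON (`alpha0`, `beta0`, `gamma`, `sigma0`, `nu`,
`delta`, `chi`, `max_states`, `margin`, `seed`, ...); omitted keys keep the
model's canonical defaults. Trajectories are written as full-precision CSV,
battery reports as JSON.

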