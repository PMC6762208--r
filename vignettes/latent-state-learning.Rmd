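---
title: "Online latent-state learning: model, assumptions, and simulation designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online latent-state learning: model, assumptions, and simulation designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentstate)
```

## The model

`latentstate` implements an online model of classical conditioning in which
a learning agent entertains `L` *latent states* — mutually exclusive
hypotheses about how cues map to rewards — and learns, on every trial, both
the cue–reward association under each hypothesis and its belief about which
hypothesis is currently active.

Each latent state `l` carries a Rescorla–Wagner-style linear association: on
a trial with feature vector `c` (raw cue indicators plus, by default, one
product feature per cue pair) the state predicts reward `c'V_l` and
registers the prediction error

    E_l = R - c'V_l .

Strengths move in proportion to the error, but with an associability that is
neither constant nor scalar:

    V_l <- V_l + alpha0 * p_l * B_l^{-1} c * E_l ,

where `p_l` is the current belief in state `l` and `B_l` is that state's
*effort matrix*, a running estimate of the cue second-moment matrix,

    B_l <- (1 - alpha0) B_l + alpha0 * p_l * c c' ,   B_l(1) = I .

Beliefs weight how much each hypothesis learns; the effort matrix rotates
and rescales updates toward directions that have not been explored (this is
what produces backwards blocking: after compound training `B^{-1}` maps the
single-cue direction partly onto the *difference* of the two cues).

Beliefs themselves follow an approximate Bayesian filter. The agent assumes
latent states form a Markov chain that stays put with probability
`1 - gamma (L-1)/L` and jumps uniformly otherwise, and scores each state by
a standardized Gaussian kernel of its prediction error:

    p_l <- (1/l0) * ((1 - gamma) p_l + gamma / L) * phi(E_l / sigma) ,

with `phi` the standard-normal density, `sigma^2` a pooled prediction-error
variance updated as `sigma^2 <- sigma^2 + beta0 (sum_l p_l E_l^2 - sigma^2)`,
and `l0` the normalizing constant. The kernel is used exactly in this
standardized form, without a `1/sigma` density factor: the factor would
cancel both in the belief normalization and in the change statistic below,
so the standardized form is self-consistent.

Unexpected uncertainty is tracked by a cumulative-sum change detector in the
style of Page's procedure:

    q <- max(q + log(phi(0) / l0) - delta, 0) .

`phi(0)/l0` is the likelihood ratio between a hypothetical state that
predicts the observed reward perfectly and the current model; when the
accumulated evidence strictly exceeds `nu` a new latent state is spawned
with strengths `R c / (c'c)` (so it predicts the current reward exactly),
identity effort matrix, belief zero, and `q` resets to zero.

Between trials, context can shift. A temporal shift of `ITI` trial-lengths
corrodes beliefs toward uniform in closed form,
`p <- w p + (1 - w)/L` with `w = (1 - gamma)^(ITI - 1)`, and additionally
triggers *rumination*: the last trial's value update is replayed
`min(chi, ITI - 1)` times. A spatial or visual shift is the infinite-delay
limit — beliefs become exactly uniform, with no rumination.

### Per-trial ordering

`step_trial()` fixes the stage order: errors from pre-update strengths,
belief filtering, change detection (possibly spawning), value update, effort
update, variance update, then the context event (rumination before belief
corrosion). Two consequences worth knowing: a just-spawned state receives no
value update on its birth trial (its belief is zero) but does receive the
`(1 - alpha0) I` effort decay; and the recorded marginal prediction uses the
post-inference beliefs with pre-update strengths. A regression test pins a
three-trial trace against values computed with an independent transcription
of the equations, so any reordering fails loudly.

## Parameters

| Parameter | Meaning | Default |
|---|---|---|
| `alpha0` | associative-strength learning rate | 0.05 |
| `beta0`  | variance learning rate | 0.05 |
| `gamma`  | latent-state transition probability mass | 0.05 |
| `sigma0` | initial reward standard deviation | 0.5 |
| `nu`     | new-state threshold on `q` (strict) | 0.2 |
| `delta`  | per-trial drift subtracted from `q` | 0.6 |
| `chi`    | rumination step cap | 5 |
| `max_states` | cap on `L` | 15 |

These defaults are used, unchanged, for every experiment in the battery.
Rewards are centered (`+1/2` reinforced, `-1/2` not), so a zero strength
means a 50–50 expectation and reported strengths live on `[-1/2, +1/2]`;
`report_strength(..., uncenter = TRUE)` shifts back to the 0/1 scale used by
the Rescorla–Wagner baseline, which consumes uncentered rewards and no
interaction features.

The threshold is a single parameter `nu` with strict inequality `q > nu`,
and the effort recursion decays each state's own matrix `B_l` — the only
reading under which the per-state inverse in the associability is coherent
with per-state initialization at the identity.

## Numerical choices

* **Linear solves, not inverses.** `B_l^{-1} c` is computed by `solve()`,
  and effort matrices are re-symmetrized after every update. Long runs at
  extreme `alpha0` can still drive unattended directions of `B_l` toward
  zero geometrically; if a solve becomes numerically singular the error
  names the offending component rather than returning garbage.
* **Kernel underflow.** `phi(E/sigma)` underflows around `|E|/sigma > 38`.
  If the normalizer falls below `1e-300` beliefs fall back to the Markov
  prior (likelihoods treated as uninformative), the change statistic uses
  the clamped normalizer, and a diagnostic line is logged (enable with
  `options(latentstate.verbose = TRUE)`).
* **Variance floor.** Perfect prediction drives `sigma^2` toward zero,
  which would degenerate the filter; it is clamped at `1e-8`.
* **State cap.** At `L = max_states` spawning is suppressed, the candidate
  `q` is kept, and the event is logged.
* **Determinism.** All model computation is deterministic; randomness only
  enters through the optional shuffled schedule variant, under a seed.

## The simulation battery

`build_schedule()` constructs eleven classic designs (twelve ids — partial
reinforcement has two variants), `run_schedule()` produces per-trial
trajectories, and `check_effect()` reduces each experiment to one signed
statistic that must strictly exceed a margin (default 0.01 on the centered
reward scale) for the effect to count as reproduced:

* **blocking** — pretrained A blocks B in compound: `strength(A) - strength(B)`
  at the end of compound training.
* **overexpectation** — separately trained cues lose strength in compound:
  end-of-stage-1 minus end-of-stage-2 `strength(A)`.
* **conditioned_inhibition** — A+ interleaved with AB−:
  `min(strength(A), -strength(B))` at the end.
* **wilson1992** (Hall–Pearce) — group E (tone omitted on non-reinforced
  middle-stage trials) ends up responding *more* to the light: mean stage-3
  `strength(A)`, E minus C.
* **rescorla2000_1A/1B** — unequal associability within a compound:
  stage-2 change of B minus change of A (1A), and `|change of A| -
  |change of B|` (1B).
* **partial_reinforcement_1/2** — slower extinction after partial
  reinforcement, without and with an interposed continuous block: mean
  extinction-phase `strength(A)`, partial minus continuous.
* **backwards_blocking** — X loses strength while only A is trained:
  `strength(X)` end of stage 1 minus end of stage 2.
* **renewal** — rapid return after extinction: mean predicted reward over
  the first three reacquisition trials minus the first three acquisition
  trials. The context-shift benefit (shifted minus same context on those
  trials) is computed and reported alongside as a secondary quantity; it
  does not gate the pass, because the Rescorla–Wagner baseline with its
  context-as-cue encoding would trivially show a shifted-context advantage,
  and because the benefit is expected to be slight.
* **spontaneous_recovery** — `strength(A)` at test onset (after the delay's
  belief corrosion, before any test feedback), delay minus no-delay.
* **memory_modification** — `min(test at delay 1, test at delay 100) -
  test at delay 5`, with test strength read the same way after a final long
  delay.

The spontaneous-recovery and memory-modification readouts deliberately use
the trajectory row of the last pre-test trial *after* its temporal event:
that is the agent's state at test onset. Reading one row later would mix one
trial of test feedback into the readout in every condition.

### Design choices for trial counts

Exact per-stage trial counts are a free design dimension, and two mechanisms
constrain them in opposite directions:

* Stages that must *establish* an association run 20 presentations of each
  trial type — with `alpha0 = 0.05` that reaches about two thirds of
  asymptote, enough that compound predictions overshoot (overexpectation)
  and omissions surprise (Rescorla 2000).
* The Wilson design's alternation phases are kept brief (stages of 10, 20,
  20 trials). Long runs of identical compound trials drive the effort
  matrix toward a rank-one limit, and its inverse then hands group C a very
  large novelty-direction associability in stage 3 — the opposite of the
  slowly-learning control group this paradigm is about. Brief exposure
  keeps group C in the plain-associability regime (one latent state, slow
  stage-3 learning) while group E still detects the contingency change and
  shifts to a new state; the stage-2 length of 20 also lets the baseline
  model reach its alternation steady state rather than showing a transient
  group difference.
* Memory modification uses a long (40-trial) acquisition: the
  retrieval–extinction paradigm presupposes a well-consolidated memory. A
  strong acquisition memory makes immediate extinction (delay 1) so
  surprising that the agent rejects the old state outright and builds new
  ones, preserving the original association, while inside the
  reconsolidation window (delay 5) beliefs linger on the acquisition state
  long enough for extinction and rumination to rewrite it.

Alternation is strict and deterministic by default (reinforced type first)
so the battery is exactly reproducible; `shuffle = TRUE` gives a seeded
randomized variant. Conditioned inhibition uses "no reward" (centered
`-1/2`) on compound trials. Within-phase ITI is 1 everywhere except where a
design inserts an explicit event.

```{r battery, eval = FALSE}
run_battery("latent_state")   # 12 of 12 effects reproduced
run_battery("rescorla_wagner")  # exactly blocking, overexpectation,
                                # conditioned inhibition
```

## What the generator does and does not emulate

Schedules are idealized: deterministic alternation, binary rewards, no
session structure, no inter-subject variability, and single-group designs
for paradigms that in the laboratory involve counterbalancing and
response measures (lever pressing, magazine entries, skin conductance) that
relate to associative strength only monotonically. Passing the battery
shows the *model* reproduces the direction of each group-level effect under
these idealized conditions; it says nothing about effect sizes in real
subjects, about fitting individual behavior, or about designs outside the
battery. Action selection, multidimensional rewards, and parameter fitting
to empirical data are out of scope.

## Known limitations

* The effort-matrix inverse can legitimately amplify updates beyond the
  error magnitude (associability above one) after long exposure to a fixed
  cue compound; with extreme learning rates the matrices can also become
  numerically singular. Both are properties of the update equations, not of
  this implementation; the package surfaces the latter as an error.
* The pooled variance is shared across states, so a single surprising trial
  inflates expected uncertainty for every hypothesis.
* The reconsolidation-window statistic is small (about 0.05 on the
  half-unit reward scale) and depends on the acquisition memory being near
  asymptote; the package exposes `stage_lengths` so this sensitivity can be
  explored directly.
* Rumination replays only the value update, holding beliefs, effort
  matrices, variance, and the change statistic fixed — one of several
  defensible readings of "performing the end-of-trial updates again"; the
  alternatives (replaying inference too) would couple rumination and
  belief corrosion in ways the per-trial ordering above does not define.
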