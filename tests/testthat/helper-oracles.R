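# Independent oracles and fixture generators used across the suite.

# Exact HMM forward recursion for the agent's assumed Markov chain
# (self-transition 1 - gamma*(L-1)/L, each other state gamma/L) with
# standardized Gaussian emission weights. Coded with an explicit transition
# matrix and matrix products, independently of the package's closed-form
# prior.
hmm_forward_oracle <- function(p0, error_seq, sigma_seq, gamma) {
  L <- length(p0)
  Tm <- matrix(gamma / L, L, L)
  diag(Tm) <- 1 - gamma * (L - 1) / L
  p <- p0
  out <- matrix(NA_real_, nrow = nrow(error_seq), ncol = L)
  for (t in seq_len(nrow(error_seq))) {
    prior <- as.vector(t(Tm) %*% p)
    w <- prior * dnorm(error_seq[t, ] / sigma_seq[t])
    p <- w / sum(w)
    out[t, ] <- p
  }
  out
}

# Random trial schedule over a small cue universe, with occasional context
# events; rewards follow the centered +/- 1/2 coding.
random_schedule <- function(n_trials = 30, universe = c("A", "B", "C"),
                            p_event = 0.15) {
  trials <- lapply(seq_len(n_trials), function(i) {
    cues <- sample(universe, sample(seq_along(universe), 1))
    ev <- if (runif(1) < p_event) {
      if (runif(1) < 0.5) context_event("spatial")
      else context_event("temporal", iti = sample(c(2L, 5L, 50L), 1))
    } else {
      context_event()
    }
    trial_spec(cues, reinforced = runif(1) < 0.5, post_event = ev)
  })
  ls_schedule(sprintf("fuzz"), trials, universe)
}

# Drives a learner through a schedule step by step, invoking `probe` after
# every trial with the updated state and the step output.
walk_schedule <- function(sched, params = ls_params(), probe = NULL) {
  state <- ls_learner(sched$cue_universe, params)
  for (tr in sched$trials) {
    cues <- expand_cues(tr$cues, sched$cue_universe,
                        params$include_interactions)
    reward <- center_reward(tr$reinforced, params$center_rewards)
    out <- step_trial(state, cues, reward, tr$post_event, params)
    state <- out$state
    if (!is.null(probe)) probe(state, out, cues, reward)
  }
  state
}

min_effort_eigenvalue <- function(state) {
  min(vapply(state$B, function(B) min(eigen(B, symmetric = TRUE,
                                            only.values = TRUE)$values),
             numeric(1)))
}
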