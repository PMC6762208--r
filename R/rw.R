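#' Create a Rescorla-Wagner learner
#'
#' The constant-associability baseline: a single strength vector over raw
#' cues (no interaction features), initialized at zero.
#'
#' @param cue_universe Character vector of cue labels (may include context
#'   labels when context is encoded as a cue).
#' @return An object of class `rw_state`.
#' @export
rw_learner <- function(cue_universe) {
  feats <- feature_names(cue_universe, include_interactions = FALSE)
  structure(
    list(universe = cue_universe, features = feats, dim = length(feats),
         V = stats::setNames(rep(0, length(feats)), feats)),
    class = "rw_state"
  )
}

#' One Rescorla-Wagner trial
#'
#' `V <- V + alpha * c * (R - c'V)`: every present cue moves toward the
#' shared prediction error at the constant rate `alpha`; absent cues are
#' unchanged.
#'
#' @param state An `rw_state`.
#' @param cues Numeric feature vector (same length as the learner's
#'   universe).
#' @param reward Observed reward.
#' @param params [rw_params()].
#' @return List with `state`, `prediction` (pre-update `c'V`) and `error`.
#' @examples
#' st <- rw_learner("A")
#' rw_step(st, expand_cues("A", "A", include_interactions = FALSE), 1)$error
#' @export
rw_step <- function(state, cues, reward, params = rw_params()) {
  if (!is.numeric(cues) || length(cues) != state$dim)
    stop(sprintf("feature vector has length %d but the learner tracks %d cues",
                 length(cues), state$dim), call. = FALSE)
  cues <- unname(cues)
  prediction <- sum(cues * state$V)
  error <- reward - prediction
  state$V <- state$V + params$alpha * cues * error
  list(state = state, prediction = prediction, error = error)
}

#' Run a schedule through the Rescorla-Wagner baseline
#'
#' Context handling follows the conventions used when comparing against the
#' latent-state learner: each distinct spatial context label in the schedule
#' contributes an always-on indicator cue for its trials, temporal events
#' are no-ops, rewards are uncentered (1/0), and interaction features are
#' off.
#'
#' @param sched An [ls_schedule()].
#' @param params [rw_params()].
#' @param context_as_cue Encode spatial context labels as cues?
#' @return A trajectory `data.frame` (see [run_schedule()] for the column
#'   layout).
#' @export
rw_run <- function(sched, params = rw_params(), context_as_cue = TRUE) {
  ctx <- unique(sched$context_labels)
  universe <- sched$cue_universe
  if (context_as_cue && length(ctx) > 0) universe <- c(universe, ctx)
  state <- rw_learner(universe)
  rows <- vector("list", length(sched$trials))
  for (i in seq_along(sched$trials)) {
    tr <- sched$trials[[i]]
    present <- tr$cues
    if (context_as_cue && length(ctx) > 0)
      present <- c(present, sched$context_labels[[i]])
    cues <- expand_cues(present, universe, include_interactions = FALSE)
    reward <- center_reward(tr$reinforced, center_rewards = FALSE)
    out <- rw_step(state, cues, reward, params)
    state <- out$state
    rows[[i]] <- trajectory_row(
      trial = i, condition = sched$label, phase = tr$phase,
      strengths = state$V[sched$cue_universe],
      prediction = out$prediction,
      beliefs = 1, n_states = 1L, sigma2 = NA_real_, q = NA_real_,
      state_added = FALSE, max_states = 1L,
      cue_universe = sched$cue_universe)
  }
  do.call(rbind, rows)
}
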