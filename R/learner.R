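#' Create a latent-state learner
#'
#' Initializes the agent with a single latent state: zero associative
#' strengths, identity effort matrix, belief 1, pooled variance `sigma0^2`,
#' and change statistic 0.
#'
#' @param cue_universe Character vector of raw cue labels the agent can
#'   encounter.
#' @param params [ls_params()] parameter set (controls whether interaction
#'   features are included).
#' @return An object of class `ls_state` with elements `universe`,
#'   `features`, `dim`, `V` (L x d strength matrix), `B` (list of d x d
#'   effort matrices), `p` (beliefs), `sigma2`, and `q`.
#' @examples
#' st <- ls_learner(c("A", "B"))
#' st$features
#' @export
ls_learner <- function(cue_universe, params = ls_params()) {
  feats <- feature_names(cue_universe, params$include_interactions)
  d <- length(feats)
  structure(
    list(universe = cue_universe, features = feats, dim = d,
         V = matrix(0, nrow = 1, ncol = d, dimnames = list(NULL, feats)),
         B = list(diag(d)),
         p = 1,
         sigma2 = params$sigma0^2,
         q = 0),
    class = "ls_state"
  )
}

#' Number of latent states currently entertained
#' @param state An `ls_state`.
#' @return Integer count of latent states.
#' @export
n_states <- function(state) nrow(state$V)

as_feature_vector <- function(cues, state) {
  if (!is.numeric(cues) || length(cues) != state$dim)
    stop(sprintf("feature vector has length %d but the learner tracks %d features",
                 length(cues), state$dim), call. = FALSE)
  unname(cues)
}

#' Per-state and belief-weighted reward predictions
#'
#' State `l` predicts the inner product of the feature vector with its
#' strength vector; the marginal prediction weights these by the current
#' beliefs. Pure function: the learner is not modified.
#'
#' @param state An `ls_state`.
#' @param cues Feature vector from [expand_cues()].
#' @return List with `state_predictions` (one per latent state) and
#'   `marginal` (belief-weighted expectation).
#' @export
predict_rewards <- function(state, cues) {
  cues <- as_feature_vector(cues, state)
  preds <- as.vector(state$V %*% cues)
  list(state_predictions = preds, marginal = sum(state$p * preds))
}

#' Per-state prediction errors
#'
#' `E_l = R - c'V_l`, computed from the pre-update strengths.
#'
#' @inheritParams predict_rewards
#' @param reward Observed reward value for the trial.
#' @return Numeric vector of one error per latent state.
#' @export
compute_errors <- function(state, cues, reward) {
  cues <- as_feature_vector(cues, state)
  as.vector(reward - state$V %*% cues)
}

#' Approximate Bayesian filter update of latent-state beliefs
#'
#' Each belief is propagated one step through the assumed Markov chain
#' (`prior_l = (1 - gamma) p_l + gamma / L`), reweighted by the standardized
#' Gaussian kernel of its prediction error, and renormalized. If every
#' kernel underflows, beliefs fall back to the Markov prior (likelihoods
#' treated as uninformative) and the returned normalizer is clamped at the
#' underflow floor.
#'
#' @inheritParams predict_rewards
#' @param errors Per-state prediction errors from [compute_errors()].
#' @param params [ls_params()].
#' @return List with `state` (beliefs replaced) and `norm_const` (the
#'   normalizer `l0`, clamped below at the underflow floor).
#' @export
update_beliefs <- function(state, errors, params = ls_params()) {
  L <- n_states(state)
  if (length(errors) != L)
    stop("`errors` must have one entry per latent state", call. = FALSE)
  stopifnot(state$sigma2 > 0)
  prior <- (1 - params$gamma) * state$p + params$gamma / L
  w <- prior * stats::dnorm(errors / sqrt(state$sigma2))
  l0 <- sum(w)
  if (!is.finite(l0) || l0 < .l0_floor) {
    ls_log("belief normalizer underflow (l0 = %g); falling back to the Markov prior", l0)
    state$p <- prior
    l0 <- max(l0, .l0_floor)
    if (!is.finite(l0)) l0 <- .l0_floor
  } else {
    state$p <- w / l0
  }
  list(state = state, norm_const = l0)
}

#' Candidate change-point statistic
#'
#' One step of Page's cumulative-sum change detector: the statistic grows by
#' the log likelihood ratio between a hypothetical perfectly-predicting
#' one-state model (`phi(0)`) and the current model (`l0`), drifts down by
#' `delta`, and is clamped at zero. The caller commits either this candidate
#' or a reset to zero when a state is spawned.
#'
#' @inheritParams update_beliefs
#' @param norm_const Belief normalizer `l0` from [update_beliefs()].
#' @return The candidate statistic (the learner is not modified).
#' @export
update_change_stat <- function(state, norm_const, params = ls_params()) {
  check_positive(norm_const, "norm_const")
  max(state$q + log(stats::dnorm(0) / norm_const) - params$delta, 0)
}

#' Spawn a new latent state
#'
#' Appends a latent state whose strengths are initialized so that its
#' prediction on the spawning cue vector equals the spawning reward exactly
#' (`V_new = R c / (c'c)`), with identity effort matrix and belief 0, and
#' resets the change statistic to zero. Existing beliefs are untouched (they
#' already sum to one).
#'
#' @inheritParams compute_errors
#' @param params [ls_params()] (supplies the state cap).
#' @return The modified `ls_state`.
#' @export
spawn_state <- function(state, cues, reward, params = ls_params()) {
  cues <- as_feature_vector(cues, state)
  cc <- sum(cues^2)
  if (cc <= 0)
    stop("cannot spawn a latent state from an all-zero cue vector",
         call. = FALSE)
  if (n_states(state) >= params$max_states)
    stop(sprintf("latent-state cap reached (max_states = %d)",
                 params$max_states), call. = FALSE)
  state$V <- rbind(state$V, reward * cues / cc)
  state$B <- c(state$B, list(diag(state$dim)))
  state$p <- c(state$p, 0)
  state$q <- 0
  state
}

#' Value update of associative strengths
#'
#' For each latent state, `V_l <- V_l + alpha0 * p_l * solve(B_l, c) * E_l`.
#' The effort-matrix inverse is realized as a linear solve; a numerically
#' singular effort matrix raises an error naming the component.
#'
#' @inheritParams update_beliefs
#' @param cues Feature vector.
#' @return The modified `ls_state`.
#' @export
update_strengths <- function(state, cues, errors, params = ls_params()) {
  cues <- as_feature_vector(cues, state)
  L <- n_states(state)
  if (length(errors) != L)
    stop("`errors` must have one entry per latent state", call. = FALSE)
  for (l in seq_len(L)) {
    if (state$p[l] == 0 || errors[l] == 0) next
    x <- tryCatch(solve(state$B[[l]], cues),
                  error = function(e)
                    stop(sprintf("effort matrix of latent state %d is numerically singular", l),
                         call. = FALSE))
    state$V[l, ] <- state$V[l, ] + params$alpha0 * state$p[l] * x * errors[l]
  }
  state
}

#' Effort-matrix (cue second moment) update
#'
#' `B_l <- (1 - alpha0) B_l + alpha0 * p_l * c c'`, re-symmetrized to cancel
#' roundoff.
#'
#' @inheritParams update_strengths
#' @return The modified `ls_state`.
#' @export
update_effort <- function(state, cues, params = ls_params()) {
  cues <- as_feature_vector(cues, state)
  cc <- tcrossprod(cues)
  for (l in seq_len(n_states(state))) {
    B <- state$B[[l]] + params$alpha0 * (state$p[l] * cc - state$B[[l]])
    state$B[[l]] <- (B + t(B)) / 2
  }
  state
}

#' Pooled prediction-error variance update
#'
#' The belief-averaged squared error `sum_l p_l E_l^2` is blended into the
#' pooled variance at rate `beta0`; the variance is clamped below at a small
#' positive floor so the filter's Gaussian kernel stays proper.
#'
#' @inheritParams update_strengths
#' @return The modified `ls_state`.
#' @export
update_variance <- function(state, errors, params = ls_params()) {
  if (length(errors) != n_states(state))
    stop("`errors` must have one entry per latent state", call. = FALSE)
  msq <- sum(state$p * errors^2)
  state$sigma2 <- max(state$sigma2 + params$beta0 * (msq - state$sigma2),
                      .sigma2_floor)
  state
}

#' Corrode beliefs for a context shift
#'
#' A temporal shift applies `ITI - 1` steps of the assumed Markov chain in
#' closed form: `p_l <- w p_l + (1 - w)/L` with `w = (1 - gamma)^(ITI - 1)`.
#' A spatial/visual shift is the infinite-delay limit: beliefs become exactly
#' uniform.
#'
#' @inheritParams update_strengths
#' @param event A [context_event()] with kind `"temporal"` or `"spatial"`.
#' @return The modified `ls_state`.
#' @export
apply_context_shift <- function(state, event, params = ls_params()) {
  L <- n_states(state)
  if (event$kind == "temporal") {
    w <- (1 - params$gamma)^(event$iti - 1)
    state$p <- w * state$p + (1 - w) / L
  } else if (event$kind == "spatial") {
    state$p <- rep(1 / L, L)
  } else {
    stop("`event` must be a temporal or spatial context event", call. = FALSE)
  }
  state
}

#' Rumination during a temporal context shift
#'
#' Replays the value update `min(chi, ITI - 1)` times: each iteration
#' recomputes the prediction errors with the current strengths and applies
#' [update_strengths()]. Beliefs, effort matrices, the pooled variance, and
#' the change statistic are held fixed throughout.
#'
#' @inheritParams compute_errors
#' @param event A temporal [context_event()].
#' @param params [ls_params()].
#' @return The modified `ls_state`.
#' @export
ruminate <- function(state, cues, reward, event, params = ls_params()) {
  if (event$kind != "temporal")
    stop("rumination applies only to temporal context shifts", call. = FALSE)
  n_iter <- min(params$chi, event$iti - 1)
  for (i in seq_len(n_iter)) {
    errs <- compute_errors(state, cues, reward)
    state <- update_strengths(state, cues, errs, params)
  }
  state
}

#' One full trial of latent-state learning
#'
#' Executes the per-trial update in its canonical order: (1) prediction
#' errors from pre-update strengths; (2) belief filtering; (3) change-point
#' statistic, spawning a new latent state when the candidate strictly
#' exceeds `nu` (suppressed with a log entry at the state cap, in which case
#' the candidate is committed); (4) value update over all current states (a
#' just-spawned state has belief 0 and is untouched); (5) effort-matrix
#' update over all states; (6) pooled variance update; (7) the post-trial
#' context event, with rumination before belief corrosion for temporal
#' shifts and a uniform reset for spatial shifts.
#'
#' @inheritParams compute_errors
#' @param post_event [context_event()] applied after the trial.
#' @param params [ls_params()].
#' @return A list with `state` (the updated learner) and the step record:
#'   `errors` and `state_predictions` for the states present at inference
#'   time, `marginal_prediction` (belief-weighted, using the post-inference
#'   beliefs), `norm_const`, `mean_sq_error`, `state_added`, and
#'   `new_state_index`.
#' @examples
#' st <- ls_learner("A")
#' out <- step_trial(st, expand_cues("A", "A"), 0.5)
#' out$errors
#' @export
step_trial <- function(state, cues, reward, post_event = context_event(),
                       params = ls_params()) {
  cues <- as_feature_vector(cues, state)

  # (1) inference inputs: errors and per-state predictions, pre-update
  errs <- compute_errors(state, cues, reward)
  preds <- as.vector(state$V %*% cues)

  # (2) belief filtering
  bel <- update_beliefs(state, errs, params)
  state <- bel$state
  marginal <- sum(state$p * preds)

  # (3) unexpected-uncertainty learning / change-point detection
  cand_q <- update_change_stat(state, bel$norm_const, params)
  state_added <- FALSE
  new_idx <- NA_integer_
  if (cand_q > params$nu && sum(cues^2) > 0) {
    if (n_states(state) < params$max_states) {
      state <- spawn_state(state, cues, reward, params)
      state_added <- TRUE
      new_idx <- n_states(state)
      ls_log("spawned latent state %d (candidate q = %g)", new_idx, cand_q)
    } else {
      state$q <- cand_q
      ls_log("state cap reached; spawn suppressed (candidate q = %g)", cand_q)
    }
  } else {
    state$q <- cand_q
  }
  # a just-spawned state predicts the current reward exactly: error 0
  full_errs <- if (state_added) c(errs, 0) else errs

  # (4) value learning, (5) effort update, (6) expected uncertainty
  state <- update_strengths(state, cues, full_errs, params)
  state <- update_effort(state, cues, params)
  msq <- sum(state$p * full_errs^2)
  state <- update_variance(state, full_errs, params)

  # (7) between-trial context
  if (post_event$kind == "temporal") {
    state <- ruminate(state, cues, reward, post_event, params)
    state <- apply_context_shift(state, post_event, params)
  } else if (post_event$kind == "spatial") {
    state <- apply_context_shift(state, post_event, params)
  }

  list(state = state, errors = errs, state_predictions = preds,
       marginal_prediction = marginal, norm_const = bel$norm_const,
       mean_sq_error = msq, state_added = state_added,
       new_state_index = new_idx)
}

#' Reported associative strength of a single raw cue
#'
#' The belief-weighted expected reward if the cue were presented alone
#' (interaction features are then zero, so this is the belief-weighted raw
#' coefficient). With `uncenter = TRUE` the value is shifted by `+1/2` onto
#' the uncentered 0/1 reward scale.
#'
#' @param state An `ls_state`.
#' @param cue_label A raw cue label in the learner's universe.
#' @param uncenter Shift by one half?
#' @return A single strength value.
#' @export
report_strength <- function(state, cue_label, uncenter = FALSE) {
  idx <- match(cue_label, state$universe)
  if (is.na(idx))
    stop(sprintf("unknown cue label: %s", cue_label), call. = FALSE)
  val <- sum(state$p * state$V[, idx])
  if (uncenter) val + 0.5 else val
}

#' @export
print.ls_state <- function(x, ...) {
  cat(sprintf("Latent-state learner: %d state(s) over %d feature(s)\n",
              n_states(x), x$dim))
  cat("  beliefs:", paste(format(round(x$p, 4)), collapse = " "), "\n")
  cat(sprintf("  sigma2 = %g, q = %g\n", x$sigma2, x$q))
  for (cue in x$universe)
    cat(sprintf("  strength(%s) = %g\n", cue, report_strength(x, cue)))
  invisible(x)
}
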