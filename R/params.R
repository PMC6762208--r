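#' Latent-state learner parameters
#'
#' Constructs and validates the parameter set of the latent-state learner.
#' Defaults are the fixed parameter values used for every simulated
#' experiment in the battery.
#'
#' @param alpha0 Associative-strength learning rate, in `[0, 1]`. Scales how
#'   strongly prediction errors move associative strengths (and how fast
#'   effort matrices track cue second moments).
#' @param beta0 Variance learning rate, in `[0, 1]`. Rate at which the pooled
#'   prediction-error variance `sigma^2` tracks the belief-averaged squared
#'   error.
#' @param gamma Latent-state transition parameter, in `[0, 1]`. The agent's
#'   assumed Markov chain stays in its current state with probability
#'   `1 - gamma * (L - 1) / L` and jumps to each other state with probability
#'   `gamma / L`.
#' @param sigma0 Initial reward standard deviation, `> 0`. The filter's
#'   initial expected uncertainty is `sigma0^2`.
#' @param nu Threshold for creating a new latent state, `> 0` (may be `Inf`
#'   to disable state creation). A state is spawned when the change statistic
#'   strictly exceeds `nu`.
#' @param delta Drift subtracted from the change statistic each trial, `> 0`.
#'   Larger values demand stronger evidence of model failure before a new
#'   state is added.
#' @param chi Rumination step count, non-negative integer. During a temporal
#'   context shift the value update is replayed `min(chi, ITI - 1)` times.
#' @param max_states Positive integer cap on the number of latent states.
#' @param include_interactions If `TRUE`, every unordered pair of raw cues
#'   contributes a product (interaction) feature.
#' @param center_rewards If `TRUE`, rewards are coded `+1/2` (reinforced) and
#'   `-1/2` (not reinforced) instead of `1`/`0`, so zero associative strength
#'   means a 50-50 reward expectation.
#'
#' @return An object of class `ls_params`.
#' @seealso [rw_params()] for the Rescorla-Wagner baseline parameters.
#' @examples
#' p <- ls_params()
#' p$alpha0
#' @export
ls_params <- function(alpha0 = 0.05, beta0 = 0.05, gamma = 0.05,
                      sigma0 = 0.5, nu = 0.2, delta = 0.6, chi = 5L,
                      max_states = 15L, include_interactions = TRUE,
                      center_rewards = TRUE) {
  check_unit_interval(alpha0, "alpha0")
  check_unit_interval(beta0, "beta0")
  check_unit_interval(gamma, "gamma")
  check_positive(sigma0, "sigma0")
  check_positive(nu, "nu", allow_inf = TRUE)
  check_positive(delta, "delta")
  check_count(chi, "chi")
  check_count(max_states, "max_states", min = 1L)
  check_flag(include_interactions, "include_interactions")
  check_flag(center_rewards, "center_rewards")
  structure(
    list(alpha0 = alpha0, beta0 = beta0, gamma = gamma, sigma0 = sigma0,
         nu = nu, delta = delta, chi = as.integer(chi),
         max_states = as.integer(max_states),
         include_interactions = include_interactions,
         center_rewards = center_rewards),
    class = "ls_params"
  )
}

#' Rescorla-Wagner baseline parameters
#'
#' @param alpha Constant learning rate, in `[0, 1]`.
#' @return An object of class `rw_params`.
#' @examples
#' rw_params()$alpha
#' @export
rw_params <- function(alpha = 0.15) {
  check_unit_interval(alpha, "alpha")
  structure(list(alpha = alpha), class = "rw_params")
}

#' @export
print.ls_params <- function(x, ...) {
  cat("Latent-state learner parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @export
print.rw_params <- function(x, ...) {
  cat(sprintf("Rescorla-Wagner parameters: alpha = %g\n", x$alpha))
  invisible(x)
}
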