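# Unit checks of the individual update operations against hand-derived
# values (standard-normal densities evaluated with dnorm).

two_state <- function(V1, V2, p = c(0.5, 0.5), sigma2 = 0.25, q = 0,
                      universe = c("A", "B")) {
  st <- ls_learner(universe, ls_params(include_interactions = FALSE))
  st$V <- rbind(V1, V2)
  dimnames(st$V) <- list(NULL, st$features)
  st$B <- list(diag(st$dim), diag(st$dim))
  st$p <- p
  st$sigma2 <- sigma2
  st$q <- q
  st
}

test_that("predictions are per-state inner products with a belief-weighted marginal", {
  st <- ls_learner(c("A", "B"), ls_params(include_interactions = FALSE))
  st$V[1, ] <- c(0.4, 0)
  out <- predict_rewards(st, c(1, 0))
  expect_equal(out$state_predictions, 0.4)
  expect_equal(out$marginal, 0.4)

  st2 <- two_state(c(0.2, 0), c(-0.2, 0))
  expect_equal(predict_rewards(st2, c(1, 0))$marginal, 0)

  st3 <- two_state(c(0.4, 0), c(0, 0), p = c(0.8808, 0.1192))
  expect_equal(predict_rewards(st3, c(1, 0))$marginal, 0.35232)
  expect_error(predict_rewards(st3, c(1, 0, 0)), "length")
})

test_that("errors are reward minus prediction from pre-update strengths", {
  st <- ls_learner(c("A", "B"))
  expect_equal(compute_errors(st, expand_cues("A", c("A", "B")), 0.5), 0.5)
  st2 <- two_state(c(0.5, 0), c(-0.5, 0))
  expect_equal(compute_errors(st2, c(1, 0), 0.5), c(0, 1))
  expect_equal(compute_errors(st2, c(1, 0), -0.5), c(-1, 0))
})

test_that("belief filtering matches the Gaussian-kernel posterior", {
  # L = 1 renormalizes to certainty no matter the error
  st1 <- ls_learner("A")
  expect_equal(update_beliefs(st1, 37, ls_params())$state$p, 1)

  # symmetric case stays symmetric
  st <- two_state(c(0, 0), c(0, 0))
  expect_equal(update_beliefs(st, c(0.3, 0.3))$state$p, c(0.5, 0.5))

  # asymmetric errors: p1 = phi(0) / (phi(0) + phi(2)) with sigma = 0.5
  out <- update_beliefs(st, c(0, 1))
  expect_equal(out$state$p,
               c(dnorm(0), dnorm(2)) / (dnorm(0) + dnorm(2)),
               tolerance = 1e-12)
  expect_equal(out$state$p[1], 0.88080, tolerance = 1e-4)
  expect_equal(out$norm_const, 0.5 * dnorm(0) + 0.5 * dnorm(2))
})

test_that("belief underflow falls back to the Markov prior with a clamped normalizer", {
  st <- two_state(c(0, 0), c(0, 0), p = c(0.7, 0.3), sigma2 = 1e-4)
  out <- update_beliefs(st, c(5, 5))  # |E|/sigma = 500: both kernels underflow
  prior <- 0.95 * c(0.7, 0.3) + 0.05 / 2
  expect_equal(out$state$p, prior)
  expect_identical(out$norm_const, 1e-300)
})

test_that("change statistic accumulates the log likelihood ratio minus drift", {
  st <- ls_learner("A")
  p <- ls_params()
  # perfectly predicted trial only drains the statistic
  expect_equal(update_change_stat(st, dnorm(0), p), 0)
  # single state with E/sigma = 2: log(phi(0)/phi(2)) = 2 exactly
  expect_equal(update_change_stat(st, dnorm(2), p), 1.4)
  st$q <- 5
  expect_equal(update_change_stat(st, dnorm(0), p), 4.4)
})

test_that("spawning initializes a state that predicts the current reward exactly", {
  st <- ls_learner(c("A", "B"), ls_params(include_interactions = FALSE))
  st$q <- 3
  out <- spawn_state(st, c(1, 0), 0.5)
  expect_equal(n_states(out), 2)
  expect_equal(unname(out$V[2, ]), c(0.5, 0))
  expect_equal(out$p, c(1, 0))
  expect_identical(out$q, 0)

  out2 <- spawn_state(st, c(1, 1), 0.5)
  expect_equal(unname(out2$V[2, ]), c(0.25, 0.25))
  expect_identical(sum(c(1, 1) * out2$V[2, ]), 0.5)

  expect_error(spawn_state(st, c(0, 0), 0.5), "all-zero")
  expect_error(spawn_state(st, c(1, 0), 0.5, ls_params(max_states = 1)),
               "cap")
})

test_that("value update scales the solved cue direction by belief and error", {
  st <- two_state(c(0.2, 0), c(0.1, 0), p = c(0, 1))
  # belief 0 or error 0 leave a component untouched
  upd <- update_strengths(st, c(1, 0), c(0.4, 0), ls_params())
  expect_equal(upd$V, st$V)
  # scalar case: delta V = alpha0 * p * B^{-1} c * E = 0.05 * 0.5
  st1 <- ls_learner("A")
  upd1 <- update_strengths(st1, 1, 0.5, ls_params())
  expect_equal(unname(upd1$V[1, 1]), 0.025)
  # singular effort matrix is reported by component
  st$B[[2]] <- matrix(0, 2, 2)
  expect_error(update_strengths(st, c(1, 0), c(0, 1), ls_params()),
               "state 2")
})

test_that("effort matrices decay toward the belief-weighted cue outer product", {
  p <- ls_params()
  st <- two_state(c(0, 0), c(0, 0), p = c(0, 1))
  upd <- update_effort(st, c(1, 1), p)
  expect_equal(upd$B[[1]], 0.95 * diag(2))          # p = 0: pure decay
  expect_equal(upd$B[[2]], matrix(c(1, 0.05, 0.05, 1), 2))
  # scalar fixed point: B = 1 with p = 1, c = 1
  st1 <- ls_learner("A")
  expect_equal(update_effort(st1, 1, p)$B[[1]], matrix(1))
})

test_that("pooled variance tracks the belief-averaged squared error with a floor", {
  p <- ls_params()
  st <- ls_learner("A")                              # sigma2 = 0.25
  expect_equal(update_variance(st, 0.5, p)$sigma2, 0.25)   # fixed point
  expect_equal(update_variance(st, 1, p)$sigma2, 0.2875)
  expect_equal(update_variance(st, 0, p)$sigma2, 0.95 * 0.25)
  st$sigma2 <- 1e-8
  expect_identical(update_variance(st, 0, p)$sigma2, 1e-8) # floored
})

test_that("context shifts corrode beliefs toward uniform", {
  p <- ls_params()
  st <- two_state(c(0, 0), c(0, 0), p = c(1, 0))
  expect_equal(apply_context_shift(st, context_event("temporal", 1), p)$p,
               c(1, 0))
  expect_equal(apply_context_shift(st, context_event("spatial"), p)$p,
               c(0.5, 0.5))
  out <- apply_context_shift(st, context_event("temporal", 3), p)
  expect_equal(out$p, c(0.95125, 0.04875))
  expect_error(apply_context_shift(st, context_event("none"), p), "temporal")
})

test_that("rumination replays the value update min(chi, ITI - 1) times", {
  p <- ls_params()
  st <- ls_learner("A")
  # ITI = 1: no iterations
  same <- ruminate(st, 1, 0.5, context_event("temporal", 1), p)
  expect_identical(same$V, st$V)
  # scalar contraction: V <- V + alpha0 (R - V), applied n times
  two <- ruminate(st, 1, 0.5, context_event("temporal", 3), p)
  expect_equal(unname(two$V[1, 1]), 0.5 * (1 - 0.95^2))
  # chi caps the count for long delays
  capped <- ruminate(st, 1, 0.5, context_event("temporal", 100), p)
  expect_equal(unname(capped$V[1, 1]), 0.5 * (1 - 0.95^5))
  expect_error(ruminate(st, 1, 0.5, context_event("spatial"), p), "temporal")
})

test_that("reported strength is the belief-weighted raw coefficient", {
  st <- two_state(c(0.4, 0), c(0, 0), p = c(0.8808, 0.1192))
  expect_equal(report_strength(st, "A"), 0.35232)
  expect_equal(report_strength(st, "A", uncenter = TRUE), 0.85232)
  st$p <- c(0.5, 0.5)
  expect_equal(report_strength(st, "A"), mean(st$V[, 1]))
  expect_error(report_strength(st, "Z"), "Z")
})
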