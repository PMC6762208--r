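#' Identifiers of the simulated conditioning experiments
#'
#' @return Character vector of the twelve experiment ids (partial
#'   reinforcement contributes two designs).
#' @export
experiment_ids <- function() {
  c("blocking", "overexpectation", "conditioned_inhibition", "wilson1992",
    "rescorla2000_1A", "rescorla2000_1B", "partial_reinforcement_1",
    "partial_reinforcement_2", "backwards_blocking", "renewal",
    "spontaneous_recovery", "memory_modification")
}

#' Build the canonical schedule(s) for one experiment
#'
#' Returns the experiment definition: one or more condition schedules over a
#' shared cue universe. Designs default to 20 trials per stage; alternating
#' stages cycle their trial types in strict deterministic alternation
#' starting with the reinforced type, so every build is reproducible.
#' `shuffle = TRUE` instead randomizes trial order within each
#' alternating stage under `seed`.
#'
#' The designs: blocking (A+ then AB+); overexpectation (A+/B+ interleaved
#' then AB+); conditioned inhibition (A+ interleaved with AB-); Wilson et al
#' 1992 (groups C and E alternate AB+/AB-, E replaces AB- by A- in the
#' middle stage, then A+ for both); Rescorla 2000 1A (A+/B- then AB+) and 1B
#' (A+/B- then AB-); partial reinforcement 1 (alternating A+/- vs continuous
#' A+, then extinction A-) and 2 (the same with an interposed continuous A+
#' block); backwards blocking (AX+ then A+); renewal (A+/A-/A+ with or
#' without a spatial context shift into and out of extinction); spontaneous
#' recovery (A+/A-/A+ with a long temporal delay before the final stage vs
#' an ITI-1 control); memory modification (A+, one retrieval trial A-, a
#' temporal delay of 1, 5 or 100, extinction A-, then a long delay before
#' test).
#'
#' @param id One of [experiment_ids()].
#' @param stage_lengths Optional numeric vector overriding the per-stage
#'   trial counts (recycled to the number of stages).
#' @param seed Integer seed; used only when `shuffle = TRUE`.
#' @param shuffle Randomize trial order within alternating stages?
#' @return List with `id`, `conditions` (named [ls_schedule()] objects) and
#'   `stage_lengths`.
#' @examples
#' def <- build_schedule("blocking")
#' names(def$conditions)
#' @export
build_schedule <- function(id, stage_lengths = NULL, seed = 1L,
                           shuffle = FALSE) {
  ids <- experiment_ids()
  if (!is.character(id) || length(id) != 1 || !(id %in% ids))
    stop(sprintf("unknown experiment id '%s'; valid ids: %s",
                 paste(id, collapse = ","), paste(ids, collapse = ", ")),
         call. = FALSE)
  n_stages <- switch(id,
    conditioned_inhibition = 1L,
    blocking = , rescorla2000_1A = , rescorla2000_1B = ,
    overexpectation = , partial_reinforcement_1 = ,
    backwards_blocking = 2L,
    3L)
  lens <- stage_default_lengths(id)
  if (!is.null(stage_lengths))
    lens <- as.integer(rep_len(stage_lengths, n_stages))
  builder <- switch(id,
    blocking = build_blocking,
    overexpectation = build_overexpectation,
    conditioned_inhibition = build_conditioned_inhibition,
    wilson1992 = build_wilson1992,
    rescorla2000_1A = function(l) build_rescorla2000(l, reinforced2 = TRUE),
    rescorla2000_1B = function(l) build_rescorla2000(l, reinforced2 = FALSE),
    partial_reinforcement_1 = function(l) build_partial(l, interposed = FALSE),
    partial_reinforcement_2 = function(l) build_partial(l, interposed = TRUE),
    backwards_blocking = build_backwards_blocking,
    renewal = build_renewal,
    spontaneous_recovery = build_spontaneous_recovery,
    memory_modification = build_memory_modification)
  conditions <- builder(lens)
  if (shuffle) conditions <- lapply(conditions, shuffle_within_phases, seed)
  list(id = id, conditions = conditions, stage_lengths = lens)
}

# Stage trial counts. Stages establishing associations run 20 presentations
# of each trial type (about two thirds of asymptote at alpha0 = 0.05);
# Wilson's alternation phases are brief so unpredictability, not effort-
# matrix degeneracy, drives stage-3 associability; memory modification uses
# a long acquisition so the to-be-modified memory is well consolidated.
stage_default_lengths <- function(id) {
  switch(id,
    blocking = c(20L, 20L),
    overexpectation = c(40L, 20L),
    conditioned_inhibition = 40L,
    wilson1992 = c(10L, 20L, 20L),
    rescorla2000_1A = , rescorla2000_1B = c(40L, 20L),
    partial_reinforcement_1 = c(40L, 20L),
    partial_reinforcement_2 = c(40L, 20L, 20L),
    backwards_blocking = c(20L, 20L),
    renewal = c(20L, 20L, 20L),
    spontaneous_recovery = c(20L, 20L, 20L),
    memory_modification = c(40L, 1L, 20L))
}

pat <- function(cues, reinforced) list(cues = cues, reinforced = reinforced)

build_blocking <- function(lens) {
  trials <- c(
    sched_block(list(pat("A", TRUE)), lens[1], "stage1"),
    sched_block(list(pat(c("A", "B"), TRUE)), lens[2], "stage2"))
  list(main = ls_schedule("blocking", trials, c("A", "B")))
}

build_overexpectation <- function(lens) {
  trials <- c(
    sched_block(list(pat("A", TRUE), pat("B", TRUE)), lens[1], "stage1"),
    sched_block(list(pat(c("A", "B"), TRUE)), lens[2], "stage2"))
  list(main = ls_schedule("overexpectation", trials, c("A", "B")))
}

build_conditioned_inhibition <- function(lens) {
  trials <- sched_block(list(pat("A", TRUE), pat(c("A", "B"), FALSE)),
                        lens[1], "stage1")
  list(main = ls_schedule("conditioned_inhibition", trials, c("A", "B")))
}

build_wilson1992 <- function(lens) {
  s1 <- sched_block(list(pat(c("A", "B"), TRUE), pat(c("A", "B"), FALSE)),
                    lens[1], "stage1")
  s2_c <- sched_block(list(pat(c("A", "B"), TRUE), pat(c("A", "B"), FALSE)),
                      lens[2], "stage2")
  s2_e <- sched_block(list(pat(c("A", "B"), TRUE), pat("A", FALSE)),
                      lens[2], "stage2")
  s3 <- sched_block(list(pat("A", TRUE)), lens[3], "stage3")
  list(C = ls_schedule("C", c(s1, s2_c, s3), c("A", "B")),
       E = ls_schedule("E", c(s1, s2_e, s3), c("A", "B")))
}

build_rescorla2000 <- function(lens, reinforced2) {
  trials <- c(
    sched_block(list(pat("A", TRUE), pat("B", FALSE)), lens[1], "stage1"),
    sched_block(list(pat(c("A", "B"), reinforced2)), lens[2], "stage2"))
  lab <- if (reinforced2) "rescorla2000_1A" else "rescorla2000_1B"
  list(main = ls_schedule(lab, trials, c("A", "B")))
}

build_partial <- function(lens, interposed) {
  mk <- function(label, stage1_patterns) {
    trials <- sched_block(stage1_patterns, lens[1], "stage1")
    ext_phase <- "stage2"
    if (interposed) {
      trials <- c(trials,
                  sched_block(list(pat("A", TRUE)), lens[2], "stage2"))
      ext_phase <- "stage3"
    }
    n_ext <- lens[length(lens)]
    trials <- c(trials,
                sched_block(list(pat("A", FALSE)), n_ext, ext_phase))
    ls_schedule(label, trials, "A")
  }
  list(partial = mk("partial", list(pat("A", TRUE), pat("A", FALSE))),
       continuous = mk("continuous", list(pat("A", TRUE))))
}

build_backwards_blocking <- function(lens) {
  trials <- c(
    sched_block(list(pat(c("A", "X"), TRUE)), lens[1], "stage1"),
    sched_block(list(pat("A", TRUE)), lens[2], "stage2"))
  list(main = ls_schedule("backwards_blocking", trials, c("A", "X")))
}

build_renewal <- function(lens) {
  same <- c(
    sched_block(list(pat("A", TRUE)), lens[1], "stage1"),
    sched_block(list(pat("A", FALSE)), lens[2], "stage2"),
    sched_block(list(pat("A", TRUE)), lens[3], "stage3"))
  shift <- c(
    sched_block(list(pat("A", TRUE)), lens[1], "stage1",
                final_event = context_event("spatial")),
    sched_block(list(pat("A", FALSE)), lens[2], "stage2",
                final_event = context_event("spatial")),
    sched_block(list(pat("A", TRUE)), lens[3], "stage3"))
  ctx_same <- rep("ctx1", sum(lens))
  ctx_shift <- c(rep("ctx1", lens[1]), rep("ctx2", lens[2]),
                 rep("ctx1", lens[3]))
  list(same = ls_schedule("same", same, "A", context_labels = ctx_same),
       shift = ls_schedule("shift", shift, "A", context_labels = ctx_shift))
}

build_spontaneous_recovery <- function(lens) {
  mk <- function(label, iti) {
    trials <- c(
      sched_block(list(pat("A", TRUE)), lens[1], "stage1"),
      sched_block(list(pat("A", FALSE)), lens[2], "stage2",
                  final_event = context_event("temporal", iti = iti)),
      sched_block(list(pat("A", TRUE)), lens[3], "stage3"))
    ls_schedule(label, trials, "A")
  }
  list(delay = mk("delay", 100L), control = mk("control", 1L))
}

build_memory_modification <- function(lens, delays = c(1L, 5L, 100L)) {
  mk <- function(delay) {
    trials <- c(
      sched_block(list(pat("A", TRUE)), lens[1], "stage1"),
      sched_block(list(pat("A", FALSE)), lens[2], "stage2",
                  final_event = context_event("temporal", iti = delay)),
      sched_block(list(pat("A", FALSE)), lens[3], "stage3",
                  final_event = context_event("temporal", iti = 100L)))
    ls_schedule(paste0("delay", delay), trials, "A")
  }
  stats::setNames(lapply(delays, mk), paste0("delay", delays))
}

shuffle_within_phases <- function(sched, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  phases <- vapply(sched$trials, function(tr) tr$phase, character(1))
  idx <- seq_along(sched$trials)
  for (ph in unique(phases)) {
    sel <- which(phases == ph)
    idx[sel] <- sel[sample.int(length(sel))]
  }
  # context events stay attached to their position in the block, not the
  # shuffled trial, so stage boundaries keep their shifts
  events <- lapply(sched$trials, function(tr) tr$post_event)
  trials <- sched$trials[idx]
  for (i in seq_along(trials)) trials[[i]]$post_event <- events[[i]]
  sched$trials <- trials
  sched
}

trajectory_row <- function(trial, condition, phase, strengths, prediction,
                           beliefs, n_states, sigma2, q, state_added,
                           max_states, cue_universe) {
  row <- data.frame(trial = trial, condition = condition, phase = phase,
                    stringsAsFactors = FALSE)
  for (cue in cue_universe)
    row[[paste0("strength_", cue)]] <- unname(strengths[cue])
  row$prediction <- prediction
  bel <- rep(NA_real_, max_states)
  bel[seq_along(beliefs)] <- beliefs
  for (l in seq_len(max_states)) row[[paste0("belief_", l)]] <- bel[l]
  row$n_states <- n_states
  row$sigma2 <- sigma2
  row$q <- q
  row$state_added <- state_added
  row
}

#' Run one condition schedule through a model
#'
#' Feeds the trials in order, applying each trial's post-trial context
#' event, and records one trajectory row per trial (the learner's state
#' after the full trial, context event included).
#'
#' @param sched An [ls_schedule()].
#' @param model `"latent_state"` or `"rescorla_wagner"`.
#' @param params [ls_params()] or [rw_params()] matching the model; `NULL`
#'   for defaults.
#' @return A `data.frame` with columns `trial`, `condition`, `phase`, one
#'   `strength_<cue>` column per raw cue (the reported associative
#'   strength), `prediction` (the trial's belief-weighted predicted reward),
#'   `belief_1..belief_<max_states>` (padded with `NA`), `n_states`,
#'   `sigma2`, `q`, and `state_added`.
#' @examples
#' def <- build_schedule("blocking")
#' traj <- run_schedule(def$conditions$main)
#' tail(traj[, c("trial", "strength_A", "strength_B")], 3)
#' @export
run_schedule <- function(sched, model = c("latent_state", "rescorla_wagner"),
                         params = NULL) {
  model <- match.arg(model)
  if (model == "rescorla_wagner") {
    if (is.null(params)) params <- rw_params()
    return(rw_run(sched, params))
  }
  if (is.null(params)) params <- ls_params()
  state <- ls_learner(sched$cue_universe, params)
  rows <- vector("list", length(sched$trials))
  for (i in seq_along(sched$trials)) {
    tr <- sched$trials[[i]]
    cues <- expand_cues(tr$cues, sched$cue_universe,
                        params$include_interactions)
    reward <- center_reward(tr$reinforced, params$center_rewards)
    out <- step_trial(state, cues, reward, tr$post_event, params)
    state <- out$state
    strengths <- vapply(sched$cue_universe,
                        function(cue) report_strength(state, cue),
                        numeric(1))
    rows[[i]] <- trajectory_row(
      trial = i, condition = sched$label, phase = tr$phase,
      strengths = strengths, prediction = out$marginal_prediction,
      beliefs = state$p, n_states = n_states(state),
      sigma2 = state$sigma2, q = state$q, state_added = out$state_added,
      max_states = params$max_states, cue_universe = sched$cue_universe)
  }
  do.call(rbind, rows)
}

phase_rows <- function(traj, phase) traj[traj$phase == phase, , drop = FALSE]

last_of <- function(traj, phase, col) {
  rows <- phase_rows(traj, phase)
  rows[[col]][nrow(rows)]
}

first_mean <- function(traj, phase, col, k = 3L) {
  rows <- phase_rows(traj, phase)
  mean(rows[[col]][seq_len(min(k, nrow(rows)))])
}

#' Directional effect check for one experiment
#'
#' Computes the experiment's signed statistic from the condition
#' trajectories and declares the effect reproduced when the statistic
#' strictly exceeds `margin`. Statistics are defined on the reported
#' associative strengths (the `strength_<cue>` columns) except where a
#' design calls for the predicted reward (renewal). See the methods
#' vignette for each definition.
#'
#' @param id One of [experiment_ids()].
#' @param trajectories Named list of trajectory `data.frame`s, one per
#'   condition of the experiment (as produced by [run_schedule()] on the
#'   conditions of [build_schedule()]).
#' @param margin Decision margin; strict inequality.
#' @return List of class `ls_effect` with `id`, `passed`, `statistic`,
#'   `margin`, and a `details` vector of named intermediate quantities (for
#'   renewal this includes the context-shift `secondary` statistic, which is
#'   reported alongside but does not gate `passed`).
#' @export
check_effect <- function(id, trajectories, margin = 0.01) {
  ids <- experiment_ids()
  if (!(id %in% ids))
    stop(sprintf("unknown experiment id '%s'; valid ids: %s", id,
                 paste(ids, collapse = ", ")), call. = FALSE)
  need <- names(build_schedule(id)$conditions)
  missing <- setdiff(need, names(trajectories))
  if (length(missing) > 0)
    stop(sprintf("missing condition trajectory(ies): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  details <- numeric(0)
  statistic <- switch(id,
    blocking = {
      tr <- trajectories$main
      last_of(tr, "stage2", "strength_A") - last_of(tr, "stage2", "strength_B")
    },
    overexpectation = {
      tr <- trajectories$main
      last_of(tr, "stage1", "strength_A") - last_of(tr, "stage2", "strength_A")
    },
    conditioned_inhibition = {
      tr <- trajectories$main
      a <- last_of(tr, "stage1", "strength_A")
      b <- last_of(tr, "stage1", "strength_B")
      details <- c(strength_A = a, strength_B = b)
      min(a, -b)
    },
    wilson1992 = {
      e <- mean(phase_rows(trajectories$E, "stage3")$strength_A)
      c_ <- mean(phase_rows(trajectories$C, "stage3")$strength_A)
      details <- c(group_E = e, group_C = c_)
      e - c_
    },
    rescorla2000_1A = {
      tr <- trajectories$main
      dA <- last_of(tr, "stage2", "strength_A") - last_of(tr, "stage1", "strength_A")
      dB <- last_of(tr, "stage2", "strength_B") - last_of(tr, "stage1", "strength_B")
      details <- c(delta_A = dA, delta_B = dB)
      dB - dA
    },
    rescorla2000_1B = {
      tr <- trajectories$main
      dA <- last_of(tr, "stage2", "strength_A") - last_of(tr, "stage1", "strength_A")
      dB <- last_of(tr, "stage2", "strength_B") - last_of(tr, "stage1", "strength_B")
      details <- c(delta_A = dA, delta_B = dB)
      abs(dA) - abs(dB)
    },
    partial_reinforcement_1 = ,
    partial_reinforcement_2 = {
      ext <- if (id == "partial_reinforcement_1") "stage2" else "stage3"
      p <- mean(phase_rows(trajectories$partial, ext)$strength_A)
      cont <- mean(phase_rows(trajectories$continuous, ext)$strength_A)
      details <- c(partial = p, continuous = cont)
      p - cont
    },
    backwards_blocking = {
      tr <- trajectories$main
      last_of(tr, "stage1", "strength_X") - last_of(tr, "stage2", "strength_X")
    },
    renewal = {
      reacq <- first_mean(trajectories$same, "stage3", "prediction")
      acq <- first_mean(trajectories$same, "stage1", "prediction")
      reacq_shift <- first_mean(trajectories$shift, "stage3", "prediction")
      details <- c(rapid_return = reacq - acq,
                   secondary = reacq_shift - reacq)
      reacq - acq
    },
    spontaneous_recovery = {
      d <- last_of(trajectories$delay, "stage2", "strength_A")
      ctl <- last_of(trajectories$control, "stage2", "strength_A")
      details <- c(delay = d, control = ctl)
      d - ctl
    },
    memory_modification = {
      t1 <- last_of(trajectories$delay1, "stage3", "strength_A")
      t5 <- last_of(trajectories$delay5, "stage3", "strength_A")
      t100 <- last_of(trajectories$delay100, "stage3", "strength_A")
      details <- c(test_delay1 = t1, test_delay5 = t5, test_delay100 = t100)
      min(t1, t100) - t5
    })
  structure(list(id = id, passed = statistic > margin,
                 statistic = statistic, margin = margin, details = details),
            class = "ls_effect")
}

#' Run the full simulation battery for one model
#'
#' Builds every experiment, runs all of its conditions through the chosen
#' model, and applies the directional effect check. Deterministic given
#' `seed` (the default designs are fully deterministic).
#'
#' @param model `"latent_state"` or `"rescorla_wagner"`.
#' @param params Model parameters; `NULL` for defaults.
#' @param margin Decision margin passed to [check_effect()].
#' @param stage_lengths Optional per-stage trial-count override applied to
#'   every experiment.
#' @param seed Integer seed (used only for shuffled designs).
#' @param shuffle Randomize trial order within alternating stages?
#' @return An object of class `ls_battery`: list with `model`, `margin`, and
#'   `results` (one `ls_effect` per experiment id).
#' @examples
#' \donttest{
#' rep <- run_battery("rescorla_wagner")
#' sum(vapply(rep$results, function(r) r$passed, logical(1)))
#' }
#' @export
run_battery <- function(model = c("latent_state", "rescorla_wagner"),
                        params = NULL, margin = 0.01, stage_lengths = NULL,
                        seed = 1L, shuffle = FALSE) {
  model <- match.arg(model)
  results <- lapply(experiment_ids(), function(id) {
    def <- build_schedule(id, stage_lengths = stage_lengths, seed = seed,
                          shuffle = shuffle)
    trajs <- lapply(def$conditions, run_schedule, model = model,
                    params = params)
    check_effect(id, trajs, margin = margin)
  })
  names(results) <- experiment_ids()
  structure(list(model = model, margin = margin, results = results),
            class = "ls_battery")
}

#' @export
print.ls_effect <- function(x, ...) {
  cat(sprintf("%-24s %s  statistic = %+.4f (margin %g)\n", x$id,
              if (x$passed) "PASS" else "FAIL", x$statistic, x$margin))
  invisible(x)
}

#' @export
print.ls_battery <- function(x, ...) {
  cat(sprintf("Simulation battery for model '%s' (margin %g):\n",
              x$model, x$margin))
  for (r in x$results)
    cat(sprintf("  %-24s %s  %+.4f\n", r$id,
                if (r$passed) "✔" else "✘", r$statistic))
  n <- sum(vapply(x$results, function(r) r$passed, logical(1)))
  cat(sprintf("  passed %d of %d\n", n, length(x$results)))
  invisible(x)
}
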