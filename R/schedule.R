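#' One trial of an experiment schedule
#'
#' @param cues Character vector of raw cue labels presented (non-empty).
#' @param reinforced Is the trial reinforced?
#' @param post_event [context_event()] applied after the trial.
#' @param phase Label of the experimental stage the trial belongs to.
#' @return An object of class `ls_trial`.
#' @export
trial_spec <- function(cues, reinforced, post_event = context_event(),
                       phase = "stage1") {
  if (!is.character(cues) || length(cues) < 1)
    stop("`cues` must be a non-empty character vector", call. = FALSE)
  check_flag(reinforced, "reinforced")
  structure(list(cues = cues, reinforced = reinforced,
                 post_event = post_event, phase = phase),
            class = "ls_trial")
}

#' An experiment condition as an ordered trial schedule
#'
#' @param label Condition name.
#' @param trials List of [trial_spec()] objects.
#' @param cue_universe Ordered character vector of raw cue labels; every
#'   trial's cues must be a subset.
#' @param context_labels Optional character vector, one spatial-context tag
#'   per trial, used by baselines that encode context as a cue.
#' @return An object of class `ls_schedule`.
#' @export
ls_schedule <- function(label, trials, cue_universe, context_labels = NULL) {
  for (tr in trials)
    if (!all(tr$cues %in% cue_universe))
      stop(sprintf("trial cues {%s} outside the cue universe {%s}",
                   paste(tr$cues, collapse = ","),
                   paste(cue_universe, collapse = ",")), call. = FALSE)
  if (!is.null(context_labels) && length(context_labels) != length(trials))
    stop("`context_labels` must have one entry per trial", call. = FALSE)
  structure(list(label = label, trials = trials,
                 cue_universe = cue_universe,
                 context_labels = context_labels),
            class = "ls_schedule")
}

# A block of n trials cycling deterministically through `patterns`, a list
# of list(cues=, reinforced=) templates. The final trial of the block can
# carry a context event.
sched_block <- function(patterns, n, phase, final_event = context_event()) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- patterns[[(i - 1L) %% length(patterns) + 1L]]
    ev <- if (i == n) final_event else context_event()
    out[[i]] <- trial_spec(p$cues, p$reinforced, post_event = ev,
                           phase = phase)
  }
  out
}

#' @export
print.ls_schedule <- function(x, ...) {
  cat(sprintf("Schedule '%s': %d trials over cues {%s}\n", x$label,
              length(x$trials), paste(x$cue_universe, collapse = ", ")))
  invisible(x)
}
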