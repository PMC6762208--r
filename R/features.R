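#' Canonical feature names for a cue universe
#'
#' Features are the raw cues in their declared order followed, when
#' interactions are enabled, by every unordered pair of distinct raw cues in
#' lexicographic order. Pair features are labelled `"A:B"` with the two cue
#' labels sorted.
#'
#' @param universe Character vector of raw cue labels (order is preserved for
#'   the raw block).
#' @param include_interactions Add pairwise product features?
#' @return Character vector of feature names.
#' @examples
#' feature_names(c("A", "B", "C"))
#' @export
feature_names <- function(universe, include_interactions = TRUE) {
  if (!is.character(universe) || length(universe) < 1 ||
      anyDuplicated(universe))
    stop("`universe` must be a character vector of distinct cue labels",
         call. = FALSE)
  nms <- universe
  if (include_interactions && length(universe) >= 2) {
    pairs <- utils::combn(sort(universe), 2)
    pair_labels <- paste(pairs[1, ], pairs[2, ], sep = ":")
    nms <- c(nms, sort(pair_labels))
  }
  nms
}

#' Expand raw cues into the model's feature vector
#'
#' Builds the feature vector for one trial: indicator (or real) loadings for
#' every raw cue in the universe, then, if enabled, one product feature per
#' unordered pair of raw cues. For indicator cues a pair feature is 1 exactly
#' when both members are present.
#'
#' @param raw_cues Either a character vector of present cue labels (each gets
#'   loading 1) or a named numeric vector of loadings.
#' @param universe Ordered character vector of all raw cue labels.
#' @param include_interactions Add pairwise product features?
#' @return Named numeric feature vector in canonical order.
#' @examples
#' expand_cues(c("A", "B"), c("A", "B", "C"))
#' @export
expand_cues <- function(raw_cues, universe, include_interactions = TRUE) {
  if (is.character(raw_cues)) {
    loadings <- stats::setNames(rep(1, length(raw_cues)), raw_cues)
  } else if (is.numeric(raw_cues) && !is.null(names(raw_cues))) {
    loadings <- raw_cues
  } else if (length(raw_cues) == 0) {
    loadings <- stats::setNames(numeric(0), character(0))
  } else {
    stop("`raw_cues` must be a character vector or a named numeric vector",
         call. = FALSE)
  }
  unknown <- setdiff(names(loadings), universe)
  if (length(unknown) > 0)
    stop(sprintf("unknown cue label(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  raw <- stats::setNames(rep(0, length(universe)), universe)
  raw[names(loadings)] <- loadings
  feats <- raw
  if (include_interactions && length(universe) >= 2) {
    pair_names <- setdiff(feature_names(universe, TRUE), universe)
    parts <- strsplit(pair_names, ":", fixed = TRUE)
    pair_vals <- vapply(parts, function(p) raw[[p[1]]] * raw[[p[2]]],
                        numeric(1))
    feats <- c(feats, stats::setNames(pair_vals, pair_names))
  }
  feats
}

#' Numeric reward coding for a trial
#'
#' With centering on, a reinforced trial is `+1/2` and a non-reinforced trial
#' is `-1/2`, so that zero associative strength corresponds to a neutral
#' 50-50 reward expectation. With centering off the coding is `1`/`0`.
#'
#' @param reinforced Was the trial reinforced?
#' @param center_rewards Use the centered coding?
#' @return A single reward value.
#' @examples
#' center_reward(TRUE)    # 0.5
#' center_reward(FALSE)   # -0.5
#' @export
center_reward <- function(reinforced, center_rewards = TRUE) {
  check_flag(reinforced, "reinforced")
  check_flag(center_rewards, "center_rewards")
  if (center_rewards) {
    if (reinforced) 0.5 else -0.5
  } else {
    if (reinforced) 1 else 0
  }
}

#' Between-trial context event
#'
#' Describes what happens between one trial and the next: nothing, a temporal
#' shift (a delay of `iti` trial-lengths, corroding beliefs toward uniform
#' and triggering rumination), or a spatial/visual shift (treated as an
#' infinite delay, resetting beliefs to uniform).
#'
#' @param kind One of `"none"`, `"temporal"`, `"spatial"`.
#' @param iti Positive integer inter-trial interval; meaningful only for
#'   temporal events.
#' @return An object of class `ls_context_event`.
#' @examples
#' context_event("temporal", iti = 100)
#' @export
context_event <- function(kind = c("none", "temporal", "spatial"), iti = 1L) {
  kind <- match.arg(kind)
  if (kind == "temporal") check_count(iti, "iti", min = 1L)
  structure(list(kind = kind, iti = as.integer(iti)),
            class = "ls_context_event")
}
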