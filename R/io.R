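ls_param_keys <- c("alpha0", "beta0", "gamma", "sigma0", "nu", "delta",
                   "chi", "max_states", "include_interactions",
                   "center_rewards")
rw_param_keys <- "alpha"
run_keys <- c("model", "experiment", "margin", "seed", "stage_lengths",
              "out", "verbose", "shuffle")

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration (a file path or inline text) and
#' resolves it against the default parameter values; omitted fields keep
#' their defaults and unknown keys are rejected. Recognized keys: `model`
#' (`"latent_state"` or `"rescorla_wagner"`), `experiment` (an experiment id
#' or `"battery"`), `margin`, `seed`, `stage_lengths`, `out`, `verbose`,
#' `shuffle`, the latent-state parameters (`alpha0`, `beta0`, `gamma`,
#' `sigma0`, `nu`, `delta`, `chi`, `max_states`, `include_interactions`,
#' `center_rewards`), and the baseline learning rate `alpha`.
#'
#' @param config A file path, or a character string of YAML/JSON.
#' @return An object of class `ls_config`: list with `model`, `experiment`,
#'   `params` ([ls_params()]), `rw` ([rw_params()]), `margin`, `seed`,
#'   `stage_lengths`, `out`, `verbose`, `shuffle`.
#' @examples
#' cfg <- load_config("alpha0: 0.1\nexperiment: blocking")
#' cfg$params$alpha0
#' @export
load_config <- function(config = "") {
  raw <- if (length(config) == 1 && !grepl("[:{\n]", config) &&
             nzchar(config) && file.exists(config)) {
    paste(readLines(config, warn = FALSE), collapse = "\n")
  } else {
    paste(config, collapse = "\n")
  }
  vals <- if (!nzchar(trimws(raw))) {
    list()
  } else if (grepl("^\\s*\\{", raw)) {
    jsonlite::fromJSON(raw, simplifyVector = TRUE)
  } else {
    tryCatch(yaml::yaml.load(raw),
             error = function(e)
               stop(sprintf("could not parse configuration: %s",
                            conditionMessage(e)), call. = FALSE))
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("configuration must be a mapping", call. = FALSE)
  known <- c(run_keys, ls_param_keys, rw_param_keys)
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)

  params <- do.call(ls_params, vals[intersect(names(vals), ls_param_keys)])
  rw <- do.call(rw_params, vals[intersect(names(vals), rw_param_keys)])
  model <- vals$model %||% "latent_state"
  if (!(model %in% c("latent_state", "rescorla_wagner")))
    stop("`model` must be 'latent_state' or 'rescorla_wagner'",
         call. = FALSE)
  experiment <- vals$experiment %||% "battery"
  if (!(experiment %in% c("battery", experiment_ids())))
    stop(sprintf("`experiment` must be 'battery' or one of: %s",
                 paste(experiment_ids(), collapse = ", ")), call. = FALSE)
  margin <- vals$margin %||% 0.01
  check_positive(margin, "margin")
  seed <- vals$seed %||% 1L
  check_count(seed, "seed")
  structure(
    list(model = model, experiment = experiment, params = params, rw = rw,
         margin = margin, seed = as.integer(seed),
         stage_lengths = vals$stage_lengths,
         out = vals$out %||% ".",
         verbose = isTRUE(vals$verbose),
         shuffle = isTRUE(vals$shuffle)),
    class = "ls_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run configuration to YAML
#'
#' Writes every resolved field (round-trips through [load_config()]).
#'
#' @param cfg An `ls_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  vals <- c(list(model = cfg$model, experiment = cfg$experiment,
                 margin = cfg$margin, seed = cfg$seed,
                 out = cfg$out, verbose = cfg$verbose,
                 shuffle = cfg$shuffle),
            unclass(cfg$params), list(alpha = cfg$rw$alpha))
  if (!is.null(cfg$stage_lengths)) vals$stage_lengths <- cfg$stage_lengths
  writeLines(yaml::as.yaml(vals), path)
  invisible(path)
}

num_cols <- function(df) names(df)[vapply(df, is.numeric, logical(1))]

#' Write a trajectory table as CSV
#'
#' Numeric columns are rendered with 17 significant digits so a read-back
#' reproduces every value bit-identically.
#'
#' @param trajectory Trajectory `data.frame` from [run_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- trajectory
  for (col in num_cols(out)) {
    v <- sprintf("%.17g", out[[col]])
    v[is.na(out[[col]])] <- ""
    out[[col]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path File path.
#' @return Trajectory `data.frame`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("trial", "n_states"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  for (col in grep("^belief_", names(df), value = TRUE))
    df[[col]] <- as.numeric(df[[col]])   # all-NA columns parse as logical
  if ("state_added" %in% names(df))
    df$state_added <- as.logical(df$state_added)
  df
}

#' Write a battery report as JSON
#'
#' One entry per experiment: id, pass flag, signed statistic and margin
#' (plus any named detail quantities such as renewal's secondary
#' context-shift statistic), in stable battery order.
#'
#' @param report An `ls_battery` from [run_battery()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  entries <- lapply(report$results, function(r) {
    e <- list(id = r$id, passed = r$passed, statistic = r$statistic,
              margin = r$margin)
    if (length(r$details) > 0) e$details <- as.list(r$details)
    e
  })
  doc <- list(model = report$model, margin = report$margin,
              results = unname(entries))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a battery report written by [write_report()]
#'
#' @param path File path.
#' @return List with `model`, `margin` and `results`.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
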