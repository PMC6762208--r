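# Internal argument checks and logging.

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single number in [0, 1], got %s",
                 name, format(x)), call. = FALSE)
  invisible(x)
}

check_positive <- function(x, name, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0 &&
    (allow_inf || is.finite(x))
  if (!ok)
    stop(sprintf("`%s` must be a single positive%s number, got %s",
                 name, if (allow_inf) "" else " finite", format(x)),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok)
    stop(sprintf("`%s` must be a single integer >= %d, got %s",
                 name, min, format(x)), call. = FALSE)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x))
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

# Diagnostic log stream (stderr). Enabled per call or via
# options(latentstate.verbose = TRUE).
ls_log <- function(..., verbose = getOption("latentstate.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[latentstate] ", sprintf(...))
  invisible(NULL)
}

# Numerical guards: density underflow floor for the belief normalizer and
# lower clamp for the pooled variance (see the methods vignette).
.l0_floor <- 1e-300
.sigma2_floor <- 1e-8
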