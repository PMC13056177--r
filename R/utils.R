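#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr unnest nest
#' @importFrom purrr map map_dbl map2 pmap imap list_rbind
#' @importFrom stats lm coef quantile median sd rnorm runif cor.test setNames
#' @importFrom utils head tail
NULL

# Boltzmann constant, J/K (exact, 2019 SI)
KB <- 1.380649e-23

abort_param <- function(msg) abort(msg, class = "ptmr_invalid_parameter")

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    abort_param(sprintf("`%s` must be a positive finite number (got %s).",
                        name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort_param(sprintf("`%s` must be non-negative and finite.", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort_param(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Package-level progress/filter logging; silenced via options(ptmr.verbose = FALSE).
ptmr_log <- function(fmt, ...) {
  if (isTRUE(getOption("ptmr.verbose", TRUE))) {
    inform(paste0("[ptmr] ", sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# Deterministic child seeds: all randomness in multi-stage simulations flows
# from one master seed.
child_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

is_tracks <- function(x) {
  is.data.frame(x) && all(c("particle", "frame", "x", "y") %in% names(x))
}

check_tracks <- function(tracks) {
  if (!is_tracks(tracks)) {
    abort_param("`tracks` must be a data frame with columns particle, frame, x, y.")
  }
  invisible(tracks)
}
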