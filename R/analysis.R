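#' Analysis configuration
#'
#' @param alpha Significance level for all tests (default 0.05).
#' @param stat Aggregation statistic, `"median"` (default) or `"mean"`.
#' @param transform `"log10"` (default), `"raw"`, or `"auto"` (choose by
#'   [choose_transform_family()]).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, stat = c("median", "mean"),
                            transform = c("log10", "raw", "auto")) {
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1)) {
    abort_param("`alpha` must lie in (0, 1).")
  }
  structure(list(alpha = alpha, stat = match.arg(stat),
                 transform = match.arg(transform)),
            class = "analysis_config")
}

#' Choose a distribution family by Anderson-Darling testing
#'
#' Runs the Anderson-Darling normality test on each ensemble of values both
#' raw and log10-transformed and selects the family with more non-rejections
#' at level `alpha`; ties go to log10 (viscosity and velocity ensembles are
#' typically right-skewed). Ensembles that are constant are skipped with a
#' flag; ensembles containing non-positive values count as rejections for the
#' log10 family.
#'
#' @param ensembles List of numeric vectors, each with at least 8 finite
#'   values.
#' @param alpha Significance level (default 0.05).
#' @return A list: `family` (`"log10"` or `"raw"`), `tests` (tibble with one
#'   row per ensemble: p-values under each family and `skipped`), and
#'   `non_rejections` (named counts).
#' @export
choose_transform_family <- function(ensembles, alpha = 0.05) {
  stopifnot(is.list(ensembles), length(ensembles) > 0)
  rows <- imap(ensembles, function(v, i) {
    v <- v[is.finite(v)]
    if (length(v) < 8L) {
      abort_param(sprintf(
        "Ensemble %s has %d finite values; the Anderson-Darling test needs >= 8.",
        i, length(v)))
    }
    if (sd(v) == 0) {
      return(tibble(ensemble = as.integer(i), p_raw = NA_real_,
                    p_log10 = NA_real_, skipped = TRUE))
    }
    p_raw <- nortest::ad.test(v)$p.value
    p_log10 <- if (all(v > 0) && sd(base::log10(v)) > 0) {
      nortest::ad.test(base::log10(v))$p.value
    } else {
      0 # cannot be lognormal
    }
    tibble(ensemble = as.integer(i), p_raw = p_raw, p_log10 = p_log10,
           skipped = FALSE)
  })
  tests <- list_rbind(rows)
  usable <- tests |> filter(!.data$skipped)
  if (nrow(usable) == 0L) {
    abort("All ensembles are constant; no family can be selected.",
          class = "ptmr_empty_input")
  }
  nr <- c(raw = sum(usable$p_raw > alpha),
          log10 = sum(usable$p_log10 > alpha))
  family <- if (nr["log10"] >= nr["raw"]) "log10" else "raw"
  if (any(tests$skipped)) {
    ptmr_log("choose_transform_family: %d constant ensembles skipped.",
             sum(tests$skipped))
  }
  list(family = family, tests = tests, non_rejections = nr)
}

#' Aggregate replicate measurements of one dilution point
#'
#' Replicate-level aggregation on the log10 scale: the summary of log10 eta*
#' and of log10 velocity across technical replicates, with non-positive
#' replicates excluded (and counted).
#'
#' @param eta_star Replicate complex viscosities, Pa s.
#' @param velocity Replicate velocity summaries, um/s (already per-replicate
#'   central values). Velocities may also be supplied directly on the log10
#'   scale via `velocity_log10 = TRUE`.
#' @param config An [analysis_config()].
#' @param velocity_log10 Set TRUE when `velocity` is already log10.
#' @return One-row tibble `(log_eta, log_v, n_eta, n_v, n_excluded)`; `log_*`
#'   are NA when a modality has no usable replicate.
#' @export
aggregate_dilution_point <- function(eta_star, velocity,
                                     config = analysis_config(),
                                     velocity_log10 = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  stat_fun <- if (config$stat == "median") median else mean
  agg <- function(v, logged) {
    if (!logged) {
      ok <- is.finite(v) & v > 0
      v <- base::log10(v[ok])
    } else {
      ok <- is.finite(v)
      v <- v[ok]
    }
    list(value = if (length(v) > 0) stat_fun(v) else NA_real_,
         n = length(v), excl = sum(!ok))
  }
  e <- agg(eta_star, FALSE)
  v <- agg(velocity, velocity_log10)
  if (e$excl + v$excl > 0) {
    ptmr_log("aggregate_dilution_point: excluded %d non-positive replicates.",
             e$excl + v$excl)
  }
  tibble(log_eta = e$value, log_v = v$value,
         n_eta = e$n, n_v = v$n, n_excluded = e$excl + v$excl)
}

#' Pearson correlation between log10 velocity and log10 eta*
#'
#' Pearson correlation (two-sided p-value from the t distribution on n - 2
#' degrees of freedom) together with the least-squares line of log10 velocity
#' on log10 eta*, over all aggregated animal-by-dilution points.
#'
#' @param points Tibble with columns `log_eta` and `log_v` (one row per
#'   animal-by-dilution point); rows with non-finite values are dropped.
#' @return An object of class `ptmr_correlation` with fields `r`, `p`,
#'   `slope`, `intercept`, `n`, `conf_int`; supports [generics::tidy()],
#'   [generics::glance()] and `print()`.
#' @export
correlate_log_values <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("log_eta", "log_v") %in% names(points)))
  pts <- points |> filter(is.finite(.data$log_eta), is.finite(.data$log_v))
  n <- nrow(pts)
  if (n < 3L) {
    abort("Pearson correlation needs at least 3 finite points.",
          class = "ptmr_empty_input")
  }
  if (sd(pts$log_eta) == 0 || sd(pts$log_v) == 0) {
    abort("Zero variance in log10 eta* or log10 velocity.",
          class = "ptmr_degenerate")
  }
  ct <- cor.test(pts$log_eta, pts$log_v, method = "pearson",
                 alternative = "two.sided")
  fit <- lm(log_v ~ log_eta, data = pts)
  structure(
    list(r = unname(ct$estimate), p = ct$p.value,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n = n, conf_int = as.numeric(ct$conf.int),
         data = pts),
    class = "ptmr_correlation"
  )
}

#' @export
print.ptmr_correlation <- function(x, ...) {
  cat(sprintf(
    "Pearson correlation of log10 velocity vs log10 eta*\n  r = %.4f, p = %.3g, n = %d\n  log10 v = %.4f %+.4f * log10 eta*\n",
    x$r, x$p, x$n, x$intercept, x$slope))
  invisible(x)
}

#' @rdname correlate_log_values
#' @param x,object A `ptmr_correlation`.
#' @param ... Unused.
#' @method tidy ptmr_correlation
#' @export
tidy.ptmr_correlation <- function(x, ...) {
  tibble(term = c("intercept", "log_eta"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname correlate_log_values
#' @method glance ptmr_correlation
#' @export
glance.ptmr_correlation <- function(x, ...) {
  tibble(r = x$r, p.value = x$p, n = x$n,
         conf.low = x$conf_int[1], conf.high = x$conf_int[2])
}

#' Fit a power law by log-log least squares
#'
#' Least-squares slope of log10(v) on log10(c). The reported `exponent` is
#' the slope magnitude, with the sign retained in `slope`; the standard error
#' comes from the regression.
#'
#' @param concentration Positive concentrations (or any positive predictor).
#' @param velocity Positive responses.
#' @return An object of class `ptmr_power_law` with `exponent`, `slope`,
#'   `se`, `intercept`, `n`, `r_squared`; supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_power_law <- function(concentration, velocity) {
  if (length(concentration) != length(velocity)) {
    abort_param("`concentration` and `velocity` must have equal length.")
  }
  bad <- which(!(is.finite(concentration) & concentration > 0 &
                   is.finite(velocity) & velocity > 0))
  if (length(bad) > 0) {
    abort_param(sprintf(
      "Power-law fit needs positive values; offending indices: %s.",
      paste(bad, collapse = ", ")))
  }
  if (length(concentration) < 3L) {
    abort("Power-law fit needs at least 3 points.", class = "ptmr_empty_input")
  }
  fit <- lm(lv ~ lc, data = list(lc = base::log10(concentration),
                                 lv = base::log10(velocity)))
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  structure(
    list(exponent = abs(slope), slope = slope,
         se = unname(sm$coefficients[2, 2]),
         intercept = unname(coef(fit)[1]),
         n = length(concentration), r_squared = sm$r.squared),
    class = "ptmr_power_law"
  )
}

#' @export
print.ptmr_power_law <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: v ~ c^%+.4f (exponent magnitude %.4f, SE %.4f, n = %d)\n",
    x$slope, x$exponent, x$se, x$n))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x,object A `ptmr_power_law`.
#' @param ... Unused.
#' @method tidy ptmr_power_law
#' @export
tidy.ptmr_power_law <- function(x, ...) {
  tibble(term = c("intercept", "log_c"),
         estimate = c(x$intercept, x$slope),
         std.error = c(NA_real_, x$se))
}

#' @rdname fit_power_law
#' @method glance ptmr_power_law
#' @export
glance.ptmr_power_law <- function(x, ...) {
  tibble(exponent = x$exponent, slope = x$slope, std.error = x$se,
         r.squared = x$r_squared, n = x$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
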