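#' Time-averaged mean squared displacement of one trajectory
#'
#' 2-D MSD at each integer-frame lag, averaged over all overlapping pairs of
#' observations. Frames missing from the trajectory (gaps bridged by linking
#' memory) simply contribute no pairs at the affected lags.
#'
#' @param track Tibble `(frame, x, y)` for a single particle (a `particle`
#'   column is ignored); coordinates in pixels or um.
#' @param frame_rate Acquisition rate, Hz.
#' @param pixel_size Calibration applied to coordinates, um/pixel; use 1 when
#'   positions are already in um.
#' @param max_lag_fraction Largest lag as a fraction of the track's frame
#'   span. Long lags average few pairs and are noisy; 0.3 is a common cap.
#' @param min_lag_frames Smallest lag, frames.
#' @return Tibble of class contract `msd_curve`: `(lag, msd, n_obs)` with
#'   `lag` in seconds (strictly increasing) and `msd` in um^2.
#' @export
#' @examples
#' tr <- tibble::tibble(frame = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
#' compute_msd(tr, frame_rate = 1, max_lag_fraction = 1)
compute_msd <- function(track, frame_rate, pixel_size = 1,
                        max_lag_fraction = 0.3, min_lag_frames = 1L) {
  stopifnot(is.data.frame(track), all(c("frame", "x", "y") %in% names(track)))
  check_positive(frame_rate, "frame_rate")
  check_positive(pixel_size, "pixel_size")
  if ("particle" %in% names(track) && length(unique(track$particle)) > 1L) {
    abort_param("`track` must contain a single particle; see ensemble_msd().")
  }
  track <- track |> arrange(.data$frame)
  if (nrow(track) < 2L) {
    abort("MSD requires a trajectory of at least 2 points.",
          class = "ptmr_short_track")
  }
  f <- as.integer(track$frame)
  if (anyDuplicated(f)) abort_param("Trajectory has duplicated frames.")
  x <- track$x * pixel_size
  y <- track$y * pixel_size
  span <- max(f) - min(f)
  max_lag <- max(min_lag_frames, floor(max_lag_fraction * span))
  lags <- min_lag_frames:min(max_lag, span)
  j <- matrix(match(outer(f, lags, `+`), f), length(f), length(lags))
  d2 <- (x[j] - x)^2 + (y[j] - y)^2 # NA where the partner frame is absent
  dim(d2) <- dim(j)
  n_obs <- colSums(!is.na(j))
  msd <- colMeans(d2, na.rm = TRUE)
  keep <- n_obs > 0L
  if (!any(keep)) {
    abort("No displacement pairs available at the requested lags.",
          class = "ptmr_short_track")
  }
  tibble(lag = lags[keep] / frame_rate, msd = msd[keep],
         n_obs = as.integer(n_obs[keep]))
}

#' Ensemble-average MSD curves
#'
#' Per-lag mean of per-track MSD values weighted by the number of
#' displacement pairs, over the intersection of the lag grids; the combined
#' `n_obs` is the sum.
#'
#' @param curves List of MSD tibbles from [compute_msd()], or one tibble with
#'   a `particle` column.
#' @param grid `"intersection"` (default): only lags present in every curve
#'   are reported; `"union"`: every observed lag is reported, averaging over
#'   the curves that reach it (useful when linking fragments tracks into
#'   unequal lengths).
#' @param min_n_obs Drop lags whose combined `n_obs` falls below this count.
#' @return One MSD tibble `(lag, msd, n_obs)`.
#' @export
ensemble_msd <- function(curves, grid = c("intersection", "union"),
                         min_n_obs = 1L) {
  grid <- match.arg(grid)
  if (is.data.frame(curves)) {
    curves <- if ("particle" %in% names(curves)) {
      curves |> group_by(.data$particle) |> group_split(.keep = FALSE)
    } else {
      list(curves)
    }
  }
  if (length(curves) == 0L) {
    abort("ensemble_msd() needs at least one curve.", class = "ptmr_empty_input")
  }
  if (grid == "intersection") {
    common <- Reduce(intersect, map(curves, function(cv) cv$lag))
    if (length(common) == 0L) {
      abort("MSD curves share no common lags.", class = "ptmr_empty_input")
    }
    stacked <- list_rbind(map(curves, function(cv) cv[cv$lag %in% common, ]))
  } else {
    stacked <- list_rbind(curves)
  }
  out <- stacked |>
    group_by(.data$lag) |>
    summarise(msd = sum(.data$msd * .data$n_obs) / sum(.data$n_obs),
              n_obs = sum(.data$n_obs), .groups = "drop") |>
    filter(.data$n_obs >= min_n_obs) |>
    arrange(.data$lag)
  if (nrow(out) == 0L) {
    abort("No lags satisfy the ensemble n_obs requirement.",
          class = "ptmr_empty_input")
  }
  out
}

#' Subtract common-mode drift from simultaneous trajectories
#'
#' Estimates per-frame ensemble mean displacement from all trajectories
#' observed across each frame transition and subtracts the accumulated drift
#' from every position. Transitions with fewer than `min_tracks` simultaneous
#' trajectories contribute zero drift. Intended for beads (thermal motion);
#' sperm tracks should not be drift-corrected since directed motion is the
#' signal.
#'
#' @param tracks Tibble `(particle, frame, x, y)`.
#' @param min_tracks Minimum simultaneous tracks for a transition estimate.
#' @return Tracks tibble with drift-corrected `x`, `y`.
#' @export
correct_drift <- function(tracks, min_tracks = 5L) {
  check_tracks(tracks)
  if (nrow(tracks) == 0L) return(tracks)
  steps <- tracks |>
    group_by(.data$particle) |>
    arrange(.data$frame, .by_group = TRUE) |>
    mutate(dx = .data$x - lag(.data$x), dy = .data$y - lag(.data$y),
           dframe = .data$frame - lag(.data$frame)) |>
    ungroup() |>
    filter(.data$dframe == 1)
  per_frame <- steps |>
    group_by(.data$frame) |>
    summarise(mdx = mean(.data$dx), mdy = mean(.data$dy), n = n(),
              .groups = "drop") |>
    mutate(mdx = ifelse(.data$n >= min_tracks, .data$mdx, 0),
           mdy = ifelse(.data$n >= min_tracks, .data$mdy, 0))
  all_frames <- tibble(frame = seq(min(tracks$frame), max(tracks$frame))) |>
    left_join(per_frame, by = "frame") |>
    mutate(across(c("mdx", "mdy"), ~ tidyr::replace_na(.x, 0)),
           drift_x = cumsum(.data$mdx), drift_y = cumsum(.data$mdy))
  tracks |>
    left_join(all_frames |> select("frame", "drift_x", "drift_y"),
              by = "frame") |>
    mutate(x = .data$x - .data$drift_x, y = .data$y - .data$drift_y) |>
    select(-"drift_x", -"drift_y")
}
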