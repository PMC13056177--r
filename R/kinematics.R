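#' CASA-style kinematics of one trajectory
#'
#' Computes the standard computer-assisted sperm analysis metrics:
#' * `vsl` straight-line velocity: net first-to-last displacement over the
#'   recorded duration;
#' * `vcl` curvilinear velocity: summed point-to-point path length over the
#'   duration;
#' * `vap` average-path velocity: path length of a centered moving-average
#'   smooth of the raw path (window `vap_window` points, ends padded by
#'   anti-symmetric reflection so straight paths smooth to themselves) over
#'   the duration;
#' * `lin` = VSL/VCL, `str` = VSL/VAP;
#' * `alh` amplitude of lateral head displacement: twice the mean (or with
#'   `alh_method = "max"`, twice the maximum) absolute deviation of the raw
#'   path from the average path, measured perpendicular to the local
#'   average-path direction.
#'
#' Duration is `(last_frame - first_frame) / frame_rate`. All outputs are in
#' um and seconds.
#'
#' @param track Tibble `(frame, x, y)` of a single particle.
#' @param frame_rate Acquisition rate, Hz.
#' @param pixel_size um/pixel calibration (1 if positions are in um).
#' @param vap_window Moving-average window, points (default 5, about one
#'   head-oscillation period at 20 fps).
#' @param alh_method `"mean"` (default) or `"max"`; CASA vendors differ.
#' @return One-row tibble
#'   `(duration, vsl, vcl, vap, lin, str, alh, n_points)`.
#' @export
#' @examples
#' zig <- tibble::tibble(frame = 0:4, x = 0:4, y = c(0, 1, 0, 1, 0))
#' track_kinematics(zig, frame_rate = 1)
track_kinematics <- function(track, frame_rate, pixel_size = 1,
                             vap_window = 5L, alh_method = c("mean", "max")) {
  alh_method <- match.arg(alh_method)
  stopifnot(is.data.frame(track), all(c("frame", "x", "y") %in% names(track)))
  check_positive(frame_rate, "frame_rate")
  if ("particle" %in% names(track) && length(unique(track$particle)) > 1L) {
    abort_param("`track` must contain a single particle; see sperm_kinematics().")
  }
  track <- track |> arrange(.data$frame)
  n <- nrow(track)
  duration <- (max(track$frame) - min(track$frame)) / frame_rate
  if (n < 2L || duration <= 0) {
    abort("Kinematics require a trajectory spanning positive duration.",
          class = "ptmr_short_track")
  }
  x <- track$x * pixel_size
  y <- track$y * pixel_size
  vsl <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2) / duration
  vcl <- sum(sqrt(diff(x)^2 + diff(y)^2)) / duration

  # centered moving average with anti-symmetric (value-reflecting) edge
  # padding, which preserves linear trends exactly: a straight path smooths
  # to itself, so VAP = VSL on straight tracks
  half <- max(0L, (check_count(vap_window, "vap_window") - 1L) %/% 2L)
  smooth1 <- function(v) {
    vapply(seq_len(n), function(i) {
      idx <- (i - half):(i + half)
      vals <- numeric(length(idx))
      lo <- idx < 1L; hi <- idx > n; mid <- !lo & !hi
      vals[mid] <- v[idx[mid]]
      vals[lo] <- 2 * v[1] - v[pmin(n, 2L - idx[lo])]
      vals[hi] <- 2 * v[n] - v[pmax(1L, 2L * n - idx[hi])]
      mean(vals)
    }, numeric(1))
  }
  sx <- smooth1(x); sy <- smooth1(y)
  vap <- sum(sqrt(diff(sx)^2 + diff(sy)^2)) / duration

  # perpendicular deviation of raw path from the average path
  tx <- ty <- numeric(n)
  tx[1] <- sx[2] - sx[1]; tx[n] <- sx[n] - sx[n - 1]
  ty[1] <- sy[2] - sy[1]; ty[n] <- sy[n] - sy[n - 1]
  if (n > 2L) {
    tx[2:(n - 1)] <- sx[3:n] - sx[1:(n - 2)]
    ty[2:(n - 1)] <- sy[3:n] - sy[1:(n - 2)]
  }
  tangent <- cbind(tx, ty)
  tnorm <- sqrt(rowSums(tangent^2))
  dev_x <- x - sx; dev_y <- y - sy
  perp <- ifelse(tnorm > 0,
                 (dev_x * -tangent[, 2] + dev_y * tangent[, 1]) / tnorm,
                 sqrt(dev_x^2 + dev_y^2))
  alh <- if (alh_method == "mean") 2 * mean(abs(perp)) else 2 * max(abs(perp))

  tibble(
    duration = duration, vsl = vsl, vcl = vcl, vap = vap,
    lin = ifelse(vcl > 0, vsl / vcl, NA_real_),
    str = ifelse(vap > 0, vsl / vap, NA_real_),
    alh = alh, n_points = n
  )
}

#' Kinematics for every trajectory in a track table
#'
#' @param tracks Tibble `(particle, frame, x, y)`.
#' @inheritParams track_kinematics
#' @return Tibble with one row per particle: `particle` plus the
#'   [track_kinematics()] columns.
#' @export
sperm_kinematics <- function(tracks, frame_rate, pixel_size = 1,
                             vap_window = 5L, alh_method = c("mean", "max")) {
  check_tracks(tracks)
  alh_method <- match.arg(alh_method)
  tracks |>
    group_by(.data$particle) |>
    group_modify(~ track_kinematics(.x, frame_rate = frame_rate,
                                    pixel_size = pixel_size,
                                    vap_window = vap_window,
                                    alh_method = alh_method)) |>
    ungroup()
}

#' Summarize per-track kinematics for one sample
#'
#' Central tendency of (optionally log10) VSL plus dispersion and counts.
#' Non-finite values (e.g. log10 of a zero-VSL track) are excluded and
#' counted.
#'
#' @param records Tibble from [sperm_kinematics()] (needs a `vsl` column).
#' @param stat `"median"` (default) or `"mean"`.
#' @param log10 Summarize log10 VSL (default TRUE, matching the analysis
#'   chain's log-scale aggregation).
#' @return One-row tibble `(vsl_center, vsl_spread, n, n_excluded, stat,
#'   log10)`; `vsl_center` is on the log10 scale when `log10 = TRUE`.
#' @export
summarize_kinematics <- function(records, stat = c("median", "mean"),
                                 log10 = TRUE) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(records), "vsl" %in% names(records))
  if (nrow(records) == 0L) {
    abort("summarize_kinematics() needs at least one record.",
          class = "ptmr_empty_input")
  }
  v <- if (log10) base::log10(records$vsl) else records$vsl
  ok <- is.finite(v)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    ptmr_log("summarize_kinematics: excluded %d non-finite values.", n_excluded)
  }
  v <- v[ok]
  if (length(v) == 0L) {
    abort("No finite VSL values to summarize.", class = "ptmr_empty_input")
  }
  center <- if (stat == "median") median(v) else mean(v)
  tibble(
    vsl_center = center,
    vsl_spread = if (length(v) > 1L) sd(v) else 0,
    n = length(v), n_excluded = n_excluded,
    stat = stat, log10 = log10
  )
}
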