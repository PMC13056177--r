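#' Viscoelastic spectrum from an MSD curve (generalized Stokes-Einstein)
#'
#' Mason-style local power-law inversion of the generalized Stokes-Einstein
#' relation. For each lag tau the probing frequency is omega = 1/tau; the
#' local logarithmic slope alpha(omega) = d ln MSD / d ln tau is estimated by
#' a quadratic fit in log-log space over a centered window (edge-truncated)
#' and clipped to [0, 1] (1 = purely viscous, 0 = purely elastic). The
#' modulus is
#' \deqn{|G*(\omega)| = k_B T / (\pi a \cdot f_d \cdot MSD(\tau) \cdot
#'   \Gamma[1 + \alpha(\omega)])}
#' with `f_d = dimensionality_factor` converting the 2-D MSD to its 3-D
#' equivalent (default 3/2, i.e. the familiar
#' `2 k_B T / (3 pi a MSD Gamma)` form, under which a Newtonian fluid
#' recovers eta*(omega) = eta exactly). G' = |G*| cos(pi alpha / 2),
#' G'' = |G*| sin(pi alpha / 2), eta* = |G*| / omega.
#'
#' @param msd MSD tibble `(lag, msd, n_obs)` with `msd` in um^2.
#' @param params A [rheo_params()].
#' @param dimensionality_factor Multiplier applied to the measured MSD before
#'   the 3-D inversion; 3/2 for a 2-D MSD.
#' @param alpha_window Window (points) of the local log-log slope fit.
#' @return Tibble `(omega, lag, alpha, G_mod, G_prime, G_dprime, eta_star)`
#'   sorted by increasing omega; omega in rad/s, moduli in Pa, eta* in Pa s.
#' @export
gser_spectrum <- function(msd, params = rheo_params(),
                          dimensionality_factor = 3 / 2,
                          alpha_window = 5L) {
  stopifnot(is.data.frame(msd), all(c("lag", "msd") %in% names(msd)))
  stopifnot(inherits(params, "rheo_params"))
  check_positive(dimensionality_factor, "dimensionality_factor")
  alpha_window <- check_count(alpha_window, "alpha_window", min = 2L)

  bad <- !is.finite(msd$msd) | msd$msd <= 0
  if (any(bad)) {
    warn(sprintf("gser_spectrum: excluding %d lags with non-positive MSD.",
                 sum(bad)))
    msd <- msd[!bad, , drop = FALSE]
  }
  if (nrow(msd) == 0L) {
    abort("No usable lags: all MSD values are non-positive.",
          class = "ptmr_empty_input")
  }
  msd <- msd |> arrange(.data$lag)
  lt <- log(msd$lag)
  lm_ <- log(msd$msd)
  n <- length(lt)
  half <- alpha_window %/% 2L

  alpha_raw <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    if (length(idx) < 2L) return(NA_real_)
    if (length(idx) == 2L) {
      return(diff(lm_[idx]) / diff(lt[idx]))
    }
    fit <- lm(y ~ x + I(x^2), data = list(x = lt[idx], y = lm_[idx]))
    unname(coef(fit)[2] + 2 * coef(fit)[3] * lt[i])
  }, numeric(1))

  n_super <- sum(alpha_raw > 1 + 1e-6, na.rm = TRUE)
  n_sub <- sum(alpha_raw < 0, na.rm = TRUE)
  if (n_super > 0) {
    warn(sprintf("gser_spectrum: %d superdiffusive log-slopes (> 1) clipped to 1.",
                 n_super))
  }
  if (n_sub > 0) {
    ptmr_log("gser_spectrum: %d negative log-slopes clipped to 0.", n_sub)
  }
  alpha <- pmin(pmax(alpha_raw, 0), 1)

  kT <- params$kB * params$temperature
  msd_m2 <- msd$msd * 1e-12
  G_mod <- kT / (pi * params$bead_radius * dimensionality_factor * msd_m2 *
                   gamma(1 + alpha))
  omega <- 1 / msd$lag
  tibble(
    omega = omega, lag = msd$lag, alpha = alpha,
    G_mod = G_mod,
    G_prime = G_mod * cos(pi * alpha / 2),
    G_dprime = G_mod * sin(pi * alpha / 2),
    eta_star = G_mod / omega
  ) |>
    arrange(.data$omega)
}

#' Complex viscosity at a reference frequency
#'
#' Log-log linear interpolation of eta*(omega) at `omega_ref`. The default
#' reference is 1 Hz (omega = 2*pi rad/s).
#'
#' @param spectrum Tibble from [gser_spectrum()].
#' @param omega_ref Reference angular frequency, rad/s; must lie within the
#'   spectrum's omega range.
#' @return eta* at `omega_ref`, Pa s.
#' @export
eta_star_at <- function(spectrum, omega_ref = 2 * pi) {
  stopifnot(is.data.frame(spectrum),
            all(c("omega", "eta_star") %in% names(spectrum)))
  check_positive(omega_ref, "omega_ref")
  rng <- range(spectrum$omega)
  if (omega_ref < rng[1] || omega_ref > rng[2]) {
    abort(sprintf(
      "omega_ref = %.4g rad/s lies outside the spectrum range [%.4g, %.4g].",
      omega_ref, rng[1], rng[2]), class = "ptmr_out_of_range")
  }
  sp <- spectrum |> arrange(.data$omega)
  10^stats::approx(log10(sp$omega), log10(sp$eta_star),
                   xout = log10(omega_ref), ties = mean)$y
}

#' Complex viscosity of a bead track set
#'
#' Convenience chain for one acquisition: optional drift correction, per-track
#' MSD, ensemble average, GSER inversion, and eta* at the reference frequency.
#'
#' @param tracks Tibble `(particle, frame, x, y)`.
#' @param frame_rate Acquisition rate, Hz.
#' @param params A [rheo_params()].
#' @param pixel_size um/pixel calibration (1 if positions are in um).
#' @param omega_ref Reference angular frequency, rad/s (default 1 Hz).
#' @param drift_correct Subtract common-mode drift first (default TRUE; beads
#'   only).
#' @param min_track_length Minimum points per track used.
#' @param max_lag_fraction,min_lag_frames Lag window passed to
#'   [compute_msd()]; the defaults skip the two shortest lags (noise-
#'   dominated) and poorly averaged long lags.
#' @param subtract_static_error Subtract the ensemble MSD's short-lag
#'   intercept (an estimate of the 4 sigma^2 static localization floor)
#'   before the GSER inversion. Off by default: it requires trusting the
#'   shortest lags, and no immobilized-bead calibration backs it.
#' @return A list: `eta_star` (Pa s at `omega_ref`), `spectrum`, `msd`,
#'   `n_tracks`, `omega_range`, `temperature`.
#' @export
eta_star_from_tracks <- function(tracks, frame_rate, params = rheo_params(),
                                 pixel_size = 1, omega_ref = 2 * pi,
                                 drift_correct = TRUE,
                                 min_track_length = 10L,
                                 max_lag_fraction = 0.3,
                                 min_lag_frames = 3L,
                                 subtract_static_error = FALSE) {
  check_tracks(tracks)
  if (drift_correct) tracks <- correct_drift(tracks)
  per_track <- tracks |>
    group_by(.data$particle) |>
    filter(n() >= min_track_length) |>
    group_split()
  if (length(per_track) == 0L) {
    abort("No tracks long enough for MSD analysis.", class = "ptmr_empty_input")
  }
  curves <- map(per_track, function(tr) {
    compute_msd(tr, frame_rate = frame_rate, pixel_size = pixel_size,
                max_lag_fraction = max_lag_fraction,
                min_lag_frames = min_lag_frames)
  })
  # union grid: linking can fragment tracks into unequal lengths, and the
  # intersection would then be dictated by the shortest fragment
  ens <- ensemble_msd(curves, grid = "union", min_n_obs = 10L)
  if (subtract_static_error && nrow(ens) >= 4L) {
    fit <- lm(msd ~ lag, data = head(ens, 5L))
    intercept <- max(0, unname(coef(fit)[1]))
    corrected <- ens$msd - intercept
    keep <- corrected > 0
    if (sum(keep) >= 2L) {
      ens <- ens[keep, , drop = FALSE]
      ens$msd <- corrected[keep]
      ptmr_log("eta_star_from_tracks: subtracted static-error intercept %.3g um^2.",
               intercept)
    }
  }
  spec <- suppressWarnings(gser_spectrum(ens, params))
  list(
    eta_star = eta_star_at(spec, omega_ref),
    spectrum = spec, msd = ens, n_tracks = length(per_track),
    omega_range = range(spec$omega), temperature = params$temperature
  )
}
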