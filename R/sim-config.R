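#' Thermodynamic parameters for microrheology
#'
#' Bundles the quantities entering the Stokes-Einstein relation and the
#' generalized Stokes-Einstein inversion: absolute temperature, tracer bead
#' radius, and the Boltzmann constant (fixed at its exact SI value).
#'
#' @param temperature Absolute temperature in kelvin. Default 293.15 K (20 C),
#'   consistent with a water-like buffer viscosity of 1e-3 Pa s; measurement
#'   temperature should be supplied when known since eta* scales linearly
#'   with the assumed T.
#' @param bead_radius Tracer bead radius in meters. Default 0.5e-6 (1 um
#'   diameter carboxylated polystyrene beads).
#'
#' @return A list of class `rheo_params` with fields `temperature`,
#'   `bead_radius`, `kB`.
#' @export
#' @examples
#' rheo_params()
rheo_params <- function(temperature = 293.15, bead_radius = 0.5e-6) {
  check_positive(temperature, "temperature")
  check_positive(bead_radius, "bead_radius")
  structure(
    list(temperature = temperature, bead_radius = bead_radius, kB = KB),
    class = "rheo_params"
  )
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = kB * T / (6 * pi * eta * a) for a sphere of radius a in a Newtonian
#' fluid of viscosity eta, returned in um^2/s.
#'
#' @param params A [rheo_params()] object.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return Diffusion coefficient in um^2/s.
#' @export
#' @examples
#' stokes_einstein_D(rheo_params(), viscosity = 1e-3) # ~0.43 um^2/s in water
stokes_einstein_D <- function(params, viscosity) {
  stopifnot(inherits(params, "rheo_params"))
  check_positive(viscosity, "viscosity")
  d_m2 <- params$kB * params$temperature /
    (6 * pi * viscosity * params$bead_radius)
  d_m2 * 1e12
}

#' Bead simulation configuration
#'
#' Settings for Brownian-dynamics simulation of tracer beads, mirroring the
#' PTMR acquisition regime (10 s at 30 frames per second by default).
#'
#' @param viscosity Newtonian viscosity of the medium, Pa s.
#' @param rheo A [rheo_params()] object.
#' @param n_particles Number of beads.
#' @param duration Recording duration, seconds.
#' @param frame_rate Acquisition rate, Hz.
#' @param localization_noise_sd Per-axis Gaussian localization error added to
#'   *reported* (not true) positions, um. Adds 4*sd^2 to the 2-D MSD.
#' @param drift_velocity Constant drift, um/s, length-2 `(vx, vy)` or scalar
#'   applied to both axes.
#' @param arena Field-of-view size `(width, height)` in um within which
#'   initial positions are drawn uniformly (with `margin`).
#' @param margin Margin from the arena edge for initial positions, um.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `bead_sim_config`.
#' @export
bead_sim_config <- function(viscosity = 1e-3,
                            rheo = rheo_params(),
                            n_particles = 100L,
                            duration = 10,
                            frame_rate = 30,
                            localization_noise_sd = 0.01,
                            drift_velocity = c(0, 0),
                            arena = c(25.6, 25.6),
                            margin = 4,
                            seed = 1L) {
  check_positive(viscosity, "viscosity")
  stopifnot(inherits(rheo, "rheo_params"))
  n_particles <- check_count(n_particles, "n_particles")
  check_positive(duration, "duration")
  check_positive(frame_rate, "frame_rate")
  check_nonneg(localization_noise_sd, "localization_noise_sd")
  if (length(drift_velocity) == 1L) drift_velocity <- rep(drift_velocity, 2L)
  check_positive(arena, "arena")
  if (duration * frame_rate < 1) {
    abort_param("duration * frame_rate must span at least 2 frames.")
  }
  D <- stokes_einstein_D(rheo, viscosity)
  if (!is.finite(D) || D <= 0) abort_param("Derived diffusion coefficient is not positive.")
  structure(
    list(viscosity = viscosity, rheo = rheo, n_particles = n_particles,
         duration = duration, frame_rate = frame_rate,
         localization_noise_sd = localization_noise_sd,
         drift_velocity = drift_velocity, arena = arena, margin = margin,
         seed = as.integer(seed), diffusion_um2_s = D),
    class = "bead_sim_config"
  )
}

#' Swimmer simulation configuration
#'
#' Settings for progressive sperm motion with lateral head oscillation. The
#' median progressive speed scales with relative mucus concentration as a
#' power law: `base_speed * relative_concentration^(-concentration_exponent)`,
#' so halving the concentration multiplies the median speed by
#' `2^concentration_exponent`.
#'
#' @param base_speed Median progressive speed at relative concentration 1
#'   (undiluted mucus), um/s.
#' @param concentration_exponent Power-law exponent beta; default 0.5.
#' @param relative_concentration Relative mucus concentration c = 1/dilution
#'   factor, in (0, 1].
#' @param speed_dispersion Between-sperm lognormal dispersion, expressed as
#'   the standard deviation of log10 speed.
#' @param wobble_amplitude Amplitude of sinusoidal lateral head displacement
#'   about the average path, um.
#' @param wobble_frequency Head oscillation frequency, Hz.
#' @param heading_persistence Timescale of heading decorrelation, seconds
#'   (heading angle performs Brownian motion with variance t/persistence);
#'   `Inf` gives perfectly straight average paths.
#' @param n_sperm Number of sperm.
#' @param duration Recording duration, seconds (default 5).
#' @param frame_rate Acquisition rate, Hz (default 20).
#' @param arena Field-of-view `(width, height)` in um for initial positions.
#' @param seed Integer seed.
#' @return A list of class `swimmer_sim_config`.
#' @export
swimmer_sim_config <- function(base_speed = 10,
                               concentration_exponent = 0.5,
                               relative_concentration = 1,
                               speed_dispersion = 0.15,
                               wobble_amplitude = 2,
                               wobble_frequency = 4,
                               heading_persistence = 5,
                               n_sperm = 20L,
                               duration = 5,
                               frame_rate = 20,
                               arena = c(256, 256),
                               seed = 1L) {
  check_positive(base_speed, "base_speed")
  check_nonneg(concentration_exponent, "concentration_exponent")
  check_positive(relative_concentration, "relative_concentration")
  if (relative_concentration > 1) {
    abort_param("`relative_concentration` must lie in (0, 1].")
  }
  check_nonneg(speed_dispersion, "speed_dispersion")
  check_nonneg(wobble_amplitude, "wobble_amplitude")
  check_positive(wobble_frequency, "wobble_frequency")
  if (!(is.numeric(heading_persistence) && heading_persistence > 0)) {
    abort_param("`heading_persistence` must be positive (Inf allowed).")
  }
  n_sperm <- check_count(n_sperm, "n_sperm")
  check_positive(duration, "duration")
  check_positive(frame_rate, "frame_rate")
  check_positive(arena, "arena")
  structure(
    list(base_speed = base_speed,
         concentration_exponent = concentration_exponent,
         relative_concentration = relative_concentration,
         speed_dispersion = speed_dispersion,
         wobble_amplitude = wobble_amplitude,
         wobble_frequency = wobble_frequency,
         heading_persistence = heading_persistence,
         n_sperm = n_sperm, duration = duration, frame_rate = frame_rate,
         arena = arena, seed = as.integer(seed)),
    class = "swimmer_sim_config"
  )
}

#' Image rendering configuration
#'
#' Camera/optics stand-in used to turn simulated trajectories into image
#' stacks: particles are drawn as 2-D Gaussian spots on a constant background
#' with optional noise.
#'
#' @param image_size `(height, width)` in pixels.
#' @param pixel_size Calibration, um/pixel.
#' @param psf_sigma Spot standard deviation, pixels.
#' @param spot_intensity Peak spot amplitude above background, counts.
#' @param background Constant background level, counts.
#' @param noise_model One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sd Gaussian read-noise standard deviation, counts (used when
#'   `noise_model = "gaussian"`).
#' @param bit_depth 8 or 16.
#' @param spot_aspect Elongation of the spot along the direction of motion
#'   (sigma_major/sigma_minor); 1 renders circular bead-like spots, ~1.5
#'   renders sperm-head-like elongated spots.
#' @param preset `"bead"` or `"sperm"`: fills mode-appropriate defaults for
#'   any argument not supplied.
#' @return A list of class `render_config`.
#' @export
render_config <- function(image_size = NULL, pixel_size = NULL,
                          psf_sigma = NULL, spot_intensity = 200,
                          background = 20, noise_model = "gaussian",
                          noise_sd = 3, bit_depth = 16,
                          spot_aspect = NULL,
                          preset = c("bead", "sperm")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    bead  = list(image_size = c(128L, 128L), pixel_size = 0.2,
                 psf_sigma = 1.5, spot_aspect = 1),
    sperm = list(image_size = c(256L, 256L), pixel_size = 1.0,
                 psf_sigma = 2.2, spot_aspect = 1.5)
  )
  image_size <- as.integer(image_size %||% defaults$image_size)
  pixel_size <- pixel_size %||% defaults$pixel_size
  psf_sigma <- psf_sigma %||% defaults$psf_sigma
  spot_aspect <- spot_aspect %||% defaults$spot_aspect
  check_positive(pixel_size, "pixel_size")
  check_positive(psf_sigma, "psf_sigma")
  check_positive(spot_intensity, "spot_intensity")
  check_nonneg(background, "background")
  noise_model <- match.arg(noise_model, c("none", "gaussian", "poisson"))
  if (!bit_depth %in% c(8, 16)) abort_param("`bit_depth` must be 8 or 16.")
  if (spot_aspect < 1) abort_param("`spot_aspect` must be >= 1.")
  structure(
    list(image_size = image_size, pixel_size = pixel_size,
         psf_sigma = psf_sigma, spot_intensity = spot_intensity,
         background = background, noise_model = noise_model,
         noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
         spot_aspect = spot_aspect, preset = preset),
    class = "render_config"
  )
}
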