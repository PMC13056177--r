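#' Simulate Brownian bead trajectories
#'
#' Brownian dynamics of tracer beads in a Newtonian fluid. Per-axis position
#' increments over one frame interval dt are independent Gaussian with
#' variance 2*D*dt, where D comes from the Stokes-Einstein relation; the
#' increments are exact at any dt so no sub-stepping is needed. Optional
#' constant drift is added to the true positions; optional localization noise
#' is added to the *reported* positions only.
#'
#' @param config A [bead_sim_config()].
#' @return A list with elements
#'   * `tracks`: tibble `(particle, frame, x, y)` of reported positions, um,
#'     frames 0-based;
#'   * `truth`: tibble `(particle, frame, x, y)` of true (noise-free)
#'     positions;
#'   * `config`: the input configuration (with the derived `diffusion_um2_s`).
#' @export
#' @examples
#' sim <- simulate_brownian_tracks(bead_sim_config(n_particles = 3, duration = 1))
#' head(sim$tracks)
simulate_brownian_tracks <- function(config) {
  stopifnot(inherits(config, "bead_sim_config"))
  n <- config$n_particles
  n_frames <- floor(config$duration * config$frame_rate) + 1L
  dt <- 1 / config$frame_rate
  D <- config$diffusion_um2_s
  step_sd <- sqrt(2 * D * dt)

  withr::with_seed(config$seed, {
    x0 <- runif(n, config$margin, config$arena[1] - config$margin)
    y0 <- runif(n, config$margin, config$arena[2] - config$margin)
    # rows = frames, cols = particles
    dx <- matrix(rnorm(n * (n_frames - 1L), 0, step_sd), n_frames - 1L, n)
    dy <- matrix(rnorm(n * (n_frames - 1L), 0, step_sd), n_frames - 1L, n)
    x <- rbind(x0, sweep(apply(dx, 2, cumsum), 2, x0, `+`) +
                 config$drift_velocity[1] * dt * seq_len(n_frames - 1L))
    y <- rbind(y0, sweep(apply(dy, 2, cumsum), 2, y0, `+`) +
                 config$drift_velocity[2] * dt * seq_len(n_frames - 1L))
    noise_x <- noise_y <- 0
    if (config$localization_noise_sd > 0) {
      noise_x <- matrix(rnorm(n * n_frames, 0, config$localization_noise_sd),
                        n_frames, n)
      noise_y <- matrix(rnorm(n * n_frames, 0, config$localization_noise_sd),
                        n_frames, n)
    }
    truth <- tibble(
      particle = rep(seq_len(n), each = n_frames),
      frame = rep(0:(n_frames - 1L), n),
      x = as.vector(x), y = as.vector(y)
    )
    tracks <- truth
    tracks$x <- tracks$x + as.vector(noise_x + x * 0)
    tracks$y <- tracks$y + as.vector(noise_y + y * 0)
    list(tracks = tracks, truth = truth, config = config)
  })
}

#' Simulate progressive swimmer trajectories
#'
#' Each sperm's progressive speed is drawn lognormal with median
#' `base_speed * c^(-beta)` (c = relative concentration, beta =
#' concentration exponent) and log10-sd `speed_dispersion`. The path is a
#' persistent-heading walk (heading angle diffuses with variance
#' dt/heading_persistence per step) plus a sinusoidal lateral displacement of
#' amplitude `wobble_amplitude` perpendicular to the heading, emulating
#' lateral head oscillation.
#'
#' @param config A [swimmer_sim_config()].
#' @return A list with `tracks` (tibble `(particle, frame, x, y)`, um),
#'   `truth` (same positions plus `true_speed` um/s per particle), and
#'   `config`.
#' @export
simulate_swimmer_tracks <- function(config) {
  stopifnot(inherits(config, "swimmer_sim_config"))
  n <- config$n_sperm
  n_frames <- floor(config$duration * config$frame_rate) + 1L
  dt <- 1 / config$frame_rate
  t_grid <- (0:(n_frames - 1L)) * dt
  median_speed <- config$base_speed *
    config$relative_concentration^(-config$concentration_exponent)

  withr::with_seed(config$seed, {
    speeds <- median_speed * 10^rnorm(n, 0, config$speed_dispersion)
    x0 <- runif(n, 0, config$arena[1])
    y0 <- runif(n, 0, config$arena[2])
    theta0 <- runif(n, 0, 2 * pi)
    phase0 <- runif(n, 0, 2 * pi)
    heading_sd <- if (is.finite(config$heading_persistence)) {
      sqrt(dt / config$heading_persistence)
    } else 0

    paths <- map(seq_len(n), function(i) {
      dtheta <- if (heading_sd > 0) {
        rnorm(n_frames - 1L, 0, heading_sd)
      } else {
        rep(0, n_frames - 1L)
      }
      theta <- theta0[i] + c(0, cumsum(dtheta))
      # progressive displacement integrated along the (piecewise) heading
      cx <- x0[i] + c(0, cumsum(speeds[i] * dt * cos(theta[-n_frames])))
      cy <- y0[i] + c(0, cumsum(speeds[i] * dt * sin(theta[-n_frames])))
      wob <- config$wobble_amplitude *
        sin(2 * pi * config$wobble_frequency * t_grid + phase0[i])
      tibble(
        particle = i, frame = 0:(n_frames - 1L),
        x = cx - wob * sin(theta),
        y = cy + wob * cos(theta),
        true_speed = speeds[i]
      )
    })
    truth <- list_rbind(paths)
    list(tracks = truth[c("particle", "frame", "x", "y")],
         truth = truth, config = config)
  })
}
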