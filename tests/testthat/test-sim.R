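test_that("Stokes-Einstein diffusion coefficient matches direct arithmetic", {
  D <- stokes_einstein_D(rheo_params(temperature = 293.15), viscosity = 1e-3)
  expect_equal(D, 1.380649e-23 * 293.15 / (6 * pi * 1e-3 * 0.5e-6) * 1e12,
               tolerance = 1e-12)
  expect_equal(D, 0.4294, tolerance = 2e-4)
  # inverse proportionality in viscosity, proportionality in T
  expect_equal(stokes_einstein_D(rheo_params(), 2e-3), D / 2)
  expect_lt(stokes_einstein_D(rheo_params(temperature = 1e-9), 1e-3), 1e-10)
  expect_error(stokes_einstein_D(rheo_params(), -1),
               class = "ptmr_invalid_parameter")
  expect_error(rheo_params(temperature = 0), class = "ptmr_invalid_parameter")
})

test_that("Brownian tracks reproduce the expected MSD slope and are seeded", {
  cfg <- bead_sim_config(viscosity = 1e-3, n_particles = 500, duration = 3,
                         localization_noise_sd = 0, seed = 3)
  sim <- simulate_brownian_tracks(cfg)
  curves <- lapply(split(sim$tracks, sim$tracks$particle), compute_msd,
                   frame_rate = cfg$frame_rate)
  ens <- ensemble_msd(curves)
  fit <- lm(msd ~ lag, data = ens[ens$lag <= 1, ])
  expect_equal(unname(coef(fit)[2]), 4 * cfg$diffusion_um2_s, tolerance = 0.05)
  # determinism and seed sensitivity
  again <- simulate_brownian_tracks(cfg)
  expect_identical(sim$tracks, again$tracks)
  other <- simulate_brownian_tracks(bead_sim_config(seed = 4, n_particles = 2,
                                                    duration = 0.5))
  expect_false(identical(sim$tracks$x[1:5], other$tracks$x[1:5]))
})

test_that("near-zero diffusion freezes the beads in place", {
  cfg <- bead_sim_config(viscosity = 1e300, n_particles = 3, duration = 1,
                         localization_noise_sd = 0, seed = 1)
  sim <- simulate_brownian_tracks(cfg)
  spread <- sim$tracks |>
    dplyr::group_by(particle) |>
    dplyr::summarise(r = max(abs(x - x[1]) + abs(y - y[1])))
  expect_true(all(spread$r < 1e-100))
})

test_that("localization noise adds ~4 sigma^2 to the MSD intercept", {
  sigma <- 0.05
  base <- bead_sim_config(viscosity = 1e-2, n_particles = 300, duration = 2,
                          localization_noise_sd = 0, seed = 9)
  noisy <- base
  noisy$localization_noise_sd <- sigma
  msd_of <- function(cfg) {
    sim <- simulate_brownian_tracks(cfg)
    ensemble_msd(lapply(split(sim$tracks, sim$tracks$particle), compute_msd,
                        frame_rate = cfg$frame_rate))
  }
  m0 <- msd_of(base); m1 <- msd_of(noisy)
  offset <- mean(m1$msd[1:5] - m0$msd[1:5])
  expect_equal(offset, 4 * sigma^2, tolerance = 0.15)
})

test_that("swimmer speeds follow the concentration power law", {
  base <- swimmer_sim_config(wobble_amplitude = 0, heading_persistence = Inf,
                             speed_dispersion = 0, n_sperm = 4, seed = 2)
  quarter <- base
  quarter$relative_concentration <- 1 / 4
  v1 <- unique(simulate_swimmer_tracks(base)$truth$true_speed)
  v4 <- unique(simulate_swimmer_tracks(quarter)$truth$true_speed)
  # beta = 0.5: four-fold dilution doubles the median speed
  expect_equal(v4, 2 * v1, tolerance = 1e-12)

  # straight path: net displacement over duration equals the drawn speed
  sim <- simulate_swimmer_tracks(base)
  kin <- sperm_kinematics(sim$tracks, frame_rate = base$frame_rate)
  expect_equal(kin$vsl, rep(v1, 4), tolerance = 1e-10)
  expect_identical(simulate_swimmer_tracks(base)$tracks, sim$tracks)
})

test_that("rendering places spots, conserves mass and clips gracefully", {
  rc <- render_config(preset = "bead", noise_model = "none")
  tr <- tibble::tibble(particle = 1L, frame = 0L, x = 40 * rc$pixel_size,
                       y = 60 * rc$pixel_size)
  st <- render_stack(tr, rc, 30)
  f <- matrix(st[, , 1], dim(st)[1], dim(st)[2])
  pk <- which(f == max(f), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(61, 41)) # 1-based (row, col) of (y, x)

  # integrated intensity above background ~ n_particles x per-spot mass
  tr3 <- tibble::tibble(particle = 1:3, frame = 0L,
                        x = c(30, 64, 98) * rc$pixel_size,
                        y = c(30, 64, 98) * rc$pixel_size)
  st3 <- render_stack(tr3, rc, 30)
  mass1 <- sum(f - rc$background)
  mass3 <- sum(matrix(st3[, , 1], 128, 128) - rc$background)
  expect_equal(mass3, 3 * mass1, tolerance = 0.01)

  # empty tracks give a pure background stack; off-frame spots are clipped
  st0 <- render_stack(tibble::tibble(), rc, 30)
  expect_true(all(st0 == rc$background))
  far <- tibble::tibble(particle = 1L, frame = 0L, x = 1e4, y = 1e4)
  expect_true(all(render_stack(far, rc, 30) == rc$background))

  # poisson noise model: counts stay non-negative, mean tracks the signal
  rp <- render_config(preset = "bead", noise_model = "poisson")
  stp <- render_stack(tibble::tibble(), rp, 30, seed = 3)
  expect_true(all(stp >= 0))
  expect_equal(mean(stp), rp$background, tolerance = 0.05)
})

test_that("dilution series has the right design, laws and monotonicity", {
  ser <- simulate_dilution_series(
    n_animals = 6, dilution_factors = 2^(0:7),
    bead_cfg_template = bead_sim_config(n_particles = 2, duration = 0.2),
    swimmer_cfg_template = swimmer_sim_config(n_sperm = 2, duration = 0.2),
    seed = 5)
  expect_equal(nrow(ser), 48)
  expect_equal(ser$conc, 1 / ser$dilution)
  med <- ser |>
    dplyr::group_by(dilution) |>
    dplyr::summarise(eta = median(eta_true), v = median(speed_median_true))
  expect_true(all(diff(med$eta) <= 0))
  expect_true(all(diff(med$v) >= 0))

  # zero noise, zero animal effects: exactly on the configured power laws
  exact <- simulate_dilution_series(
    n_animals = 1, dilution_factors = c(1, 2, 4),
    bead_cfg_template = bead_sim_config(n_particles = 1, duration = 0.2),
    swimmer_cfg_template = swimmer_sim_config(n_sperm = 1, duration = 0.2,
                                              speed_dispersion = 0),
    rheology_scaling_exponent = 3, eta_buffer = 1e-3, eta_neat = 1,
    animal_sd_log10 = 0, seed = 1)
  expect_equal(exact$eta_true, 1e-3 + (1 - 1e-3) * exact$conc^3)
  expect_equal(exact$speed_median_true, 10 * exact$conc^-0.5)
  expect_error(simulate_dilution_series(dilution_factors = numeric()),
               class = "ptmr_invalid_parameter")
})
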