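test_that("compute_msd matches a brute-force oracle on short tracks", {
  # worked example: (0,0), (1,0), (1,1) um at 1 fps
  tr <- tibble::tibble(frame = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
  msd <- compute_msd(tr, frame_rate = 1, max_lag_fraction = 1)
  expect_equal(msd$msd, c(1, 2))
  expect_equal(msd$n_obs, c(2L, 1L))

  # random <= 5-point tracks, with and without gaps, against the oracle
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(2:5, 1)
      f <- sort(sample(0:7, n))
      x <- rnorm(n); y <- rnorm(n)
      got <- compute_msd(tibble::tibble(frame = f, x = x, y = y),
                         frame_rate = 2, max_lag_fraction = 1)
      want <- brute_msd(f, x, y, frame_rate = 2)
      expect_equal(got$lag, want$lag)
      expect_equal(got$msd, want$msd)
      expect_equal(got$n_obs, want$n_obs)
    }
  })
})

test_that("compute_msd closed forms and contracts hold", {
  t_ball <- tibble::tibble(frame = 0:9, x = 2 * (0:9), y = 0)
  msd <- compute_msd(t_ball, frame_rate = 1, max_lag_fraction = 1)
  expect_equal(msd$msd, (2 * msd$lag)^2) # ballistic: v^2 tau^2
  t_still <- tibble::tibble(frame = 0:5, x = 1, y = 2)
  expect_true(all(compute_msd(t_still, 1, max_lag_fraction = 1)$msd == 0))
  expect_error(compute_msd(tibble::tibble(frame = 0, x = 0, y = 0), 1),
               class = "ptmr_short_track")
  # pixel calibration: msd in um^2 scales with pixel_size^2
  m_px <- compute_msd(t_ball, 1, pixel_size = 0.5, max_lag_fraction = 1)
  expect_equal(m_px$msd, msd$msd * 0.25)
})

test_that("ensemble_msd averages with n_obs weights on the shared grid", {
  c1 <- tibble::tibble(lag = c(1, 2), msd = c(1, 2), n_obs = c(10L, 5L))
  c2 <- tibble::tibble(lag = c(1, 3), msd = c(3, 9), n_obs = c(30L, 2L))
  ens <- ensemble_msd(list(c1, c2))
  expect_equal(ens$lag, 1)                 # intersection grid
  expect_equal(ens$msd, (1 * 10 + 3 * 30) / 40)
  expect_equal(ens$n_obs, 40L)
  uni <- ensemble_msd(list(c1, c2), grid = "union")
  expect_equal(uni$lag, c(1, 2, 3))
  expect_identical(ensemble_msd(list(c1)), c1)  # single curve: identity
  expect_error(ensemble_msd(list()), class = "ptmr_empty_input")
})

test_that("drift correction removes a common drift without killing diffusion", {
  cfg <- bead_sim_config(viscosity = 1e-2, n_particles = 50, duration = 2,
                         localization_noise_sd = 0,
                         drift_velocity = c(3, -2), seed = 12)
  sim <- simulate_brownian_tracks(cfg)
  corr <- correct_drift(sim$tracks)
  ens <- ensemble_msd(lapply(split(corr, corr$particle), compute_msd,
                             frame_rate = 30))
  fit <- lm(msd ~ lag, data = ens[ens$lag <= 0.5, ])
  # drifting MSD would grow ~ (v tau)^2; corrected slope is ~ 4D
  expect_equal(unname(coef(fit)[2]), 4 * cfg$diffusion_um2_s, tolerance = 0.15)
})

test_that("GSER recovers the Newtonian identity exactly", {
  D <- stokes_einstein_D(rheo_params(), 1e-3)
  lags <- seq(0.1, 3, by = 0.1)
  msd <- tibble::tibble(lag = lags, msd = 4 * D * lags, n_obs = 100L)
  sp <- gser_spectrum(msd, rheo_params())
  expect_equal(sp$alpha, rep(1, nrow(sp)), tolerance = 1e-9)
  expect_equal(sp$eta_star, rep(1e-3, nrow(sp)), tolerance = 1e-9)
  expect_equal(sp$G_prime, rep(0, nrow(sp)), tolerance = 1e-10)
  expect_equal(sp$G_dprime, 1e-3 * sp$omega, tolerance = 1e-9)
  expect_equal(sp$G_mod^2, sp$G_prime^2 + sp$G_dprime^2, tolerance = 1e-12)
})

test_that("GSER handles elastic plateaus and clips superdiffusive slopes", {
  params <- rheo_params()
  delta2 <- 0.01 # um^2
  msd <- tibble::tibble(lag = seq(0.1, 2, by = 0.1), msd = delta2, n_obs = 50L)
  sp <- gser_spectrum(msd, params)
  expect_equal(sp$alpha, rep(0, nrow(sp)), tolerance = 1e-9)
  expect_equal(sp$G_dprime, rep(0, nrow(sp)), tolerance = 1e-12)
  g_expect <- 2 * params$kB * params$temperature /
    (3 * pi * params$bead_radius * delta2 * 1e-12)
  expect_equal(sp$G_prime, rep(g_expect, nrow(sp)), tolerance = 1e-9)

  lags <- seq(0.1, 2, by = 0.1)
  super <- tibble::tibble(lag = lags, msd = lags^1.4, n_obs = 10L)
  expect_warning(sp2 <- gser_spectrum(super, params), "superdiffusive")
  expect_true(all(sp2$alpha <= 1))
  neg <- tibble::tibble(lag = c(0.1, 0.2, 0.3), msd = c(1, -1, 2), n_obs = 3L)
  expect_warning(sp3 <- gser_spectrum(neg, params), "non-positive")
  expect_equal(nrow(sp3), 2)
})

test_that("eta_star_at interpolates log-log and enforces its range", {
  sp <- tibble::tibble(omega = c(1, 100), eta_star = c(1e-2, 1e-3))
  expect_equal(eta_star_at(sp, 10), 10^-2.5)
  expect_error(eta_star_at(sp, 0.5), class = "ptmr_out_of_range")
  expect_error(eta_star_at(sp, 200), class = "ptmr_out_of_range")
})

test_that("end-to-end Newtonian recovery within 15% across three decades", {
  for (eta in c(1e-3, 1e-2, 1e-1)) {
    cfg <- bead_sim_config(viscosity = eta, n_particles = 100,
                           seed = round(1e3 * eta) + 17)
    sim <- simulate_brownian_tracks(cfg)
    res <- eta_star_from_tracks(sim$tracks, frame_rate = cfg$frame_rate,
                                params = cfg$rheo)
    expect_equal(res$eta_star, eta, tolerance = 0.15)
  }
})

test_that("eta* is invariant to the pixel calibration when applied consistently", {
  cfg <- bead_sim_config(viscosity = 1e-2, n_particles = 40, duration = 3,
                         seed = 31)
  sim <- simulate_brownian_tracks(cfg)
  in_px <- sim$tracks |> dplyr::mutate(x = x / 0.2, y = y / 0.2)
  a <- eta_star_from_tracks(sim$tracks, cfg$frame_rate, cfg$rheo,
                            pixel_size = 1)
  b <- eta_star_from_tracks(in_px, cfg$frame_rate, cfg$rheo, pixel_size = 0.2)
  expect_equal(a$eta_star, b$eta_star, tolerance = 1e-10)
})
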