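test_that("bandpass filter removes flat background and preserves peaks", {
  expect_true(all(bandpass_filter(matrix(7, 40, 40), 1, 11) == 0))
  f <- spot_frame(20.0, 25.0)
  bp <- bandpass_filter(f, 1, 11)
  expect_gte(min(bp), 0)
  expect_equal(unname(which(bp == max(bp), arr.ind = TRUE)[1, ]),
               unname(which(f == max(f), arr.ind = TRUE)[1, ]))
  expect_error(bandpass_filter(f, 5, 3), class = "ptmr_invalid_parameter")
})

test_that("batched stack bandpass equals the per-frame filter", {
  sim <- simulate_brownian_tracks(bead_sim_config(n_particles = 4,
                                                  duration = 0.3, seed = 8))
  st <- render_stack(sim$truth, render_config(preset = "bead"), 30, seed = 2)
  bps <- ptmr:::bandpass_stack(st, 1, 11)
  for (k in c(1, 5, 10)) {
    expect_equal(bps[[k]],
                 bandpass_filter(matrix(st[, , k], 128, 128), 1, 11),
                 tolerance = 1e-9)
  }
})

test_that("sub-pixel localization of a noiseless spot is within 0.1 px", {
  f <- spot_frame(10.3, 20.7)
  det <- locate_features(f, detection_params(preset = "bead"))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - 10.3), 0.1)
  expect_lt(abs(det$y - 20.7), 0.1)
})

test_that("eccentricity separates beads from sperm-like elongated spots", {
  circ <- locate_features(spot_frame(100, 100, preset = "sperm",
                                     spot_aspect = 1),
                          detection_params(preset = "sperm"))
  expect_equal(nrow(circ), 1)
  expect_lt(circ$ecc, 0.05)

  # 1.5:1 sigma elongation: rejected at the bead threshold 0.3, accepted at
  # the sperm threshold 0.5
  f_el <- spot_frame(100, 100, preset = "sperm", spot_aspect = 1.5)
  el_sperm <- locate_features(f_el, detection_params(preset = "sperm"))
  expect_equal(nrow(el_sperm), 1)
  expect_gt(el_sperm$ecc, 0.3)
  expect_lte(el_sperm$ecc, 0.5)
  el_bead <- locate_features(f_el, detection_params(feature_diameter = 17L,
                                                    max_eccentricity = 0.3))
  expect_equal(nrow(el_bead), 0)
})

test_that("pure background frames yield no detections", {
  withr::with_seed(1, {
    f <- matrix(20 + rnorm(128 * 128, 0, 3), 128, 128)
  })
  det <- locate_features(f, detection_params(preset = "bead", min_mass = 500,
                                             threshold_percentile = 99.5))
  expect_equal(nrow(det), 0)
})

test_that("linking follows the contracts for gaps, breaks and counts", {
  det <- grid_detections(n = 2, n_frames = 10)
  tr <- link_features(det, search_range = 5)
  expect_equal(length(unique(tr$particle)), 2)
  expect_equal(as.vector(table(tr$particle)), c(10L, 10L))

  # a missing detection with memory = 1 leaves one unbroken track with a gap
  gap <- grid_detections(n = 1, n_frames = 10) |> dplyr::filter(frame != 4)
  tr_gap <- link_features(gap, search_range = 5, memory = 1)
  expect_equal(length(unique(tr_gap$particle)), 1)
  expect_equal(nrow(tr_gap), 9)
  tr_nogap <- link_features(gap, search_range = 5, memory = 0)
  expect_equal(length(unique(tr_nogap$particle)), 2)

  # displacement beyond search_range terminates the track
  jump <- tibble::tibble(frame = 0:3, x = c(10, 11, 50, 51), y = 10)
  tr_jump <- link_features(jump, search_range = 5)
  expect_equal(length(unique(tr_jump$particle)), 2)
})

test_that("linking is invariant to detection order within a frame", {
  withr::with_seed(42, {
    det <- tibble::tibble(
      frame = rep(0:5, each = 4),
      x = rep(c(10, 30, 50, 70), 6) + rnorm(24, 0, 1),
      y = rep(c(10, 30, 50, 70), 6) + rnorm(24, 0, 1)
    )
    shuffled <- det |> dplyr::group_by(frame) |> dplyr::slice_sample(prop = 1) |>
      dplyr::ungroup()
  })
  canon <- function(tr) {
    tr |> dplyr::arrange(particle, frame) |>
      dplyr::group_by(particle) |>
      dplyr::mutate(key = paste(round(x, 6), round(y, 6), collapse = ";")) |>
      dplyr::ungroup() |> dplyr::distinct(key) |> dplyr::arrange(key)
  }
  expect_equal(canon(link_features(det, 5)),
               canon(link_features(shuffled, 5)))
})

test_that("oversized linking subnetworks raise an informative error", {
  det <- tidyr::expand_grid(frame = 0:1, i = 1:40) |>
    dplyr::mutate(x = 10 + i * 0.1, y = 10) |>
    dplyr::select(frame, x, y)
  expect_error(link_features(det, search_range = 50, hard_cap = 20),
               class = "ptmr_link_subnetwork")
})

test_that("duration filter uses (last - first)/frame_rate with >= 1 s kept", {
  tracks <- dplyr::bind_rows(
    tibble::tibble(particle = 1L, frame = 0:20, x = 0, y = 0),  # 1.00 s
    tibble::tibble(particle = 2L, frame = 0:19, x = 0, y = 0)   # 0.95 s
  )
  kept <- filter_trajectories(tracks, min_duration = 1, frame_rate = 20)
  expect_equal(unique(kept$particle), 1L)
  expect_identical(filter_trajectories(tracks, 0, 20), tracks)
  expect_equal(nrow(filter_trajectories(tracks[0, ], 1, 20)), 0)
  expect_warning(filter_trajectories(tracks, 10, 20), "removed")
})

test_that("simulate -> render -> locate -> link recovers ground truth", {
  cfg <- bead_sim_config(viscosity = 5e-3, n_particles = 4, duration = 1,
                         localization_noise_sd = 0, seed = 21,
                         arena = c(25.6, 25.6), margin = 6)
  sim <- simulate_brownian_tracks(cfg)
  # re-anchor each bead's path on a grid so the four stay well separated
  gx <- c(6.4, 19.2, 6.4, 19.2); gy <- c(6.4, 6.4, 19.2, 19.2)
  truth <- sim$truth |>
    dplyr::group_by(particle) |>
    dplyr::mutate(x = gx[particle[1]] + x - x[1],
                  y = gy[particle[1]] + y - y[1]) |>
    dplyr::ungroup()
  rc <- render_config(preset = "bead")
  st <- render_stack(truth, rc, 30, seed = 22)
  det <- locate_stack(st, detection_params(preset = "bead", min_mass = 500,
                                           threshold_percentile = 99.5))
  tr <- link_features(det, search_range = 5, memory = 3)
  expect_equal(length(unique(tr$particle)), 4)
  # recall: every truth point has a detection in its frame
  expect_equal(nrow(tr), nrow(truth))
  err <- tr |>
    dplyr::mutate(x_um = x * rc$pixel_size, y_um = y * rc$pixel_size) |>
    dplyr::left_join(truth, by = "frame", suffix = c("", "_t"),
                     relationship = "many-to-many") |>
    dplyr::group_by(particle, frame) |>
    dplyr::summarise(e = min(sqrt((x_um - x_t)^2 + (y_um - y_t)^2)),
                     .groups = "drop")
  expect_lt(mean(err$e), 0.05)           # um
  expect_lt(max(err$e) / rc$pixel_size, 0.5) # px, worst case
})
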