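#' Run configuration for the single-mode pipeline
#'
#' Bundles the mode-specific defaults: beads are detected with an 11 px
#' feature diameter and maximum eccentricity 0.3 at 30 fps, sperm with 17 px
#' and 0.5 at 20 fps plus a 1 s minimum trajectory duration. Linking defaults
#' derive from the expected per-frame displacement (see the package
#' vignette): beads 5 px search range with memory 3, sperm 15 px with
#' memory 0.
#'
#' @param mode `"bead"` or `"sperm"`.
#' @param seed Integer seed governing all randomness in the run.
#' @param input Path to a multi-page TIFF (or frame directory); `NULL`
#'   simulates an acquisition instead.
#' @param out_dir Directory for persisted outputs; `NULL` keeps results in
#'   memory only.
#' @param frame_rate,pixel_size Calibration; defaults are mode-specific
#'   (30 fps / 0.2 um per px for beads, 20 fps / 1.0 um per px for sperm) and
#'   mandatory when reading external images.
#' @param viscosity Simulated medium viscosity, Pa s (bead mode).
#' @param relative_concentration Simulated relative mucus concentration
#'   (sperm mode).
#' @param n_particles Simulated particle count.
#' @param temperature Kelvin, for the GSER inversion.
#' @param min_duration Minimum trajectory duration, seconds (sperm default 1).
#' @param search_range,memory Linking parameters, pixels / frames.
#' @param min_mass,threshold_percentile Detection overrides (intensity units
#'   of the band-passed image / percent).
#' @param omega_ref Reference angular frequency for eta*, rad/s.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("bead", "sperm"), seed = 1L, input = NULL,
                       out_dir = NULL, frame_rate = NULL, pixel_size = NULL,
                       viscosity = 1e-3, relative_concentration = 1,
                       n_particles = NULL, temperature = 293.15,
                       min_duration = NULL, search_range = NULL,
                       memory = NULL, min_mass = NULL,
                       threshold_percentile = NULL, omega_ref = 2 * pi) {
  if (length(mode) == 1L && !mode %in% c("bead", "sperm")) {
    abort_param(sprintf("Invalid mode '%s'; valid modes: bead, sperm.", mode))
  }
  mode <- match.arg(mode)
  def <- switch(mode,
    bead = list(frame_rate = 30, pixel_size = 0.2, n_particles = 12L,
                min_duration = 0, search_range = 5, memory = 3L,
                min_mass = 500, threshold_percentile = 99.5),
    sperm = list(frame_rate = 20, pixel_size = 1.0, n_particles = 20L,
                 min_duration = 1, search_range = 15, memory = 0L,
                 min_mass = 1500, threshold_percentile = 99.5)
  )
  structure(
    list(mode = mode, seed = as.integer(seed), input = input,
         out_dir = out_dir,
         frame_rate = frame_rate %||% def$frame_rate,
         pixel_size = pixel_size %||% def$pixel_size,
         viscosity = viscosity,
         relative_concentration = relative_concentration,
         n_particles = n_particles %||% def$n_particles,
         temperature = temperature,
         min_duration = min_duration %||% def$min_duration,
         search_range = search_range %||% def$search_range,
         memory = memory %||% def$memory,
         min_mass = min_mass %||% def$min_mass,
         threshold_percentile = threshold_percentile %||% def$threshold_percentile,
         omega_ref = omega_ref),
    class = "run_config"
  )
}

mode_detection_params <- function(config) {
  detection_params(preset = config$mode, min_mass = config$min_mass,
                   threshold_percentile = config$threshold_percentile)
}

#' Run the single-mode pipeline
#'
#' Executes the stage chain for one acquisition: obtain an image stack
#' (simulate + render, or read from disk), detect and link features, filter
#' trajectories, then convert to the mode's readout -- eta* at the reference
#' frequency (bead mode, via MSD and the GSER) or the per-sample kinematics
#' summary (sperm mode). Reruns with the same configuration and seed produce
#' identical outputs.
#'
#' @param config A [run_config()].
#' @return A report list: `mode`, `seed`, `n_detections`, `n_tracks`, and
#'   either `eta_star`/`omega_ref`/`temperature` (bead) or `kinematics`
#'   summary columns (sperm); `tracks` holds the linked trajectories in
#'   pixels. When `config$out_dir` is set the report JSON, trajectory CSV and
#'   config YAML are persisted there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- child_seeds(config$seed, 2L)

  if (is.null(config$input)) {
    if (config$mode == "bead") {
      sim <- simulate_brownian_tracks(bead_sim_config(
        viscosity = config$viscosity,
        rheo = rheo_params(temperature = config$temperature),
        n_particles = config$n_particles, seed = seeds[1]))
      render <- render_config(preset = "bead",
                              pixel_size = config$pixel_size)
    } else {
      sim <- simulate_swimmer_tracks(swimmer_sim_config(
        relative_concentration = config$relative_concentration,
        n_sperm = config$n_particles, seed = seeds[1]))
      render <- render_config(preset = "sperm",
                              pixel_size = config$pixel_size)
    }
    stack <- render_stack(sim$tracks, render, config$frame_rate,
                          seed = seeds[2])
  } else {
    stack <- read_image_stack(config$input, frame_rate = config$frame_rate,
                              pixel_size = config$pixel_size)
  }

  detections <- locate_stack(stack, mode_detection_params(config))
  tracks <- link_features(detections, search_range = config$search_range,
                          memory = config$memory)
  tracks <- filter_trajectories(tracks, config$min_duration,
                                config$frame_rate)
  if (nrow(tracks) == 0L) {
    abort(sprintf("Pipeline stage 'tracking' (%s mode): no trajectories survived.",
                  config$mode), class = "ptmr_pipeline")
  }

  report <- list(mode = config$mode, seed = config$seed,
                 n_detections = nrow(detections),
                 n_tracks = length(unique(tracks$particle)))
  if (config$mode == "bead") {
    rheo <- eta_star_from_tracks(
      tracks, frame_rate = config$frame_rate,
      params = rheo_params(temperature = config$temperature),
      pixel_size = config$pixel_size, omega_ref = config$omega_ref)
    report$eta_star <- rheo$eta_star
    report$omega_ref <- config$omega_ref
    report$omega_range <- rheo$omega_range
    report$temperature <- config$temperature
  } else {
    kin <- sperm_kinematics(tracks, frame_rate = config$frame_rate,
                            pixel_size = config$pixel_size)
    summ <- summarize_kinematics(kin, stat = "median", log10 = TRUE)
    report$kinematics <- as.list(summ)
    report$vsl_median_um_s <- 10^summ$vsl_center
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectories(tracks, file.path(config$out_dir, "tracks.csv"))
    write_run_config(config, file.path(config$out_dir, "config.yaml"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report$tracks <- tracks
  report
}

# Track one rendered acquisition back to calibrated trajectories.
track_stack <- function(tracks_um, render, frame_rate, dparams, search_range,
                        memory, seed) {
  stack <- render_stack(tracks_um, render, frame_rate, seed = seed)
  detections <- locate_stack(stack, dparams)
  link_features(detections, search_range = search_range, memory = memory)
}

#' Run the paired dilution cohort end to end
#'
#' Simulates (or accepts) a paired dilution series and processes every
#' (animal, dilution) point through both arms: bead trajectories through
#' MSD -> GSER -> eta* at the reference frequency, and sperm trajectories
#' through the 1 s duration filter and CASA kinematics to the median log10
#' VSL. With `via = "images"` each acquisition is first rendered to a
#' synthetic image stack and re-tracked with the mode-specific detection
#' parameters, exercising the full imaging chain; with `via = "tracks"` the
#' simulated (localization-noise-bearing) trajectories are used directly.
#' Finally the aggregated points are correlated (log10 velocity vs log10
#' eta*, Pearson).
#'
#' @param series Output of [simulate_dilution_series()]; `NULL` simulates one
#'   with the given design arguments.
#' @param n_animals,dilution_factors,seed Cohort design, used when `series`
#'   is `NULL`.
#' @param via `"tracks"` or `"images"`.
#' @param omega_ref Reference angular frequency for eta*, rad/s.
#' @param min_duration Minimum sperm trajectory duration, seconds.
#' @param config An [analysis_config()] controlling aggregation.
#' @param ... Passed to [simulate_dilution_series()] when `series` is `NULL`.
#' @return A list: `points` (tibble with one row per animal-by-dilution:
#'   truth, measured `eta_star`, `log_eta`, `log_v`, track counts),
#'   `correlation` (a `ptmr_correlation`), `via`, `seed`.
#' @export
run_dilution_cohort <- function(series = NULL, n_animals = 6L,
                                dilution_factors = 2^(0:7), seed = 42L,
                                via = c("tracks", "images"),
                                omega_ref = 2 * pi, min_duration = 1,
                                config = analysis_config(), ...) {
  via <- match.arg(via)
  if (is.null(series)) {
    args <- list(n_animals = n_animals, dilution_factors = dilution_factors,
                 seed = seed, ...)
    if (!"bead_cfg_template" %in% names(args)) {
      # 12 beads is a realistic single-field occupancy at this crowding limit
      args$bead_cfg_template <- bead_sim_config(n_particles = 12L)
    }
    series <- do.call(simulate_dilution_series, args)
  }
  render_seeds <- child_seeds(seed + 1L, 2L * nrow(series))
  bead_run <- run_config("bead")
  sperm_run <- run_config("sperm")
  bead_render <- render_config(preset = "bead")
  sperm_render <- render_config(preset = "sperm")

  points <- map(seq_len(nrow(series)), function(k) {
    row <- series[k, ]
    bead_cfg <- row$bead_config[[1]]
    swim_cfg <- row$swimmer_config[[1]]
    if (via == "images") {
      # render the true positions: localization error is produced by the
      # detector itself on this route
      bead_px <- track_stack(row$bead_truth[[1]], bead_render,
                             bead_cfg$frame_rate, mode_detection_params(bead_run),
                             bead_run$search_range, bead_run$memory,
                             seed = render_seeds[2L * k - 1L])
      rheo <- eta_star_from_tracks(bead_px, frame_rate = bead_cfg$frame_rate,
                                   params = bead_cfg$rheo,
                                   pixel_size = bead_render$pixel_size,
                                   omega_ref = omega_ref)
      sperm_px <- track_stack(row$sperm_tracks[[1]], sperm_render,
                              swim_cfg$frame_rate,
                              mode_detection_params(sperm_run),
                              sperm_run$search_range, sperm_run$memory,
                              seed = render_seeds[2L * k])
      sperm_tr <- filter_trajectories(sperm_px, min_duration,
                                      swim_cfg$frame_rate)
      sperm_ps <- sperm_render$pixel_size
    } else {
      rheo <- eta_star_from_tracks(row$bead_tracks[[1]],
                                   frame_rate = bead_cfg$frame_rate,
                                   params = bead_cfg$rheo, pixel_size = 1,
                                   omega_ref = omega_ref)
      sperm_tr <- filter_trajectories(row$sperm_tracks[[1]], min_duration,
                                      swim_cfg$frame_rate)
      sperm_ps <- 1
    }
    kin <- sperm_kinematics(sperm_tr, frame_rate = swim_cfg$frame_rate,
                            pixel_size = sperm_ps)
    agg <- aggregate_dilution_point(eta_star = rheo$eta_star,
                                    velocity = 10^summarize_kinematics(
                                      kin, stat = config$stat)$vsl_center,
                                    config = config)
    tibble(
      animal = row$animal, dilution = row$dilution, conc = row$conc,
      eta_true = row$eta_true, speed_median_true = row$speed_median_true,
      eta_star = rheo$eta_star, log_eta = agg$log_eta, log_v = agg$log_v,
      n_tracks_bead = rheo$n_tracks,
      n_tracks_sperm = length(unique(sperm_tr$particle))
    )
  }) |> list_rbind()

  list(points = points, correlation = correlate_log_values(points),
       via = via, seed = seed)
}
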