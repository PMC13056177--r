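#' Simulate a paired dilution series
#'
#' Emulates the paired study design: per animal, mucus is serially diluted
#' and each (animal, dilution) point yields one bead acquisition (for PTMR)
#' and one sperm acquisition (for kinematics). Bead dynamics use the
#' concentration-viscosity law
#' `eta(c) = eta_buffer + (eta_neat - eta_buffer) * c^rheology_scaling_exponent`
#' with c = 1/dilution factor; sperm median speed follows the swimmer
#' power law `base_speed * c^(-beta)`. Animal-level heterogeneity is a
#' lognormal multiplier (sd `animal_sd_log10` in log10 units) applied to the
#' neat viscosity and to the base speed.
#'
#' @param n_animals Number of animals.
#' @param dilution_factors Positive dilution factors, typically `2^(0:7)`.
#' @param bead_cfg_template A [bead_sim_config()] whose viscosity is
#'   overridden per point; its noise settings define the bead noise level.
#' @param swimmer_cfg_template A [swimmer_sim_config()] whose
#'   `relative_concentration` and `base_speed` are overridden per point.
#' @param rheology_scaling_exponent Exponent of the concentration-viscosity
#'   law; default 3 (steep, mucus-like). Only the monotone direction is
#'   data-constrained.
#' @param eta_buffer,eta_neat Buffer and undiluted-mucus viscosities, Pa s.
#' @param animal_sd_log10 SD of the animal-level lognormal multiplier in
#'   log10 units; 0 disables animal effects.
#' @param seed Master seed; all per-point seeds derive from it.
#' @return A tibble with one row per (animal, dilution):
#'   `animal`, `dilution`, `conc`, `eta_true` (Pa s), `speed_median_true`
#'   (um/s), list-columns `bead_tracks` and `sperm_tracks` (reported
#'   positions, um), `bead_truth`/`sperm_truth` (noise-free positions, the
#'   latter with `true_speed`), and the per-point
#'   `bead_config`/`swimmer_config` objects.
#' @export
#' @examples
#' ser <- simulate_dilution_series(
#'   n_animals = 2, dilution_factors = c(1, 4),
#'   bead_cfg_template = bead_sim_config(n_particles = 5, duration = 1),
#'   swimmer_cfg_template = swimmer_sim_config(n_sperm = 3, duration = 1),
#'   seed = 1
#' )
#' ser[c("animal", "dilution", "eta_true", "speed_median_true")]
simulate_dilution_series <- function(n_animals = 6L,
                                     dilution_factors = 2^(0:7),
                                     bead_cfg_template = bead_sim_config(),
                                     swimmer_cfg_template = swimmer_sim_config(),
                                     rheology_scaling_exponent = 3,
                                     eta_buffer = 1e-3,
                                     eta_neat = 1,
                                     animal_sd_log10 = 0.2,
                                     seed = 1L) {
  n_animals <- check_count(n_animals, "n_animals")
  if (length(dilution_factors) == 0L) {
    abort_param("`dilution_factors` must be a non-empty vector.")
  }
  check_positive(dilution_factors, "dilution_factors")
  if (any(dilution_factors < 1)) {
    abort_param("Dilution factors must be >= 1.")
  }
  check_positive(eta_buffer, "eta_buffer")
  check_positive(eta_neat, "eta_neat")
  check_nonneg(animal_sd_log10, "animal_sd_log10")
  stopifnot(inherits(bead_cfg_template, "bead_sim_config"),
            inherits(swimmer_cfg_template, "swimmer_sim_config"))

  grid <- tidyr::expand_grid(
    animal = seq_len(n_animals),
    dilution = sort(dilution_factors)
  )
  n_pts <- nrow(grid)
  seeds <- child_seeds(seed, 2L * n_pts + n_animals)
  animal_mult <- withr::with_seed(seeds[2L * n_pts + 1L],
                                  10^rnorm(n_animals, 0, animal_sd_log10))

  points <- pmap(list(grid$animal, grid$dilution, seq_len(n_pts)),
                 function(animal, dilution, k) {
    conc <- 1 / dilution
    eta_neat_a <- eta_neat * animal_mult[animal]
    eta <- eta_buffer + (eta_neat_a - eta_buffer) * conc^rheology_scaling_exponent
    base_speed_a <- swimmer_cfg_template$base_speed * animal_mult[animal]

    bead_cfg <- bead_cfg_template
    bead_cfg$viscosity <- eta
    bead_cfg$diffusion_um2_s <- stokes_einstein_D(bead_cfg$rheo, eta)
    bead_cfg$seed <- seeds[k]
    swim_cfg <- swimmer_cfg_template
    swim_cfg$relative_concentration <- conc
    swim_cfg$base_speed <- base_speed_a
    swim_cfg$seed <- seeds[n_pts + k]

    beads <- simulate_brownian_tracks(bead_cfg)
    sperm <- simulate_swimmer_tracks(swim_cfg)
    tibble(
      animal = animal, dilution = dilution, conc = conc,
      eta_true = eta,
      speed_median_true = base_speed_a *
        conc^(-swim_cfg$concentration_exponent),
      bead_tracks = list(beads$tracks),
      bead_truth = list(beads$truth),
      sperm_tracks = list(sperm$tracks),
      sperm_truth = list(sperm$truth),
      bead_config = list(bead_cfg),
      swimmer_config = list(swim_cfg)
    )
  })
  out <- list_rbind(points)
  ptmr_log("simulate_dilution_series: %d animals x %d dilutions = %d points.",
           n_animals, length(unique(out$dilution)), nrow(out))
  out
}
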