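#' @import ggplot2
NULL

#' Plot an MSD curve
#'
#' Log-log MSD versus lag time; the dashed guide line has slope 1 (purely
#' viscous diffusion).
#'
#' @param msd MSD tibble from [compute_msd()] or [ensemble_msd()].
#' @return A ggplot.
#' @export
plot_msd <- function(msd) {
  ref <- msd$msd[1] / msd$lag[1]
  ggplot(msd, aes(x = .data$lag, y = .data$msd)) +
    geom_abline(slope = 1, intercept = log10(ref), linetype = "dashed",
                colour = "grey60") +
    geom_point() +
    geom_line(alpha = 0.6) +
    scale_x_log10() + scale_y_log10() +
    labs(x = expression(tau ~ "(s)"),
         y = expression("MSD" ~ (mu * m^2)),
         title = "Mean squared displacement")
}

#' Plot a viscoelastic spectrum
#'
#' G' and G'' versus angular frequency on log-log axes.
#'
#' @param spectrum Tibble from [gser_spectrum()].
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  long <- spectrum |>
    select("omega", "G_prime", "G_dprime") |>
    tidyr::pivot_longer(c("G_prime", "G_dprime"),
                        names_to = "modulus", values_to = "value") |>
    mutate(modulus = dplyr::recode(.data$modulus,
                                   G_prime = "G' (elastic)",
                                   G_dprime = "G'' (viscous)")) |>
    filter(.data$value > 0)
  ggplot(long, aes(x = .data$omega, y = .data$value,
                   colour = .data$modulus)) +
    geom_point() + geom_line(alpha = 0.6) +
    scale_x_log10() + scale_y_log10() +
    labs(x = expression(omega ~ "(rad/s)"), y = "Modulus (Pa)",
         colour = NULL, title = "Viscoelastic spectrum (GSER)")
}

#' Plot a dilution series
#'
#' Measured eta* and median VSL versus dilution factor, per animal.
#'
#' @param points `points` tibble from [run_dilution_cohort()].
#' @return A ggplot.
#' @export
plot_dilution_series <- function(points) {
  long <- points |>
    mutate(vsl = 10^.data$log_v) |>
    select("animal", "dilution", "eta_star", "vsl") |>
    tidyr::pivot_longer(c("eta_star", "vsl"),
                        names_to = "quantity", values_to = "value") |>
    mutate(quantity = dplyr::recode(.data$quantity,
                                    eta_star = "eta* (Pa s)",
                                    vsl = "median VSL (um/s)"))
  ggplot(long, aes(x = .data$dilution, y = .data$value,
                   group = .data$animal, colour = factor(.data$animal))) +
    geom_point() + geom_line(alpha = 0.5) +
    scale_x_log10(breaks = unique(long$dilution)) +
    scale_y_log10() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "Dilution factor", y = NULL, colour = "Animal",
         title = "Complex viscosity and sperm velocity across dilution")
}

#' @rdname correlate_log_values
#' @method autoplot ptmr_correlation
#' @export
autoplot.ptmr_correlation <- function(object, ...) {
  ggplot(object$data, aes(x = .data$log_eta, y = .data$log_v)) +
    geom_point(shape = 1, size = 2) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "steelblue") +
    labs(x = expression(log[10] ~ eta * "*" ~ "(Pa s)"),
         y = expression(log[10] ~ "VSL" ~ (mu * m / s)),
         title = sprintf("r = %.3f, p = %.2g, n = %d",
                         object$r, object$p, object$n))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
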