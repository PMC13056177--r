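options(ptmr.verbose = FALSE)

# brute-force time-averaged 2-D MSD over all frame pairs (independent oracle)
brute_msd <- function(frame, x, y, frame_rate = 1) {
  lags <- sort(unique(as.vector(outer(frame, frame, `-`))))
  lags <- lags[lags > 0]
  out <- lapply(lags, function(L) {
    acc <- c()
    for (i in seq_along(frame)) {
      j <- which(frame == frame[i] + L)
      if (length(j) == 1) {
        acc <- c(acc, (x[j] - x[i])^2 + (y[j] - y[i])^2)
      }
    }
    if (length(acc) == 0) return(NULL)
    data.frame(lag = L / frame_rate, msd = mean(acc), n_obs = length(acc))
  })
  do.call(rbind, out)
}

# hand-rolled Pearson r (independent of stats::cor)
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# a single rendered frame containing one spot at (x_px, y_px), noiseless
spot_frame <- function(x_px, y_px, preset = "bead", spot_aspect = NULL,
                       size = NULL) {
  rc <- render_config(preset = preset, noise_model = "none",
                      spot_aspect = spot_aspect, image_size = size)
  tr <- tibble::tibble(particle = 1L, frame = 0:1,
                       x = c(x_px, x_px + 1) * rc$pixel_size,
                       y = c(y_px, y_px) * rc$pixel_size)
  st <- render_stack(tr, rc, frame_rate = 10)
  matrix(st[, , 1], dim(st)[1], dim(st)[2])
}

# well-separated grid of n quasi-stationary particles for linking tests
grid_detections <- function(n = 2, n_frames = 10, spacing = 40) {
  expand.grid(p = seq_len(n), frame = 0:(n_frames - 1)) |>
    dplyr::mutate(x = 20 + (.data$p - 1) * spacing, y = 25) |>
    dplyr::select("frame", "x", "y") |>
    dplyr::arrange(.data$frame) |>
    tibble::as_tibble()
}
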