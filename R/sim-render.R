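#' Render trajectories into a synthetic image stack
#'
#' Draws each particle as a 2-D Gaussian spot of standard deviation
#' `psf_sigma` (pixels) centered at its position in um divided by
#' `pixel_size`, on a constant background, then applies the configured noise
#' model and clips to the bit depth. When `spot_aspect > 1` the spot is
#' elongated along the particle's instantaneous direction of motion
#' (sigma_major = psf_sigma * aspect, sigma_minor = psf_sigma / sqrt(aspect)
#' normalized so the spot mass is aspect-independent). Pixel convention:
#' 0-based pixel centers, x = column, y = row, origin at the top-left.
#'
#' @param tracks Tibble `(particle, frame, x, y)` with positions in um.
#' @param render A [render_config()].
#' @param frame_rate Acquisition rate, Hz (stored as stack metadata).
#' @param seed Optional integer seed scoping the rendering noise; when `NULL`
#'   the session RNG stream is used.
#' @return An `image_stack`: integer array `(row, col, frame)` with
#'   attributes `frame_rate` and `pixel_size`.
#' @export
render_stack <- function(tracks, render, frame_rate, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            render_stack(tracks, render, frame_rate)))
  }
  stopifnot(inherits(render, "render_config"))
  check_positive(frame_rate, "frame_rate")
  if (nrow(tracks) > 0) {
    check_tracks(tracks)
    if (any(!is.finite(tracks$x)) || any(!is.finite(tracks$y))) {
      abort_param("Track positions must be finite.")
    }
  }
  h <- render$image_size[1]; w <- render$image_size[2]
  frames <- if (nrow(tracks) > 0) sort(unique(tracks$frame)) else 0L
  n_frames <- length(frames)
  maxval <- 2^render$bit_depth - 1
  half <- ceiling(4 * render$psf_sigma * max(1, render$spot_aspect))

  # per-particle motion direction for elongated spots
  if (nrow(tracks) > 0 && render$spot_aspect > 1) {
    tracks <- tracks |>
      group_by(.data$particle) |>
      arrange(.data$frame, .by_group = TRUE) |>
      mutate(
        dxn = c(diff(.data$x), NA), dyn = c(diff(.data$y), NA),
        theta = atan2(coalesce(.data$dyn, lag(.data$dyn, default = 0)),
                      coalesce(.data$dxn, lag(.data$dxn, default = 1)))
      ) |>
      ungroup() |>
      mutate(theta = ifelse(is.finite(.data$theta), .data$theta, 0))
  } else if (nrow(tracks) > 0) {
    tracks$theta <- 0
  }

  n_clipped <- 0L
  # plain vectors for the hot loop
  tx <- if (nrow(tracks) > 0) tracks$x else numeric()
  ty <- if (nrow(tracks) > 0) tracks$y else numeric()
  tth <- if (nrow(tracks) > 0 && render$spot_aspect > 1) tracks$theta else NULL
  by_frame <- if (nrow(tracks) > 0) {
    split(seq_len(nrow(tracks)), tracks$frame)
  } else {
    list()
  }
  s_maj <- render$psf_sigma * sqrt(render$spot_aspect)
  s_min <- render$psf_sigma / sqrt(render$spot_aspect)
  stack <- array(0, dim = c(h, w, n_frames))

  for (k in seq_len(n_frames)) {
    img <- matrix(render$background, h, w)
    idx <- by_frame[[as.character(frames[k])]]
    if (!is.null(idx)) {
      for (i in idx) {
        px <- tx[i] / render$pixel_size
        py <- ty[i] / render$pixel_size
        if (px < -half || px > w - 1 + half || py < -half || py > h - 1 + half) {
          n_clipped <- n_clipped + 1L
          next
        }
        c0 <- max(0L, floor(px) - half); c1 <- min(w - 1L, floor(px) + half)
        r0 <- max(0L, floor(py) - half); r1 <- min(h - 1L, floor(py) + half)
        if (c1 < c0 || r1 < r0) { n_clipped <- n_clipped + 1L; next }
        cols <- c0:c1; rows <- r0:r1
        dx <- outer(rep(1, length(rows)), cols - px)
        dy <- outer(rows - py, rep(1, length(cols)))
        if (render$spot_aspect > 1) {
          th <- tth[i]
          u <- dx * cos(th) + dy * sin(th)   # along motion
          v <- -dx * sin(th) + dy * cos(th)  # across motion
          spot <- render$spot_intensity *
            exp(-u^2 / (2 * s_maj^2) - v^2 / (2 * s_min^2))
        } else {
          spot <- render$spot_intensity *
            exp(-(dx^2 + dy^2) / (2 * render$psf_sigma^2))
        }
        img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] + spot
      }
    }
    stack[, , k] <- img
  }
  # apply noise and quantization to the whole stack at once
  if (render$noise_model == "gaussian") {
    stack <- stack + rnorm(length(stack), 0, render$noise_sd)
  } else if (render$noise_model == "poisson") {
    dims <- dim(stack)
    stack[stack < 0] <- 0
    stack <- stats::rpois(length(stack), lambda = stack)
    dim(stack) <- dims
    stack <- stack * 1 # integer -> double storage
  }
  stack <- round(stack)
  stack[stack < 0] <- 0
  stack[stack > maxval] <- maxval
  if (n_clipped > 0) {
    ptmr_log("render_stack: %d particle draws outside the frame were clipped.",
             n_clipped)
  }
  image_stack(stack, frame_rate = frame_rate, pixel_size = render$pixel_size)
}

#' Construct an image stack
#'
#' @param frames Numeric array `(row, col, frame)` or a list of equal-size
#'   matrices.
#' @param frame_rate Acquisition rate, Hz.
#' @param pixel_size Calibration, um/pixel.
#' @return An `image_stack` array with calibration attributes.
#' @export
image_stack <- function(frames, frame_rate, pixel_size) {
  if (is.list(frames)) {
    dims <- unique(map(frames, dim))
    if (length(dims) != 1L) abort_param("All frames must have identical size.")
    arr <- array(0, dim = c(dims[[1]][1], dims[[1]][2], length(frames)))
    for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
    frames <- arr
  }
  if (length(dim(frames)) != 3L) {
    abort_param("`frames` must be a (row, col, frame) array.")
  }
  check_positive(frame_rate, "frame_rate")
  check_positive(pixel_size, "pixel_size")
  structure(frames, frame_rate = frame_rate, pixel_size = pixel_size,
            class = c("image_stack", "array"))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d frames of %d x %d px, %.3g fps, %.3g um/px\n",
              d[3], d[1], d[2], attr(x, "frame_rate"), attr(x, "pixel_size")))
  invisible(x)
}
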