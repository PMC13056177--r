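#' Detection parameters
#'
#' Shape and intensity filters for feature detection. The bead regime uses a
#' feature diameter of 11 px and a maximum eccentricity of 0.3; the sperm
#' regime enlarges these to 17 px and 0.5 to admit the bigger, elongated
#' sperm heads while leaving the algorithm itself unchanged.
#'
#' @param feature_diameter Odd integer feature size, pixels.
#' @param max_eccentricity Maximum moment eccentricity
#'   (lambda1 - lambda2)/(lambda1 + lambda2) of the masked intensity; 0 is
#'   circular.
#' @param min_mass Minimum integrated (band-passed) intensity; 0 disables.
#' @param noise_size Band-pass blur scale, pixels.
#' @param threshold_percentile Percentile of the band-passed image below
#'   which local maxima are ignored.
#' @param preset `"bead"` (default) or `"sperm"`; the preset fills any of
#'   the shape arguments not supplied explicitly.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(feature_diameter = NULL, max_eccentricity = NULL,
                             min_mass = NULL, noise_size = 1,
                             threshold_percentile = 64,
                             preset = c("bead", "sperm")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    bead  = list(feature_diameter = 11L, max_eccentricity = 0.3, min_mass = 0),
    sperm = list(feature_diameter = 17L, max_eccentricity = 0.5, min_mass = 0)
  )
  feature_diameter <- feature_diameter %||% defaults$feature_diameter
  max_eccentricity <- max_eccentricity %||% defaults$max_eccentricity
  min_mass <- min_mass %||% defaults$min_mass
  feature_diameter <- check_count(feature_diameter, "feature_diameter", min = 3L)
  if (feature_diameter %% 2L == 0L) {
    abort_param("`feature_diameter` must be odd.")
  }
  if (max_eccentricity < 0 || max_eccentricity >= 1) {
    abort_param("`max_eccentricity` must lie in [0, 1).")
  }
  check_nonneg(min_mass, "min_mass")
  structure(
    list(feature_diameter = feature_diameter,
         max_eccentricity = max_eccentricity, min_mass = min_mass,
         noise_size = noise_size,
         threshold_percentile = threshold_percentile, preset = preset),
    class = "detection_params"
  )
}

# Iterative Crocker-Grier centroid refinement plus moment statistics for one
# candidate local maximum. `bp` is the band-passed frame; (row, col) 1-based.
refine_feature <- function(bp, row, col, radius, max_iter = 10L, tol = 0.05) {
  h <- nrow(bp); w <- ncol(bp)
  offs <- -radius:radius
  dx <- outer(rep(1, length(offs)), offs)
  dy <- outer(offs, rep(1, length(offs)))
  mask <- (dx^2 + dy^2) <= radius^2
  off_x <- off_y <- 0
  for (iter in seq_len(max_iter)) {
    if (row <= radius || row > h - radius || col <= radius || col > w - radius) {
      return(NULL) # mask would leave the frame
    }
    patch <- bp[(row - radius):(row + radius), (col - radius):(col + radius)]
    pm <- patch * mask
    mass <- sum(pm)
    if (mass <= 0) return(NULL)
    off_x <- sum(pm * dx) / mass
    off_y <- sum(pm * dy) / mass
    if (max(abs(off_x), abs(off_y)) <= max(0.5, tol)) break
    col <- col + sign(off_x) * (abs(off_x) > 0.5)
    row <- row + sign(off_y) * (abs(off_y) > 0.5)
  }
  if (row <= radius || row > h - radius || col <= radius || col > w - radius) {
    return(NULL)
  }
  # moments about the refined centroid
  rx <- dx - off_x; ry <- dy - off_y
  pm <- bp[(row - radius):(row + radius), (col - radius):(col + radius)] * mask
  mass <- sum(pm)
  if (mass <= 0) return(NULL)
  mu20 <- sum(pm * rx^2) / mass
  mu02 <- sum(pm * ry^2) / mass
  mu11 <- sum(pm * rx * ry) / mass
  denom <- mu20 + mu02
  ecc <- if (denom > 0) sqrt((mu20 - mu02)^2 + 4 * mu11^2) / denom else 0
  c(x = unname(col - 1 + off_x), y = unname(row - 1 + off_y),
    mass = mass, size = sqrt(denom), ecc = ecc)
}

empty_detections <- function() {
  matrix(numeric(0), 0, 5,
         dimnames = list(NULL, c("x", "y", "mass", "size", "ecc")))
}

#' Locate particle-like features in a frame
#'
#' Crocker-Grier detection: band-pass filter, local maxima above an intensity
#' percentile, iterative sub-pixel centroid refinement within a circular mask
#' of radius `feature_diameter %/% 2`, intensity-moment statistics (mass,
#' radius of gyration, eccentricity), then mass/eccentricity filters and
#' merging of duplicate maxima closer than one feature diameter (the larger
#' mass wins; ties break toward lower (y, x)). Coordinates are 0-based pixel
#' centers with x = column, y = row.
#'
#' @param frame Numeric matrix.
#' @param params A [detection_params()].
#' @return Tibble `(x, y, mass, size, ecc)`; zero rows when nothing is found.
#' @export
locate_features <- function(frame, params = detection_params()) {
  stopifnot(is.matrix(frame), inherits(params, "detection_params"))
  d <- params$feature_diameter
  if (nrow(frame) <= d || ncol(frame) <= d) {
    abort_param("Frame dimensions must exceed `feature_diameter`.")
  }
  bp <- bandpass_filter(frame, params$noise_size, d)
  detections_tibble(locate_in_bandpassed(bp, params))
}

detections_tibble <- function(m) {
  tibble(x = m[, "x"], y = m[, "y"], mass = m[, "mass"],
         size = m[, "size"], ecc = m[, "ecc"])
}

# Candidate selection, refinement and shape filtering on an already
# band-passed frame (shared by locate_features and locate_stack); returns a
# matrix with columns x, y, mass, size, ecc.
locate_in_bandpassed <- function(bp, params) {
  d <- params$feature_diameter
  radius <- d %/% 2L
  thr <- max(intensity_threshold(bp, params$threshold_percentile), 0)
  above <- which(bp > thr)
  if (length(above) == 0L) return(empty_detections())
  if (length(above) <= 4000L) {
    # sparse: test the local-max property only at above-threshold pixels
    h <- nrow(bp)
    rr <- ((above - 1L) %% h) + 1L
    cc <- ((above - 1L) %/% h) + 1L
    is_max <- vapply(seq_along(above), function(i) {
      r0 <- max(1L, rr[i] - radius); r1 <- min(h, rr[i] + radius)
      c0 <- max(1L, cc[i] - radius); c1 <- min(ncol(bp), cc[i] + radius)
      bp[rr[i], cc[i]] >= max(bp[r0:r1, c0:c1])
    }, logical(1))
    cand <- cbind(row = rr[is_max], col = cc[is_max])
  } else {
    mf <- max_filter(bp, d)
    cand <- which(bp == mf & bp > thr & bp > 0, arr.ind = TRUE)
  }
  if (nrow(cand) == 0L) return(empty_detections())
  # drop candidates whose mask would leave the frame, and candidates whose
  # peak provably cannot reach min_mass (mass <= mask pixel count * peak)
  mask_px <- sum(outer((-radius:radius)^2, (-radius:radius)^2, `+`) <= radius^2)
  peak <- bp[cand]
  keep <- cand[, 1] > radius & cand[, 1] <= nrow(bp) - radius &
    cand[, 2] > radius & cand[, 2] <= ncol(bp) - radius &
    peak * mask_px >= params$min_mass
  cand <- cand[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    refine_feature(bp, cand[i, 1], cand[i, 2], radius)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_detections())
  m <- do.call(rbind, rows)
  # merge duplicates closer than one diameter, larger mass first (ties break
  # toward lower (y, x))
  ord <- order(-m[, "mass"], m[, "y"], m[, "x"])
  m <- m[ord, , drop = FALSE]
  nf <- nrow(m)
  kept <- rep(TRUE, nf)
  for (i in seq_len(nf)) {
    if (!kept[i] || i == nf) next
    j <- (i + 1L):nf
    too_close <- (m[j, "x"] - m[i, "x"])^2 + (m[j, "y"] - m[i, "y"])^2 < d^2
    kept[j][too_close & kept[j]] <- FALSE
  }
  keep <- kept & m[, "mass"] >= params$min_mass &
    m[, "ecc"] <= params$max_eccentricity
  m <- m[keep, , drop = FALSE]
  m[order(m[, "y"], m[, "x"]), , drop = FALSE]
}

#' Locate features in every frame of a stack
#'
#' @param stack An [image_stack()].
#' @param params A [detection_params()].
#' @return Tibble `(frame, x, y, mass, size, ecc)` with 0-based frames.
#' @export
locate_stack <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack)
  if (d[1] <= params$feature_diameter || d[2] <= params$feature_diameter) {
    abort_param("Frame dimensions must exceed `feature_diameter`.")
  }
  n_frames <- d[3]
  bps <- bandpass_stack(stack, params$noise_size, params$feature_diameter)
  mats <- map(seq_len(n_frames), function(k) {
    m <- locate_in_bandpassed(bps[[k]], params)
    cbind(frame = rep(k - 1L, nrow(m)), m)
  })
  m <- do.call(rbind, mats)
  out <- tibble(frame = as.integer(m[, "frame"]), x = m[, "x"], y = m[, "y"],
                mass = m[, "mass"], size = m[, "size"], ecc = m[, "ecc"])
  ptmr_log("locate_stack: %d detections across %d frames.", nrow(out), n_frames)
  out
}
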