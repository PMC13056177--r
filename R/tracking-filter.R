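# Separable image filters used by the Crocker-Grier detector. Kernels are
# 1-D and applied along columns then rows; edges are replicated so constant
# images are preserved exactly. Implementations lean on indexed shifts and
# cumulative sums, which keeps per-frame cost linear in pixels.

shift_rows <- function(m, s) {
  # shift rows by s (positive pulls later rows up) with edge replication
  n <- nrow(m)
  idx <- pmin(pmax(seq_len(n) + s, 1L), n)
  m[idx, , drop = FALSE]
}

convolve_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  centre <- r + 1L
  out <- m * k[centre]
  for (s in seq_len(r)) {
    out <- out + k[centre + s] * shift_rows(m, s) +
      k[centre - s] * shift_rows(m, -s)
  }
  out
}

convolve_sep <- function(m, k) {
  convolve_cols(t(convolve_cols(t(m), k)), k)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(2 * sigma)) # 2 sigma truncation, renormalized
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Column-wise boxcar mean of width w (odd) via one running cumulative sum
# over the padded matrix laid out column-major (per-column baselines are the
# totals at the end of the preceding column).
boxcar_cols <- function(m, w) {
  r <- (w - 1L) %/% 2L
  n <- nrow(m); nc <- ncol(m)
  mp <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
  np <- n + 2L * r
  csv <- cumsum(as.numeric(mp))
  cs <- matrix(csv, np, nc)
  upper <- cs[(2L * r + 1L):np, , drop = FALSE]
  prev <- c(0, csv[np * seq_len(nc - 1L)])
  lower <- rbind(prev, cs[seq_len(np - 1L), , drop = FALSE])[seq_len(n), ,
                                                             drop = FALSE]
  out <- (upper - lower) / w
  dimnames(out) <- NULL
  out
}

boxcar_sep <- function(m, w) {
  boxcar_cols(t(boxcar_cols(t(m), w)), w)
}

# Column-wise running max over offsets 0..r (dir = 1) or -r..0 (dir = -1),
# by doubling; edge replication is harmless for a max.
running_max_cols <- function(m, r, dir) {
  out <- m
  cover <- 1L
  while (cover <= r) {
    step <- min(cover, r - cover + 1L)
    out <- pmax(out, shift_rows(out, dir * step))
    cover <- cover + step
  }
  out
}

max_filter_cols <- function(m, w) {
  r <- (w - 1L) %/% 2L
  if (r == 0L) return(m)
  pmax(running_max_cols(m, r, 1L), running_max_cols(m, r, -1L))
}

# Grayscale max filter over a w x w square window (w odd).
max_filter <- function(m, w) {
  t(max_filter_cols(t(max_filter_cols(m, w)), w))
}

# kth-smallest threshold (partial sort; cheaper than a full quantile)
intensity_threshold <- function(x, percentile) {
  n <- length(x)
  k <- min(n, max(1L, ceiling(percentile / 100 * n)))
  sort(x, partial = k)[k]
}

# Band-pass a whole (H, W, T) stack by applying the separable passes to all
# frames laid out side by side (vertical pass on an H x (W*T) matrix, then,
# after a per-frame transpose, on a W x (H*T) matrix), which amortises
# per-call overhead across frames. The blur and background parts are carried
# separately through both passes. Chunked to bound peak memory. Returns a
# list of H x W band-passed matrices.
bandpass_stack <- function(stack, noise_size, feature_diameter,
                           chunk_px = 3e5) {
  d <- dim(stack)
  h <- d[1]; w <- d[2]; n_frames <- d[3]
  gk <- gaussian_kernel(noise_size)
  if (feature_diameter %% 2L == 0L) feature_diameter <- feature_diameter + 1L
  chunk <- max(1L, floor(chunk_px / (h * w)))
  out <- vector("list", n_frames)
  pos <- 1L
  while (pos <= n_frames) {
    idx <- pos:min(pos + chunk - 1L, n_frames)
    nt <- length(idx)
    # horizontal pass on per-frame transposes, then vertical pass after
    # flipping back: one flip in each direction serves both kernels
    vt <- matrix(aperm(stack[, , idx, drop = FALSE], c(2, 1, 3)), w, h * nt)
    blur_t <- convolve_cols(vt, gk)
    bg_t <- boxcar_cols(vt, feature_diameter)
    unflip <- function(m) {
      matrix(aperm(array(m, c(w, h, nt)), c(2, 1, 3)), h, w * nt)
    }
    bp <- convolve_cols(unflip(blur_t), gk) -
      boxcar_cols(unflip(bg_t), feature_diameter)
    bp[bp < 0] <- 0
    dim(bp) <- c(h, w, nt)
    for (k in seq_len(nt)) {
      out[[idx[k]]] <- matrix(bp[, , k], h, w)
    }
    pos <- pos + chunk
  }
  out
}

#' Band-pass filter a frame
#'
#' Standard Crocker-Grier preprocessing: a Gaussian blur at the noise length
#' scale minus a boxcar (flat) background estimate at the feature length
#' scale, with negative values clipped to zero. A uniform image maps to all
#' zeros.
#'
#' @param frame Numeric matrix (one image frame).
#' @param noise_size Gaussian blur standard deviation, pixels.
#' @param feature_diameter Background boxcar width, pixels (odd integer,
#'   larger than `noise_size`).
#' @return Filtered matrix, same size, min >= 0.
#' @export
bandpass_filter <- function(frame, noise_size = 1, feature_diameter = 11) {
  stopifnot(is.matrix(frame))
  check_positive(noise_size, "noise_size")
  feature_diameter <- check_count(feature_diameter, "feature_diameter", min = 3L)
  if (feature_diameter <= noise_size) {
    abort_param("`feature_diameter` must exceed `noise_size`.")
  }
  if (feature_diameter %% 2L == 0L) feature_diameter <- feature_diameter + 1L
  out <- convolve_sep(frame, gaussian_kernel(noise_size)) -
    boxcar_sep(frame, feature_diameter)
  out[out < 0] <- 0
  out
}
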