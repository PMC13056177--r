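#' Read a time-lapse image stack
#'
#' Accepts a multi-page TIFF file or a directory of per-frame images (TIFF or
#' PNG, ordered lexicographically by file name). Calibration must be supplied
#' explicitly: frame rate and pixel size are not trusted from file metadata.
#'
#' @param path Multi-page TIFF file or directory of per-frame images.
#' @param frame_rate Acquisition rate, Hz (required).
#' @param pixel_size Calibration, um/pixel (required).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, frame_rate = NULL, pixel_size = NULL) {
  if (is.null(frame_rate) || is.null(pixel_size)) {
    abort_param("Explicit `frame_rate` and `pixel_size` are required to read a stack.")
  }
  if (!file.exists(path)) {
    abort(sprintf("Path does not exist: %s", path), class = "ptmr_io")
  }
  read_one <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      round(img * 255)
    } else {
      img <- tiff::readTIFF(f, as.is = TRUE)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img
    }
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      abort(sprintf("No frame images found in %s", path), class = "ptmr_io")
    }
    frames <- map(files, read_one)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- map(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  }
  dims <- unique(map(frames, dim))
  if (length(dims) != 1L) {
    abort("Frames have mixed sizes; a stack must be homogeneous.",
          class = "ptmr_io")
  }
  ptmr_log("read_image_stack: %d frames of %d x %d px.",
           length(frames), dims[[1]][1], dims[[1]][2])
  image_stack(frames, frame_rate = frame_rate, pixel_size = pixel_size)
}

#' Write an image stack
#'
#' @param stack An [image_stack()].
#' @param path Output path: a `.tif`/`.tiff` file (multi-page, 16-bit) or a
#'   directory (per-frame PNGs, 8-bit, lexicographically ordered names).
#' @param bit_depth Bits per sample for TIFF output.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bit_depth = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack)[3]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    maxval <- 2^bit_depth - 1
    pages <- map(seq_len(n), function(k) {
      matrix(pmin(pmax(stack[, , k], 0), maxval) / maxval,
             dim(stack)[1], dim(stack)[2])
    })
    tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(n)) {
      png::writePNG(
        matrix(pmin(pmax(stack[, , k], 0), 255) / 255,
               dim(stack)[1], dim(stack)[2]),
        file.path(path, sprintf("frame_%05d.png", k - 1L)))
    }
  }
  invisible(path)
}

#' Write trajectories to CSV
#'
#' Columns: `particle, frame, x, y` plus any extra columns present (e.g.
#' `mass`, `size`, `ecc`, `true_speed`).
#'
#' @param tracks Tracks tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tracks, path) {
  check_tracks(tracks[, , drop = FALSE])
  first <- intersect(c("particle", "frame", "x", "y"), names(tracks))
  readr::write_csv(tracks |> select(all_of(first), everything()), path)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Validates the trajectory contract: required columns present and frame
#' indices strictly increasing within each particle (the offending data line
#' is reported otherwise).
#'
#' @param path CSV written by [write_trajectories()].
#' @return Tracks tibble.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Path does not exist: %s", path), class = "ptmr_io")
  }
  tracks <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(c("particle", "frame", "x", "y"), names(tracks))
  if (length(missing_cols) > 0) {
    abort(sprintf("Malformed trajectory CSV %s: missing column(s) %s.",
                  path, paste(missing_cols, collapse = ", ")),
          class = "ptmr_io")
  }
  if (nrow(tracks) == 0L) return(tracks)
  if (!is.numeric(tracks$frame) || !is.numeric(tracks$x) ||
      !is.numeric(tracks$y)) {
    abort(sprintf("Malformed trajectory CSV %s: non-numeric coordinates.",
                  path), class = "ptmr_io")
  }
  bad <- tracks |>
    mutate(.line = dplyr::row_number() + 1L) |>
    group_by(.data$particle) |>
    filter(.data$frame <= lag(.data$frame, default = -Inf)) |>
    ungroup()
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Malformed trajectory CSV %s: non-increasing frame for particle %s at line %d.",
      path, format(bad$particle[1]), bad$.line[1]), class = "ptmr_io")
  }
  tracks
}

#' Read/write a run configuration as YAML
#'
#' @param config A [run_config()] (or plain list).
#' @param path YAML path.
#' @return `read_run_config()` returns a [run_config()]; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Path does not exist: %s", path), class = "ptmr_io")
  }
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
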