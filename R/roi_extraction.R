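#' Rectangular region-of-interest specification
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner and
#' half-open ranges: the ROI covers columns `[x0, x0 + width)` and rows
#' `[y0, y0 + height)`.
#'
#' @param x0,y0 Top-left corner, 0-based pixel indices, >= 0.
#' @param width,height ROI extent in pixels, > 0.
#' @param frame_interval Time between consecutive frames in seconds, > 0.
#'   The acquisition frame rate is device-dependent and must be supplied.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x0, y0, width, height, frame_interval) {
  v <- c(x0, y0, width, height, frame_interval)
  if (!all(is.finite(v))) {
    stop_icg("roi_spec fields must be finite", class = "icg_validation_error")
  }
  if (x0 < 0 || y0 < 0) {
    stop_icg("`x0` and `y0` must be >= 0", class = "icg_validation_error")
  }
  if (width <= 0 || height <= 0) {
    stop_icg("`width` and `height` must be > 0",
             class = "icg_validation_error")
  }
  if (frame_interval <= 0) {
    stop_icg("`frame_interval` must be > 0", class = "icg_validation_error")
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height),
                 frame_interval = frame_interval),
            class = "roi_spec")
}

# ITU-R BT.709 luma weights used to reduce RGB frames to grayscale
.luma_weights <- c(0.2126, 0.7152, 0.0722)

#' Reduce a fluorescence frame stack to a ROI time-intensity curve
#'
#' The intensity at frame `i` is the arithmetic mean of the pixel values
#' inside the ROI; the time axis is `(i - 1) * frame_interval` so the record
#' starts at 0 s. Multi-channel (RGB) frames are reduced to luminance with
#' BT.709 weights before averaging.
#'
#' @param frames One of: a numeric 3-D array `[rows, cols, frames]` (or 2-D
#'   for a single frame, which is rejected as too short); a path to a
#'   multi-page TIFF; a directory containing PNG/TIFF frames, taken in
#'   lexicographic filename order; or a character vector of frame file paths.
#' @param roi A [roi_spec()].
#' @return A curve tibble (`time_s`, `intensity_au`), one row per frame.
#' @export
extract_roi_series <- function(frames, roi) {
  if (!inherits(roi, "roi_spec")) {
    stop_icg("`roi` must be a roi_spec()", class = "icg_validation_error")
  }
  mats <- as_frame_list(frames)
  if (length(mats) < 2) {
    stop_icg("a frame stack needs at least 2 frames",
             class = "icg_validation_error")
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_icg("all frames must have the same size",
             class = "icg_validation_error")
  }
  nr <- dims[1, 1]; nc <- dims[2, 1]
  # 0-based half-open [x0, x0+w) x [y0, y0+h) -> 1-based R row/col ranges
  rows <- (roi$y0 + 1L):(roi$y0 + roi$height)
  cols <- (roi$x0 + 1L):(roi$x0 + roi$width)
  if (roi$y0 + roi$height > nr || roi$x0 + roi$width > nc) {
    stop_icg(sprintf("ROI [%d,%d) x [%d,%d) exceeds frame bounds %d x %d",
                     roi$x0, roi$x0 + roi$width, roi$y0, roi$y0 + roi$height,
                     nc, nr),
             class = "icg_validation_error")
  }
  intensity <- vapply(mats, function(m) mean(m[rows, cols]), numeric(1))
  tibble::tibble(
    time_s = (seq_along(mats) - 1) * roi$frame_interval,
    intensity_au = intensity
  )
}

# normalise any accepted frame input into a list of numeric matrices
as_frame_list <- function(frames) {
  if (is.array(frames) && !is.list(frames)) {
    nd <- length(dim(frames))
    if (nd == 2) return(list(to_gray(frames)))
    if (nd == 3) {
      return(lapply(seq_len(dim(frames)[3]),
                    function(k) to_gray(frames[, , k])))
    }
    if (nd == 4) { # rows x cols x channels x frames
      return(lapply(seq_len(dim(frames)[4]),
                    function(k) to_gray(frames[, , , k])))
    }
    stop_icg("frame arrays must be 2-D, 3-D or 4-D",
             class = "icg_validation_error")
  }
  if (is.list(frames)) {
    if (length(frames) == 0) {
      stop_icg("empty frame stack", class = "icg_validation_error")
    }
    return(lapply(frames, to_gray))
  }
  if (is.character(frames)) {
    paths <- frames
    if (length(paths) == 1 && dir.exists(paths)) {
      paths <- sort(list.files(paths, pattern = "\\.(png|tif|tiff)$",
                               ignore.case = TRUE, full.names = TRUE))
    }
    if (length(paths) == 0) {
      stop_icg("no frame files found", class = "icg_io_error")
    }
    mats <- list()
    for (p in paths) mats <- c(mats, read_frames_file(p))
    return(mats)
  }
  stop_icg("unsupported frame stack input", class = "icg_validation_error")
}

read_frames_file <- function(path) {
  if (!file.exists(path)) {
    stop_icg(sprintf("frame file '%s' not found", path),
             class = "icg_io_error")
  }
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    x <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(x)) x <- list(x)
    lapply(x, to_gray)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    list(to_gray(png::readPNG(path)))
  } else {
    stop_icg(sprintf("unsupported frame format: '%s'", path),
             class = "icg_io_error")
  }
}

# collapse a rows x cols x channels array to grayscale; channels beyond 3
# (alpha) are ignored
to_gray <- function(m) {
  if (length(dim(m)) == 2 || is.null(dim(m))) return(as.matrix(m))
  ch <- dim(m)[3]
  if (ch == 1) return(m[, , 1])
  if (ch >= 3) {
    return(.luma_weights[1] * m[, , 1] + .luma_weights[2] * m[, , 2] +
             .luma_weights[3] * m[, , 3])
  }
  # 2-channel (gray + alpha): use the gray channel
  m[, , 1]
}

#' Render a synthetic frame stack from an intensity sequence
#'
#' Produces frames whose every pixel equals the given per-frame intensity;
#' useful for testing ROI extraction round trips against a known curve.
#'
#' @param intensity Numeric vector, one value per frame.
#' @param width,height Frame size in pixels.
#' @return A numeric array `[height, width, frames]`.
#' @export
render_frames <- function(intensity, width = 16, height = 12) {
  array(rep(intensity, each = width * height),
        dim = c(height, width, length(intensity)))
}
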