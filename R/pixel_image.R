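#' Calibrated pixel image
#'
#' Light container for a 2-D intensity grid with optional spatial
#' calibration. Intensities follow the 8-bit convention (0–255); values are
#' stored as doubles so noisy or averaged images keep sub-integer precision.
#'
#' @param intensities numeric matrix (single channel) or an
#'   `nrow x ncol x 3` array (RGB).
#' @param um_per_px optional calibration, micrometres per pixel (> 0).
#' @return A `pixel_image`: the numeric array with attributes `um_per_px`.
#' @examples
#' img <- pixel_image(matrix(128, 16, 16), um_per_px = 1.25)
#' dim(img)
#' @export
pixel_image <- function(intensities, um_per_px = NULL) {
  if (!is.numeric(intensities)) {
    stop("`intensities` must be numeric", call. = FALSE)
  }
  d <- dim(intensities)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L))) {
    stop("`intensities` must be a 2-D matrix or an nrow x ncol x 3 array",
         call. = FALSE)
  }
  if (d[1] == 0L || d[2] == 0L) stop("image must be non-empty", call. = FALSE)
  if (!is.null(um_per_px)) {
    stopifnot(is.numeric(um_per_px), length(um_per_px) == 1L)
    if (!is.finite(um_per_px) || um_per_px <= 0) {
      stop("`um_per_px` must be a positive number", call. = FALSE)
    }
  }
  structure(intensities, um_per_px = um_per_px, class = "pixel_image")
}

#' @export
print.pixel_image <- function(x, ...) {
  d <- dim(x)
  ch <- if (length(d) == 3L) d[3] else 1L
  cal <- attr(x, "um_per_px")
  cat(sprintf("<pixel_image> %d x %d, %d channel%s, range [%.4g, %.4g]%s\n",
              d[1], d[2], ch, if (ch > 1) "s" else "",
              min(x), max(x),
              if (is.null(cal)) "" else sprintf(", %g um/px", cal)))
  invisible(x)
}

n_channels <- function(image) {
  d <- dim(image)
  if (length(d) == 3L) d[3] else 1L
}

# strip class/attrs, return plain matrix (single channel required)
as_intensity_matrix <- function(image) {
  if (n_channels(image) != 1L) {
    stop("single-channel image required; run to_grayscale() first",
         call. = FALSE)
  }
  m <- unclass(image)
  attr(m, "um_per_px") <- NULL
  m
}

image_calibration <- function(image) attr(image, "um_per_px")

#' Convert an image to single-channel grayscale
#'
#' RGB images are reduced with the Rec. 601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B), the convention used by common 8-bit
#' greyscale conversions; single-channel input is returned unchanged.
#' Output is clipped to \[0, 255\].
#'
#' @param image a [pixel_image()] (or numeric matrix/array) with 1 or 3
#'   channels.
#' @return single-channel `pixel_image`, calibration preserved.
#' @export
to_grayscale <- function(image) {
  ch <- n_channels(image)
  if (ch == 1L) {
    if (inherits(image, "pixel_image")) return(image)
    return(pixel_image(image, um_per_px = image_calibration(image)))
  }
  if (ch != 3L) stop("unsupported channel count: ", ch, call. = FALSE)
  w <- c(0.299, 0.587, 0.114)
  m <- w[1] * image[, , 1] + w[2] * image[, , 2] + w[3] * image[, , 3]
  m <- pmin(pmax(m, 0), 255)
  pixel_image(m, um_per_px = image_calibration(image))
}
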