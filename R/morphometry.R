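#' Otsu automated threshold
#'
#' Implements the classic automated global threshold: pixels are binned into
#' the 256 integer levels of the 8-bit scale and the threshold `T` maximizing
#' the between-class variance \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} of
#' the split \{intensity <= T\} / \{intensity > T\} is returned. When several
#' thresholds tie, the smallest is returned. Pixels exactly at `T` belong to
#' the upper-intensity class's complement, i.e. the background side for a
#' dark object (see [segment_spheroid()]).
#'
#' @param image single-channel [pixel_image()], numeric matrix, or a bare
#'   numeric vector of intensities.
#' @return threshold intensity, an integer level in `[min, max)` of the
#'   observed intensities.
#' @export
auto_threshold <- function(image) {
  x <- if (is.matrix(image) || inherits(image, "pixel_image")) {
    as.vector(as_intensity_matrix(image))
  } else {
    as.numeric(image)
  }
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite intensities", call. = FALSE)
  bins <- pmin(pmax(round(x), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L) {
    stop("degenerate input: image has fewer than 2 distinct intensity levels",
         call. = FALSE)
  }
  levels <- 0:255
  n <- sum(counts)
  w0 <- cumsum(counts)               # pixels <= t
  s0 <- cumsum(counts * levels)      # intensity sum <= t
  total <- s0[256L]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0 / w0
  mu1 <- (total - s0) / w1
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  levels[which.max(bcv)]
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally.
label_components8 <- function(fg) {
  lab <- EBImage::imageData(EBImage::bwlabel(fg * 1))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left neighbours
  pa <- c(a1, a2); pb <- c(b1, b2)
  sel <- pa > 0 & pb > 0 & pa != pb
  if (!any(sel)) return(lab)
  pairs <- unique(cbind(pmin(pa[sel], pb[sel]), pmax(pa[sel], pb[sel])))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Fill interior holes: background components (4-connected, the complement
# convention for 8-connected foreground) not touching the frame border
# become foreground.
fill_holes <- function(mask) {
  bg <- EBImage::imageData(EBImage::bwlabel((!mask) * 1))
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

#' Segmented spheroid mask
#'
#' Constructor for the result of [segment_spheroid()]: a single filled
#' connected component plus the threshold that produced it.
#'
#' @param mask logical matrix, `TRUE` inside the spheroid.
#' @param threshold_used intensity threshold applied.
#' @param n_components_discarded number of foreground components removed in
#'   favour of the largest one.
#' @return a `spheroid_mask` object.
#' @export
spheroid_mask <- function(mask, threshold_used = NA_real_,
                          n_components_discarded = 0L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  structure(list(mask = mask,
                 threshold_used = threshold_used,
                 n_components_discarded = as.integer(n_components_discarded)),
            class = "spheroid_mask")
}

#' @export
print.spheroid_mask <- function(x, ...) {
  cat(sprintf("<spheroid_mask> %d x %d, area %d px, threshold %s, %d component(s) discarded\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              format(x$threshold_used), x$n_components_discarded))
  invisible(x)
}

as_mask_matrix <- function(section) {
  if (inherits(section, "spheroid_mask")) return(section$mask)
  stopifnot(is.logical(section), is.matrix(section))
  section
}

#' Segment a spheroid from a brightfield micrograph
#'
#' Reproduces the automated measurement macro: the image is converted to
#' greyscale, an automated (Otsu) threshold is found, the object side of the
#' threshold becomes foreground, the largest 8-connected component is kept
#' and its interior holes are filled. Brightfield spheroids are darker than
#' the background, so by default foreground means intensity strictly below
#' the threshold (pixels exactly at the threshold count as background).
#'
#' @param image [pixel_image()] or numeric matrix/array, 1 or 3 channels.
#' @param dark_object object darker than background (`TRUE`, brightfield
#'   default); set `FALSE` for inverted modalities (foreground strictly
#'   above threshold).
#' @param exclude_border discard components touching the image border
#'   (default `FALSE`: a spheroid grazing the frame is still eligible).
#' @param blur_sigma optional Gaussian pre-blur sigma in pixels; `NULL`
#'   (default) applies no pre-filter.
#' @return a [spheroid_mask()].
#' @export
segment_spheroid <- function(image, dark_object = TRUE,
                             exclude_border = FALSE, blur_sigma = NULL) {
  gray <- to_grayscale(image)
  m <- as_intensity_matrix(gray)
  if (!is.null(blur_sigma) && blur_sigma > 0) {
    m <- EBImage::imageData(EBImage::gblur(m, sigma = blur_sigma))
  }
  thr <- auto_threshold(m)
  fg <- if (dark_object) m < thr else m > thr
  if (!any(fg)) {
    stop(sprintf(
      "segmentation failure: empty foreground (threshold %g, intensity range [%g, %g], dark_object = %s)",
      thr, min(m), max(m), dark_object), call. = FALSE)
  }
  lab <- label_components8(fg)
  nlab <- max(lab)
  discarded <- 0L
  if (exclude_border) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                              lab[, 1], lab[, ncol(lab)]))
    border_labels <- border_labels[border_labels > 0]
    if (length(border_labels)) {
      lab[lab %in% border_labels] <- 0L
      discarded <- discarded + length(border_labels)
    }
    if (!any(lab > 0)) {
      stop("segmentation failure: all foreground components touch the border",
           call. = FALSE)
    }
  }
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which.max(sizes)
  discarded <- discarded + sum(sizes > 0) - 1L
  mask <- fill_holes(lab == keep)
  spheroid_mask(mask, threshold_used = thr,
                n_components_discarded = discarded)
}

#' Sphere volume from diameter
#'
#' \eqn{V = \frac{4}{3}\pi (d/2)^3}, the spherical-shape assumption used to
#' convert a spheroid's cross-sectional equivalent diameter to a volume.
#'
#' @param diameter_um diameter in micrometres.
#' @return volume in cubic micrometres.
#' @export
sphere_volume <- function(diameter_um) (4 / 3) * pi * (diameter_um / 2)^3

#' Measure a segmented spheroid
#'
#' Converts the mask's pixel area to a calibrated area, the diameter of the
#' circle of equal area (\eqn{d = 2\sqrt{A/\pi}}), and the volume of the
#' sphere of that diameter.
#'
#' @param mask a [spheroid_mask()] or logical matrix.
#' @param um_per_px calibration, micrometres per pixel.
#' @return one-row data.frame of class `morphometry` with columns
#'   `area_px`, `area_um2`, `equivalent_diameter_um`, `volume_um3`,
#'   `threshold`.
#' @export
measure_spheroid <- function(mask, um_per_px) {
  if (missing(um_per_px) || is.null(um_per_px)) {
    stop("calibration `um_per_px` is required", call. = FALSE)
  }
  stopifnot(is.numeric(um_per_px), length(um_per_px) == 1L, um_per_px > 0)
  m <- as_mask_matrix(mask)
  area_px <- sum(m)
  if (area_px == 0L) stop("mask is empty", call. = FALSE)
  area_um2 <- area_px * um_per_px^2
  d <- 2 * sqrt(area_um2 / pi)
  out <- data.frame(
    area_px = area_px,
    area_um2 = area_um2,
    equivalent_diameter_um = d,
    volume_um3 = sphere_volume(d),
    threshold = if (inherits(mask, "spheroid_mask")) mask$threshold_used
                else NA_real_
  )
  class(out) <- c("morphometry", "data.frame")
  out
}

#' Validate automated volumes against manual measurements
#'
#' Ordinary least-squares regression of automated on manual volumes, the
#' standard agreement check between an automated measurement pipeline and
#' manual caliper-style readings (manual = sphere volume from the average of
#' the largest and smallest diameters).
#'
#' @param auto automated volumes: numeric vector, or a list of
#'   `morphometry` rows (their `volume_um3` is used).
#' @param manual numeric vector of manual volumes, same length.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
validate_against_manual <- function(auto, manual) {
  if (is.list(auto) && !is.data.frame(auto)) {
    auto <- vapply(auto, function(m) m$volume_um3, numeric(1))
  }
  auto <- as.numeric(auto); manual <- as.numeric(manual)
  if (length(auto) != length(manual)) {
    stop("`auto` and `manual` must be paired lists of equal length",
         call. = FALSE)
  }
  if (length(auto) < 3L) stop("need at least 3 paired measurements",
                              call. = FALSE)
  fit <- lm(auto ~ manual)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
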