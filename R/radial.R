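#' Positive-stain mask
#'
#' Pixels inside the section whose intensity is strictly above the
#' threshold. With `threshold = "auto"` the Otsu threshold is computed from
#' the in-section intensities only.
#'
#' @param image single-channel [pixel_image()] or numeric matrix.
#' @param section section mask ([spheroid_mask()] or logical matrix), same
#'   shape as `image`.
#' @param threshold numeric intensity or `"auto"`.
#' @return logical matrix, `TRUE` on positive pixels; the threshold used is
#'   attached as attribute `threshold`.
#' @export
positive_mask <- function(image, section, threshold = "auto") {
  m <- as_intensity_matrix(image)
  sec <- as_mask_matrix(section)
  if (!identical(dim(m), dim(sec))) {
    stop("image and section mask have different shapes", call. = FALSE)
  }
  thr <- if (identical(threshold, "auto")) auto_threshold(m[sec]) else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  structure(sec & m > thr, threshold = thr)
}

#' Euclidean depth map of a section mask
#'
#' For every in-mask pixel, the Euclidean distance to the nearest
#' out-of-mask pixel ("depth" below the section boundary); outside pixels
#' are 0. Pixels beyond the image frame count as out-of-mask, so a section
#' grazing the frame still gets depth 1 at the frame edge.
#'
#' @param section [spheroid_mask()] or logical matrix, nonempty.
#' @return numeric matrix of depths, same shape as the mask.
#' @export
depth_map <- function(section) {
  sec <- as_mask_matrix(section)
  if (!any(sec)) stop("empty mask", call. = FALSE)
  nr <- nrow(sec); nc <- ncol(sec)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- sec
  d <- EBImage::imageData(EBImage::distmap(padded, metric = "euclidean"))
  d[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

#' Concentric region map of a section
#'
#' Partitions the section into three concentric regions of equidistant
#' thickness — periphery, intermediate and core, each one third of the
#' section radius — where the radius `R` is the maximum of the Euclidean
#' depth map (so the definition also works for non-circular sections).
#' Region boundaries sit at depths `R/3` and `2R/3`; a pixel exactly on a
#' boundary belongs to the shallower (outer) region.
#'
#' @param section [spheroid_mask()] or logical matrix, nonempty.
#' @return a `region_map`: list with `labels` (integer matrix, 0 = outside,
#'   1 = periphery, 2 = intermediate, 3 = core), `depth_map`, and
#'   `max_depth_px` (R).
#' @export
assign_regions <- function(section) {
  depth <- depth_map(section)
  R <- max(depth)
  labels <- matrix(0L, nrow(depth), ncol(depth))
  labels[depth > 0] <- 1L
  labels[depth > R / 3] <- 2L
  labels[depth > 2 * R / 3] <- 3L
  structure(list(labels = labels, depth_map = depth, max_depth_px = R),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  n <- tabulate(x$labels[x$labels > 0], nbins = 3L)
  cat(sprintf("<region_map> R = %.2f px; periphery %d, intermediate %d, core %d px\n",
              x$max_depth_px, n[1], n[2], n[3]))
  invisible(x)
}

region_names <- c("periphery", "intermediate", "core")

#' Radial distribution of positive stain
#'
#' Thresholds the section for positive signal, then sums the positive
#' pixels' intensities within the periphery/intermediate/core thirds (see
#' [assign_regions()]) and expresses each region as a percent of the total
#' positive signal in the section. By default sums are intensity-weighted;
#' `binary = TRUE` counts positive pixels instead.
#'
#' If the section contains no positive signal the percentages are undefined:
#' they are returned as `NA` with `defined = FALSE` rather than an error.
#'
#' @inheritParams positive_mask
#' @param binary count positive pixels instead of summing their intensities.
#' @return a `radial_distribution`: list with `pct_periphery`,
#'   `pct_intermediate`, `pct_core`, `region_sums`, `total_positive_signal`,
#'   `positive_threshold`, `max_depth_px`, `defined`.
#' @export
radial_signal_distribution <- function(image, section, threshold = "auto",
                                       binary = FALSE) {
  m <- as_intensity_matrix(image)
  pos <- positive_mask(image, section, threshold)
  thr <- attr(pos, "threshold")
  regions <- assign_regions(section)
  weights <- if (binary) (pos * 1) else (m * pos)
  sums <- vapply(1:3, function(k) sum(weights[regions$labels == k]),
                 numeric(1))
  total <- sum(sums)
  pct <- if (total > 0) 100 * sums / total else rep(NA_real_, 3L)
  structure(list(pct_periphery = pct[1],
                 pct_intermediate = pct[2],
                 pct_core = pct[3],
                 region_sums = setNames(sums, region_names),
                 total_positive_signal = total,
                 positive_threshold = thr,
                 max_depth_px = regions$max_depth_px,
                 defined = total > 0),
            class = "radial_distribution")
}

#' @export
print.radial_distribution <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<radial_distribution> periphery %.1f%% | intermediate %.1f%% | core %.1f%% (total signal %.4g, threshold %g)\n",
                x$pct_periphery, x$pct_intermediate, x$pct_core,
                x$total_positive_signal, x$positive_threshold))
  } else {
    cat("<radial_distribution> no positive signal; percentages undefined\n")
  }
  invisible(x)
}
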