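#' Read an image file as a pixel image
#'
#' Reads 8- or 16-bit TIFF or PNG, single-channel or RGB. Intensities are
#' preserved on their native integer scale by default (0–255 for 8-bit,
#' 0–65535 for 16-bit); `rescale_8bit = TRUE` maps deeper images onto the
#' 8-bit scale. RGBA alpha channels are dropped.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param um_per_px optional calibration to attach.
#' @param rescale_8bit rescale 16-bit intensities to 0–255.
#' @return a [pixel_image()].
#' @export
read_pixel_image <- function(path, um_per_px = NULL, rescale_8bit = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)  # native integer scale
    depth <- if (max(a) > 255) 65535 else 255
  } else if (ext == "png") {
    a <- png::readPNG(path)                  # [0,1]
    depth <- 255
    a <- round(a * 255)
  } else {
    stop("unknown image format: .", ext, call. = FALSE)
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3]  # drop alpha
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
  if (rescale_8bit && depth > 255) a <- a / depth * 255
  storage.mode(a) <- "double"
  pixel_image(a, um_per_px = um_per_px)
}

#' Write a pixel image to an 8-bit TIFF or PNG
#'
#' Intensities are clipped to \[0, 255\], rounded, and written as 8-bit.
#'
#' @param image a [pixel_image()] or numeric matrix/array on the 8-bit
#'   scale.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_pixel_image <- function(image, path) {
  a <- unclass(image)
  attr(a, "um_per_px") <- NULL
  a <- round(pmin(pmax(a, 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(a, path)
  } else {
    stop("unknown image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read tabular pipeline inputs with schema validation
#'
#' CSV readers for the four tabular inputs; each checks for its required
#' columns and reports any that are missing by name.
#'
#' * growth table: `arm`, `replicate`, `day`, `volume_um3`
#' * plate table: `well`, `role` (treatment/control/media),
#'   `concentration_ng_ml`, `absorbance`
#' * clonogenic table: `condition`, `cells_plated`, `colonies`
#' * release table: `time_h`, `cumulative_fraction`
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_growth_table <- function(path) {
  check_columns(read.csv(path), c("arm", "replicate", "day", "volume_um3"),
                "growth table")
}

#' @rdname read_growth_table
#' @export
read_plate_table <- function(path) {
  df <- check_columns(read.csv(path),
                      c("well", "role", "concentration_ng_ml", "absorbance"),
                      "plate table")
  bad <- setdiff(unique(df$role), c("treatment", "control", "media"))
  if (length(bad)) {
    stop("plate table: unknown role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_growth_table
#' @export
read_clonogenic_table <- function(path) {
  check_columns(read.csv(path), c("condition", "cells_plated", "colonies"),
                "clonogenic table")
}

#' @rdname read_growth_table
#' @export
read_release_table <- function(path) {
  check_columns(read.csv(path), c("time_h", "cumulative_fraction"),
                "release table")
}

#' Normalize and fit a dose-response plate table
#'
#' Convenience wrapper joining the plate roles: mean control and media
#' absorbances are taken across their wells, every treatment well is
#' normalized with [normalize_viability()], and the Hill curve is fitted on
#' the individual wells with [fit_hill()].
#'
#' @param plate plate data.frame as from [read_plate_table()] or
#'   [gen_dose_response()].
#' @return list with `fit` (a `hill_fit`), `viability` (per-well data.frame
#'   with `concentration_ng_ml`, `viability_pct`, `out_of_range` flag),
#'   `a_control`, `a_media`.
#' @export
analyze_plate <- function(plate) {
  check_columns(plate, c("role", "concentration_ng_ml", "absorbance"),
                "plate table")
  a_control <- mean(plate$absorbance[plate$role == "control"])
  a_media <- mean(plate$absorbance[plate$role == "media"])
  if (!is.finite(a_control) || !is.finite(a_media)) {
    stop("plate must contain control and media wells", call. = FALSE)
  }
  tr <- plate[plate$role == "treatment", ]
  v <- normalize_viability(tr$absorbance, a_control, a_media)
  fit <- fit_hill(tr$concentration_ng_ml, v)
  list(fit = fit,
       viability = data.frame(concentration_ng_ml = tr$concentration_ng_ml,
                              viability_pct = v,
                              out_of_range = v < 0 | v > 100),
       a_control = a_control, a_media = a_media)
}
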