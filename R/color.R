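#' Linear-RGB pixel patch
#'
#' Container for the pixel data of one analysed image region: three
#' equal-length vectors of linear channel values and an optional logical
#' mask selecting the region of interest (e.g. the corolla or calyx area).
#'
#' @param red,green,blue numeric vectors of linear channel values, all of
#'   the same length and `>= 0`.
#' @param mask optional logical vector of the same length; at least one
#'   pixel must be selected.
#' @param dim optional `c(rows, cols)` layout, kept for provenance only.
#' @return An object of class `"rgb_patch"`.
#' @export
rgb_patch <- function(red, green, blue, mask = NULL, dim = NULL) {
  n <- length(red)
  if (n < 1 || length(green) != n || length(blue) != n)
    stop("channels must be equal-length vectors of length >= 1", call. = FALSE)
  if (any(!is.finite(red)) || any(!is.finite(green)) || any(!is.finite(blue)))
    stop("channel values must be finite", call. = FALSE)
  if (any(red < 0) || any(green < 0) || any(blue < 0))
    stop("channel values must be >= 0", call. = FALSE)
  if (!is.null(mask)) {
    if (!is.logical(mask) || length(mask) != n)
      stop("'mask' must be a logical vector matching the channels", call. = FALSE)
    if (!any(mask)) stop("'mask' selects no pixels", call. = FALSE)
  }
  structure(list(red = as.numeric(red), green = as.numeric(green),
                 blue = as.numeric(blue), mask = mask, dim = dim),
            class = "rgb_patch")
}

#' @export
print.rgb_patch <- function(x, ...) {
  cat(sprintf("rgb_patch: %d pixels%s%s\n", length(x$red),
              if (!is.null(x$dim)) sprintf(" (%d x %d)", x$dim[1], x$dim[2]) else "",
              if (!is.null(x$mask)) sprintf(", %d masked-in", sum(x$mask)) else ""))
  cat(sprintf("  channel means R/G/B: %.4f / %.4f / %.4f\n",
              mean(x$red), mean(x$green), mean(x$blue)))
  invisible(x)
}

#' Two-point gray calibration standards
#'
#' Measured and expected values, per channel, for the two neutral gray
#' patches of a colour checker (the field protocol used Neutral 3.5 and
#' Neutral 8). The expected reflectances are inputs, not constants: supply
#' the values appropriate for your chart and linearisation.
#'
#' @param measured a 2-row, 3-column numeric matrix (rows = the two
#'   standards, columns = R, G, B) of measured values.
#' @param expected matching matrix of expected values.
#' @return An object of class `"gray_standards"`.
#' @export
gray_standards <- function(measured, expected) {
  measured <- as.matrix(measured); expected <- as.matrix(expected)
  if (!all(dim(measured) == c(2, 3)) || !all(dim(expected) == c(2, 3)))
    stop("'measured' and 'expected' must be 2 x 3 matrices (2 standards, RGB)",
         call. = FALSE)
  if (any(measured[1, ] == measured[2, ]))
    stop("the two measured standard values must differ within every channel",
         call. = FALSE)
  structure(list(measured = measured, expected = expected),
            class = "gray_standards")
}

#' Calibrate patch channels against two gray standards
#'
#' Applies, independently per channel, the two-point linear map that sends
#' the measured standard values to their expected values. Mapped values
#' below zero are clamped to zero with a warning reporting the count.
#'
#' @param patch an [rgb_patch()].
#' @param standards a [gray_standards()] object.
#' @return A new, calibrated `rgb_patch`.
#' @export
calibrate_channels <- function(patch, standards) {
  stopifnot(inherits(patch, "rgb_patch"), inherits(standards, "gray_standards"))
  chans <- c("red", "green", "blue")
  out <- patch
  clamped <- 0L
  for (k in 1:3) {
    m <- standards$measured[, k]; e <- standards$expected[, k]
    slope <- (e[2] - e[1]) / (m[2] - m[1])
    mapped <- e[1] + slope * (patch[[chans[k]]] - m[1])
    clamped <- clamped + sum(mapped < 0)
    out[[chans[k]]] <- pmax(mapped, 0)
  }
  if (clamped > 0)
    warning(sprintf("%d calibrated pixel values were negative and clamped to 0",
                    clamped), call. = FALSE)
  out
}

#' R:G anthocyanin colour index of a patch
#'
#' The mean pixel value of the red channel divided by that of the green
#' channel, over the masked region (the whole patch when no mask is set).
#' The ratio of channel means -- rather than the mean of per-pixel ratios --
#' is used because it is robust to dark pixels.
#'
#' @param patch an [rgb_patch()].
#' @return A single number, the R:G ratio.
#' @export
rg_ratio <- function(patch) {
  stopifnot(inherits(patch, "rgb_patch"))
  sel <- patch$mask %||% rep(TRUE, length(patch$red))
  if (!any(sel)) stop("mask selects no pixels", call. = FALSE)
  g <- mean(patch$green[sel])
  if (g <= 0) stop("mean green over the selected region is zero", call. = FALSE)
  mean(patch$red[sel]) / g
}

#' Read a PNG or TIFF image into an rgb_patch
#'
#' Thin raster reader: pixel values are taken as already linear (the field
#' protocol linearises images before analysis). Requires the `png` or
#' `tiff` package for the respective format.
#'
#' @param path image file path (`.png`, `.tif`/`.tiff`).
#' @param mask optional logical matrix/vector selecting the region.
#' @return An [rgb_patch()].
#' @export
read_patch <- function(path, mask = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package", call. = FALSE)
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported raster format: ", ext, call. = FALSE))
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("image must have at least 3 channels", call. = FALSE)
  rgb_patch(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]),
            mask = if (!is.null(mask)) as.vector(mask) else NULL,
            dim = dim(img)[1:2])
}
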