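#' Metelli episcotister filter
#'
#' A transparent layer in Metelli's episcotister model is described by two
#' numbers: its transmittance `alpha` (the fraction of background luminance it
#' passes) and its reflectance `t` (the luminance it would show if fully
#' opaque). Compositing a background pixel of luminance `b` behind the layer
#' gives `p = alpha * b + t * (1 - alpha)`, a convex combination that shifts
#' and compresses the luminance histogram of whatever lies behind the layer.
#'
#' @param t Reflectance of the layer when opaque, in \[0, 1\].
#' @param alpha Transmittance of the layer, in \[0, 1\].
#' @return An object of class `metelli_filter`.
#' @examples
#' f <- metelli_filter(t = 1, alpha = 0.5)
#' apply_filter(matrix(0.4, 2, 2), f) # all pixels become 0.70
#' @export
metelli_filter <- function(t, alpha) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0 || t > 1)
    abort("`t` must be a single number in [0, 1].", class = "glosstrans_invalid_parameter")
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1)
    abort("`alpha` must be a single number in [0, 1].", class = "glosstrans_invalid_parameter")
  structure(list(t = t, alpha = alpha), class = "metelli_filter")
}

#' @export
print.metelli_filter <- function(x, ...) {
  cat(sprintf("<metelli_filter> t = %g, alpha = %g\n", x$t, x$alpha))
  invisible(x)
}

check_luminance_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    abort(sprintf("`%s` must be a numeric matrix.", arg), class = "glosstrans_format_error")
  if (anyNA(image) || any(image < 0) || any(image > 1))
    abort(sprintf("`%s` must contain luminances in [0, 1].", arg),
          class = "glosstrans_format_error")
  invisible(image)
}

#' Composite a luminance image behind a transparent layer
#'
#' Applies the episcotister model pixelwise: `p = alpha * b + t * (1 - alpha)`.
#' The map sends \[0, 1\] into \[0, 1\]; the result is clipped defensively
#' against floating-point drift. Pixels whose luminance equals `t` are fixed
#' points for every `alpha`.
#'
#' @param image Numeric matrix of luminances in \[0, 1\].
#' @param filter A [metelli_filter()].
#' @return A luminance matrix of the same dimensions.
#' @export
apply_filter <- function(image, filter) {
  check_luminance_image(image)
  stopifnot(inherits(filter, "metelli_filter"))
  out <- filter$alpha * image + filter$t * (1 - filter$alpha)
  pmin(pmax(out, 0), 1)
}

#' Convert an RGB image to luminance
#'
#' Uses the standard NTSC grayscale weights
#' `0.2989 * R + 0.5870 * G + 0.1140 * B`.
#'
#' @param rgb_image Numeric array `height x width x 3` with values in \[0, 1\].
#' @return A luminance matrix.
#' @export
rgb_to_luminance <- function(rgb_image) {
  if (!is.array(rgb_image) || length(dim(rgb_image)) != 3 || dim(rgb_image)[3] != 3)
    abort("`rgb_image` must be a height x width x 3 array.",
          class = "glosstrans_format_error")
  if (anyNA(rgb_image) || any(rgb_image < 0) || any(rgb_image > 1))
    abort("`rgb_image` values must lie in [0, 1].", class = "glosstrans_format_error")
  lum <- 0.2989 * rgb_image[, , 1] + 0.5870 * rgb_image[, , 2] +
    0.1140 * rgb_image[, , 3]
  matrix(lum, dim(rgb_image)[1], dim(rgb_image)[2])
}

region_values <- function(image, mask, arg = "region_mask") {
  if (is.null(mask)) return(as.vector(image))
  if (!identical(dim(mask), dim(image)))
    abort("`region_mask` must have the same dimensions as `image`.",
          class = "glosstrans_format_error")
  v <- image[as.logical(mask)]
  if (length(v) == 0)
    abort("`region_mask` selects no pixels.", class = "glosstrans_invalid_region")
  v
}

#' Michelson contrast of an image region
#'
#' `(Lmax - Lmin) / (Lmax + Lmin)` over the masked region (whole image by
#' default). An all-black region has an undefined ratio; by convention 0 is
#' returned with a warning so summaries stay finite.
#'
#' @param image Luminance matrix in \[0, 1\].
#' @param region_mask Optional logical matrix selecting the region.
#' @return A number in \[0, 1\].
#' @export
michelson_contrast <- function(image, region_mask = NULL) {
  check_luminance_image(image)
  v <- region_values(image, region_mask)
  lo <- min(v); hi <- max(v)
  if (hi + lo == 0) {
    warn("All-black region: Michelson contrast undefined, returning 0.")
    return(0)
  }
  (hi - lo) / (hi + lo)
}

#' Luminance histogram statistics
#'
#' Mean, minimum, maximum, range and skewness of the luminances in a region.
#' Skewness is the population (moment) estimator, the standardized third
#' central moment; a zero-variance region returns skewness 0 by convention.
#'
#' @inheritParams michelson_contrast
#' @return A one-row tibble with columns `mean`, `min`, `max`, `range`,
#'   `skewness`, `n`.
#' @export
histogram_stats <- function(image, region_mask = NULL) {
  check_luminance_image(image)
  v <- region_values(image, region_mask)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  skew <- if (m2 == 0) 0 else mean((v - m)^3) / m2^1.5
  tibble::tibble(
    mean = m, min = min(v), max = max(v),
    range = max(v) - min(v), skewness = skew, n = length(v)
  )
}

#' Fraction of pixels darkened by a manipulation
#'
#' The strict fraction of pixels whose luminance decreased between two images
#' of identical size; ties count as not darkened. For a Metelli filter the
#' pixels above the layer reflectance `t` darken and those below lighten, so
#' this diagnostic summarizes which way a layer shifts the histogram.
#'
#' @param before,after Luminance matrices of identical dimensions.
#' @return A number in \[0, 1\].
#' @export
fraction_darkened <- function(before, after) {
  check_luminance_image(before, "before")
  check_luminance_image(after, "after")
  if (!identical(dim(before), dim(after)))
    abort("`before` and `after` must have identical dimensions.",
          class = "glosstrans_format_error")
  mean(after < before)
}
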