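#' Procedural glossy-object stimulus
#'
#' Generates a grayscale stimulus emulating the structure of a rendered bumpy
#' glossy object on a checkerboard: a checkerboard background, a smoothly
#' shaded circular blob whose peak diffuse luminance equals `albedo`, and
#' `n_highlights` localized Gaussian highlights whose peak amplitude grows
#' linearly with `gloss`. It is a stand-in with the right photometric
#' statistics (diffuse shading gradient plus sparse bright highlights), not a
#' physically based rendering.
#'
#' @param size Image side in pixels (square), at least 16.
#' @param albedo Peak diffuse luminance of the object, in \[0, 1\].
#' @param gloss Specular strength in \[0, 1\]; 0 produces no highlights.
#' @param n_highlights Number of highlight spots.
#' @param seed Integer seed; the image is bit-reproducible given the seed.
#' @param n_checks Checks across the background (default 8).
#' @return A `size x size` luminance matrix in \[0, 1\].
#' @examples
#' img <- glossy_image(64, albedo = 0.5, gloss = 0.8, seed = 1)
#' michelson_contrast(img)
#' @export
glossy_image <- function(size = 128, albedo = 0.5, gloss = 0.5,
                         n_highlights = 4, seed, n_checks = 8) {
  if (size < 16) abort("`size` must be at least 16.", class = "glosstrans_invalid_parameter")
  if (albedo < 0 || albedo > 1) abort("`albedo` must be in [0, 1].", class = "glosstrans_invalid_parameter")
  if (gloss < 0 || gloss > 1) abort("`gloss` must be in [0, 1].", class = "glosstrans_invalid_parameter")
  if (n_highlights < 0) abort("`n_highlights` must be non-negative.", class = "glosstrans_invalid_parameter")
  withr::with_seed(as.integer(seed), {
    check <- ceiling(size / n_checks)
    idx <- (seq_len(size) - 1) %/% check
    board <- ifelse(outer(idx, idx, "+") %% 2 == 0, 0.25, 0.65)

    # hemispherical shading profile: peaks at `albedo` in the blob center
    cx <- (size + 1) / 2
    r <- sqrt(outer((seq_len(size) - cx)^2, (seq_len(size) - cx)^2, "+"))
    radius <- 0.35 * size
    inside <- r < radius
    shading <- matrix(0, size, size)
    shading[inside] <- albedo * sqrt(1 - (r[inside] / radius)^2)

    img <- board
    img[inside] <- shading[inside]

    if (gloss > 0 && n_highlights > 0) {
      amp <- 0.8 * gloss
      hw <- size / 40
      for (h in seq_len(n_highlights)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, 0.6 * radius)
        hx <- cx + rad * cos(ang); hy <- cx + rad * sin(ang)
        d2 <- outer((seq_len(size) - hx)^2, (seq_len(size) - hy)^2, "+")
        img <- img + inside * amp * exp(-d2 / (2 * hw^2))
      }
    } else {
      # burn the same number of draws so the layout is gloss-invariant
      if (n_highlights > 0) runif(2 * n_highlights)
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Read and write luminance images
#'
#' Two plain interchange formats are supported, chosen by file extension:
#' `.png` (grayscale, via the png package) and whitespace-delimited text
#' matrices (any other extension), which round-trip luminances exactly.
#'
#' @param image Luminance matrix in \[0, 1\].
#' @param path File path; `.png` selects PNG, anything else a text matrix.
#' @return `read_luminance()` returns a luminance matrix;
#'   `write_luminance()` returns `path` invisibly.
#' @export
write_luminance <- function(image, path) {
  check_luminance_image(image)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image, path)
  } else {
    writeLines(apply(image, 1, function(row) paste(format(row, digits = 17), collapse = " ")), path)
  }
  invisible(path)
}

#' @rdname write_luminance
#' @export
read_luminance <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- rgb_to_luminance(img[, , 1:3, drop = FALSE])
    img
  } else {
    rows <- readLines(path)
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    check_luminance_image(mat, "file contents")
  }
}
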