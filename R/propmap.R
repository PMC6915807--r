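#' Group proportional body map
#'
#' Pixel-wise mean of per-subject binary concern masks: each pixel holds
#' the proportion of subjects reporting some concern covering it.
#'
#' @param masks non-empty list of H x W 0/1 matrices with identical dims.
#' @return an object of class `prop_map`: list with `grid` (H x W matrix in
#'   \[0,1\]) and `n` (number of subjects aggregated).
#' @export
proportional_map <- function(masks) {
  if (!is.list(masks) || length(masks) < 1L)
    stop_f("need at least one mask")
  d <- dim(masks[[1]])
  acc <- matrix(0, nrow = d[1], ncol = d[2])
  for (m in masks) {
    if (!identical(dim(m), d)) stop_f("mask dimension mismatch")
    acc <- acc + m
  }
  structure(list(grid = acc / length(masks), n = length(masks)),
            class = "prop_map")
}

#' Gaussian FWHM to standard deviation
#'
#' sigma = FWHM / (2 * sqrt(2 * ln 2)) = FWHM / 2.3548.
#'
#' @param fwhm full width at half maximum, in pixels (> 0).
#' @return sigma in pixels.
#' @export
fwhm_to_sigma <- function(fwhm) {
  if (!is.numeric(fwhm) || any(fwhm <= 0)) stop_f("fwhm must be positive")
  fwhm / (2 * sqrt(2 * log(2)))
}

# Normalized 1-D Gaussian kernel truncated at 4 sigma (mass error < 1e-4).
gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Symmetric (mirror) boundary index for i in 1-r .. n+r, period 2n.
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j, 2L * n - 1L - j) + 1L
}

# Separable convolution with reflective padding; kernel must sum to 1.
convolve_reflect <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  # vertical pass
  pad <- m[reflect_index((1L - r):(H + r), H), , drop = FALSE]
  v <- matrix(0, H, W)
  for (t in seq_along(k)) v <- v + k[t] * pad[(t - 1L) + seq_len(H), , drop = FALSE]
  # horizontal pass
  pad <- v[, reflect_index((1L - r):(W + r), W), drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k)) out <- out + k[t] * pad[, (t - 1L) + seq_len(W), drop = FALSE]
  out
}

#' Gaussian spatial smoothing of a proportion map
#'
#' Isotropic Gaussian convolution with sigma = [fwhm_to_sigma]`(fwhm_px)`,
#' reflective (mirror) boundary handling, kernel truncated at 4 sigma and
#' renormalized so constants are preserved and values stay in \[0, 1\].
#'
#' @param map a `prop_map`, or a bare numeric matrix.
#' @param fwhm_px kernel full width at half maximum in pixels (> 0).
#' @return same type as the input, smoothed.
#' @export
smooth_map <- function(map, fwhm_px) {
  sigma <- fwhm_to_sigma(fwhm_px)
  k <- gaussian_kernel1d(sigma)
  if (inherits(map, "prop_map")) {
    g <- convolve_reflect(map$grid, k)
    structure(list(grid = pmin(pmax(g, 0), 1), n = map$n), class = "prop_map")
  } else {
    pmin(pmax(convolve_reflect(map, k), 0), 1)
  }
}

#' @export
print.prop_map <- function(x, ...) {
  cat(sprintf("<prop_map> %dx%d px over n = %d subjects; range [%.3f, %.3f]\n",
              ncol(x$grid), nrow(x$grid), x$n, min(x$grid), max(x$grid)))
  invisible(x)
}

#' Write a raster to CSV (no header, one row per pixel row)
#' @param m numeric matrix (or `prop_map`).
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
write_raster_csv <- function(m, path) {
  if (inherits(m, "prop_map")) m <- m$grid
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Render a raster (optionally over a silhouette) to a PNG figure
#'
#' Uses the standard `grDevices::png()` device; values are shown with a
#' diverging palette centred at 0 for signed maps and a sequential palette
#' for proportions.
#'
#' @param m numeric matrix (or `prop_map`).
#' @param path destination PNG.
#' @param main plot title.
#' @param diverging centre the palette at zero.
#' @param outline optional 0/1 matrix drawn as a contour (e.g. surviving
#'   clusters or a body silhouette).
#' @return invisibly, `path`.
#' @export
render_raster_png <- function(m, path, main = "", diverging = FALSE,
                              outline = NULL) {
  if (inherits(m, "prop_map")) m <- m$grid
  grDevices::png(path, width = 480, height = 720)
  on.exit(grDevices::dev.off())
  H <- nrow(m); W <- ncol(m)
  # image() draws x rightward, y upward; flip rows so y runs downward
  z <- t(m[H:1, , drop = FALSE])
  if (diverging) {
    lim <- max(abs(m), 1e-12)
    col <- grDevices::hcl.colors(101, "Blue-Red 2")
    graphics::image(seq_len(W) - 0.5, seq_len(H) - 0.5, z,
                    zlim = c(-lim, lim), col = col, xlab = "x", ylab = "y",
                    main = main, useRaster = TRUE, asp = 1)
  } else {
    col <- grDevices::hcl.colors(101, "YlOrRd", rev = TRUE)
    graphics::image(seq_len(W) - 0.5, seq_len(H) - 0.5, z,
                    zlim = c(0, max(m, 1e-12)), col = col, xlab = "x",
                    ylab = "y", main = main, useRaster = TRUE, asp = 1)
  }
  if (!is.null(outline) && any(outline > 0))
    graphics::contour(seq_len(W) - 0.5, seq_len(H) - 0.5,
                      t(outline[H:1, , drop = FALSE]), levels = 0.5,
                      add = TRUE, drawlabels = FALSE, lwd = 2)
  invisible(path)
}
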