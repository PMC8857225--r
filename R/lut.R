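#' Rainbow lookup table for MBF display
#'
#' The display colormap is a piecewise-linear HSV sweep from hue 240 deg
#' (blue, at the scale minimum) to hue 0 deg (red, at the scale maximum) at
#' full saturation and value. The same table drives rendering
#' ([render_polar_map()]) and inversion ([invert_colormap()]), so image-based
#' classification is self-consistent with the generator. Values outside the
#' display scale are clipped to its ends before lookup.
#'
#' @param n Number of table entries (quantization levels along the hue sweep).
#' @return A list with `rgb`, an `n x 3` matrix of RGB coordinates in
#'   `[0, 1]` (row 1 = scale minimum), and `n`.
#' @examples
#' lut <- rainbow_lut()
#' lut$rgb[1, ]    # blue end, MBF = scale minimum
#' lut$rgb[1024, ] # red end, MBF = scale maximum
#' @export
rainbow_lut <- function(n = 1024L) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  hue <- 240 * (1 - seq(0, 1, length.out = n)) / 360
  rgb <- t(grDevices::col2rgb(grDevices::hsv(hue, 1, 1))) / 255
  dimnames(rgb) <- list(NULL, c("r", "g", "b"))
  # quantize to the 8-bit grid images are stored on
  rgb <- round(rgb * 255) / 255
  list(rgb = rgb, n = n)
}

# Fractional position t in [0,1] along the display scale for MBF values.
mbf_to_t <- function(mbf, scale) {
  pmin(pmax((mbf - scale[1]) / (scale[2] - scale[1]), 0), 1)
}

#' Map MBF values to rainbow colors
#'
#' @param mbf Numeric vector of MBF values (ml/g/min); values outside
#'   `scale` are clipped.
#' @param scale Display scale `c(min, max)` in ml/g/min.
#' @param lut Lookup table from [rainbow_lut()].
#' @return An `length(mbf) x 3` matrix of RGB values in `[0, 1]`.
#' @export
mbf_to_rgb <- function(mbf, scale = c(0, 3.5), lut = rainbow_lut()) {
  stopifnot(scale[1] < scale[2])
  idx <- 1L + as.integer(round(mbf_to_t(mbf, scale) * (lut$n - 1L)))
  lut$rgb[idx, , drop = FALSE]
}

#' Invert rainbow colors back to MBF estimates
#'
#' Recovers the MBF value whose LUT color is nearest (Euclidean distance in
#' RGB) to each pixel. Background pixels (near-black) and overlay pixels
#' (near-white, a color reserved outside the rainbow sweep) return `NA`
#' ("no tissue"). The search is hue-guided: the pixel hue proposes a LUT
#' index and a local window around it is scanned, which returns the exact
#' nearest entry for pixels on or near the LUT curve.
#'
#' @param rgb Numeric matrix `n x 3` of RGB values in `[0, 1]` (a single
#'   pixel may be given as a length-3 vector).
#' @param scale Display scale `c(min, max)` in ml/g/min.
#' @param lut Lookup table from [rainbow_lut()].
#' @param window Half-width of the index window scanned around the
#'   hue-proposed candidate.
#' @return Numeric vector of MBF estimates (ml/g/min); `NA` for
#'   background/overlay pixels.
#' @examples
#' invert_colormap(mbf_to_rgb(2.0))  # ~ 2.0
#' invert_colormap(c(0, 0, 0))       # NA: background
#' @export
invert_colormap <- function(rgb, scale = c(0, 3.5), lut = rainbow_lut(),
                            window = 8L) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  stopifnot(ncol(rgb) == 3, scale[1] < scale[2])
  n <- nrow(rgb)
  out <- rep(NA_real_, n)
  mx <- pmax(rgb[, 1], pmax(rgb[, 2], rgb[, 3]))
  mn <- pmin(rgb[, 1], pmin(rgb[, 2], rgb[, 3]))
  tissue <- mx > 0.10 & (mx - mn) > 0.10  # excludes black background and
                                          # the white/grey overlay reserve
  if (!any(tissue)) return(out)
  px <- rgb[tissue, , drop = FALSE]
  hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 1)
  h <- hsv[1, ]
  # LUT hue runs 240/360 -> 0 linearly in t; hues past red (wrap-around
  # magentas, h > 240/360) clamp to the red end
  tpos <- 1 - pmin(h * 360 / 240, 1)
  cand <- 1L + as.integer(round(tpos * (lut$n - 1L)))
  best_idx <- cand
  best_d <- rep(Inf, nrow(px))
  for (off in seq.int(-window, window)) {
    idx <- pmin(pmax(cand + off, 1L), lut$n)
    d <- (px[, 1] - lut$rgb[idx, 1])^2 + (px[, 2] - lut$rgb[idx, 2])^2 +
      (px[, 3] - lut$rgb[idx, 3])^2
    upd <- d < best_d | (d == best_d & idx < best_idx)
    best_d[upd] <- d[upd]
    best_idx[upd] <- idx[upd]
  }
  out[tissue] <- scale[1] + (best_idx - 1) / (lut$n - 1) * (scale[2] - scale[1])
  out
}
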