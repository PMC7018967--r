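#' Render an en-face map to a PNG image
#'
#' Deterministic rendering of a 2-D metric map: values are mapped onto a
#' color ramp (`"linear"` for intensities/retardance/entropy, `"cyclic"`
#' HSV ramp for orientation angles so that 0 and pi render identically,
#' `"gray"`), with optional micrometer scale bar and colorbar strip.
#' Invalid (`NA`) cells render black. Re-rendering identical inputs yields
#' byte-identical files.
#'
#' @param map Numeric matrix (rows = x, columns = y).
#' @param file Output PNG path.
#' @param palette One of `"linear"`, `"cyclic"`, `"gray"`.
#' @param zlim Length-2 value range; defaults to the finite data range
#'   (`c(0, pi)` for the cyclic palette). A constant map renders at the
#'   colormap minimum.
#' @param pitch_um Cell pitch in um (needed for the scale bar).
#' @param scale_bar_um Optional scale bar length in um.
#' @param colorbar Append a vertical colorbar strip on the right.
#' @return Invisibly, the normalized RGB array written.
#' @export
render_map <- function(map, file, palette = c("linear", "cyclic", "gray"),
                       zlim = NULL, pitch_um = NULL, scale_bar_um = NULL,
                       colorbar = FALSE) {
  palette <- match.arg(palette)
  stopifnot(is.matrix(map))
  ncol_ramp <- 256L
  ramp <- switch(palette,
    linear = grDevices::colorRampPalette(
      c("#440154", "#31688E", "#35B779", "#FDE725"))(ncol_ramp),
    cyclic = grDevices::hsv(seq(0, 1, length.out = ncol_ramp + 1)[1:ncol_ramp],
                            0.85, 0.9),
    gray = grDevices::gray(seq(0, 1, length.out = ncol_ramp)))
  rgbmat <- grDevices::col2rgb(ramp) / 255
  if (palette == "cyclic") {
    zlim <- zlim %||% c(0, pi)
    idx <- 1L + (floor((map - zlim[1]) / diff(zlim) * ncol_ramp) %% ncol_ramp)
  } else {
    zlim <- zlim %||% range(map, finite = TRUE)
    if (!is.finite(diff(zlim)) || diff(zlim) <= 0) {
      idx <- array(1L, dim(map))    # constant map: colormap minimum
    } else {
      f <- (map - zlim[1]) / diff(zlim)
      idx <- 1L + pmin(pmax(floor(f * ncol_ramp), 0), ncol_ramp - 1L)
    }
  }
  bad <- !is.finite(map)
  h <- ncol(map); w <- nrow(map)   # image rows = y, columns = x
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(rgbmat[ch, idx], nrow(map), ncol(map))
    plane[bad] <- 0
    img[, , ch] <- t(plane)[h:1, , drop = FALSE]
  }
  if (!is.null(scale_bar_um)) {
    if (is.null(pitch_um)) stop("scale bar needs pitch_um")
    len <- max(1L, round(scale_bar_um / pitch_um[1]))
    rows <- max(1L, h - 3L):max(1L, h - 2L)
    cols <- 2L:min(w, 1L + len)
    img[rows, cols, ] <- 1
  }
  if (colorbar) {
    strip <- array(0, c(h, 4L, 3))
    levels <- rev(1L + floor(seq(0, ncol_ramp - 1e-9,
                                 length.out = h)))
    for (ch in 1:3) strip[, , ch] <- matrix(rgbmat[ch, levels], h, 4L)
    img2 <- array(0, c(h, w + 5L, 3))
    img2[, 1:w, ] <- img
    img2[, (w + 2L):(w + 5L), ] <- strip
    img <- img2
  }
  png::writePNG(img, file)
  invisible(img)
}

#' Write an en-face map as 32-bit TIFF
#'
#' Stores `map / scale` clipped to `[0, 1]` as a 32-bit-per-sample TIFF;
#' the scale factor (default: the maximum finite value) is returned so the
#' physical values can be recovered.
#'
#' @param map Numeric matrix.
#' @param file Output TIFF path.
#' @param scale Normalization divisor.
#' @return Invisibly, `scale`.
#' @export
write_map_tiff <- function(map, file, scale = NULL) {
  stopifnot(is.matrix(map))
  scale <- scale %||% max(map[is.finite(map)], 1e-12)
  img <- t(map / scale)
  img[!is.finite(img)] <- 0
  img <- pmin(pmax(img, 0), 1)
  tiff::writeTIFF(img, file, bits.per.sample = 32L)
  invisible(scale)
}
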