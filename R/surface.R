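#' Detect the tissue surface in an intensity volume
#'
#' Per A-line, the surface is the first depth at which the median-smoothed
#' intensity exceeds a noise-derived threshold `floor + k_sd * sd`. The
#' noise floor and spread are estimated robustly (median and MAD) from the
#' quietest axial slice of the volume - with air above the tissue, the
#' shallowest slices contain noise only. The resulting index map is
#' regularized with a 2-D median filter. A-lines with no crossing are
#' masked; a fully masked map triggers a warning.
#'
#' @param intensity 3-D numeric array `nx x ny x nz` (e.g. the Stokes `I`
#'   component averaged over input states).
#' @param k_sd Threshold factor above the noise floor (default 4).
#' @param z_smooth Odd axial median-smoothing window in pixels (default 5).
#' @param reg_size Odd window of the 2-D median regularization (default 5).
#' @return A `surface_map`: list with `z_index` (matrix of axial indices,
#'   `NA` where masked), `valid`, and `method` metadata.
#' @export
detect_surface <- function(intensity, k_sd = 4, z_smooth = 5, reg_size = 5) {
  stopifnot(length(dim(intensity)) == 3, z_smooth %% 2 == 1,
            reg_size %% 2 == 1)
  slice_med <- apply(intensity, 3, stats::median)
  kmin <- which.min(slice_med)
  quiet <- as.vector(intensity[, , kmin])
  floor_est <- stats::median(quiet)
  sd_est <- stats::mad(quiet)
  thr <- floor_est + k_sd * max(sd_est, .Machine$double.eps)
  zmap <- apply(intensity, c(1, 2), function(a) {
    sm <- if (length(a) > z_smooth) stats::runmed(a, z_smooth, endrule = "constant") else a
    i <- which(sm > thr)
    if (length(i) == 0) NA_integer_ else i[1]
  })
  if (all(is.na(zmap))) {
    warning("no surface detected in any A-line")
  } else if (reg_size > 1) {
    zmap <- round(median_filter2(zmap, reg_size))
  }
  structure(list(z_index = zmap, valid = !is.na(zmap),
                 method = list(name = "threshold_first_crossing",
                               threshold = thr, k_sd = k_sd,
                               z_smooth = z_smooth, reg_size = reg_size)),
            class = "surface_map")
}

#' Construct a surface map directly
#'
#' @param z_index Matrix of axial surface indices (`NA` = masked).
#' @return A `surface_map`.
#' @export
surface_map <- function(z_index) {
  structure(list(z_index = z_index, valid = !is.na(z_index),
                 method = list(name = "given")),
            class = "surface_map")
}

#' Surface-referenced depth-window mask
#'
#' Selects, per A-line, the axial samples whose depth below the detected
#' surface lies in the half-open interval `[z_start_um, z_stop_um)`. The
#' surface pixel itself has depth 0.
#'
#' @param dims Length-3 integer volume dimensions, or a 3-D array.
#' @param surface A `surface_map`.
#' @param z_start_um,z_stop_um Window bounds in um, `z_start_um < z_stop_um`.
#' @param dz_um Axial pixel pitch in um.
#' @return Logical array `nx x ny x nz`; masked A-lines contribute nothing.
#'   Warns when the window selects no samples (e.g. entirely below the
#'   volume bottom).
#' @export
depth_window <- function(dims, surface, z_start_um, z_stop_um, dz_um) {
  if (is.array(dims)) dims <- dim(dims)
  stopifnot(length(dims) == 3, inherits(surface, "surface_map"), dz_um > 0)
  if (z_stop_um <= z_start_um) stop("empty depth window")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  stopifnot(all(dim(surface$z_index) == c(nx, ny)))
  kidx <- aperm(array(seq_len(nz), c(nz, nx, ny)), c(2, 3, 1))
  depth <- (kidx - array(surface$z_index, c(nx, ny, nz))) * dz_um
  sel <- depth >= z_start_um & depth < z_stop_um
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) warning("depth window selects no samples")
  sel
}
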