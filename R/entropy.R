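#' Shannon entropy of an orientation sample
#'
#' Histogram entropy of orientation angles: values in `[0, pi)` are binned
#' into `n_bins` equal left-closed bins (an angle of exactly pi wraps to bin
#' 1), counts are normalized to probabilities and
#' \eqn{H = -\sum_{p_i > 0} p_i \log_2 p_i} is returned in bits. Zero-count
#' bins are dropped (the `0 log 0 = 0` limit convention), so
#' `0 <= H <= log2(min(n_bins, length(theta)))`.
#'
#' @param theta Numeric vector of angles (radians); `NA`s are dropped.
#' @param n_bins Number of histogram bins (default 256).
#' @return Entropy in bits (scalar); `NA` for an empty sample.
#' @examples
#' angle_entropy(rep(0.3, 100))                        # 0 bits
#' angle_entropy((seq_len(256) - 0.5) * pi / 256)      # 8 bits
#' @export
angle_entropy <- function(theta, n_bins = 256) {
  stopifnot(n_bins >= 1)
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0) return(NA_real_)
  theta <- theta %% pi
  bins <- pmin(floor(theta / (pi / n_bins)) + 1L, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Voxel-wise optic-axis entropy map
#'
#' Tiles the transverse plane into non-overlapping square blocks of
#' `block_xy_um` per side and, within each block, computes the Shannon
#' entropy ([angle_entropy()]) of the valid orientation angles lying in a
#' surface-referenced depth window. Two modes are available:
#'
#' * volumetric (default): all samples with depth in
#'   `[z_window_um[1], z_window_um[2])` below the per-A-line surface;
#' * single-plane (`plane_z_um` set): one z-sample per A-line at the given
#'   depth below the surface, as used for en-face entropy maps.
#'
#' Blocks overhanging the volume edge are kept when at least 50% of their
#' transverse area is inside; voxels with fewer than `min_count` valid
#' samples are flagged invalid.
#'
#' @param angles An `angle_field`.
#' @param surface A `surface_map` (or `NULL` for a flat surface at the first
#'   axial pixel, i.e. depth measured from the top of the volume).
#' @param block_xy_um Transverse block size in um (default 100).
#' @param z_window_um Length-2 numeric `(start, stop)` depth window below
#'   the surface in um, half-open (default `c(120, 190)`).
#' @param n_bins Histogram bins (default 256).
#' @param min_count Minimum valid samples per voxel (default 16).
#' @param plane_z_um If non-`NULL`, single-plane mode at this depth (um).
#' @return An `entropy_map`: list with `entropy` (matrix, bits; `NA` on
#'   invalid voxels), `n` (sample counts), `valid`, block geometry
#'   (`block_px`, `block_um`, `origin_x`, `origin_y`), `n_bins`,
#'   `z_window_um`, `mode` and `min_count`.
#' @export
voxel_entropy <- function(angles, surface = NULL, block_xy_um = 100,
                          z_window_um = c(120, 190), n_bins = 256,
                          min_count = 16, plane_z_um = NULL) {
  stopifnot(inherits(angles, "angle_field"))
  d <- dim(angles$theta)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  dx <- angles$pitch[1]; dy <- angles$pitch[2]; dzp <- angles$pitch[3]
  bx <- round(block_xy_um / dx)
  by <- round(block_xy_um / dy)
  if (bx < 1 || by < 1) stop("block size is smaller than one pixel")

  zs <- if (is.null(surface)) matrix(1, nx, ny) else surface$z_index
  stopifnot(all(dim(zs) == c(nx, ny)))
  kidx <- aperm(array(rep(seq_len(nz), each = 1), c(nz, nx, ny)), c(2, 3, 1))
  depth <- (kidx - array(zs, c(nx, ny, nz))) * dzp
  if (is.null(plane_z_um)) {
    if (z_window_um[2] <= z_window_um[1]) stop("empty depth window")
    sel <- depth >= z_window_um[1] & depth < z_window_um[2]
    mode <- "window"
  } else {
    sel <- kidx == array(zs + round(plane_z_um / dzp), c(nx, ny, nz))
    mode <- "plane"
    z_window_um <- c(plane_z_um, plane_z_um)
  }
  sel <- sel & angles$valid & !is.na(depth)
  if (!any(sel)) warning("depth window selects no samples")

  starts_x <- seq(1L, nx, by = bx)
  starts_y <- seq(1L, ny, by = by)
  # only the trailing block in each dimension can overhang the volume edge;
  # a block is kept when >= 50% of its transverse area lies inside
  frac_x <- (pmin(starts_x + bx - 1L, nx) - starts_x + 1L) / bx
  frac_y <- (pmin(starts_y + by - 1L, ny) - starts_y + 1L) / by
  area_ok <- outer(frac_x, frac_y) >= 0.5
  keep_x <- apply(area_ok, 1, any)
  keep_y <- apply(area_ok, 2, any)
  starts_x <- starts_x[keep_x]
  starts_y <- starts_y[keep_y]
  area_ok <- area_ok[keep_x, keep_y, drop = FALSE]

  nbx <- length(starts_x); nby <- length(starts_y)
  H <- matrix(NA_real_, nbx, nby)
  N <- matrix(0L, nbx, nby)
  for (i in seq_len(nbx)) {
    xr <- starts_x[i]:min(starts_x[i] + bx - 1L, nx)
    for (j in seq_len(nby)) {
      if (!area_ok[i, j]) next
      yr <- starts_y[j]:min(starts_y[j] + by - 1L, ny)
      s <- sel[xr, yr, , drop = FALSE]
      th <- angles$theta[xr, yr, , drop = FALSE][s]
      N[i, j] <- length(th)
      if (length(th) >= min_count) H[i, j] <- angle_entropy(th, n_bins)
    }
  }
  structure(list(entropy = H, n = N, valid = !is.na(H),
                 block_px = c(bx, by), block_um = c(bx * dx, by * dy),
                 origin_x = starts_x, origin_y = starts_y,
                 n_bins = n_bins, z_window_um = z_window_um, mode = mode,
                 min_count = min_count,
                 map_pitch_um = c(bx * dx, by * dy)),
            class = "entropy_map")
}

#' @export
print.entropy_map <- function(x, ...) {
  cat(sprintf(
    "<entropy_map> %d x %d voxels (%g x %g um blocks), %s mode, %d bins\n",
    nrow(x$entropy), ncol(x$entropy), x$block_um[1], x$block_um[2],
    x$mode, x$n_bins))
  if (any(x$valid))
    cat(sprintf("  mean %.3f bits over %d valid voxels\n",
                mean(x$entropy[x$valid]), sum(x$valid)))
  invisible(x)
}

#' Mean optic-axis entropy over a region
#'
#' Unweighted mean of the valid voxel entropies, optionally restricted to a
#' region mask (e.g. to exclude ink-marked registration areas).
#'
#' @param map An `entropy_map`.
#' @param region_mask Optional logical matrix of the map's dimensions.
#' @return Mean entropy in bits (scalar).
#' @export
mean_entropy <- function(map, region_mask = NULL) {
  stopifnot(inherits(map, "entropy_map"))
  sel <- map$valid
  if (!is.null(region_mask)) {
    stopifnot(all(dim(region_mask) == dim(map$entropy)))
    sel <- sel & region_mask
  }
  if (!any(sel)) stop("no valid voxels in region")
  mean(map$entropy[sel])
}
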