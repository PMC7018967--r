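#' Least-squares plane fit of optic-axis vectors on the Poincare sphere
#'
#' The sample's true optic axes are linear (Q-U equator of the sphere), but
#' an unknown fiber birefringence rotates them onto an arbitrary great
#' circle. The plane through the origin containing the measured axes is
#' found by least squares: the normal is the eigenvector of the smallest
#' eigenvalue of the second-moment matrix `sum(v v^T)` over valid axes. The
#' normal's sign is fixed so its V-component is `>= 0` (tie-breaks: U, then
#' Q); `e1` is the normalized projection of the Q-axis onto the plane
#' (falling back to the U-axis when that projection is degenerate) and
#' `e2 = normal x e1`, so `{e1, e2, normal}` is a right-handed orthonormal
#' triad.
#'
#' @param oa An `oa_volume`.
#' @param mask Optional logical array restricting which pixels contribute
#'   (intersected with the validity mask).
#' @return A `plane_basis`: list with `normal`, `e1`, `e2`, `rms_residual`
#'   (mean squared out-of-plane component) and `n_points`.
#' @export
fit_axis_plane <- function(oa, mask = NULL) {
  stopifnot(inherits(oa, "oa_volume"))
  sel <- oa$valid
  if (!is.null(mask)) sel <- sel & mask
  idx <- which(sel)
  n3 <- prod(dim(oa$axis)[1:3])
  V <- cbind(oa$axis[idx], oa$axis[n3 + idx], oa$axis[2 * n3 + idx])
  V <- V[stats::complete.cases(V), , drop = FALSE]
  if (nrow(V) < 3) stop("plane fit needs at least 3 valid axis vectors")
  M <- crossprod(V)
  ee <- eigen(M, symmetric = TRUE)
  if (ee$values[2] <= 1e-10 * ee$values[1])
    stop("axis vectors are collinear; plane is undetermined")
  normal <- ee$vectors[, 3]
  # hemisphere sign fix: V >= 0, tie-break U then Q
  key <- c(normal[3], normal[2], normal[1])
  lead <- key[which(abs(key) > 1e-12)[1]]
  if (!is.na(lead) && lead < 0) normal <- -normal
  q <- c(1, 0, 0)
  e1 <- q - sum(q * normal) * normal
  if (sqrt(sum(e1^2)) < 1e-6) {
    u <- c(0, 1, 0)
    e1 <- u - sum(u * normal) * normal
  }
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  structure(list(normal = normal, e1 = e1, e2 = e2,
                 rms_residual = ee$values[3] / nrow(V),
                 n_points = nrow(V)),
            class = "plane_basis")
}

#' @export
print.plane_basis <- function(x, ...) {
  cat(sprintf(
    "<plane_basis> normal (%.4f, %.4f, %.4f), residual %.3g, n = %d\n",
    x$normal[1], x$normal[2], x$normal[3], x$rms_residual, x$n_points))
  invisible(x)
}

#' Project optic axes to scalar in-plane angles
#'
#' Converts each axis vector to the scalar angle
#' \deqn{\theta = \tfrac{1}{2}\,\mathrm{atan2}(S_2, S_1) \bmod \pi}
#' where `S1`, `S2` are the axis components along the plane basis vectors
#' `e1`, `e2`. The half-angle undoes the Poincare-sphere angle doubling, so
#' `theta` lives on the real-space orientation scale; the modulo maps it
#' into `[0, pi)`, preserving the circular (period-pi) topology of fiber
#' orientations.
#'
#' @param oa An `oa_volume`.
#' @param basis A `plane_basis` from [fit_axis_plane()].
#' @return An `angle_field`: list with `theta` (radians, `[0, pi)`, `NA`
#'   on invalid pixels), `valid`, `pitch`.
#' @export
project_angle <- function(oa, basis) {
  stopifnot(inherits(oa, "oa_volume"), inherits(basis, "plane_basis"))
  ax <- oa$axis
  d3 <- dim(ax)[1:3]
  S1 <- ax[, , , 1] * basis$e1[1] + ax[, , , 2] * basis$e1[2] +
    ax[, , , 3] * basis$e1[3]
  S2 <- ax[, , , 1] * basis$e2[1] + ax[, , , 2] * basis$e2[2] +
    ax[, , , 3] * basis$e2[3]
  theta <- array((0.5 * atan2(S2, S1)) %% pi, d3)
  theta[!oa$valid] <- NA_real_
  angle_field(theta, valid = oa$valid & is.finite(theta), pitch = oa$pitch)
}

#' Construct an angle field
#'
#' @param theta Array of orientation angles in `[0, pi)` (radians); values
#'   equal to pi wrap to 0.
#' @param valid Optional logical array (default: finite angles).
#' @param pitch Length-3 pixel pitch in um (transverse pitch is used by the
#'   entropy block tiling).
#' @return An `angle_field`.
#' @export
angle_field <- function(theta, valid = NULL, pitch = c(1, 1, 1)) {
  theta <- theta %% pi
  if (is.null(valid)) valid <- is.finite(theta)
  valid <- valid & is.finite(theta)
  structure(list(theta = theta, valid = valid, pitch = pitch),
            class = "angle_field")
}
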