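#' Local retardance and optic axis from dual-state Stokes data
#'
#' The two-state geometric solution. At each pixel and depth `z`, the
#' polarization parts of both probe states are normalized to unit Poincare
#' vectors `s_a(z)`, `s_b(z)`. Between depths `z` and `z + dz` the tissue
#' slab acts (after the depth-independent fiber transformation) as a common
#' rotation of the sphere; its axis is perpendicular to both difference
#' vectors `D_a = s_a(z + dz) - s_a(z)` and `D_b`, hence
#' `A = (D_a x D_b) / ||D_a x D_b||`. The rotation angle is measured per
#' state as the angle between the components of `s(z)` and `s(z + dz)`
#' perpendicular to `A`, combined as the weighted mean with weights equal to
#' the squared perpendicular-component magnitudes, and converted to a
#' retardance rate in degrees per um (double-pass, Stokes-rotation
#' convention: a uniform layer of single-pass rate `r` yields `2 r`).
#'
#' The sign of `A` is fixed physically: the axis about which the measured
#' rotation angle is positive (for states `s(z)` rotating toward
#' `s(z + dz)`), which makes recovered axes exactly equivariant under a
#' global fiber rotation. Pixels where the construction is degenerate -
#' cross-product norm below `eps`, both perpendicular weights below `eps`,
#' or vanishing polarization - are flagged invalid, as is the trailing
#' axial slab where `z + dz` exceeds the volume.
#'
#' @param filtered A filtered `stokes_volume` with both input states.
#' @param dz_um Depth offset for the differential, um; realized as
#'   `round(dz_um / axial_pitch)` pixels (the actual um value is recorded
#'   in the output).
#' @param eps Validity threshold on the cross-product norm and the
#'   perpendicular weights.
#' @return An `oa_volume`: list with `axis` (unit Poincare 3-vectors,
#'   array `nx x ny x nz x 3`), `retardance` (deg/um, `nx x ny x nz`),
#'   `valid` (logical array), `dz_um` (actual offset used) and `pitch`.
#' @export
local_birefringence <- function(filtered, dz_um = 20, eps = 1e-3) {
  stopifnot(inherits(filtered, "stokes_volume"))
  if (!filtered$filtered)
    stop("local birefringence expects filtered Stokes data")
  d <- dim(filtered$data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  dzp <- filtered$pitch[3]
  m <- round(dz_um / dzp)
  if (m < 1) stop("dz_um must be at least one axial pitch")
  if (m >= nz) stop("dz_um exceeds the axial extent of the volume")
  actual_um <- m * dzp

  unit_state <- function(s) {
    p <- filtered$data[, , , 2:4, s]
    n <- v3_norm(p)
    list(u = v3_scale(p, 1 / pmax(n, 1e-300)), ok = n > 1e-12)
  }
  ua <- unit_state(1); ub <- unit_state(2)

  i1 <- 1:(nz - m); i2 <- (m + 1):nz
  sA1 <- ua$u[, , i1, , drop = FALSE]; sA2 <- ua$u[, , i2, , drop = FALSE]
  sB1 <- ub$u[, , i1, , drop = FALSE]; sB2 <- ub$u[, , i2, , drop = FALSE]
  Da <- sA2 - sA1
  Db <- sB2 - sB1
  C <- v3_cross(Da, Db)
  nC <- v3_norm(C)
  A <- v3_scale(C, 1 / pmax(nC, 1e-300))

  # eigenstate special case: when one probe state sits on the rotation axis
  # its difference vector vanishes and the cross product is degenerate, but
  # the axis is then the probe state itself; the perpendicular weighting
  # below automatically ignores the eigen state's (zero-length) angle
  na <- v3_norm(Da); nb <- v3_norm(Db)
  eig_a <- nC < eps & na < eps & nb >= eps
  eig_b <- nC < eps & nb < eps & na >= eps
  if (any(eig_a)) for (k in 1:3) {
    Ak <- A[, , , k]; Ak[eig_a] <- sA1[, , , k][eig_a]; A[, , , k] <- Ak
  }
  if (any(eig_b)) for (k in 1:3) {
    Ak <- A[, , , k]; Ak[eig_b] <- sB1[, , , k][eig_b]; A[, , , k] <- Ak
  }

  perp_angle <- function(s1, s2) {
    p1 <- s1 - v3_scale(A, v3_dot(s1, A))
    p2 <- s2 - v3_scale(A, v3_dot(s2, A))
    w <- v3_dot(p1, p1)                      # squared perpendicular magnitude
    psi <- atan2(v3_dot(A, v3_cross(p1, p2)), v3_dot(p1, p2))
    list(psi = psi, w = w)
  }
  ga <- perp_angle(sA1, sA2)
  gb <- perp_angle(sB1, sB2)
  wsum <- ga$w + gb$w
  psi <- (ga$w * ga$psi + gb$w * gb$psi) / pmax(wsum, 1e-300)

  # physical sign: flip axis where the weighted rotation angle is negative
  flip <- psi < 0
  psi <- abs(psi)
  sgn <- ifelse(flip, -1, 1)
  A <- v3_scale(A, sgn)

  okpol <- ua$ok[, , i1] & ua$ok[, , i2] & ub$ok[, , i1] & ub$ok[, , i2]
  valid_core <- okpol & (nC >= eps | eig_a | eig_b) &
    !(ga$w < eps & gb$w < eps)

  axis <- array(NA_real_, c(nx, ny, nz, 3))
  ret <- array(NA_real_, c(nx, ny, nz))
  valid <- array(FALSE, c(nx, ny, nz))
  axis[, , i1, ] <- A
  ret[, , i1] <- rad2deg(psi) / actual_um
  valid[, , i1] <- valid_core
  axis[is.na(axis)] <- NA_real_
  structure(list(axis = axis, retardance = ret, valid = valid,
                 dz_um = actual_um, eps = eps, pitch = filtered$pitch),
            class = "oa_volume")
}

#' Construct an optic-axis volume directly
#'
#' Lightweight constructor for workflows that start from axis fields rather
#' than tomograms (e.g. applying a known rotation to measured axes).
#'
#' @param axis Array `nx x ny x nz x 3` of Poincare-sphere axis vectors
#'   (normalized internally).
#' @param retardance Optional `nx x ny x nz` array (deg/um).
#' @param valid Optional logical array; default: all finite axes valid.
#' @param pitch Length-3 pixel pitch in um.
#' @param dz_um Depth offset metadata (um).
#' @return An `oa_volume`.
#' @export
oa_volume <- function(axis, retardance = NULL, valid = NULL,
                      pitch = c(1, 1, 1), dz_um = NA_real_) {
  stopifnot(length(dim(axis)) == 4, dim(axis)[4] == 3)
  d3 <- dim(axis)[1:3]
  n <- v3_norm(axis)
  if (is.null(valid)) valid <- is.finite(n) & n > 0
  valid <- array(valid, d3)
  axis <- v3_scale(axis, 1 / pmax(n, 1e-300))
  if (is.null(retardance))
    retardance <- array(NA_real_, d3)
  structure(list(axis = axis, retardance = retardance, valid = valid,
                 dz_um = dz_um, eps = NA_real_, pitch = pitch),
            class = "oa_volume")
}

#' Apply a global Poincare-sphere rotation to an optic-axis volume
#'
#' @param oa An `oa_volume`.
#' @param R A 3x3 rotation matrix.
#' @return An `oa_volume` with every axis replaced by `R %*% axis`.
#' @export
rotate_oa <- function(oa, R) {
  stopifnot(inherits(oa, "oa_volume"), all(dim(R) == c(3, 3)))
  ax <- oa$axis
  out <- ax
  for (k in 1:3)
    out[, , , k] <- R[k, 1] * ax[, , , 1] + R[k, 2] * ax[, , , 2] +
      R[k, 3] * ax[, , , 3]
  oa$axis <- out
  oa
}
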