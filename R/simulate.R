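#' Simulate a PS-OCT tomogram from a phantom specification
#'
#' Forward Jones-calculus model of a reflective PS-OCT measurement of a
#' layered birefringent phantom. For every A-line and depth `z` the noiseless
#' detected Jones vector is
#' \deqn{E_{det}(z) = U \, J_{cum}^T(z) \, J_{cum}(z) \, U \, E_{in} \, a(z)}
#' where `J_cum(z)` is the ordered product of the linear-retarder Jones
#' matrices of all tissue slabs above `z` (fast axis from the layer's
#' orientation field, single-pass retardance `rate * dz` per axial step),
#' the transpose encodes the reciprocal double pass, `U` is the fiber unitary
#' applied on both paths, and `a(z)` the depth-decayed scattering amplitude
#' \eqn{a(z) = A_{layer} e^{-d/L}} (`d` = depth below the surface, `L` the
#' SNR decay length). Optional fully developed speckle multiplies each
#' pixel's field by a circular complex Gaussian factor; additive complex
#' Gaussian channel noise of sd `noise_floor` is added last. Pixels above the
#' surface or below the last layer carry noise only.
#'
#' The discretization contract (used identically by test oracles): the
#' measurement at axial pixel `k` (center depth `(k - 1/2) dz`) uses the
#' cumulative product over steps `1..k`, each step applying the retarder of
#' the layer containing that pixel's center.
#'
#' The simulation is bit-for-bit reproducible given `(spec, spec$seed)`.
#'
#' @param spec A [phantom_spec()].
#' @return A `raw_tomogram`: list with `field` (complex array
#'   `nx x ny x nz x channel(H,V) x input state`), `pitch` (um), `seed`,
#'   `digest` and the originating `spec`.
#' @examples
#' spec <- phantom_spec(grid = c(4, 4, 16), pitch = c(10, 10, 5),
#'                      surface_depth = 0,
#'                      layers = list(layer_spec(0, 80, 0.5)),
#'                      noise_floor = 0, seed = 7)
#' tom <- simulate_phantom(spec)
#' dim(tom$field)
#' @export
simulate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid[1]; ny <- spec$grid[2]; nz <- spec$grid[3]
  dx <- spec$pitch[1]; dy <- spec$pitch[2]; dz <- spec$pitch[3]
  npx <- nx * ny
  set.seed(spec$seed %% .Machine$integer.max)

  U <- if (identical(spec$fiber_rotation, "random")) random_unitary()
       else if (identical(spec$fiber_rotation, "identity")) diag(2) + 0i
       else spec$fiber_rotation
  if (max(Mod(U %*% Conj(t(U)) - diag(2))) > 1e-8)
    stop("fiber_rotation matrix must be unitary")

  nl <- length(spec$layers)
  tos <- vapply(spec$layers, `[[`, numeric(1), "z_to")
  rates <- vapply(spec$layers, `[[`, numeric(1), "retardance_rate")
  amps <- vapply(spec$layers, `[[`, numeric(1), "scattering_amplitude")
  c2 <- vector("list", nl); s2 <- vector("list", nl)
  for (i in seq_len(nl)) {
    phi <- orientation_matrix(spec$layers[[i]]$orientation, nx, ny, dx, dy)
    c2[[i]] <- cos(2 * phi); s2[[i]] <- sin(2 * phi)
  }

  S <- if (is.matrix(spec$surface_depth)) spec$surface_depth
       else matrix(spec$surface_depth, nx, ny)
  e_in <- spec$input_states
  sigma <- spec$noise_floor
  L <- spec$snr_decay_length
  breaks <- c(0, tos)

  j11 <- matrix(1 + 0i, nx, ny); j22 <- j11
  j12 <- matrix(0 + 0i, nx, ny); j21 <- j12
  field <- array(0i, c(nx, ny, nz, 2, 2))

  for (k in seq_len(nz)) {
    d <- (k - 0.5) * dz - S
    li <- matrix(findInterval(as.vector(d), breaks), nx, ny)
    in_tissue <- li >= 1L & li <= nl
    dh <- matrix(0, nx, ny)     # half single-pass retardance of this step
    cc2 <- matrix(1, nx, ny); ss2 <- matrix(0, nx, ny)
    amp <- matrix(0, nx, ny)
    for (i in seq_len(nl)) {
      m <- li == i
      if (any(m)) {
        dh[m] <- deg2rad(rates[i]) * dz / 2
        cc2[m] <- c2[[i]][m]; ss2[m] <- s2[[i]][m]
        amp[m] <- amps[i]
      }
    }
    # linear retarder, fast axis phi, step retardance 2*dh; the eigenphase
    # sign is chosen so a fast axis at real-space angle phi rotates Stokes
    # vectors positively about the Poincare axis (cos 2 phi, sin 2 phi, 0)
    cd <- cos(dh); sd <- sin(dh)
    st11 <- complex(real = cd, imaginary = -sd * cc2)
    st12 <- complex(real = 0, imaginary = -sd * ss2)
    st22 <- complex(real = cd, imaginary = sd * cc2)
    j11n <- st11 * j11 + st12 * j21
    j12n <- st11 * j12 + st12 * j22
    j21n <- st12 * j11 + st22 * j21
    j22n <- st12 * j12 + st22 * j22
    j11 <- j11n; j12 <- j12n; j21 <- j21n; j22 <- j22n

    m11 <- j11 * j11 + j21 * j21          # M = t(J) %*% J, symmetric
    m12 <- j11 * j12 + j21 * j22
    m22 <- j12 * j12 + j22 * j22
    p11 <- m11 * U[1, 1] + m12 * U[2, 1]  # P = M U
    p12 <- m11 * U[1, 2] + m12 * U[2, 2]
    p21 <- m12 * U[1, 1] + m22 * U[2, 1]
    p22 <- m12 * U[1, 2] + m22 * U[2, 2]
    t11 <- U[1, 1] * p11 + U[1, 2] * p21  # T = U M U
    t12 <- U[1, 1] * p12 + U[1, 2] * p22
    t21 <- U[2, 1] * p11 + U[2, 2] * p21
    t22 <- U[2, 1] * p12 + U[2, 2] * p22

    a <- amp * exp(-pmax(d, 0) / L) * in_tissue
    spk <- if (spec$speckle)
      matrix(complex(real = stats::rnorm(npx, sd = 1 / sqrt(2)),
                     imaginary = stats::rnorm(npx, sd = 1 / sqrt(2))), nx, ny)
      else 1
    for (s in 1:2) {
      H <- a * spk * (t11 * e_in[1, s] + t12 * e_in[2, s])
      V <- a * spk * (t21 * e_in[1, s] + t22 * e_in[2, s])
      if (sigma > 0) {
        H <- H + matrix(complex(
          real = stats::rnorm(npx, sd = sigma / sqrt(2)),
          imaginary = stats::rnorm(npx, sd = sigma / sqrt(2))), nx, ny)
        V <- V + matrix(complex(
          real = stats::rnorm(npx, sd = sigma / sqrt(2)),
          imaginary = stats::rnorm(npx, sd = sigma / sqrt(2))), nx, ny)
      }
      field[, , k, 1, s] <- H
      field[, , k, 2, s] <- V
    }
  }
  structure(list(field = field, pitch = spec$pitch, seed = spec$seed,
                 digest = spec_digest(spec), spec = spec),
            class = "raw_tomogram")
}

#' @export
print.raw_tomogram <- function(x, ...) {
  d <- dim(x$field)
  cat("<raw_tomogram>", paste(d[1:3], collapse = "x"),
      "px, 2 channels x 2 input states, pitch",
      paste(x$pitch, collapse = "x"), "um, seed", x$seed,
      "digest", x$digest, "\n")
  invisible(x)
}
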