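#' Stokes vectors from a dual-state tomogram
#'
#' Forms per-pixel Stokes vectors for each input polarization state from the
#' complex detection channels `H`, `V`:
#' `I = |H|^2 + |V|^2`, `Q = |H|^2 - |V|^2`, `U = 2 Re(H conj(V))`,
#' `V = 2 Im(conj(H) V)` (right circular `(1, i)/sqrt(2)` has `V = +1`).
#'
#' @param tomogram A `raw_tomogram` from [simulate_phantom()] (or any list
#'   with a complex `field` array `nx x ny x nz x 2 x 2` and `pitch`).
#' @return A `stokes_volume`: list with `data` (array
#'   `nx x ny x nz x component(I,Q,U,V) x state`), `filtered = FALSE`,
#'   `filter_sd_um = 0`, `pitch`.
#' @export
compute_stokes <- function(tomogram) {
  f <- tomogram$field
  stopifnot(!is.null(f), length(dim(f)) == 5, dim(f)[4] == 2, dim(f)[5] == 2)
  if (!all(is.finite(Re(f))) || !all(is.finite(Im(f))))
    stop("tomogram field contains non-finite values")
  d <- dim(f)
  out <- array(0, c(d[1:3], 4, 2))
  for (s in 1:2) {
    H <- f[, , , 1, s]; V <- f[, , , 2, s]
    hv <- H * Conj(V)
    out[, , , 1, s] <- Mod(H)^2 + Mod(V)^2
    out[, , , 2, s] <- Mod(H)^2 - Mod(V)^2
    out[, , , 3, s] <- 2 * Re(hv)
    out[, , , 4, s] <- -2 * Im(hv)
  }
  structure(list(data = out, filtered = FALSE, filter_sd_um = 0,
                 pitch = tomogram$pitch),
            class = "stokes_volume")
}

#' Transverse Gaussian filtering of Stokes data
#'
#' Smooths each Stokes component of each input state with a unit-DC-gain
#' Gaussian kernel of standard deviation `sd_um` (default 28 um, truncated
#' at 3 sd) applied in the two transverse dimensions only; the axial
#' dimension is left untouched so the depth-differential retardance
#' computation is not biased. Edges are handled by renormalized convolution.
#'
#' @param stokes An unfiltered `stokes_volume`.
#' @param sd_um Kernel standard deviation in um, `> 0`.
#' @return A filtered `stokes_volume` (`filtered = TRUE`).
#' @export
filter_stokes <- function(stokes, sd_um = 28) {
  stopifnot(inherits(stokes, "stokes_volume"))
  if (stokes$filtered) stop("stokes volume is already filtered")
  if (sd_um <= 0) stop("sd_um must be positive")
  sdx <- sd_um / stokes$pitch[1]
  sdy <- sd_um / stokes$pitch[2]
  out <- stokes$data
  for (s in 1:2) for (cmp in 1:4)
    out[, , , cmp, s] <- smooth_xy(stokes$data[, , , cmp, s], sdx, sdy)
  structure(list(data = out, filtered = TRUE, filter_sd_um = sd_um,
                 pitch = stokes$pitch),
            class = "stokes_volume")
}

#' Degree of polarization
#'
#' DOP per pixel and input state from spatially filtered Stokes data:
#' `dop = ||(Q, U, V)_filtered|| / I_filtered`, clamped to `[0, 1]`, plus
#' the mean over the two input states. On noiseless, spatially uniform data
#' the DOP is 1; additive noise and polarization-state heterogeneity within
#' the filter kernel reduce it.
#'
#' @param unfiltered The unfiltered `stokes_volume` the filtered data derive
#'   from (geometry check; the conventional filtered-polarization-over-
#'   intensity DOP uses only the filtered data).
#' @param filtered The matching filtered `stokes_volume`.
#' @return A `dop_volume`: list with `dop` (array `nx x ny x nz x state`),
#'   `mean` (array `nx x ny x nz`), `valid` (filtered intensity > 0), and
#'   `pitch`. Pixels with zero filtered intensity are `NA` and invalid.
#' @export
compute_dop <- function(unfiltered, filtered) {
  stopifnot(inherits(unfiltered, "stokes_volume"),
            inherits(filtered, "stokes_volume"))
  if (unfiltered$filtered || !filtered$filtered)
    stop("arguments must be (unfiltered, filtered) stokes volumes")
  if (!identical(dim(unfiltered$data), dim(filtered$data)))
    stop("stokes volumes have mismatched geometry")
  d <- dim(filtered$data)
  dop <- array(NA_real_, c(d[1:3], 2))
  for (s in 1:2) {
    I <- filtered$data[, , , 1, s]
    pol <- sqrt(filtered$data[, , , 2, s]^2 +
                filtered$data[, , , 3, s]^2 +
                filtered$data[, , , 4, s]^2)
    v <- pol / I
    v[I <= 0] <- NA_real_
    dop[, , , s] <- pmin(pmax(v, 0), 1)
  }
  m <- (dop[, , , 1, drop = FALSE] + dop[, , , 2, drop = FALSE]) / 2
  dim(m) <- d[1:3]
  valid <- !is.na(m)
  structure(list(dop = dop, mean = m, valid = valid,
                 pitch = filtered$pitch),
            class = "dop_volume")
}
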