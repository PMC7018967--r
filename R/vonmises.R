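#' Sample from a von Mises distribution
#'
#' Draws circular samples from the von Mises distribution VM(mu, kappa)
#' using the Best-Fisher (1979) acceptance-rejection envelope. `kappa = 0`
#' degenerates to the uniform circular distribution.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration parameter, `kappa >= 0`.
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @seealso [rvonmises_axial()] for the period-pi (axial) variant used for
#'   fiber orientations.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0, is.finite(mu))
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-9) return((mu + stats::runif(n, -pi, pi)) %% (2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) * 1.3))
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    take <- min(length(th), n - got)
    if (take > 0L) out[(got + 1L):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  (mu + out) %% (2 * pi)
}

#' Sample axial (period-pi) von Mises orientations
#'
#' Fiber orientations are axial quantities: an angle phi and phi + pi
#' describe the same fiber. Samples theta in `[0, pi)` such that the doubled
#' angle `2*theta` follows VM(2*mu, kappa); `kappa = 0` gives uniform
#' orientations.
#'
#' @inheritParams rvonmises
#' @param mu Mean orientation in `[0, pi)`.
#' @return Numeric vector of orientations in `[0, pi)`.
#' @export
rvonmises_axial <- function(n, mu = 0, kappa = 1) {
  doubled <- rvonmises(n, 0, kappa)
  centered <- ((doubled + pi) %% (2 * pi)) - pi  # (-pi, pi]
  (mu + centered / 2) %% pi
}
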