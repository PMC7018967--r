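# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# FNV-1a 32-bit hash of a character scalar; used for spec digests so that
# identical specs have byte-identical digests without a hashing dependency.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # kept exact in doubles: h*2^24 mod 2^32 == (h mod 2^8)*2^24
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Zero-padded shift of a 3-D array along dimension 1 or 2.
shift_arr <- function(a, k, dim) {
  if (k == 0L) return(a)
  d <- dim(a)
  out <- array(0, d)
  n <- d[dim]
  if (abs(k) >= n) return(out)
  src <- if (k > 0L) 1L:(n - k) else (1L - k):n
  dst <- if (k > 0L) (1L + k):n else 1L:(n + k)
  if (dim == 1L) out[dst, , ] <- a[src, , , drop = FALSE]
  else out[, dst, ] <- a[, src, , drop = FALSE]
  out
}

gauss_kernel <- function(sd_px) {
  K <- max(1L, ceiling(3 * sd_px))
  w <- stats::dnorm(seq(-K, K), sd = sd_px)
  w / sum(w)
}

conv_dim <- function(a, w, dim) {
  K <- (length(w) - 1L) / 2L
  out <- array(0, dim(a))
  for (j in seq_along(w)) out <- out + w[j] * shift_arr(a, j - K - 1L, dim)
  out
}

conv_vec <- function(v, w) {
  K <- (length(w) - 1L) / 2L
  n <- length(v)
  out <- numeric(n)
  for (j in seq_along(w)) {
    k <- j - K - 1L
    sh <- numeric(n)
    if (abs(k) < n) {
      src <- if (k > 0L) 1L:(n - k) else (1L - k):n
      dst <- if (k > 0L) (1L + k):n else 1L:(n + k)
      sh[dst] <- v[src]
    }
    out <- out + w[j] * sh
  }
  out
}

# Separable transverse Gaussian smoothing of a (nx, ny, nz) array with
# unit DC gain and renormalized (edge-aware) boundaries. Works for complex
# input as well (used nowhere hot; Stokes data are real).
smooth_xy <- function(a, sd_px_x, sd_px_y) {
  d <- dim(a)
  two_d <- length(d) == 2L
  if (two_d) {
    a <- array(a, c(d, 1L))
    d <- dim(a)
  }
  wx <- gauss_kernel(sd_px_x)
  wy <- gauss_kernel(sd_px_y)
  out <- conv_dim(conv_dim(a, wx, 1L), wy, 2L)
  norm2d <- outer(conv_vec(rep(1, d[1]), wx), conv_vec(rep(1, d[2]), wy))
  out <- out / as.vector(norm2d)  # recycles per z-slice (dims 1,2 contiguous)
  if (two_d) out <- out[, , 1L]
  out
}

# Smoothed standard-normal random field (nx x ny), standardized to unit
# variance; building block for spatially correlated orientation fields.
smooth_normal_field <- function(nx, ny, corr_px) {
  g <- matrix(stats::rnorm(nx * ny), nx, ny)
  if (corr_px > 0.5) g <- smooth_xy(g, corr_px, corr_px)
  (g - mean(g)) / stats::sd(as.vector(g))
}

# 2-D median filter on a matrix, NA-aware, odd window size.
median_filter2 <- function(m, size = 5L) {
  half <- (size - 1L) %/% 2L
  nx <- nrow(m); ny <- ncol(m)
  stack <- array(NA_real_, c(nx, ny, size * size))
  s <- 0L
  for (i in -half:half) for (j in -half:half) {
    s <- s + 1L
    xs <- pmin(pmax(seq_len(nx) + i, 1L), nx)
    ys <- pmin(pmax(seq_len(ny) + j, 1L), ny)
    stack[, , s] <- m[xs, ys]
  }
  apply(stack, c(1, 2), stats::median, na.rm = TRUE)
}

# --- small 3-vector field algebra on (nx, ny, nz, 3) arrays -----------------

v3_dot <- function(a, b) a[, , , 1] * b[, , , 1] + a[, , , 2] * b[, , , 2] +
  a[, , , 3] * b[, , , 3]

v3_cross <- function(a, b) {
  out <- array(0, dim(a))
  out[, , , 1] <- a[, , , 2] * b[, , , 3] - a[, , , 3] * b[, , , 2]
  out[, , , 2] <- a[, , , 3] * b[, , , 1] - a[, , , 1] * b[, , , 3]
  out[, , , 3] <- a[, , , 1] * b[, , , 2] - a[, , , 2] * b[, , , 1]
  out
}

v3_norm <- function(a) sqrt(pmax(v3_dot(a, a), 0))

v3_scale <- function(a, s) {
  out <- a
  for (k in 1:3) out[, , , k] <- a[, , , k] * s
  out
}

#' Random polarization unitary
#'
#' Draws a 2x2 Jones unitary uniformly (Haar) from SU(2) via a normalized
#' quaternion, emulating the unknown birefringence of a single-mode fiber.
#' Uses the current RNG state.
#'
#' @return Complex 2x2 unitary matrix.
#' @export
random_unitary <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(complex(real = q[1], imaginary = q[4]),
           complex(real = -q[3], imaginary = q[2]),
           complex(real = q[3], imaginary = q[2]),
           complex(real = q[1], imaginary = -q[4])), 2, 2)
}

jones_to_stokes <- function(e) {
  h <- e[1]; v <- e[2]
  c(Mod(h)^2 + Mod(v)^2,
    Mod(h)^2 - Mod(v)^2,
    2 * Re(h * Conj(v)),
    2 * Im(Conj(h) * v))
}

#' Stokes rotation of a Jones unitary
#'
#' Returns the 3x3 rotation matrix acting on (Q, U, V) Poincare-sphere
#' coordinates that corresponds to the Jones map \eqn{E \mapsto U E}.
#'
#' @param U Complex 2x2 unitary.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
stokes_rotation <- function(U) {
  # basis Jones states with Stokes (Q,U,V) = (1,0,0), (0,1,0), (0,0,1)
  basis <- list(c(1, 0), c(1, 1) / sqrt(2), c(1, 1i) / sqrt(2))
  vapply(basis, function(e) jones_to_stokes(U %*% e)[2:4], numeric(3))
}
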