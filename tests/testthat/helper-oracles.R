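# Independent oracles, deliberately written with different constructions
# than the package internals (explicit matrix products, cut()/table(),
# exhaustive loops).

deg2rad_test <- function(x) x * pi / 180

# Rotation-conjugation Jones retarder: R(phi) diag(e^{-i d/2}, e^{i d/2}) R(-phi)
oracle_retarder <- function(phi, delta) {
  R <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  R(phi) %*% diag(c(exp(-1i * delta / 2), exp(1i * delta / 2))) %*% R(-phi)
}

# Naive per-pixel forward model: same discretization contract as the
# simulator (measurement at pixel k uses the cumulative product over steps
# 1..k, layer chosen by the pixel-center depth), built from explicit 2x2
# matrix products. Uniform-orientation layers only; no noise, no speckle.
oracle_simulate <- function(grid, pitch, surface_depth, layers, U,
                            input_states, decay_um) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  dz <- pitch[3]
  tos <- vapply(layers, `[[`, numeric(1), "z_to")
  field <- array(0i, c(nx, ny, nz, 2, 2))
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    S <- if (is.matrix(surface_depth)) surface_depth[ix, iy] else surface_depth
    J <- diag(2) + 0i
    for (k in seq_len(nz)) {
      d <- (k - 0.5) * dz - S
      li <- which(d >= c(0, tos[-length(tos)]) & d < tos)
      if (d >= 0 && length(li) == 1) {
        l <- layers[[li]]
        J <- oracle_retarder(l$phi0, l$rate * dz * pi / 180) %*% J
        a <- l$amp * exp(-d / decay_um)
      } else {
        a <- 0
      }
      TT <- U %*% t(J) %*% J %*% U
      for (s in 1:2) {
        E <- a * (TT %*% input_states[, s])
        field[ix, iy, k, , s] <- E
      }
    }
  }
  field
}

# Histogram entropy in bits via cut()/table()
oracle_entropy <- function(theta, n_bins = 256) {
  theta <- (theta[is.finite(theta)]) %% pi
  cts <- table(cut(theta, breaks = seq(0, pi, length.out = n_bins + 1),
                   include.lowest = TRUE, right = FALSE))
  p <- as.numeric(cts) / sum(cts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Exhaustive best-block search
oracle_best_block <- function(map, sr, sc, mode, min_frac = 0.8) {
  best <- NULL
  for (i in seq_len(nrow(map) - sr + 1)) for (j in seq_len(ncol(map) - sc + 1)) {
    blk <- map[i:(i + sr - 1), j:(j + sc - 1)]
    nv <- sum(is.finite(blk))
    if (nv < min_frac * sr * sc) next
    m <- mean(blk[is.finite(blk)])
    if (is.null(best) ||
        (mode == "max" && m > best$mean) ||
        (mode == "min" && m < best$mean))
      best <- list(row = i, col = j, mean = m)
  }
  best
}

# Rodrigues rotation matrix about a unit axis
rot_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# oa_volume whose axes lie on the Q-U great circle at sphere angles 2*theta
axes_on_equator <- function(theta, nx, ny, pitch = c(10, 10, 5)) {
  stopifnot(length(theta) == nx * ny)
  ax <- array(0, c(nx, ny, 1, 3))
  ax[, , 1, 1] <- matrix(cos(2 * theta), nx, ny)
  ax[, , 1, 2] <- matrix(sin(2 * theta), nx, ny)
  oa_volume(ax, pitch = pitch)
}

# Small noiseless uniform-layer phantom helper
uniform_phantom <- function(rate, phi0, grid = c(8, 8, 48),
                            pitch = c(10, 10, 2.5), fiber = "identity",
                            noise = 0, seed = 1) {
  phantom_spec(grid = grid, pitch = pitch, surface_depth = 0,
               layers = list(layer_spec(0, grid[3] * pitch[3] + 1, rate,
                                        orient_uniform(phi0))),
               fiber_rotation = fiber, noise_floor = noise,
               snr_decay_length = 1e6, seed = seed)
}
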