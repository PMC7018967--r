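make_tomogram <- function(H, V, pitch = c(10, 10, 5)) {
  # tiny single-state-duplicated tomogram with constant channel amplitudes
  f <- array(0i, c(2, 2, 3, 2, 2))
  f[, , , 1, ] <- H
  f[, , , 2, ] <- V
  list(field = f, pitch = pitch)
}

test_that("Stokes formation reproduces the canonical states", {
  cases <- list(
    list(H = 1 + 0i, V = 0 + 0i, s = c(1, 1, 0, 0)),          # horizontal
    list(H = 1 / sqrt(2) + 0i, V = 1 / sqrt(2) + 0i,
         s = c(1, 0, 1, 0)),                                   # linear 45
    list(H = 1 / sqrt(2) + 0i, V = 1i / sqrt(2), s = c(1, 0, 0, 1)))
  for (cs in cases) {
    st <- compute_stokes(make_tomogram(cs$H, cs$V))
    expect_equal(as.numeric(st$data[1, 1, 1, , 1]), cs$s, tolerance = 1e-12)
    expect_false(st$filtered)
  }
  # unfiltered pure states are fully polarized: Q^2+U^2+V^2 = I^2
  spec <- uniform_phantom(0.5, 1.1, grid = c(4, 4, 16), fiber = "random")
  st <- compute_stokes(simulate_phantom(spec))
  I2 <- st$data[, , , 1, ]^2
  P2 <- st$data[, , , 2, ]^2 + st$data[, , , 3, ]^2 + st$data[, , , 4, ]^2
  expect_equal(P2, I2, tolerance = 1e-12)
})

test_that("Gaussian Stokes filtering has unit DC gain and matches direct convolution", {
  # constant field is unchanged
  tom <- make_tomogram(0.6 + 0.2i, 0.3 - 0.4i)
  st <- compute_stokes(tom)
  fl <- filter_stokes(st, sd_um = 28)
  expect_equal(fl$data, st$data, tolerance = 1e-12)
  expect_true(fl$filtered)
  expect_error(filter_stokes(fl, 28), "already")
  expect_error(filter_stokes(st, 0), "positive")

  # impulse response equals a dense direct-space convolution oracle
  # (impulse placed so its response stays clear of the edge-renormalized
  # boundary zone)
  nx <- 41; ny <- 41
  f <- array(0i, c(nx, ny, 1, 2, 2))
  f[21, 21, 1, 1, ] <- 1   # unit H impulse -> unit impulse in I and Q
  tom <- list(field = f, pitch = c(10, 10, 5))
  fl <- filter_stokes(compute_stokes(tom), sd_um = 28)
  sdp <- 28 / 10
  K <- ceiling(3 * sdp)
  w <- dnorm(seq(-K, K), sd = sdp); w <- w / sum(w)
  ker <- outer(w, w)
  direct <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    di <- i - 21; dj <- j - 21
    if (abs(di) <= K && abs(dj) <= K)
      direct[i, j] <- ker[di + K + 1, dj + K + 1]
  }
  expect_equal(fl$data[, , 1, 2, 1], direct, tolerance = 1e-12)
  # normalization: total Q mass conserved away from edges
  expect_equal(sum(fl$data[, , 1, 2, 1]), 1, tolerance = 1e-9)
})

test_that("DOP is 1 for pure states and matches a Monte-Carlo depolarization oracle", {
  spec <- uniform_phantom(0.5, 0.9, grid = c(6, 6, 20), fiber = "random")
  st <- compute_stokes(simulate_phantom(spec))
  fl <- filter_stokes(st, 28)
  dop <- compute_dop(st, fl)
  expect_true(all(abs(dop$mean - 1) < 1e-9))

  # per-pixel states uniform on the sphere: filtered DOP collapses toward
  # the norm of a weighted mean of random unit vectors
  set.seed(101)
  nx <- 61; ny <- 61
  reps <- 12
  center_vals <- numeric(reps)
  for (r in seq_len(reps)) {
    v <- matrix(rnorm(3 * nx * ny), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    f <- array(0, c(nx, ny, 1, 4, 2))
    f[, , 1, 1, ] <- 1
    for (k in 1:3) f[, , 1, k + 1, ] <- matrix(v[, k], nx, ny)
    st <- structure(list(data = f, filtered = FALSE, filter_sd_um = 0,
                         pitch = c(10, 10, 5)), class = "stokes_volume")
    fl <- filter_stokes(st, sd_um = 50)
    center_vals[r] <- compute_dop(st, fl)$mean[31, 31, 1]
  }
  sdp <- 5
  K <- ceiling(3 * sdp)
  w <- dnorm(seq(-K, K), sd = sdp); w <- w / sum(w)
  ker <- as.vector(outer(w, w))
  nmc <- 2000
  mc <- replicate(nmc, {
    v <- matrix(rnorm(3 * length(ker)), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    sqrt(sum(colSums(ker * v)^2))
  })
  se <- sqrt(var(mc) / reps + var(center_vals) / reps)
  expect_lt(abs(mean(center_vals) - mean(mc)), 3 * se + 3 * sd(mc) / sqrt(nmc))
})

test_that("mean DOP decreases monotonically with channel noise", {
  sds <- c(0, 0.05, 0.1, 0.2, 0.4)
  mean_dop <- matrix(NA_real_, 10, length(sds))
  for (r in 1:10) for (i in seq_along(sds)) {
    spec <- uniform_phantom(0.4, 0.6, grid = c(10, 10, 16),
                            pitch = c(10, 10, 5),
                            noise = sds[i], seed = 500 + r)
    st <- compute_stokes(simulate_phantom(spec))
    fl <- filter_stokes(st, 28)
    mean_dop[r, i] <- mean(compute_dop(st, fl)$mean)
  }
  expect_true(all(diff(colMeans(mean_dop)) < 0))
})

test_that("the geometric solution recovers axis and retardance, incl. the eigenstate case", {
  # generic axis
  spec <- uniform_phantom(0.5, pi / 6, grid = c(6, 6, 48))
  fl <- filter_stokes(compute_stokes(simulate_phantom(spec)), 28)
  oa <- local_birefringence(fl, 20)
  sel <- oa$valid
  expect_true(mean(sel) > 0.7)
  expect_equal(mean(oa$retardance[sel]), 2 * 0.5, tolerance = 1e-6)
  truth <- c(cos(pi / 3), sin(pi / 3), 0)
  ax <- cbind(oa$axis[, , , 1][sel], oa$axis[, , , 2][sel],
              oa$axis[, , , 3][sel])
  expect_true(all(acos(pmin(1, ax %*% truth)) < 1e-4))

  # axis parallel to the linear probe: H state is an eigenpolarization and
  # the axis comes from the eigenstate fallback
  spec0 <- uniform_phantom(0.5, 0, grid = c(4, 4, 48))
  fl0 <- filter_stokes(compute_stokes(simulate_phantom(spec0)), 28)
  oa0 <- local_birefringence(fl0, 20)
  sel0 <- oa0$valid
  expect_true(any(sel0))
  expect_equal(mean(oa0$retardance[sel0]), 1, tolerance = 1e-6)
  expect_true(all(abs(oa0$axis[, , , 1][sel0] - 1) < 1e-6))

  # zero birefringence: degenerate everywhere
  specz <- uniform_phantom(0, 0.8, grid = c(4, 4, 32))
  flz <- filter_stokes(compute_stokes(simulate_phantom(specz)), 28)
  expect_false(any(local_birefringence(flz, 20)$valid))
})

test_that("axes are equivariant and retardance/DOP invariant under a fiber rotation", {
  set.seed(7)
  U <- random_unitary()
  R <- stokes_rotation(U)
  base <- uniform_phantom(0.4, 1.0, grid = c(5, 5, 48), seed = 11)
  rot <- base; rot$fiber_rotation <- U
  run <- function(s) {
    st <- compute_stokes(simulate_phantom(s))
    fl <- filter_stokes(st, 28)
    list(oa = local_birefringence(fl, 20), dop = compute_dop(st, fl))
  }
  a <- run(base); b <- run(rot)
  sel <- a$oa$valid & b$oa$valid
  expect_true(any(sel))
  expect_equal(b$oa$retardance[sel], a$oa$retardance[sel], tolerance = 1e-6)
  expect_equal(b$dop$mean, a$dop$mean, tolerance = 1e-6)
  axa <- cbind(a$oa$axis[, , , 1][sel], a$oa$axis[, , , 2][sel],
               a$oa$axis[, , , 3][sel])
  axb <- cbind(b$oa$axis[, , , 1][sel], b$oa$axis[, , , 2][sel],
               b$oa$axis[, , , 3][sel])
  expect_lt(max(abs(axb - axa %*% t(R))), 1e-6)
})
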