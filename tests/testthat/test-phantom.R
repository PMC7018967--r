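test_that("non-birefringent and eigenstate phantoms leave the probe untouched", {
  # zero retardance everywhere: detected field proportional to the input
  spec <- phantom_spec(grid = c(3, 3, 12), pitch = c(10, 10, 5),
                       surface_depth = 0,
                       layers = list(layer_spec(0, 100, 0)),
                       noise_floor = 0, seed = 1)
  tom <- simulate_phantom(spec)
  expect_true(all(Mod(tom$field[, , , 2, 1]) < 1e-14))   # V channel, state H
  h <- tom$field[, , , 1, 1]
  expect_true(all(abs(Arg(h[Mod(h) > 0])) < 1e-12))      # no phase picked up

  # fast axis along the probe: H is an eigenpolarization of the retarder
  spec2 <- uniform_phantom(rate = 0.8, phi0 = 0, grid = c(3, 3, 24))
  tom2 <- simulate_phantom(spec2)
  expect_true(all(Mod(tom2$field[, , , 2, 1]) < 1e-12))
})

test_that("a 45-degree layer rotates the H probe about the Poincare U axis", {
  rate <- 0.6
  dz <- 2.5
  spec <- uniform_phantom(rate, phi0 = pi / 4, grid = c(2, 2, 40),
                          pitch = c(10, 10, dz))
  tom <- simulate_phantom(spec)
  st <- compute_stokes(tom)
  for (k in c(5, 15, 30)) {
    s <- st$data[1, 1, k, 2:4, 1]
    s <- s / sqrt(sum(s^2))
    # double-pass Stokes rotation angle: 2 x single-pass retardance
    expected_angle <- deg2rad_test(2 * rate * k * dz)
    expect_lt(abs(s[2]), 1e-10)                          # U component fixed
    meas <- atan2(-s[3], s[1])                           # angle in Q-V plane
    expect_lt(abs((meas - expected_angle + pi) %% (2 * pi) - pi), 1e-9)
  }
})

test_that("simulator matches the naive Jones matrix-product oracle", {
  layers <- list(
    layer_spec(0, 40, 0.9, orient_uniform(0.3)),
    layer_spec(40, 90, 0.2, orient_uniform(1.8), scattering_amplitude = 0.7),
    layer_spec(90, 200, 0.5, orient_uniform(2.6), scattering_amplitude = 1.3))
  set.seed(42)
  U <- random_unitary()
  spec <- phantom_spec(grid = c(8, 8, 64), pitch = c(12, 12, 3),
                       surface_depth = 10, layers = layers,
                       fiber_rotation = U, noise_floor = 0,
                       snr_decay_length = 150, seed = 9)
  tom <- simulate_phantom(spec)
  ora <- oracle_simulate(c(8, 8, 64), c(12, 12, 3), 10,
                         list(list(z_to = 40, phi0 = 0.3, rate = 0.9, amp = 1),
                              list(z_to = 90, phi0 = 1.8, rate = 0.2,
                                   amp = 0.7),
                              list(z_to = 200, phi0 = 2.6, rate = 0.5,
                                   amp = 1.3)),
                         U, spec$input_states, 150)
  denom <- max(Mod(ora))
  expect_lt(max(Mod(tom$field - ora)) / denom, 1e-10)
})

test_that("noise-free propagation conserves per-state intensity a(z)^2", {
  spec <- phantom_spec(grid = c(4, 4, 30), pitch = c(10, 10, 5),
                       surface_depth = 20,
                       layers = list(layer_spec(0, 60, 0.7),
                                     layer_spec(60, 300, 0.3,
                                                scattering_amplitude = 0.5)),
                       fiber_rotation = "random", noise_floor = 0, seed = 5)
  tom <- simulate_phantom(spec)
  st <- compute_stokes(tom)
  d <- (seq_len(30) - 0.5) * 5 - 20
  amp <- ifelse(d < 0, 0, ifelse(d < 60, 1, ifelse(d < 300, 0.5, 0)))
  a2 <- (amp * exp(-pmax(d, 0) / 200))^2
  for (s in 1:2) {
    I <- st$data[2, 3, , 1, s]
    expect_equal(I, a2, tolerance = 1e-12)
  }
})

test_that("simulation is bit-for-bit reproducible and digests are stable", {
  spec <- preset_cohort("14", seed = 77)
  expect_identical(spec_digest(spec), spec_digest(preset_cohort("14", 77)))
  expect_false(spec_digest(spec) == spec_digest(preset_cohort("14", 78)))
  a <- simulate_phantom(uniform_phantom(0.4, 0.7, grid = c(4, 4, 16),
                                        fiber = "random", noise = 0.1,
                                        seed = 3))
  b <- simulate_phantom(uniform_phantom(0.4, 0.7, grid = c(4, 4, 16),
                                        fiber = "random", noise = 0.1,
                                        seed = 3))
  expect_identical(a$field, b$field)
})

test_that("cohort presets encode the fibrosis time course", {
  ctrl <- preset_cohort("control", seed = 1)
  d28 <- preset_cohort(28, seed = 1)
  expect_equal(ctrl$layers[[1]]$orientation$type, "random")
  expect_equal(d28$layers[[1]]$orientation$type, "radial")
  days <- c("control", "7", "14", "21", "28")
  th <- vapply(days, function(d) preset_cohort(d, 1)$meta$thickness_um,
               numeric(1))
  expect_true(all(diff(th) > 0))
  expect_error(preset_cohort("day99", 1), "unknown preset")
})

test_that("invalid phantom specifications are rejected", {
  bad_states <- cbind(c(2 + 0i, 0), c(0, 1 + 0i))
  expect_error(
    phantom_spec(grid = c(2, 2, 4), pitch = c(10, 10, 5),
                 layers = list(layer_spec(0, 100, 0.1)),
                 input_states = bad_states),
    "unit-norm")
  expect_error(
    phantom_spec(grid = c(2, 2, 4), pitch = c(10, 10, 5),
                 layers = list(layer_spec(0, 60, 0.1),
                               layer_spec(40, 100, 0.1))),
    "tile")
})
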