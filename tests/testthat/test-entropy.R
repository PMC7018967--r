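test_that("histogram entropy reproduces closed-form cases and the brute-force oracle", {
  expect_equal(angle_entropy(rep(1.234, 500)), 0)
  two <- rep(c(0.1, 0.1 + pi / 256 * 7), each = 64)
  expect_equal(angle_entropy(two), 1)
  centers <- (seq_len(256) - 0.5) * pi / 256
  expect_equal(angle_entropy(centers), 8)
  expect_equal(angle_entropy(rep(centers, 13)), 8)
  # angle exactly pi wraps into the first bin
  expect_equal(angle_entropy(c(0, pi)), 0)

  set.seed(21)
  th <- runif(1e4, 0, pi)
  expect_equal(angle_entropy(th), oracle_entropy(th), tolerance = 1e-12)
  for (n in c(57, 333)) {
    th <- rvonmises_axial(n, mu = 1, kappa = 3)
    expect_equal(angle_entropy(th), oracle_entropy(th), tolerance = 1e-12)
  }
})

test_that("entropy respects the log2(min(n_bins, N)) bound", {
  set.seed(5)
  for (r in 1:20) {
    n <- sample(c(3, 10, 100, 5000), 1)
    nb <- sample(c(8, 64, 256), 1)
    th <- rvonmises_axial(n, runif(1, 0, pi), runif(1, 0, 30))
    H <- angle_entropy(th, nb)
    expect_gte(H, 0)
    expect_lte(H, log2(min(nb, n)) + 1e-12)
  }
})

test_that("von Mises axial sampling concentrates around its mean", {
  set.seed(8)
  th <- rvonmises_axial(4000, mu = 1.1, kappa = 50)
  expect_true(all(th >= 0 & th < pi))
  circ_mean <- atan2(mean(sin(2 * th)), mean(cos(2 * th))) / 2
  expect_lt(abs(circ_mean - 1.1), 0.02)
  expect_lt(sd(th), 0.12)
  flat <- rvonmises(4000, 0, 0)
  expect_gt(min(flat), -1e-9); expect_lt(max(flat), 2 * pi)
  expect_lt(abs(mean(flat > pi) - 0.5), 0.05)
})

test_that("voxel entropy tiles blocks, references the surface, and counts samples", {
  # 20 x 20 x 8 field, 10 um pitch, two 10-px blocks per side
  th <- array(0, c(20, 20, 8))
  th[11:20, , ] <- rep(seq(0, pi - 0.01, length.out = 10), each = 10)
  ang <- angle_field(th, pitch = c(10, 10, 10))
  surf <- surface_map(matrix(1, 20, 20))
  em <- voxel_entropy(ang, surf, block_xy_um = 100, z_window_um = c(0, 40),
                      n_bins = 256, min_count = 16)
  expect_equal(dim(em$entropy), c(2, 2))
  expect_equal(em$n, matrix(400L, 2, 2))
  expect_equal(em$entropy[1, ], c(0, 0))          # constant-angle blocks
  expect_gt(em$entropy[2, 1], 3)                  # 10 distinct angles
  expect_equal(em$entropy[2, 1], oracle_entropy(th[11:20, 1:10, 1:4]))

  # stepped surface: the depth window follows the surface exactly
  zidx <- matrix(1, 20, 20); zidx[, 11:20] <- 3
  th2 <- array(rep(seq_len(8), each = 400) * 0.1, c(20, 20, 8))
  ang2 <- angle_field(th2, pitch = c(10, 10, 10))
  em2 <- voxel_entropy(ang2, surface_map(zidx), block_xy_um = 200,
                       z_window_um = c(10, 30), min_count = 1)
  # depths 10-30 um below surface: slices 2:3 on the left half, 4:5 on the
  # right half -> four equally occupied angle values in the single voxel
  expect_equal(em2$n[1, 1], 800L)
  expect_equal(em2$entropy[1, 1], 2)

  # min_count flags sparse voxels invalid
  sparse <- angle_field(array(runif(400, 0, pi), c(20, 20, 1)),
                        valid = array(c(rep(TRUE, 10), rep(FALSE, 390)),
                                      c(20, 20, 1)),
                        pitch = c(10, 10, 10))
  em3 <- voxel_entropy(sparse, surface_map(matrix(1, 20, 20)),
                       block_xy_um = 200, z_window_um = c(0, 10),
                       min_count = 16)
  expect_false(any(em3$valid))
  expect_error(voxel_entropy(ang, surf, block_xy_um = 100,
                             z_window_um = c(50, 50)), "empty depth window")
  expect_error(voxel_entropy(ang, surf, block_xy_um = 1), "smaller than one")
})

test_that("single-plane mode evaluates one slice per A-line", {
  th <- array(0, c(10, 10, 6))
  th[, , 4] <- 0.7
  ang <- angle_field(th, pitch = c(10, 10, 10))
  em <- voxel_entropy(ang, surface_map(matrix(1, 10, 10)),
                      block_xy_um = 100, plane_z_um = 30, min_count = 1)
  expect_equal(em$mode, "plane")
  expect_equal(em$n[1, 1], 100L)
  expect_equal(em$entropy[1, 1], 0)
})

test_that("edge blocks follow the 50% transverse-area rule", {
  th <- array(runif(25 * 20), c(25, 20, 1)) * pi
  ang <- angle_field(th, pitch = c(10, 10, 10))
  surf <- surface_map(matrix(1, 25, 20))
  em <- voxel_entropy(ang, surf, block_xy_um = 100, z_window_um = c(0, 10),
                      min_count = 1)
  # x: blocks at 1-10, 11-20, 21-25 (50% inside, kept); y: 2 full blocks
  expect_equal(dim(em$entropy), c(3, 2))
  expect_equal(em$n[3, 1], 50L)
})

test_that("organized radial fibrosis scores at least 1 bit below disorganized control", {
  cfg <- analysis_config(best_block_um = NA)
  h <- vapply(c("control", "28"), function(d) {
    tom <- simulate_phantom(preset_cohort(d, seed = 100))
    analyze_sample(tom, cfg)$mean_entropy
  }, numeric(1))
  expect_gte(h["control"] - h["28"], 1)
})

test_that("mean entropy averages valid voxels and honors region masks", {
  em <- structure(list(entropy = matrix(c(0, 8, NA, 4), 2, 2),
                       n = matrix(100L, 2, 2),
                       valid = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)),
                  class = "entropy_map")
  expect_equal(mean_entropy(em), 4)
  expect_equal(mean_entropy(em, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)), 4)
  expect_equal(mean_entropy(em, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)), 0)
  expect_error(mean_entropy(em, matrix(FALSE, 2, 2)), "no valid voxels")
  one <- structure(list(entropy = matrix(5.5), n = matrix(20L),
                        valid = matrix(TRUE)), class = "entropy_map")
  expect_equal(mean_entropy(one), 5.5)
})
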