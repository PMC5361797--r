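test_that("second-moment sigma estimator matches its closed forms", {
  g <- small_geometry(c(16L, 16L), 2L)
  zero <- channel_stack(array(0, c(2, 16, 16)), "fat", 1, g)
  expect_identical(estimate_noise_sigma(zero, array(TRUE, c(2, 16, 16)))$sigma, 0)
  const <- channel_stack(array(4, c(2, 16, 16)), "fat", 1, g)
  expect_equal(estimate_noise_sigma(const, array(TRUE, c(2, 16, 16)))$sigma,
               4 / sqrt(2))
})

test_that("sigma is recovered within 2% from 1e5 zero-signal voxels", {
  sigma <- 5
  st <- noise_stack(sigma, small_geometry(c(64L, 64L), 25L), seed = 12)
  est <- estimate_noise_sigma(st, array(TRUE, dim(st$data)))
  expect_gte(est$n_voxels, 1e5)
  expect_equal(est$sigma, sigma, tolerance = 0.02)
})

test_that("auto background selection uses the slice corners", {
  spec <- small_phantom(sigma = 3, seed = 5L)
  st <- simulate_chess_pair(build_truth_volumes(spec))
  est <- estimate_noise_sigma(st$fat)
  expect_match(est$method, "auto_corners")
  expect_equal(est$sigma, 3, tolerance = 0.10)   # 640 corner voxels
  tiny <- channel_stack(array(0, c(1, 4, 4)), "fat", 1,
                        acq_geometry(c(4, 4), c(4L, 4L), 1L, 1))
  expect_error(estimate_noise_sigma(tiny), "16 voxels")
})

test_that("power subtraction maps the noise floor to zero and is exact above it", {
  g <- acq_geometry(c(1, 1), c(1L, 1L), 3L, 1)
  st <- channel_stack(array(c(0, sqrt(2), 3), c(3, 1, 1)), "fat", 1, g)
  out <- correct_rician_bias(st, noise_estimate(1))
  expect_identical(as.numeric(out$data)[1:2], c(0, 0))
  expect_equal(as.numeric(out$data)[3], sqrt(7), tolerance = 1e-12)
  ident <- correct_rician_bias(st, noise_estimate(0))
  expect_identical(ident$data, st$data)
  expect_true(all(out$data >= 0))
})

test_that("gain normalization divides intensities and resets the gain", {
  g <- small_geometry(c(4L, 4L), 2L)
  st <- channel_stack(array(10, c(2, 4, 4)), "fat", 2, g,
                      noise = noise_estimate(3))
  out <- normalize_receiver_gain(st)
  expect_true(all(out$data == 5))
  expect_identical(out$receiver_gain, 1)
  expect_equal(out$noise$sigma, 1.5)
  unit <- normalize_receiver_gain(channel_stack(array(10, c(2, 4, 4)),
                                                "fat", 1, g))
  expect_true(all(unit$data == 10))
  expect_error(channel_stack(array(1, c(2, 4, 4)), "fat", 0, g),
               "receiver_gain")
})

test_that("channels with gains g and 2g end up in 2:1 ratio", {
  g <- small_geometry(c(4L, 4L), 2L)
  raw <- array(8, c(2, 4, 4))
  fat <- normalize_receiver_gain(channel_stack(raw, "fat", 1.5, g))
  water <- normalize_receiver_gain(channel_stack(raw, "water", 3, g))
  expect_equal(as.numeric(fat$data / water$data), rep(2, length(raw)))
})

test_that("fat fraction follows F / (F + W) on the foreground", {
  st <- value_stacks(c(0, 6, 2), c(8, 0, 6))
  map <- compute_fat_fraction(st$fat, st$water)
  expect_identical(as.numeric(map$values), c(0, 1, 0.25))
  expect_true(all(map$values >= 0 & map$values <= 1))
  expect_true(all(map$mask))
})

test_that("the fw ratio option returns the unbounded fat-to-water ratio", {
  st <- value_stacks(c(2, 6, 0), c(8, 0, 4))
  map <- compute_fat_fraction(st$fat, st$water, ratio = "fw")
  expect_identical(as.numeric(map$values), c(0.25, Inf, 0))
  expect_error(quantify_fat(map), "fraction")
})

test_that("fraction is bounded and masked voxels carry zero, any input", {
  for (seed in 1:5) {
    spec <- small_phantom(sigma = 6, seed = seed)
    st <- simulate_chess_pair(build_truth_volumes(spec))
    fat <- normalize_receiver_gain(
      correct_rician_bias(st$fat, estimate_noise_sigma(st$fat)))
    water <- normalize_receiver_gain(
      correct_rician_bias(st$water, estimate_noise_sigma(st$water)))
    map <- compute_fat_fraction(fat, water)
    expect_true(all(map$values >= 0 & map$values <= 1))
    expect_true(all(map$values[!map$mask] == 0))
  }
})

test_that("geometry and preparation mismatches are rejected", {
  a <- value_stacks(1, 1)
  g2 <- small_geometry(c(4L, 4L), 2L)
  other <- channel_stack(array(1, c(2, 4, 4)), "water", 1, g2)
  expect_error(compute_fat_fraction(a$fat, other), "geometry")
  raw <- channel_stack(array(1, c(1, 1, 1)), "water", 2, a$fat$geometry)
  expect_error(compute_fat_fraction(a$fat, raw), "gain-normalized")
})

test_that("quantify_fat equals a brute-force per-voxel accumulation", {
  spec <- small_phantom(sigma = 4, seed = 9L)
  st <- simulate_chess_pair(build_truth_volumes(spec))
  q <- quantify_pair(st$fat, st$water)
  fat <- normalize_receiver_gain(
    correct_rician_bias(st$fat, estimate_noise_sigma(st$fat)))
  water <- normalize_receiver_gain(
    correct_rician_bias(st$water, estimate_noise_sigma(st$water)))
  map <- compute_fat_fraction(fat, water)
  vv <- voxel_volume(spec$geometry)
  total <- 0
  for (i in seq_along(map$values)) total <- total + map$values[i] * vv
  expect_equal(q$fat_volume_mm3, total)
  expect_equal(q$fat_mass_mg, total * 0.9)
  # uniform map sanity: fraction 1 on N voxels of volume V
  ones <- value_stacks(rep(6, 4), rep(0, 4))
  uq <- quantify_fat(compute_fat_fraction(ones$fat, ones$water), density = 0.9)
  expect_equal(uq$fat_volume_mm3, 4 * voxel_volume(ones$fat$geometry))
  expect_equal(uq$fat_mass_mg, 0.9 * uq$fat_volume_mm3)
  zeros <- value_stacks(rep(0, 4), rep(1, 4))
  zq <- quantify_fat(compute_fat_fraction(zeros$fat, zeros$water))
  expect_identical(zq$fat_volume_mm3, 0)
})

test_that("noise-free unit-gain phantom is recovered exactly", {
  spec <- small_phantom(sigma = 0)
  tv <- build_truth_volumes(spec)
  st <- simulate_chess_pair(tv)
  q <- quantify_pair(st$fat, st$water)
  expect_equal(q$fat_volume_mm3, tv$truth$fat_volume_mm3, tolerance = 1e-12)
  expect_equal(q$fat_mass_mg, tv$truth$fat_mass_mg, tolerance = 1e-12)
})

test_that("quantification is invariant under joint intensity/gain rescaling", {
  spec <- small_phantom(sigma = 4, seed = 13L)
  st <- simulate_chess_pair(build_truth_volumes(spec))
  q1 <- quantify_pair(st$fat, st$water)
  scaled_fat <- channel_stack(st$fat$data * 10, "fat",
                              st$fat$receiver_gain * 10, st$fat$geometry)
  q2 <- quantify_pair(scaled_fat, st$water)
  expect_equal(q2$fat_volume_mm3, q1$fat_volume_mm3, tolerance = 1e-12)
  expect_equal(q2$fat_mass_mg, q1$fat_mass_mg, tolerance = 1e-12)
  scaled_water <- channel_stack(st$water$data * 0.25, "water",
                                st$water$receiver_gain * 0.25,
                                st$water$geometry)
  q3 <- quantify_pair(st$fat, scaled_water)
  expect_equal(q3$fat_mass_mg, q1$fat_mass_mg, tolerance = 1e-12)
})

test_that("the fat-channel noise gate suppresses spurious fat in fat-free phantoms", {
  spec <- small_phantom(depots = list(), lean_fat_fraction = 0, sigma = 5,
                        seed = 17L)
  tv <- build_truth_volumes(spec)   # water-only fish: true fat mass 0
  expect_identical(tv$truth$fat_mass_mg, 0)
  st <- simulate_chess_pair(tv)
  gated <- quantify_pair(st$fat, st$water)
  ungated <- quantify_pair(st$fat, st$water, fat_gate = FALSE)
  fov_volume <- prod(spec$geometry$fov_mm) *
    spec$geometry$n_slices * spec$geometry$slice_thickness_mm
  expect_lt(gated$fat_volume_mm3, 0.01 * fov_volume)
  expect_gt(ungated$fat_volume_mm3, 5 * gated$fat_volume_mm3)
})

test_that("without the gate, residual noise fat shrinks as k grows", {
  st <- list(fat = noise_stack(5, seed = 31, channel = "fat"),
             water = noise_stack(5, seed = 32, channel = "water"))
  masses <- vapply(c(3, 5, 8), function(k)
    quantify_pair(st$fat, st$water, k = k, fat_gate = FALSE)$fat_mass_mg,
    numeric(1))
  expect_true(all(diff(masses) <= 0))
  expect_lt(masses[3], 0.05 * masses[1] + 1e-9)
})
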