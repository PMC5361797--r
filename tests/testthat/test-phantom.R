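test_that("a single full-fat ellipsoid depot yields fat volume N * V", {
  spec <- small_phantom(
    depots = list(depot_ellipsoid("visceral", c(0, 0, 0), c(2, 2, 2),
                                  fat_fraction = 1)),
    lean_fat_fraction = 0)
  tv <- build_truth_volumes(spec)
  n_depot <- sum(tv$truth$fat_fraction == 1)
  expect_gt(n_depot, 0)
  expect_equal(tv$truth$fat_volume_mm3,
               n_depot * voxel_volume(spec$geometry))
})

test_that("zero depots and zero lean fraction give zero fat mass", {
  spec <- small_phantom(depots = list(), lean_fat_fraction = 0)
  tv <- build_truth_volumes(spec)
  expect_identical(tv$truth$fat_volume_mm3, 0)
  expect_identical(tv$truth$fat_mass_mg, 0)
})

test_that("ground-truth totals match brute-force per-voxel summation", {
  spec <- small_phantom()
  tv <- build_truth_volumes(spec)
  vv <- voxel_volume(spec$geometry)
  total <- 0
  for (i in seq_along(tv$truth$fat_fraction))
    total <- total + tv$truth$fat_fraction[i] * vv
  expect_equal(tv$truth$fat_volume_mm3, total)
  expect_equal(tv$truth$fat_mass_mg, total * spec$fat_density_mg_mm3)
  expect_equal(sum(tv$truth$depot_masses_mg), tv$truth$fat_mass_mg)
})

test_that("agarose and air contribute no fat and the right water signal", {
  spec <- small_phantom()
  tv <- build_truth_volumes(spec)
  region <- tv$truth$region
  expect_true(all(tv$fat_signal[region <= 1] == 0))
  expect_true(all(tv$water_signal[region == 1] == spec$agarose_level))
  expect_true(all(tv$water_signal[region == 0] == 0))
  expect_true(all(tv$fat_signal[region >= 2] + tv$water_signal[region >= 2]
                  == spec$signal_scale))
})

test_that("a depot outside the grid is rejected by name", {
  expect_error(
    small_phantom(depots = list(
      depot_ellipsoid("hepatic", c(12, 0, 0), c(2, 1, 1)))),
    "hepatic")
})

test_that("noise-free simulation with unit gains is the identity", {
  spec <- small_phantom(sigma = 0)
  tv <- build_truth_volumes(spec)
  st <- simulate_chess_pair(tv)
  expect_identical(as.numeric(st$fat$data), as.numeric(tv$fat_signal))
  expect_identical(as.numeric(st$water$data), as.numeric(tv$water_signal))
})

test_that("receiver gains scale the noise-free magnitude linearly", {
  spec <- small_phantom(sigma = 0, receiver_gain = c(fat = 4, water = 0.5))
  tv <- build_truth_volumes(spec)
  st <- simulate_chess_pair(tv)
  expect_equal(as.numeric(st$fat$data), as.numeric(tv$fat_signal) * 4)
  expect_equal(as.numeric(st$water$data), as.numeric(tv$water_signal) * 0.5)
})

test_that("identical spec and seed give bit-identical stacks", {
  spec <- small_phantom(sigma = 4, seed = 7L)
  tv <- build_truth_volumes(spec)
  a <- simulate_chess_pair(tv)
  b <- simulate_chess_pair(tv)
  expect_identical(a$fat$data, b$fat$data)
  expect_identical(a$water$data, b$water$data)
  c <- simulate_chess_pair(tv, seed = 8L)
  expect_false(identical(a$fat$data, c$fat$data))
})

test_that("signal-free background follows Rician zero-signal statistics", {
  sigma <- 5
  spec <- small_phantom(geometry = small_geometry(c(64L, 64L), 30L),
                        sigma = sigma, seed = 3L)
  tv <- build_truth_volumes(spec)
  st <- simulate_chess_pair(tv)
  air <- tv$truth$region == 0
  vals <- st$fat$data[air]
  n <- length(vals)
  expect_gte(n, 1e4)
  se_mean <- sigma * sqrt(2 - pi / 2) / sqrt(n)
  expect_lt(abs(mean(vals) - sigma * sqrt(pi / 2)), 3 * se_mean)
  se_m2 <- 2 * sigma^2 / sqrt(n)
  expect_lt(abs(mean(vals^2) - 2 * sigma^2), 3 * se_m2)
})

test_that("reference readout honours its noise contract", {
  expect_identical(simulate_reference_fat_mass(100, cv = 0, seed = 5), 100)
  expect_identical(simulate_reference_fat_mass(0, cv = 0.02, seed = 5), 0)
  expect_error(simulate_reference_fat_mass(-1, 0.02, 1), "true_mass_mg")
  expect_identical(simulate_reference_fat_mass(50, 0.02, seed = 9),
                   simulate_reference_fat_mass(50, 0.02, seed = 9))
  reps <- vapply(1:10000, function(s)
    simulate_reference_fat_mass(200, cv = 0.02, seed = s), numeric(1))
  expect_equal(sd(reps) / mean(reps), 0.02, tolerance = 0.05)
})

test_that("cohort masses increase monotonically across the stated range", {
  spec <- small_phantom()
  base_mass <- build_truth_volumes(spec)$truth$fat_mass_mg
  rng <- c(0.3, 1.1) * base_mass
  specs <- cohort_specs(4, rng, spec)
  masses <- vapply(specs, function(s) s$truth_volumes$truth$fat_mass_mg,
                   numeric(1))
  expect_true(all(diff(masses) > 0))
  expect_equal(masses[1], rng[1], tolerance = 0.05)
  expect_equal(masses[4], rng[2], tolerance = 0.05)

  two <- cohort_specs(2, rng, spec)
  m2 <- vapply(two, function(s) s$truth_volumes$truth$fat_mass_mg, numeric(1))
  expect_equal(m2, rng, tolerance = 0.05)
})

test_that("each cohort member's ground truth is self-consistent", {
  spec <- small_phantom()
  base_mass <- build_truth_volumes(spec)$truth$fat_mass_mg
  cohort <- make_cohort(3, c(0.4, 1) * base_mass, spec, seed = 2L)
  for (m in cohort) {
    vv <- voxel_volume(m$spec$geometry)
    expect_equal(m$truth$fat_volume_mm3, sum(m$truth$fat_fraction) * vv)
    expect_equal(sum(m$truth$depot_masses_mg), m$truth$fat_mass_mg)
  }
  again <- make_cohort(3, c(0.4, 1) * base_mass, spec, seed = 2L)
  expect_identical(cohort[[2]]$stacks$fat$data, again[[2]]$stacks$fat$data)
  expect_identical(cohort[[2]]$reference_mass_mg, again[[2]]$reference_mass_mg)
})

test_that("degenerate mass ranges and tiny cohorts are rejected", {
  spec <- small_phantom()
  expect_error(cohort_specs(4, c(100, 100), spec), "degenerate")
  expect_error(cohort_specs(4, c(120, 80), spec), "degenerate")
  expect_error(cohort_specs(1, c(50, 100), spec), "at least 2")
})

test_that("phantom spec JSON round-trips", {
  spec <- small_phantom(sigma = 2.5, seed = 21L,
                        receiver_gain = c(fat = 1.5, water = 2))
  path <- tempfile(fileext = ".json")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(unclass(back), unclass(spec))
  tv_a <- build_truth_volumes(spec)
  tv_b <- build_truth_volumes(back)
  expect_identical(tv_a$truth$fat_mass_mg, tv_b$truth$fat_mass_mg)
})
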