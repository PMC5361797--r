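# Small, fast phantom configurations for unit tests. The full printed
# protocol (128 x 128 x 50) is exercised in test-acceptance.R.

small_geometry <- function(matrix = c(32L, 32L), n_slices = 10L)
  acq_geometry(fov_mm = c(16, 16), matrix = matrix, n_slices = n_slices,
               slice_thickness_mm = 1)

small_phantom <- function(...) {
  args <- list(...)
  if (is.null(args$geometry)) args$geometry <- small_geometry()
  if (is.null(args$body_semi_axes)) args$body_semi_axes <- c(4, 3.2, 4)
  if (is.null(args$depots))
    args$depots <- list(
      depot_shell("subcutaneous", inner_scale = 0.85, fat_fraction = 0.9,
                  z_extent = 0.8),
      depot_ellipsoid("visceral", center = c(0, -0.6, 0),
                      semi_axes = c(1.8, 1.3, 2), fat_fraction = 0.9))
  do.call(phantom_spec, args)
}

# A stack of pure Rician background (zero underlying signal).
noise_stack <- function(sigma, geometry = small_geometry(), channel = "fat",
                        seed = 1) {
  dm <- c(geometry$n_slices, geometry$matrix[2], geometry$matrix[1])
  n <- prod(dm)
  data <- zebrafat:::with_seed(seed,
    sqrt(rnorm(n, 0, sigma)^2 + rnorm(n, 0, sigma)^2))
  dim(data) <- dm
  channel_stack(data, channel, receiver_gain = 1, geometry = geometry)
}

# Gain-normalized, noise-free stacks holding given per-voxel values.
value_stacks <- function(fat_values, water_values) {
  n <- length(fat_values)
  g <- acq_geometry(fov_mm = c(1, 1), matrix = c(1L, 1L), n_slices = n,
                    slice_thickness_mm = 1)
  list(fat = channel_stack(array(fat_values, c(n, 1, 1)), "fat", 1, g),
       water = channel_stack(array(water_values, c(n, 1, 1)), "water", 1, g))
}

# Integer-rounded trace of a circle of radius r px at ~1 px arc steps.
traced_circle <- function(r) {
  theta <- seq(0, 2 * pi, length.out = ceiling(2 * pi * r) + 1)
  theta <- theta[-length(theta)]
  v <- round(r * cbind(x = cos(theta), y = sin(theta)))
  v[c(TRUE, rowSums(abs(diff(v))) > 0), , drop = FALSE]
}
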