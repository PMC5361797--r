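#' Background noise estimate of a magnitude stack
#'
#' @param sigma estimated Rician noise sigma (intensity units, >= 0).
#' @param method estimation method tag.
#' @param n_voxels number of background voxels used (> 0).
#' @return A `noise_estimate` object.
#' @export
noise_estimate <- function(sigma, method = "second_moment", n_voxels = 1L) {
  check_scalar_number(sigma, "sigma", min = 0)
  check_scalar_number(n_voxels, "n_voxels", min = 0, strict = TRUE)
  structure(list(sigma = sigma, method = method,
                 n_voxels = as.integer(n_voxels)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma_hat = %.6g (%s, %d background voxels)\n",
              x$sigma, x$method, x$n_voxels))
  invisible(x)
}

#' Estimate the Rician noise level from signal-free background
#'
#' At zero underlying signal a magnitude voxel is Rayleigh distributed with
#' second moment `2 * sigma^2`, so `sigma` is estimated as
#' `sqrt(mean(M^2) / 2)` over background voxels. With `background = "auto"`
#' the four in-plane corner blocks of every slice are used (signal-free air
#' outside the agarose tube).
#'
#' @param stack a [channel_stack()].
#' @param background `"auto"`, or a logical array of the stack's dimensions
#'   selecting at least 100 background voxels.
#' @param corner_fraction with `"auto"`, the corner block edge as a fraction
#'   of the smaller in-plane matrix dimension.
#' @return A [noise_estimate()].
#' @export
estimate_noise_sigma <- function(stack, background = "auto",
                                 corner_fraction = 0.1) {
  stopifnot(inherits(stack, "channel_stack"))
  if (identical(background, "auto")) {
    dm <- dim(stack$data)
    m <- max(4L, floor(corner_fraction * min(dm[2], dm[3])))
    rows <- unique(c(seq_len(m), dm[2] - seq_len(m) + 1L))
    cols <- unique(c(seq_len(m), dm[3] - seq_len(m) + 1L))
    vals <- stack$data[, rows, cols]
    method <- sprintf("second_moment/auto_corners(%d px)", m)
  } else {
    if (!is.logical(background) || !all(dim(background) == dim(stack$data)))
      stopf("'background' must be \"auto\" or a logical array matching the stack")
    vals <- stack$data[background]
    method <- "second_moment/mask"
  }
  if (length(vals) < 100L)
    stopf("background selection has only %d voxels (>= 100 required)",
          length(vals))
  noise_estimate(sqrt(mean(vals^2) / 2), method = method,
                 n_voxels = length(vals))
}

#' Remove the Rician noise floor from a magnitude stack
#'
#' Power-subtraction de-biasing: each voxel `M` becomes
#' `sqrt(max(M^2 - 2 * sigma^2, 0))`, using `E[M^2] = A^2 + 2 * sigma^2` for
#' a Rician magnitude of true amplitude `A`. Output is non-negative and the
#' operation is the identity at `sigma = 0`. The noise estimate is attached
#' to the returned stack for the downstream foreground threshold.
#'
#' @param stack a [channel_stack()].
#' @param noise a [noise_estimate()], or a plain sigma value.
#' @return The corrected [channel_stack()].
#' @export
correct_rician_bias <- function(stack, noise) {
  stopifnot(inherits(stack, "channel_stack"))
  if (is.numeric(noise)) noise <- noise_estimate(noise, method = "given")
  stopifnot(inherits(noise, "noise_estimate"))
  # factored form of sqrt(M^2 - 2 sigma^2): maps M == sigma * sqrt(2),
  # the subtraction boundary, to exactly 0 in floating point
  floor_level <- noise$sigma * sqrt(2)
  corrected <- sqrt(pmax((stack$data - floor_level) *
                         (stack$data + floor_level), 0))
  update_stack(stack, corrected, noise = noise)
}

#' Normalize intensities by the receiver gain
#'
#' Divides every voxel by the channel's receiver gain so the two CHESS
#' channels become comparable; the recorded gain becomes 1 and any attached
#' noise sigma is rescaled accordingly.
#'
#' @param stack a [channel_stack()].
#' @return The gain-normalized [channel_stack()].
#' @export
normalize_receiver_gain <- function(stack) {
  stopifnot(inherits(stack, "channel_stack"))
  g <- stack$receiver_gain
  if (g <= 0) stopf("receiver gain must be > 0, got %g", g)
  noise <- stack$noise
  if (!is.null(noise)) noise$sigma <- noise$sigma / g
  update_stack(stack, stack$data / g, receiver_gain = 1, noise = noise,
               sigma_truth = if (!is.null(stack$sigma_truth))
                 stack$sigma_truth / g else NULL)
}

#' Per-voxel fat signal fraction map
#'
#' On bias-corrected, gain-normalized stacks, foreground voxels are those
#' whose total signal `F + W` exceeds `k` times the larger channel noise
#' sigma; on the foreground the fat fraction is `F / (F + W)` (bounded in
#' \[0, 1\]) and elsewhere 0. By default, voxels whose fat-channel signal is
#' itself below `k * sigma_fat` — i.e. indistinguishable from rectified
#' noise — carry fraction 0 as well (`fat_gate`): without this gate the
#' residual noise floor of the fat channel accumulates, over the large
#' water-only agarose compartment and threshold-passing air, into a
#' substantial spurious fat volume. Set `fat_gate = FALSE` for the plain
#' thresholded ratio. `ratio = "fw"` returns the unbounded classical
#' fat-to-water ratio `F / W` instead (not usable for volume quantification).
#'
#' @param fat,water bias-corrected, gain-normalized [channel_stack()]s of
#'   identical geometry. Channel noise sigmas are taken from the attached
#'   [noise_estimate()]s (0 when absent).
#' @param k foreground threshold multiplier.
#' @param ratio `"fraction"` for `F / (F + W)`, `"fw"` for `F / W`.
#' @param fat_gate zero the fraction where the fat channel is below its own
#'   noise floor.
#' @return A `fat_fraction_map`: `values` array, logical foreground `mask`,
#'   `geometry`, and the threshold settings used.
#' @export
compute_fat_fraction <- function(fat, water, k = 3, ratio = c("fraction", "fw"),
                                 fat_gate = TRUE) {
  ratio <- match.arg(ratio)
  stopifnot(inherits(fat, "channel_stack"), inherits(water, "channel_stack"))
  if (fat$channel != "fat" || water$channel != "water")
    stopf("arguments must be the fat and the water channel, in that order")
  if (!same_geometry(fat$geometry, water$geometry))
    stopf("fat and water stacks have mismatching geometry")
  if (fat$receiver_gain != 1 || water$receiver_gain != 1)
    stopf("stacks must be gain-normalized first (see normalize_receiver_gain)")
  check_scalar_number(k, "k", min = 0)
  sf <- if (!is.null(fat$noise)) fat$noise$sigma else 0
  sw <- if (!is.null(water$noise)) water$noise$sigma else 0
  F <- fat$data; W <- water$data
  total <- F + W
  mask <- total > k * max(sf, sw)
  values <- array(0, dim(F))
  if (ratio == "fraction") {
    values[mask] <- F[mask] / total[mask]
    if (fat_gate) values[F <= k * sf] <- 0
  } else {
    vals <- rep(NA_real_, length(F))
    ok <- mask & W > 0
    vals[ok] <- F[ok] / W[ok]
    vals[mask & W == 0] <- Inf
    vals[!mask] <- 0
    values <- array(vals, dim(F))
  }
  structure(list(values = values, mask = mask, geometry = fat$geometry,
                 ratio = ratio, k = k, fat_gate = fat_gate,
                 sigma_fat = sf, sigma_water = sw),
            class = "fat_fraction_map")
}

#' @export
print.fat_fraction_map <- function(x, ...) {
  cat(sprintf("<fat_fraction_map> (%s) %d foreground voxels, k = %g, sigma_fat %.4g / sigma_water %.4g\n",
              x$ratio, sum(x$mask), x$k, x$sigma_fat, x$sigma_water))
  invisible(x)
}

#' Total fat volume and mass from a fat fraction map
#'
#' Fat volume is the sum over foreground voxels of fat fraction times voxel
#' volume; fat mass is volume times the assumed fat density.
#'
#' @param map a `"fraction"`-type [compute_fat_fraction()] map.
#' @param density assumed fat (triglyceride) density in mg/mm^3.
#' @param noise optional list of per-channel [noise_estimate()]s to record.
#' @return A `fat_quantification`: `fat_volume_mm3`, `fat_mass_mg`,
#'   `density_mg_mm3`, `n_foreground`, `noise`.
#' @export
quantify_fat <- function(map, density = 0.9, noise = NULL) {
  stopifnot(inherits(map, "fat_fraction_map"))
  if (map$ratio != "fraction")
    stopf("volume quantification requires a bounded fat fraction map (ratio = \"fraction\")")
  check_scalar_number(density, "density", min = 0, strict = TRUE)
  volume <- sum(map$values) * voxel_volume(map$geometry)
  structure(list(fat_volume_mm3 = volume,
                 fat_mass_mg = volume * density,
                 density_mg_mm3 = density,
                 n_foreground = sum(map$mask),
                 noise = noise,
                 k = map$k, fat_gate = map$fat_gate),
            class = "fat_quantification")
}

#' @export
print.fat_quantification <- function(x, ...) {
  cat(sprintf("<fat_quantification> fat volume %.2f mm^3, fat mass %.2f mg (density %g mg/mm^3)\n",
              x$fat_volume_mm3, x$fat_mass_mg, x$density_mg_mm3))
  cat(sprintf("  foreground %d voxels, k = %g, fat gate %s\n",
              x$n_foreground, x$k, x$fat_gate))
  if (!is.null(x$noise))
    cat(sprintf("  sigma_hat: fat %.5g (%d voxels), water %.5g (%d voxels)\n",
                x$noise$fat$sigma, x$noise$fat$n_voxels,
                x$noise$water$sigma, x$noise$water$n_voxels))
  invisible(x)
}

#' Full fat/water quantification pipeline
#'
#' The complete processing chain for one acquisition: per-channel background
#' noise estimation, Rician bias correction and receiver-gain normalization,
#' then the per-voxel fat fraction and the total fat volume and mass.
#'
#' @param fat,water raw [channel_stack()]s with receiver-gain metadata.
#' @param density assumed fat density, mg/mm^3.
#' @param k foreground threshold multiplier.
#' @param background passed to [estimate_noise_sigma()].
#' @param ratio,fat_gate passed to [compute_fat_fraction()].
#' @return A `fat_quantification` including both channels' noise estimates.
#' @export
quantify_pair <- function(fat, water, density = 0.9, k = 3,
                          background = "auto", ratio = "fraction",
                          fat_gate = TRUE) {
  prep <- function(stack) {
    ns <- estimate_noise_sigma(stack, background = background)
    normalize_receiver_gain(correct_rician_bias(stack, ns))
  }
  fat_n <- prep(fat)
  water_n <- prep(water)
  map <- compute_fat_fraction(fat_n, water_n, k = k, ratio = ratio,
                              fat_gate = fat_gate)
  quantify_fat(map, density = density,
               noise = list(fat = fat_n$noise, water = water_n$noise))
}
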