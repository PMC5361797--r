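#' A single-channel magnitude image stack
#'
#' One CHESS channel (fat-selective or water-selective) as a 3-D array of
#' non-negative magnitude intensities in arbitrary scanner units, together
#' with the receiver gain it was acquired at and its acquisition geometry.
#' Array layout is (slice, row, column); the slice index is the first axis.
#'
#' @param data 3-D numeric array, dimensions (n_slices, ny, nx), values >= 0.
#' @param channel `"fat"` or `"water"`.
#' @param receiver_gain positive scanner amplification factor.
#' @param geometry an [acq_geometry()].
#' @param seed optional integer recorded for provenance.
#' @param sigma_truth optional true simulation noise sigma, for provenance.
#' @param noise optional [noise_estimate()] attached by
#'   [correct_rician_bias()].
#'
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(data, channel = c("fat", "water"), receiver_gain = 1,
                          geometry, seed = NULL, sigma_truth = NULL,
                          noise = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(geometry, "acq_geometry"))
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3-D array (slices, rows, columns)")
  expected <- stack_dim(geometry)
  if (!all(dim(data) == expected))
    stopf("stack dimensions (%s) do not match geometry (%s)",
          paste(dim(data), collapse = " x "),
          paste(expected, collapse = " x "))
  if (any(!is.finite(data)) || any(data < 0))
    stopf("magnitude intensities must be finite and non-negative")
  check_scalar_number(receiver_gain, "receiver_gain", min = 0, strict = TRUE)
  structure(
    list(data = data, channel = channel, receiver_gain = receiver_gain,
         geometry = geometry, seed = seed, sigma_truth = sigma_truth,
         noise = noise),
    class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %s channel, %s voxels, receiver gain %g\n",
              x$channel, paste(dim(x$data), collapse = " x "),
              x$receiver_gain))
  cat(sprintf("  intensity range [%g, %g]%s\n", min(x$data), max(x$data),
              if (!is.null(x$noise)) sprintf(", sigma_hat %.4g", x$noise$sigma) else ""))
  invisible(x)
}

# Replace the data array, keeping metadata.
update_stack <- function(stack, data, receiver_gain = stack$receiver_gain,
                         noise = stack$noise, sigma_truth = stack$sigma_truth) {
  channel_stack(data, channel = stack$channel, receiver_gain = receiver_gain,
                geometry = stack$geometry, seed = stack$seed,
                sigma_truth = sigma_truth, noise = noise)
}
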