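SIDECAR_KEYS <- c("channel", "fov_mm", "matrix", "n_slices",
                  "slice_thickness_mm", "receiver_gain", "seed", "sigma_truth")

sidecar_path_for <- function(path) {
  sub("\\.(nii\\.gz|nii|tiff|tif)$", ".json", path)
}

stack_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.tiff?$", path)) "tiff"
  else stopf("unsupported stack extension in '%s' (use .nii, .nii.gz, .tif or .tiff)", path)
}

#' Write a channel stack with its metadata sidecar
#'
#' Writes the magnitude array as NIfTI (`.nii`/`.nii.gz`, 64-bit float,
#' lossless) or multi-page TIFF (`.tif`/`.tiff`, one 32-bit float page per
#' axial slice), plus a JSON sidecar holding the acquisition metadata.
#' The TIFF container stores samples in \[0,1\], so TIFF intensities are
#' divided by a power-of-two scale (exact in binary floating point) recorded
#' in the sidecar as `tiff_intensity_scale`; round-trip fidelity on the TIFF
#' path is limited to the 32-bit sample quantization (2^-32 of the scale),
#' while NIfTI round-trips bit-exactly.
#'
#' @param stack a [channel_stack()].
#' @param path output image path; the format is selected by extension.
#' @param sidecar sidecar path; defaults to `path` with a `.json` extension.
#' @return Invisibly, a character vector of the files written.
#' @export
write_stack <- function(stack, path, sidecar = sidecar_path_for(path)) {
  stopifnot(inherits(stack, "channel_stack"))
  fmt <- stack_format(path)
  g <- stack$geometry
  meta <- list(channel = stack$channel,
               fov_mm = g$fov_mm,
               matrix = g$matrix,
               n_slices = g$n_slices,
               slice_thickness_mm = g$slice_thickness_mm,
               receiver_gain = stack$receiver_gain,
               seed = stack$seed,
               sigma_truth = stack$sigma_truth)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(stack$data, datatype = "double")
    RNifti::writeNifti(img, path)
  } else {
    mx <- max(stack$data)
    scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
    pages <- lapply(seq_len(dim(stack$data)[1]),
                    function(s) stack$data[s, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    meta$tiff_intensity_scale <- scale
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(path, sidecar))
}

#' Read a channel stack written by [write_stack()]
#'
#' @param path image path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param sidecar sidecar path; defaults to `path` with a `.json` extension.
#' @return A [channel_stack()].
#' @export
read_stack <- function(path, sidecar = sidecar_path_for(path)) {
  fmt <- stack_format(path)
  if (!file.exists(path)) stopf("stack file '%s' does not exist", path)
  if (!file.exists(sidecar)) stopf("sidecar file '%s' does not exist", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(SIDECAR_KEYS, names(meta))
  if (length(missing))
    stopf("sidecar '%s' is missing required key(s): %s",
          sidecar, paste(missing, collapse = ", "))
  geometry <- acq_geometry(fov_mm = meta$fov_mm, matrix = meta$matrix,
                           n_slices = meta$n_slices,
                           slice_thickness_mm = meta$slice_thickness_mm)
  if (fmt == "nifti") {
    data <- as.array(RNifti::readNifti(path))
    attributes(data) <- list(dim = dim(data))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    scale <- meta$tiff_intensity_scale %||% 1
    data <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (s in seq_along(pages)) data[s, , ] <- pages[[s]] * scale
  }
  if (!all(dim(data) == stack_dim(geometry)))
    stopf("image dimensions (%s) do not match sidecar geometry (%s)",
          paste(dim(data), collapse = " x "),
          paste(stack_dim(geometry), collapse = " x "))
  channel_stack(data, channel = meta$channel,
                receiver_gain = meta$receiver_gain, geometry = geometry,
                seed = meta$seed, sigma_truth = meta$sigma_truth)
}
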