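#' Fat depot primitives for the digital fish phantom
#'
#' A depot is either an ellipsoid in scanner coordinates (mm) or a shell
#' sector just under the body surface, defined relative to the body
#' ellipsoid: the region between `inner_scale` times the body surface and the
#' surface itself, restricted to an axial angular sector and to a fraction of
#' the body length.
#'
#' @param label one of `"subcutaneous"`, `"visceral"`, `"hepatic"`,
#'   `"intramuscular"`.
#' @param center ellipsoid centre (x, y, z) in mm.
#' @param semi_axes ellipsoid semi-axes (a, b, c) in mm.
#' @param fat_fraction true fat signal fraction of the depot tissue, in
#'   \[0, 1\].
#' @param inner_scale inner boundary of the shell as a fraction of the body
#'   surface, in \[0, 1).
#' @param z_extent axial extent of the shell as a fraction of the body
#'   z semi-axis.
#' @param angles_deg angular sector (degrees, measured from the +x axis in
#'   the axial plane) the shell is restricted to.
#' @return A `phantom_depot` object.
#' @export
depot_ellipsoid <- function(label, center, semi_axes, fat_fraction = 0.9) {
  label <- match.arg(label, DEPOT_LABELS)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stopf("depot '%s': semi-axes must be positive", label)
  check_fraction(fat_fraction, sprintf("depot '%s' fat_fraction", label))
  structure(list(label = label, shape = "ellipsoid",
                 center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 fat_fraction = fat_fraction),
            class = "phantom_depot")
}

DEPOT_LABELS <- c("subcutaneous", "visceral", "hepatic", "intramuscular")

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stopf("%s must be in [0, 1]", name)
  invisible(x)
}

#' @rdname depot_ellipsoid
#' @export
depot_shell <- function(label, inner_scale = 0.9, fat_fraction = 0.9,
                        z_extent = 0.8, angles_deg = c(0, 360)) {
  label <- match.arg(label, DEPOT_LABELS)
  if (!is.finite(inner_scale) || inner_scale < 0 || inner_scale >= 1)
    stopf("depot '%s': inner_scale must be in [0, 1)", label)
  check_fraction(fat_fraction, sprintf("depot '%s' fat_fraction", label))
  if (!is.finite(z_extent) || z_extent <= 0 || z_extent > 1)
    stopf("depot '%s': z_extent must be in (0, 1]", label)
  stopifnot(length(angles_deg) == 2L)
  structure(list(label = label, shape = "shell", inner_scale = inner_scale,
                 z_extent = z_extent, angles_deg = as.numeric(angles_deg),
                 fat_fraction = fat_fraction),
            class = "phantom_depot")
}

#' Specification of a synthetic fish-in-agarose CHESS phantom
#'
#' Describes a digital phantom emulating an adult zebrafish fixed in an
#' agarose-filled tube and imaged with a fat/water CHESS protocol: the body
#' ellipsoid, a set of fat depots with known fat fractions, the lean-tissue
#' fat fraction, the agarose water signal, per-channel receiver gains and the
#' Rician noise level. Signal is modelled directly at the magnitude-image
#' level: a voxel of fat fraction `ff` emits `ff * signal_scale` in the fat
#' channel and `(1 - ff) * signal_scale` in the water channel; agarose emits
#' water signal only; voxels outside the tube emit nothing.
#'
#' @param geometry an [acq_geometry()].
#' @param body_center,body_semi_axes body ellipsoid centre and semi-axes (mm).
#' @param tube_radius_mm radius of the agarose tube (mm), centred on the body
#'   axis.
#' @param depots list of [depot_ellipsoid()] / [depot_shell()] objects;
#'   depots later in the list take precedence where they overlap.
#' @param lean_fat_fraction fat fraction of non-depot body tissue.
#' @param signal_scale noise-free signal of a unit-fraction voxel (arbitrary
#'   scanner units).
#' @param agarose_level water-channel signal of the agarose compartment.
#' @param receiver_gain named numeric, receiver gains of the `fat` and
#'   `water` channels (both > 0).
#' @param sigma Rician noise level (Gaussian sd per quadrature channel, same
#'   units as the noise-free signal).
#' @param seed integer seed used by the simulator.
#' @param fat_density_mg_mm3 fat (triglyceride) density used to convert true
#'   fat volume to mass.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(geometry = acq_geometry(),
                         body_center = c(0, 0, 0),
                         body_semi_axes = c(4, 3.2, 11),
                         tube_radius_mm = 5.5,
                         depots = list(),
                         lean_fat_fraction = 0.05,
                         signal_scale = 100,
                         agarose_level = 100,
                         receiver_gain = c(fat = 1, water = 1),
                         sigma = 5,
                         seed = 1L,
                         fat_density_mg_mm3 = 0.9) {
  stopifnot(inherits(geometry, "acq_geometry"),
            length(body_center) == 3L, length(body_semi_axes) == 3L)
  if (any(body_semi_axes <= 0)) stopf("body semi-axes must be positive")
  check_scalar_number(tube_radius_mm, "tube_radius_mm", min = 0, strict = TRUE)
  check_fraction(lean_fat_fraction, "lean_fat_fraction")
  check_scalar_number(signal_scale, "signal_scale", min = 0, strict = TRUE)
  check_scalar_number(agarose_level, "agarose_level", min = 0)
  if (!all(c("fat", "water") %in% names(receiver_gain)))
    stopf("receiver_gain must be a named vector with 'fat' and 'water' entries")
  if (any(receiver_gain[c("fat", "water")] <= 0))
    stopf("receiver gains must be > 0")
  check_scalar_number(sigma, "sigma", min = 0)
  check_scalar_number(fat_density_mg_mm3, "fat_density_mg_mm3", min = 0,
                      strict = TRUE)
  for (d in depots)
    if (!inherits(d, "phantom_depot")) stopf("'depots' must be phantom_depot objects")
  spec <- structure(
    list(geometry = geometry, body_center = as.numeric(body_center),
         body_semi_axes = as.numeric(body_semi_axes),
         tube_radius_mm = tube_radius_mm, depots = depots,
         lean_fat_fraction = lean_fat_fraction, signal_scale = signal_scale,
         agarose_level = agarose_level,
         receiver_gain = receiver_gain[c("fat", "water")],
         sigma = sigma, seed = as.integer(seed),
         fat_density_mg_mm3 = fat_density_mg_mm3),
    class = "phantom_spec")
  check_depots_in_grid(spec)
  spec
}

check_depots_in_grid <- function(spec) {
  g <- spec$geometry
  lo <- c(-g$fov_mm[1] / 2, -g$fov_mm[2] / 2,
          -g$n_slices * g$slice_thickness_mm / 2)
  hi <- -lo
  for (i in seq_along(spec$depots)) {
    d <- spec$depots[[i]]
    box <- if (d$shape == "ellipsoid") {
      rbind(d$center - d$semi_axes, d$center + d$semi_axes)
    } else {
      rbind(spec$body_center - spec$body_semi_axes,
            spec$body_center + spec$body_semi_axes)
    }
    if (any(box[1, ] < lo) || any(box[2, ] > hi))
      stopf("depot %d ('%s') extends outside the acquisition grid", i, d$label)
  }
  invisible(spec)
}

#' Default obese-zebrafish phantom
#'
#' An obese adult zebrafish (~0.6 g body, body fat around 27%): a visceral
#' ellipsoid depot plus a subcutaneous shell over the trunk, fat fraction
#' 0.90 in both, lean tissue at 0.05, imaged with the printed small-animal
#' protocol (16 x 16 mm FOV, 128 x 128 matrix, 50 x 0.5 mm slices) at peak
#' signal-to-noise 20.
#'
#' @param ... overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
default_phantom <- function(...) {
  args <- list(...)
  if (is.null(args$depots))
    args$depots <- list(
      depot_shell("subcutaneous", inner_scale = 0.90, fat_fraction = 0.9,
                  z_extent = 0.8),
      depot_ellipsoid("visceral", center = c(0, -0.6, -1),
                      semi_axes = c(2, 1.5, 5), fat_fraction = 0.9))
  do.call(phantom_spec, args)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> body %s mm, tube r %g mm, %d depot(s), lean ff %g\n",
              paste(x$body_semi_axes, collapse = " x "), x$tube_radius_mm,
              length(x$depots), x$lean_fat_fraction))
  cat(sprintf("  gains fat %g / water %g, sigma %g, seed %d\n",
              x$receiver_gain[["fat"]], x$receiver_gain[["water"]],
              x$sigma, x$seed))
  invisible(x)
}

# Per-voxel region labels: 0 air, 1 agarose, 2 lean body, 2 + i depot i.
phantom_regions <- function(spec) {
  g <- spec$geometry
  co <- voxel_coords(g)
  bc <- spec$body_center; ba <- spec$body_semi_axes
  tube <- (co$x - bc[1])^2 + (co$y - bc[2])^2 <= spec$tube_radius_mm^2
  rn2 <- ((co$x - bc[1]) / ba[1])^2 + ((co$y - bc[2]) / ba[2])^2 +
    ((co$z - bc[3]) / ba[3])^2
  body <- rn2 <= 1
  region <- integer(length(co$x))
  region[tube] <- 1L
  region[body] <- 2L
  for (i in seq_along(spec$depots)) {
    d <- spec$depots[[i]]
    inside <- if (d$shape == "ellipsoid") {
      ((co$x - d$center[1]) / d$semi_axes[1])^2 +
        ((co$y - d$center[2]) / d$semi_axes[2])^2 +
        ((co$z - d$center[3]) / d$semi_axes[3])^2 <= 1
    } else {
      rn <- sqrt(rn2)
      ang <- (atan2(co$y - bc[2], co$x - bc[1]) * 180 / pi) %% 360
      a0 <- d$angles_deg[1] %% 360; a1 <- d$angles_deg[2]
      in_sector <- if (diff(d$angles_deg) >= 360) rep(TRUE, length(ang))
      else if (a1 %% 360 >= a0) ang >= a0 & ang <= (a1 %% 360)
      else ang >= a0 | ang <= (a1 %% 360)
      rn >= d$inner_scale & rn <= 1 &
        abs(co$z - bc[3]) <= d$z_extent * ba[3] & in_sector
    }
    region[body & inside] <- 2L + i
  }
  dim(region) <- stack_dim(g)
  region
}

#' Noise-free phantom signal volumes and their ground truth
#'
#' Evaluates the phantom on the acquisition grid: per-voxel true fat
#' fraction, noise-free fat- and water-channel signal volumes (before
#' receiver gain and noise), and the resulting ground-truth fat volume and
#' mass totals.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_truth` object: `fat_signal` and `water_signal` arrays,
#'   `truth` (a `ground_truth` with `fat_fraction` array, `fat_volume_mm3`,
#'   `fat_mass_mg`, per-depot masses and the region label array), and the
#'   originating `spec`.
#' @export
build_truth_volumes <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_depots_in_grid(spec)
  region <- phantom_regions(spec)
  ff <- numeric(length(region))
  ff[region == 2L] <- spec$lean_fat_fraction
  for (i in seq_along(spec$depots))
    ff[region == 2L + i] <- spec$depots[[i]]$fat_fraction

  in_body <- region >= 2L
  fat_sig <- water_sig <- numeric(length(region))
  fat_sig[in_body] <- ff[in_body] * spec$signal_scale
  water_sig[in_body] <- (1 - ff[in_body]) * spec$signal_scale
  water_sig[region == 1L] <- spec$agarose_level

  vv <- voxel_volume(spec$geometry)
  fat_volume <- sum(ff) * vv
  density <- spec$fat_density_mg_mm3
  labels <- make.unique(c("lean", vapply(spec$depots, `[[`, "", "label")),
                        sep = "_")
  depot_masses <- vapply(seq_along(labels), function(i)
    sum(ff[region == 1L + i]) * vv * density, numeric(1))
  names(depot_masses) <- labels

  dm <- stack_dim(spec$geometry)
  dim(ff) <- dim(fat_sig) <- dim(water_sig) <- dm
  truth <- structure(
    list(fat_fraction = ff, fat_volume_mm3 = fat_volume,
         fat_mass_mg = fat_volume * density,
         fat_density_mg_mm3 = density,
         depot_masses_mg = depot_masses, region = region),
    class = "ground_truth")
  structure(list(fat_signal = fat_sig, water_signal = water_sig,
                 truth = truth, spec = spec),
            class = "phantom_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> fat volume %.2f mm^3, fat mass %.2f mg (density %g mg/mm^3)\n",
              x$fat_volume_mm3, x$fat_mass_mg, x$fat_density_mg_mm3))
  for (nm in names(x$depot_masses_mg))
    cat(sprintf("  %-14s %8.2f mg\n", nm, x$depot_masses_mg[[nm]]))
  invisible(x)
}

#' Simulate a CHESS fat/water magnitude pair
#'
#' Applies the receiver gains and Rician magnitude noise to the noise-free
#' signal volumes: each voxel becomes `sqrt((RG * S + n1)^2 + n2^2)` with
#' `n1`, `n2` independent zero-mean Gaussians of standard deviation `sigma`.
#' With `sigma = 0` the output equals `RG * S` exactly; the same seed gives
#' bit-identical stacks.
#'
#' @param fat_signal,water_signal noise-free signal arrays, or a
#'   `phantom_truth` as the first argument.
#' @param spec the [phantom_spec()] (defaulted from a `phantom_truth`).
#' @param seed simulation seed; defaults to `spec$seed`.
#' @return `list(fat = , water = )` of [channel_stack()]s.
#' @export
simulate_chess_pair <- function(fat_signal, water_signal = NULL, spec = NULL,
                                seed = NULL) {
  if (inherits(fat_signal, "phantom_truth")) {
    tv <- fat_signal
    spec <- spec %||% tv$spec
    water_signal <- tv$water_signal
    fat_signal <- tv$fat_signal
  }
  stopifnot(inherits(spec, "phantom_spec"))
  seed <- seed %||% spec$seed
  dm <- stack_dim(spec$geometry)
  if (!all(dim(fat_signal) == dm) || !all(dim(water_signal) == dm))
    stopf("signal volumes do not match the spec geometry")
  sigma <- spec$sigma
  rician <- function(s, gain) {
    nf <- s * gain
    if (sigma == 0) return(nf)
    sqrt((nf + rnorm(length(nf), 0, sigma))^2 + rnorm(length(nf), 0, sigma)^2)
  }
  with_seed(seed, {
    fat <- rician(fat_signal, spec$receiver_gain[["fat"]])
    water <- rician(water_signal, spec$receiver_gain[["water"]])
  })
  dim(fat) <- dim(water) <- dm
  list(fat = channel_stack(fat, "fat", spec$receiver_gain[["fat"]],
                           spec$geometry, seed = seed, sigma_truth = sigma),
       water = channel_stack(water, "water", spec$receiver_gain[["water"]],
                             spec$geometry, seed = seed, sigma_truth = sigma))
}

#' Noise level giving a stated peak signal-to-noise ratio
#'
#' Peak SNR is defined as the maximum noise-free magnitude intensity over
#' both channels (after receiver gain) divided by the Rician noise sigma.
#'
#' @param spec a [phantom_spec()].
#' @param snr desired peak signal-to-noise ratio.
#' @param truth optionally, precomputed [build_truth_volumes()] output.
#' @return The sigma achieving the requested peak SNR.
#' @export
sigma_for_peak_snr <- function(spec, snr, truth = NULL) {
  check_scalar_number(snr, "snr", min = 0, strict = TRUE)
  tv <- truth %||% build_truth_volumes(spec)
  peak <- max(max(tv$fat_signal) * spec$receiver_gain[["fat"]],
              max(tv$water_signal) * spec$receiver_gain[["water"]])
  peak / snr
}

#' Simulate a reference (EchoMRI-like) whole-body fat mass readout
#'
#' Models the reference instrument as the true fat mass perturbed by
#' scale-proportional Gaussian noise: `mass * (1 + e)` with
#' `e ~ N(0, cv^2)`.
#'
#' @param true_mass_mg true fat mass in mg (>= 0).
#' @param cv coefficient of variation of the instrument (>= 0).
#' @param seed RNG seed.
#' @return Simulated fat mass in mg.
#' @export
simulate_reference_fat_mass <- function(true_mass_mg, cv = 0.02, seed = 1L) {
  check_scalar_number(true_mass_mg, "true_mass_mg", min = 0)
  check_scalar_number(cv, "cv", min = 0)
  if (cv == 0) return(true_mass_mg)
  with_seed(seed, true_mass_mg * (1 + stats::rnorm(1, 0, cv)))
}

# Scale a spec's depots by linear factor s: ellipsoid semi-axes multiply by
# s, shell thickness (1 - inner_scale) multiplies by s.
scale_depots <- function(spec, s) {
  spec$depots <- lapply(spec$depots, function(d) {
    if (d$shape == "ellipsoid") d$semi_axes <- d$semi_axes * s
    else d$inner_scale <- max(0, 1 - s * (1 - d$inner_scale))
    d
  })
  spec
}

#' Phantom geometries spanning a fat-mass range
#'
#' Solves, per animal, for the depot size scale that hits each of `n`
#' equally spaced target fat masses between `mass_range[1]` and
#' `mass_range[2]`; depot linear dimensions scale, the lean compartment does
#' not. Used by [make_cohort()]; exposed so the (seed-independent) geometry
#' work can be reused across noise realisations.
#'
#' @inheritParams make_cohort
#' @return List of `n` elements, each `list(spec, truth_volumes)`.
#' @export
cohort_specs <- function(n = 8, mass_range = c(40, 220),
                         spec = default_phantom()) {
  if (n < 2) stopf("'n' must be at least 2")
  if (length(mass_range) != 2L || !all(is.finite(mass_range)) ||
      diff(mass_range) <= 0)
    stopf("degenerate mass range: max must exceed min")
  targets <- seq(mass_range[1], mass_range[2], length.out = n)
  mass_at <- function(s) build_truth_volumes(scale_depots(spec, s))$truth$fat_mass_mg
  lo <- 1e-3; hi <- 1.25
  m_lo <- mass_at(lo); m_hi <- mass_at(hi)
  if (targets[1] < m_lo || targets[n] > m_hi)
    stopf("mass range [%g, %g] mg not achievable by depot scaling (reachable [%g, %g] mg)",
          mass_range[1], mass_range[2], m_lo, m_hi)
  lapply(targets, function(m) {
    s <- stats::uniroot(function(s) mass_at(s) - m, c(lo, hi),
                        tol = 1e-4)$root
    sp <- scale_depots(spec, s)
    list(spec = sp, truth_volumes = build_truth_volumes(sp))
  })
}

#' Simulate a synthetic validation cohort
#'
#' Builds `n` phantoms whose true fat masses increase monotonically across
#' `mass_range`, simulates each phantom's CHESS fat/water pair and a noisy
#' reference fat-mass readout, all reproducibly under `seed`.
#'
#' @param n number of animals (>= 2).
#' @param mass_range target range of true fat masses in mg (min, max).
#' @param spec base [phantom_spec()] whose depots are rescaled per animal.
#' @param seed cohort seed, driving all noise.
#' @param reference_cv coefficient of variation of the reference readout.
#' @param specs optionally, precomputed [cohort_specs()] output.
#' @return A `phantom_cohort`: a list of members, each with `stacks`
#'   (fat/water [channel_stack()]s), `truth`, `reference_mass_mg` and `spec`.
#' @export
make_cohort <- function(n = 8, mass_range = c(40, 220),
                        spec = default_phantom(), seed = 1L,
                        reference_cv = 0.02, specs = NULL) {
  specs <- specs %||% cohort_specs(n, mass_range, spec)
  n <- length(specs)
  seeds <- with_seed(seed, sample.int(2^30, 2 * n))
  members <- lapply(seq_len(n), function(i) {
    tv <- specs[[i]]$truth_volumes
    list(stacks = simulate_chess_pair(tv, seed = seeds[i]),
         truth = tv$truth,
         reference_mass_mg = simulate_reference_fat_mass(
           tv$truth$fat_mass_mg, cv = reference_cv, seed = seeds[n + i]),
         spec = specs[[i]]$spec)
  })
  structure(members, class = "phantom_cohort", seed = seed,
            reference_cv = reference_cv)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  masses <- vapply(x, function(m) m$truth$fat_mass_mg, numeric(1))
  refs <- vapply(x, `[[`, numeric(1), "reference_mass_mg")
  cat(sprintf("<phantom_cohort> n = %d, true fat mass %.1f-%.1f mg, reference cv %g\n",
              length(x), min(masses), max(masses), attr(x, "reference_cv")))
  print(data.frame(true_mass_mg = round(masses, 2),
                   reference_mass_mg = round(refs, 2)))
  invisible(x)
}

#' Read or write a phantom specification as JSON
#'
#' @param spec a [phantom_spec()].
#' @param path JSON file path.
#' @return `read_phantom_spec()` returns a `phantom_spec`;
#'   `write_phantom_spec()` invisibly returns `path`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  out <- list(
    geometry = list(fov_mm = g$fov_mm, matrix = g$matrix,
                    n_slices = g$n_slices,
                    slice_thickness_mm = g$slice_thickness_mm),
    body = list(center = spec$body_center, semi_axes = spec$body_semi_axes),
    tube_radius_mm = spec$tube_radius_mm,
    depots = lapply(spec$depots, unclass),
    lean_fat_fraction = spec$lean_fat_fraction,
    signal_scale = spec$signal_scale,
    agarose_level = spec$agarose_level,
    receiver_gain = as.list(spec$receiver_gain),
    sigma = spec$sigma, seed = spec$seed,
    fat_density_mg_mm3 = spec$fat_density_mg_mm3)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  depots <- lapply(seq_len(NROW(j$depots)), function(i) {
    d <- if (is.data.frame(j$depots)) as.list(j$depots[i, ]) else j$depots[[i]]
    if (d$shape == "ellipsoid")
      depot_ellipsoid(d$label, unlist(d$center), unlist(d$semi_axes),
                      d$fat_fraction)
    else
      depot_shell(d$label, d$inner_scale, d$fat_fraction, d$z_extent,
                  unlist(d$angles_deg))
  })
  phantom_spec(
    geometry = acq_geometry(j$geometry$fov_mm, j$geometry$matrix,
                            j$geometry$n_slices,
                            j$geometry$slice_thickness_mm),
    body_center = j$body$center, body_semi_axes = j$body$semi_axes,
    tube_radius_mm = j$tube_radius_mm, depots = depots,
    lean_fat_fraction = j$lean_fat_fraction, signal_scale = j$signal_scale,
    agarose_level = j$agarose_level,
    receiver_gain = c(fat = j$receiver_gain$fat, water = j$receiver_gain$water),
    sigma = j$sigma, seed = j$seed,
    fat_density_mg_mm3 = j$fat_density_mg_mm3)
}
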