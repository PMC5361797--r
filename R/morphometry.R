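#' Body mass index of a fish
#'
#' Weight divided by squared standard length, the convention of the
#' zebrafish obesity literature.
#'
#' @param weight_g body weight in g (> 0).
#' @param length_cm standard length in cm (> 0).
#' @return BMI in g/cm^2. Vectorized.
#' @export
bmi <- function(weight_g, length_cm) {
  check_positive_vec(weight_g, "weight_g")
  check_positive_vec(length_cm, "length_cm")
  weight_g / length_cm^2
}

check_positive_vec <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be positive and finite", name)
  invisible(x)
}

#' Fulton's condition index
#'
#' The fisheries condition factor `K = 100 * W / L^3` with weight in g and
#' standard length in cm.
#'
#' @inheritParams bmi
#' @return Condition index K. Vectorized.
#' @export
fulton_k <- function(weight_g, length_cm) {
  check_positive_vec(weight_g, "weight_g")
  check_positive_vec(length_cm, "length_cm")
  100 * weight_g / length_cm^3
}

#' Body fat percentage from fat mass and body weight
#'
#' @param fat_mass_mg whole-body fat mass in mg, between 0 and
#'   `1000 * weight_g`.
#' @param weight_g body weight in g (> 0).
#' @return Body fat percentage. Vectorized.
#' @export
body_fat_percent <- function(fat_mass_mg, weight_g) {
  check_positive_vec(weight_g, "weight_g")
  if (any(!is.finite(fat_mass_mg)) || any(fat_mass_mg < 0))
    stopf("'fat_mass_mg' must be non-negative and finite")
  if (any(fat_mass_mg > 1000 * weight_g))
    stopf("fat mass exceeds body weight")
  100 * (fat_mass_mg / 1000) / weight_g
}

#' Area of a traced cell outline
#'
#' Shoelace (signed-area) formula over the ordered vertices of a simple
#' closed polygon, scaled by the squared pixel size; orientation
#' independent. A duplicated closing vertex is tolerated.
#'
#' @param outline two-column matrix or data frame of vertex (x, y) pixel
#'   coordinates, >= 3 distinct vertices, non-self-intersecting.
#' @param pixel_size_um physical pixel edge in micrometres per pixel.
#' @return Area in square micrometres.
#' @export
polygon_area <- function(outline, pixel_size_um = 1) {
  v <- as_polygon(outline)
  check_scalar_number(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2 * pixel_size_um^2
}

as_polygon <- function(outline) {
  v <- as.matrix(outline)
  if (!is.numeric(v) || ncol(v) < 2L) stopf("an outline needs x and y columns")
  v <- v[, 1:2, drop = FALSE]
  if (nrow(v) > 1L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stopf("an outline needs at least 3 distinct vertices")
  if (any(!is.finite(v))) stopf("outline coordinates must be finite")
  if (polygon_self_intersects(v)) stopf("outline is self-intersecting")
  v
}

# Proper-crossing test between all non-adjacent edge pairs.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  p1 <- v; p2 <- v[c(2:n, 1), , drop = FALSE]
  orient <- function(a, b, c)
    sign((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
         (b[, 2] - a[, 2]) * (c[, 1] - a[, 1]))
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]          # skip edges sharing a vertex
    if (!length(js)) next
    a <- p1[rep(i, length(js)), , drop = FALSE]
    b <- p2[rep(i, length(js)), , drop = FALSE]
    c_ <- p1[js, , drop = FALSE]; d <- p2[js, , drop = FALSE]
    cross <- orient(a, b, c_) * orient(a, b, d) < 0 &
             orient(c_, d, a) * orient(c_, d, b) < 0
    if (any(cross)) return(TRUE)
  }
  FALSE
}

#' A histology field of view with traced adipocyte outlines
#'
#' @param depot `"subcutaneous"` or `"visceral"`.
#' @param pixel_size_um micrometres per pixel of the micrograph.
#' @param outlines list of adipocyte outlines (see [polygon_area()]).
#' @param fov_id optional field identifier.
#' @return An `adipocyte_fov` object.
#' @export
adipocyte_fov <- function(depot = c("subcutaneous", "visceral"),
                          pixel_size_um = 1, outlines = list(),
                          fov_id = NULL) {
  depot <- match.arg(depot)
  check_scalar_number(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  outlines <- lapply(outlines, as_polygon)   # validates each polygon
  structure(list(depot = depot, pixel_size_um = pixel_size_um,
                 outlines = outlines, fov_id = fov_id),
            class = "adipocyte_fov")
}

#' Per-depot adipocyte counts and cell areas
#'
#' Counts adipocytes per field of view and measures each cell's area,
#' grouped by depot — the quantification underlying adipocyte hypertrophy /
#' hyperplasia comparisons between diet groups.
#'
#' @param fovs list of [adipocyte_fov()] objects (>= 1).
#' @return `list(summary = , areas_um2 = )`: a per-depot data frame
#'   (`depot`, `n_fov`, `n_cells`, `cells_per_fov`, `mean_area_um2`,
#'   `median_area_um2`) and the per-depot vectors of individual cell areas.
#' @export
adipocyte_summary <- function(fovs) {
  if (!length(fovs)) stopf("at least one field of view is required")
  for (f in fovs) stopifnot(inherits(f, "adipocyte_fov"))
  depots <- c("subcutaneous", "visceral")
  areas <- stats::setNames(vector("list", length(depots)), depots)
  n_fov <- stats::setNames(integer(length(depots)), depots)
  for (f in fovs) {
    n_fov[f$depot] <- n_fov[f$depot] + 1L
    a <- vapply(f$outlines, polygon_area, numeric(1),
                pixel_size_um = f$pixel_size_um)
    areas[[f$depot]] <- c(areas[[f$depot]], a)
  }
  present <- depots[n_fov > 0]
  summary <- do.call(rbind, lapply(present, function(d) {
    a <- areas[[d]]
    data.frame(depot = d, n_fov = n_fov[[d]], n_cells = length(a),
               cells_per_fov = length(a) / n_fov[[d]],
               mean_area_um2 = if (length(a)) mean(a) else NA_real_,
               median_area_um2 = if (length(a)) stats::median(a) else NA_real_)
  }))
  rownames(summary) <- NULL
  list(summary = summary, areas_um2 = areas[present])
}

#' A diet component with its macronutrient composition
#'
#' @param name component name.
#' @param amount_mg daily ration of the component in mg.
#' @param fat,protein,carbohydrate mass fractions in \[0, 1\], summing to at
#'   most 1.
#' @return A `diet_component` object.
#' @export
diet_component <- function(name, amount_mg, fat, protein, carbohydrate) {
  check_scalar_number(amount_mg, "amount_mg", min = 0)
  for (f in c(fat = fat, protein = protein, carbohydrate = carbohydrate))
    check_fraction(f, sprintf("'%s' macronutrient fraction", name))
  if (fat + protein + carbohydrate > 1)
    stopf("'%s': macronutrient fractions sum to more than 1", name)
  structure(list(name = name, amount_mg = amount_mg, fat = fat,
                 protein = protein, carbohydrate = carbohydrate),
            class = "diet_component")
}

#' The three experimental zebrafish rations
#'
#' Daily rations of the feeding design: maintenance feeding with Artemia
#' cysts (22% fat, 44% protein, 16% carbohydrate; 5 mg/day), normal-fat-diet
#' overfeeding (60 mg/day Artemia), and high-fat-diet overfeeding (5 mg/day
#' Artemia plus 30 mg/day egg yolk powder, 59% fat / 32% protein / 2%
#' carbohydrate).
#'
#' @return Named list of [diet_component()] lists, one per group
#'   (`control`, `NFD-OF`, `HFD-OF`).
#' @export
zebrafish_diets <- function() {
  artemia <- function(mg) diet_component("artemia", mg, 0.22, 0.44, 0.16)
  yolk <- function(mg) diet_component("egg_yolk_powder", mg, 0.59, 0.32, 0.02)
  list("control" = list(artemia(5)),
       "NFD-OF" = list(artemia(60)),
       "HFD-OF" = list(artemia(5), yolk(30)))
}

#' Daily energy of a ration
#'
#' Atwater energy of a list of diet components:
#' `sum(amount_g * (fat * e_fat + protein * e_protein + carb * e_carb))`.
#'
#' @param components list of [diet_component()]s.
#' @param atwater named energy coefficients in kcal/g for `fat`, `protein`,
#'   `carbohydrate` (defaults 9, 4, 4).
#' @return Energy in kcal/day.
#' @export
diet_energy <- function(components,
                        atwater = c(fat = 9, protein = 4, carbohydrate = 4)) {
  if (inherits(components, "diet_component")) components <- list(components)
  if (!all(c("fat", "protein", "carbohydrate") %in% names(atwater)))
    stopf("'atwater' must name fat, protein and carbohydrate coefficients")
  if (any(atwater <= 0)) stopf("Atwater coefficients must be positive")
  sum(vapply(components, function(cp) {
    stopifnot(inherits(cp, "diet_component"))
    (cp$amount_mg / 1000) * (cp$fat * atwater[["fat"]] +
                             cp$protein * atwater[["protein"]] +
                             cp$carbohydrate * atwater[["carbohydrate"]])
  }, numeric(1)))
}

#' Read a per-fish measurement table
#'
#' CSV columns: `id`, `group` (control | NFD-OF | HFD-OF), `weight_g`,
#' `length_cm`, optional `fat_mass_mg`.
#'
#' @param path CSV file path.
#' @return A validated data frame of fish records.
#' @export
read_fish_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "group", "weight_g", "length_cm")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stopf("fish table is missing column(s): %s", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$group), c("control", "NFD-OF", "HFD-OF"))
  if (length(bad))
    stopf("unknown dietary group(s): %s", paste(bad, collapse = ", "))
  check_positive_vec(df$weight_g, "weight_g")
  check_positive_vec(df$length_cm, "length_cm")
  df
}

#' Anthropometric indices for a fish table
#'
#' Adds `bmi_g_cm2`, `fulton_k` and (when fat mass is available)
#' `body_fat_pct` columns to a [read_fish_records()] table.
#'
#' @param records data frame of fish records.
#' @return The augmented data frame.
#' @export
morpho_summary <- function(records) {
  records$bmi_g_cm2 <- bmi(records$weight_g, records$length_cm)
  records$fulton_k <- fulton_k(records$weight_g, records$length_cm)
  if (!is.null(records$fat_mass_mg))
    records$body_fat_pct <- body_fat_percent(records$fat_mass_mg,
                                             records$weight_g)
  records
}

#' Read adipocyte outlines from a long-format ROI table
#'
#' CSV columns: `fish_id`, `depot`, `fov_id`, `polygon_id`, `vertex_index`,
#' `x_px`, `y_px`, `pixel_size_um` (constant within a field of view).
#'
#' @param path CSV file path.
#' @return List of [adipocyte_fov()] objects, one per (fish, depot, fov).
#' @export
read_adipocyte_rois <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("fish_id", "depot", "fov_id", "polygon_id", "vertex_index",
              "x_px", "y_px", "pixel_size_um")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stopf("ROI table is missing column(s): %s", paste(missing, collapse = ", "))
  keys <- unique(df[, c("fish_id", "depot", "fov_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$fish_id == keys$fish_id[i] & df$depot == keys$depot[i] &
      df$fov_id == keys$fov_id[i]
    sub <- df[sel, ]
    outlines <- lapply(split(sub, sub$polygon_id), function(p) {
      p <- p[order(p$vertex_index), ]
      cbind(x = p$x_px, y = p$y_px)
    })
    adipocyte_fov(depot = keys$depot[i],
                  pixel_size_um = sub$pixel_size_um[1],
                  outlines = unname(outlines),
                  fov_id = paste(keys$fish_id[i], keys$fov_id[i], sep = "/"))
  })
}
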