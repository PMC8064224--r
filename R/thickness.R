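#' Per-layer thickness map from interface surfaces
#'
#' Thickness is measured along the A-scan (axial) direction as the depth
#' difference between the layer's bounding interfaces, converted to
#' micrometres with the axial pixel pitch. Layer `k` of [retina_layers()]
#' lies between interfaces `k` and `k + 1`; `"TRT"` spans interfaces 1 and 9,
#' so the eight layer maps telescope exactly to the TRT map.
#'
#' @param interfaces an `interface_set`.
#' @param layer one of `retina_layers(include_trt = TRUE)`.
#' @return an object of class `thickness_map`: list with `layer`, `values`
#'   (512 x 512 um matrix), `valid` (logical matrix, all `TRUE` initially),
#'   `orientation` (`"native"`) and the eye/group/age/subject metadata.
#' @export
#' @examples
#' iset <- generate_interfaces(sim_config(noise_sd = 0, seed = 1))
#' tm <- compute_thickness_map(iset, "INL")
#' range(tm$values)
compute_thickness_map <- function(interfaces, layer) {
  stopifnot(inherits(interfaces, "interface_set"))
  all_layers <- retina_layers(include_trt = TRUE)
  if (!is.character(layer) || length(layer) != 1L || !layer %in% all_layers)
    stop_keyed("unknown layer '%s'; expected one of: %s",
               as.character(layer)[1], paste(all_layers, collapse = ", "))
  if (layer == "TRT") {
    upper <- 1L; lower <- 9L
  } else {
    upper <- match(layer, retina_layers())
    lower <- upper + 1L
  }
  vals <- (interfaces$surfaces[, , lower] - interfaces$surfaces[, , upper]) *
    interfaces$pixel_pitch_axial
  new_thickness_map(layer, vals, interfaces)
}

new_thickness_map <- function(layer, values, meta, valid = NULL,
                              orientation = "native") {
  if (!all(dim(values) == c(GRID_N, GRID_N)))
    stop_keyed("thickness grid must be %d x %d", GRID_N, GRID_N)
  structure(list(
    layer = layer,
    values = values,
    valid = valid %||% matrix(TRUE, GRID_N, GRID_N),
    eye = meta$eye, group = meta$group,
    age_months = meta$age_months, subject = meta$subject,
    orientation = orientation
  ), class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat("<thickness_map> ", x$layer, ", ", x$group, " ", x$eye, " age ",
      x$age_months, " mo (", x$orientation, ")\n", sep = "")
  v <- x$values[x$valid]
  cat(sprintf("  %.1f%% valid; thickness %.2f-%.2f um (mean %.2f)\n",
              100 * mean(x$valid),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              if (length(v)) mean(v) else NA))
  invisible(x)
}

#' Standardize map orientation to the right-eye convention
#'
#' Left-eye (OS) maps are mirrored left-right so that, as in right-eye (OD)
#' maps, the left half of the map is temporal and the right half nasal. This
#' makes eyes directly comparable and nasal-temporal contrasts well defined.
#' Already-standardized maps are returned unchanged (with a message), so the
#' operation is idempotent.
#'
#' @param map a `thickness_map` in native orientation.
#' @return the map with `orientation = "standardized"`.
#' @export
standardize_orientation <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  if (map$orientation == "standardized") {
    message("map is already standardized; returning unchanged")
    return(map)
  }
  if (map$eye == "OS") {
    map$values <- map$values[, GRID_N:1L]
    map$valid <- map$valid[, GRID_N:1L]
  }
  map$orientation <- "standardized"
  map
}

#' Whole-area mean thickness
#'
#' Mean over the valid positions of the full (uncropped) 512 x 512 grid; the
#' standard whole-imaged-area summary.
#'
#' @param map a standardized `thickness_map`.
#' @param min_valid_fraction minimum fraction of valid positions required for
#'   the mean to be meaningful.
#' @return scalar mean thickness in um.
#' @export
whole_area_mean <- function(map, min_valid_fraction = 0.5) {
  stopifnot(inherits(map, "thickness_map"))
  if (map$orientation != "standardized")
    stop("map must be standardized before averaging", call. = FALSE)
  nv <- sum(map$valid)
  if (nv == 0L)
    stop("no valid thickness values: whole-area mean undefined", call. = FALSE)
  if (nv / length(map$valid) < min_valid_fraction)
    stop_keyed("only %.1f%% of positions are valid (< %.0f%% required)",
               100 * nv / length(map$valid), 100 * min_valid_fraction)
  mean(map$values[map$valid])
}

#' Radial thickness profile around the optic disc
#'
#' Bins valid positions by Euclidean distance (in pixels) to the optic-disc
#' centre and returns the per-bin mean thickness, quantifying the decline of
#' thickness with distance to the disc.
#'
#' @param map a standardized `thickness_map`.
#' @param disc_centre numeric `c(row, col)`; defaults to the midpoint of the
#'   bottom edge (the scan sits above the disc, horizontally centred on it).
#' @param n_bins number of equal-width distance bins (`>= 2`).
#' @return data.frame with columns `bin`, `dist_min_px`, `dist_max_px`,
#'   `mean_um`, `n`.
#' @export
radial_profile <- function(map, disc_centre = c(GRID_N + 0.5, (GRID_N + 1) / 2),
                           n_bins = 10) {
  stopifnot(inherits(map, "thickness_map"))
  if (length(disc_centre) != 2L || any(!is.finite(disc_centre)))
    stop("disc_centre must be two finite coordinates", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  d <- sqrt(outer((seq_len(GRID_N) - disc_centre[1])^2,
                  (seq_len(GRID_N) - disc_centre[2])^2, `+`))
  ok <- map$valid
  breaks <- seq(min(d[ok]), max(d[ok]), length.out = n_bins + 1L)
  bin <- cut(d[ok], breaks, include.lowest = TRUE, labels = FALSE)
  means <- tapply(map$values[ok], bin, mean)
  counts <- tapply(map$values[ok], bin, length)
  idx <- as.integer(names(means))
  data.frame(bin = idx,
             dist_min_px = breaks[idx],
             dist_max_px = breaks[idx + 1L],
             mean_um = as.numeric(means),
             n = as.integer(counts))
}
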