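#' Configuration for the synthetic segmented-volume generator
#'
#' Bundles the parameters from which [generate_interfaces()] builds a
#' segmented volume: per-layer base thicknesses, the two deterministic spatial
#' gradients, the per-pixel noise level, and acquisition metadata.
#'
#' The two gradient terms are mean-centred over the en-face grid, so each
#' layer's `base_thickness` is its whole-area mean thickness by construction;
#' the gradients only redistribute thickness spatially. The nasal-temporal
#' coordinate `x(c) = (c - 1)/511 - 0.5` runs from -0.5 at the temporal edge
#' to +0.5 at the nasal edge of an OD-convention map, so a slope of `s` um
#' separates the two edge columns by exactly `s` um. The optic-disc distance
#' coordinate is the Euclidean distance to `disc_centre` divided by the grid
#' side (512), minus its grid average; a negative `disc_distance_slope` makes
#' the retina thinner away from the disc, as observed in vivo.
#'
#' @param base_thickness_um named numeric of 8 positive per-layer mean
#'   thicknesses (um), names as [retina_layers()]. Defaults to the packaged
#'   wild-type whole-area values for `age_months`.
#' @param nasal_temporal_slope_um um of thickness difference across the full
#'   nasal-temporal extent (nasal thicker when positive).
#' @param disc_distance_slope_um um per unit normalized distance to the optic
#'   disc centre (negative = thinning away from the disc).
#' @param noise_sd_um standard deviation (um) of i.i.d. Gaussian thickness
#'   noise added per layer and en-face position.
#' @param invalid_fraction fraction in `[0, 1]` of positions to be marked
#'   invalid downstream (consumed by [inject_invalid()], kept here so a config
#'   fully describes a degradation scenario).
#' @param eye `"OD"` (right) or `"OS"` (left). OS volumes are generated in
#'   native orientation, i.e. mirrored so that nasal lies on the left.
#' @param group cohort label, e.g. `"WT"` or `"3xTg-AD"`.
#' @param age_months age at acquisition, in `1:4`.
#' @param subject subject/eye identifier carried through the pipeline.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @param top_depth_px depth (pixels) of the innermost interface; constant
#'   across the grid.
#' @param noise_sd shorthand alias for `noise_sd_um`.
#' @param disc_centre numeric `c(row, col)` of the optic-disc centre in
#'   en-face pixel coordinates. The scan is centred horizontally on the disc
#'   and placed vertically above it, so the default is the midpoint of the
#'   bottom edge.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(age_months = 1, noise_sd = 0, seed = 1)
#' cfg$base_thickness_um[["INL"]]
sim_config <- function(base_thickness_um = NULL,
                       nasal_temporal_slope_um = 2,
                       disc_distance_slope_um = -5,
                       noise_sd_um = 2,
                       invalid_fraction = 0,
                       eye = "OD",
                       group = "WT",
                       age_months = 1,
                       subject = "sim-001",
                       seed = 1L,
                       top_depth_px = 200,
                       disc_centre = c(GRID_N + 0.5, (GRID_N + 1) / 2),
                       noise_sd = NULL) {
  if (!is.null(noise_sd)) noise_sd_um <- noise_sd  # convenience alias
  layers <- retina_layers()
  if (is.null(base_thickness_um)) {
    db <- load_packaged("wt_whole_area")
    base_thickness_um <- vapply(
      layers,
      function(l) db_lookup(db, "WT", "combined", age_months, l, "whole")$mean,
      numeric(1))
  }
  if (is.null(names(base_thickness_um)) && length(base_thickness_um) == 8L)
    names(base_thickness_um) <- layers
  if (!all(layers %in% names(base_thickness_um)))
    stop_keyed("base_thickness_um must be named with all of: %s",
               paste(layers, collapse = ", "))
  base_thickness_um <- base_thickness_um[layers]
  if (any(!is.finite(base_thickness_um)) || any(base_thickness_um <= 0))
    stop("base thicknesses must be positive and finite", call. = FALSE)
  if (!is.finite(nasal_temporal_slope_um) || !is.finite(disc_distance_slope_um))
    stop("gradient slopes must be finite", call. = FALSE)
  if (!is.finite(noise_sd_um) || noise_sd_um < 0)
    stop("noise_sd_um must be a non-negative number", call. = FALSE)
  if (!is.finite(invalid_fraction) || invalid_fraction < 0 || invalid_fraction > 1)
    stop("invalid_fraction must lie in [0, 1]", call. = FALSE)
  eye <- match.arg(eye, c("OD", "OS"))
  if (!age_months %in% 1:4)
    stop("age_months must be one of 1, 2, 3, 4", call. = FALSE)
  if (any(!is.finite(disc_centre)) || length(disc_centre) != 2L)
    stop("disc_centre must be two finite coordinates", call. = FALSE)
  structure(list(
    base_thickness_um = base_thickness_um,
    nasal_temporal_slope_um = nasal_temporal_slope_um,
    disc_distance_slope_um = disc_distance_slope_um,
    noise_sd_um = noise_sd_um,
    invalid_fraction = invalid_fraction,
    eye = eye, group = group, age_months = age_months,
    subject = subject, seed = as.integer(seed),
    top_depth_px = top_depth_px, disc_centre = disc_centre
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$group, " ", x$eye, " age ", x$age_months, " mo, seed ",
      x$seed, "\n", sep = "")
  cat("  base thickness (um):",
      paste(sprintf("%s=%.2f", names(x$base_thickness_um), x$base_thickness_um),
            collapse = " "), "\n")
  cat(sprintf("  slopes: nasal-temporal %+.2f um, disc-distance %+.2f um; noise sd %.2f um\n",
              x$nasal_temporal_slope_um, x$disc_distance_slope_um, x$noise_sd_um))
  invisible(x)
}

#' Read a simulation config from YAML or JSON
#'
#' Fields mirror the arguments of [sim_config()]; unknown fields are an error
#' so typos fail loudly.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_keyed("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_keyed("unknown config field(s): %s", paste(bad, collapse = ", "))
  if (!is.null(raw$base_thickness_um)) raw$base_thickness_um <- unlist(raw$base_thickness_um)
  if (!is.null(raw$disc_centre)) raw$disc_centre <- as.numeric(unlist(raw$disc_centre))
  do.call(sim_config, raw)
}
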