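# File formats: interface sets and thickness maps as TIFF + JSON sidecar,
# and as tidy CSV. Float TIFF pages are stored normalized to [0, 1]; the
# physical scale lives in the sidecar so the round trip is lossless up to
# 32-bit float precision. CSV is the exact interchange format.

#' Write / read an interface set
#'
#' `write_interfaces()` stores the nine depth surfaces as a multi-page
#' 32-bit float TIFF (depths divided by the 1024-pixel depth range) with a
#' JSON sidecar (`<path>.json`) holding the scale, pixel pitch and metadata.
#' `read_interfaces()` reverses it.
#'
#' @param iset an `interface_set`.
#' @param path TIFF path (`.tif`).
#' @return `write_interfaces` returns `path` invisibly; `read_interfaces`
#'   an `interface_set`.
#' @export
write_interfaces <- function(iset, path) {
  stopifnot(inherits(iset, "interface_set"))
  pages <- lapply(1:9, function(k) iset$surfaces[, , k] / DEPTH_N)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(depth_scale_px = DEPTH_N,
               pixel_pitch_axial = iset$pixel_pitch_axial,
               eye = iset$eye, group = iset$group,
               age_months = iset$age_months, subject = iset$subject)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_interfaces
#' @export
read_interfaces <- function(path) {
  if (!file.exists(path)) stop_keyed("interface file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  surfaces <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) surfaces[, , k] <- pages[[k]] * meta$depth_scale_px
  structure(list(surfaces = surfaces,
                 pixel_pitch_axial = meta$pixel_pitch_axial,
                 eye = meta$eye, group = meta$group,
                 age_months = meta$age_months, subject = meta$subject),
            class = "interface_set")
}

#' Tidy CSV export of an interface set
#'
#' One row per `(row, col, interface_index)` with the sub-pixel depth. Exact
#' but large; intended for interchange of small regions or test fixtures.
#'
#' @param iset an `interface_set`.
#' @param path CSV path.
#' @param rows,cols optional index subsets to export.
#' @export
write_interfaces_csv <- function(iset, path, rows = seq_len(GRID_N),
                                 cols = seq_len(GRID_N)) {
  stopifnot(inherits(iset, "interface_set"))
  grid <- expand.grid(row = rows, col = cols, interface_index = 1:9)
  grid$depth_px <- iset$surfaces[as.matrix(grid)]
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a thickness map
#'
#' Two-page TIFF: page 1 the thickness values as 32-bit float normalized by
#' a scale recorded in the JSON sidecar, page 2 the validity mask as 0/1.
#'
#' @param map a `thickness_map`.
#' @param path TIFF path.
#' @return `write_thickness_map` returns `path` invisibly;
#'   `read_thickness_map` a `thickness_map`.
#' @export
write_thickness_map <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  scale <- max(map$values, 1)
  pages <- list(map$values / scale, (map$valid) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(scale_um = scale, layer = map$layer, eye = map$eye,
               group = map$group, age_months = map$age_months,
               subject = map$subject, orientation = map$orientation)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thickness_map
#' @export
read_thickness_map <- function(path) {
  if (!file.exists(path)) stop_keyed("thickness file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_thickness_map(meta$layer, pages[[1]] * meta$scale_um,
                    list(eye = meta$eye, group = meta$group,
                         age_months = meta$age_months, subject = meta$subject),
                    valid = pages[[2]] > 0.5,
                    orientation = meta$orientation)
}
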