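#' Generate a synthetic segmented OCT volume
#'
#' Builds the nine ordered interface depth surfaces of a retinal volume over
#' the 512 x 512 en-face grid. Each layer's axial thickness at position
#' `(r, c)` is
#' `base + nasal_temporal_slope * x(c) + disc_distance_slope * d(r, c) + noise`,
#' clamped at zero, with both gradient coordinates mean-centred over the grid
#' (see [sim_config()]). Interfaces are the cumulative sum of layer
#' thicknesses (converted to depth pixels) below a flat top surface, so the
#' monotone depth ordering holds for every generated volume.
#'
#' For left eyes (`eye = "OS"`) the deterministic gradients are mirrored
#' left-right so that the native map has nasal on the left, as acquired;
#' [standardize_orientation()] undoes this.
#'
#' @param config a [sim_config()].
#' @return an object of class `interface_set`: list with `surfaces` (a
#'   512 x 512 x 9 array of depth pixels, sub-pixel real values),
#'   `pixel_pitch_axial` (um per depth pixel) and metadata fields.
#' @export
#' @examples
#' iset <- generate_interfaces(sim_config(noise_sd = 0, seed = 7))
#' dim(iset$surfaces)
generate_interfaces <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a sim_config object", call. = FALSE)
  n <- GRID_N
  pitch <- axial_pitch_um()
  x <- (seq_len(n) - 1) / (n - 1) - 0.5               # temporal -0.5 .. nasal +0.5
  nt <- matrix(x, n, n, byrow = TRUE) * config$nasal_temporal_slope_um
  dd <- disc_distance_grid(n, config$disc_centre) * config$disc_distance_slope_um
  if (config$eye == "OS") {                            # native OS: nasal on the left
    nt <- nt[, n:1]
    dd <- dd[, n:1]
  }
  det_part <- nt + dd
  layers <- retina_layers()
  surfaces <- array(0, dim = c(n, n, 9L))
  surfaces[, , 1L] <- config$top_depth_px
  withr::with_seed(config$seed, {
    for (k in seq_along(layers)) {
      tk <- config$base_thickness_um[[k]] + det_part
      if (config$noise_sd_um > 0)
        tk <- tk + matrix(stats::rnorm(n * n, 0, config$noise_sd_um), n, n)
      tk <- pmax(tk, 0)
      surfaces[, , k + 1L] <- surfaces[, , k] + tk / pitch
    }
  })
  if (max(surfaces) >= DEPTH_N)
    stop("generated interfaces exceed the 1024-pixel imaging depth; lower top_depth_px or base thicknesses",
         call. = FALSE)
  structure(list(
    surfaces = surfaces,
    pixel_pitch_axial = pitch,
    eye = config$eye, group = config$group,
    age_months = config$age_months, subject = config$subject
  ), class = "interface_set")
}

# Normalized, grid-mean-centred Euclidean distance to the optic-disc centre.
disc_distance_grid <- function(n, disc_centre) {
  dr <- (seq_len(n) - disc_centre[1])^2
  dc <- (seq_len(n) - disc_centre[2])^2
  d <- sqrt(outer(dr, dc, `+`)) / n
  d - mean(d)
}

#' @export
print.interface_set <- function(x, ...) {
  cat("<interface_set> ", x$group, " ", x$eye, " age ", x$age_months,
      " mo, subject ", x$subject, "\n", sep = "")
  cat(sprintf("  9 surfaces over %d x %d; depth range [%.1f, %.1f] px (%.4f um/px)\n",
              dim(x$surfaces)[1], dim(x$surfaces)[2],
              min(x$surfaces), max(x$surfaces), x$pixel_pitch_axial))
  invisible(x)
}

#' Sample a synthetic cohort of eyes from a normative database
#'
#' Draws per-eye layer mean thicknesses from the normative cells of a database
#' and materializes each eye with [generate_interfaces()]. For each layer
#' named in `layers`, an eye's mean is drawn from
#' `Normal(cell$mean, between_eye_sd_scale * cell$sd)`; layers not in `layers`
#' are held at their cell means, which isolates the between-eye variability of
#' the quantity under study.
#'
#' If `"TRT"` is among `layers`, a total retinal thickness is drawn from the
#' TRT cell and the eight structural-layer thicknesses are rescaled
#' proportionally so that their sum equals the draw. Inside one volume the
#' layer thicknesses always telescope to the TRT, while the printed whole-area
#' TRT of a real cohort need not equal the sum of the printed layer means (the
#' per-layer value exclusions are independent); the rescaling reconciles the
#' two so that the generated TRT follows the normative TRT distribution.
#'
#' @param db a `normative_db` holding whole-area cells for the requested
#'   `(group, age, layer)` keys (eye-specific cells are used when present,
#'   else the eye-combined cells).
#' @param group,eye,age_months cohort key; `eye` is the generated laterality.
#' @param n_eyes number of eyes to generate.
#' @param between_eye_sd_scale multiplier on the cell sd for the between-eye
#'   draw; 0 pins every eye at the cell mean.
#' @param seed integer seed for the whole cohort.
#' @param layers layers whose means are sampled (default: all eight plus TRT).
#' @param config_base a [sim_config()] whose gradient/noise/geometry settings
#'   are reused for every eye (its base thicknesses, eye, group, age, subject
#'   and seed are overridden).
#' @return list of `interface_set`, length `n_eyes`.
#' @export
sample_cohort <- function(db, group, eye, age_months, n_eyes,
                          between_eye_sd_scale = 1, seed = 1L,
                          layers = retina_layers(include_trt = TRUE),
                          config_base = NULL) {
  n_eyes <- as.integer(n_eyes)
  if (n_eyes < 0L) stop("n_eyes must be >= 0", call. = FALSE)
  if (n_eyes == 0L) return(list())
  structural <- retina_layers()
  need <- union(structural, intersect(layers, "TRT"))
  cells <- lapply(need, function(l) db_lookup(db, group, eye, age_months, l, "whole"))
  names(cells) <- need
  base_means <- vapply(structural, function(l) cells[[l]]$mean, numeric(1))
  if (is.null(config_base)) config_base <- sim_config(base_thickness_um = base_means)
  withr::with_seed(as.integer(seed), {
    eye_seeds <- sample.int(.Machine$integer.max, n_eyes)
    draws <- lapply(seq_len(n_eyes), function(e) {
      m <- vapply(structural, function(l) {
        if (l %in% layers)
          stats::rnorm(1, cells[[l]]$mean, between_eye_sd_scale * cells[[l]]$sd)
        else cells[[l]]$mean
      }, numeric(1))
      m <- pmax(m, .Machine$double.eps)
      if ("TRT" %in% layers) {
        trt <- stats::rnorm(1, cells[["TRT"]]$mean,
                            between_eye_sd_scale * cells[["TRT"]]$sd)
        m <- m * (trt / sum(m))
      }
      m
    })
  })
  lapply(seq_len(n_eyes), function(e) {
    cfg <- config_base
    cfg$base_thickness_um <- draws[[e]]
    cfg$eye <- eye
    cfg$group <- group
    cfg$age_months <- age_months
    cfg$subject <- sprintf("%s-%s-m%d-%03d", group, eye, age_months, e)
    cfg$seed <- eye_seeds[e]
    generate_interfaces(cfg)
  })
}

#' Mark thickness-map positions invalid
#'
#' Degrades a thickness map's validity mask, either at random positions over
#' the whole map or confined to one of the nine aggregation blocks, to
#' exercise the per-value exclusion and block-retention logic.
#'
#' @param map a `thickness_map`.
#' @param fraction fraction in `[0, 1]`. For `pattern = "random"`, the
#'   fraction of the map's currently valid positions to invalidate; for
#'   `"block_targeted"`, the fraction of the target block's valid positions.
#'   Exactly `round(fraction * n_valid)` positions are marked.
#' @param pattern `"random"` or `"block_targeted"`.
#' @param block_index block 1..9 (row-major from the top-left on the cropped
#'   grid) for `"block_targeted"`.
#' @param seed integer seed for the position draw.
#' @return the map with an updated validity mask.
#' @export
inject_invalid <- function(map, fraction, pattern = c("random", "block_targeted"),
                           block_index = NULL, seed = 1L) {
  stopifnot(inherits(map, "thickness_map"))
  pattern <- match.arg(pattern)
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  valid <- map$valid
  if (pattern == "block_targeted") {
    if (is.null(block_index)) stop("block_index is required for block_targeted", call. = FALSE)
    b <- block_bounds_full(block_index)
    candidate <- matrix(FALSE, GRID_N, GRID_N)
    candidate[b$rows, b$cols] <- TRUE
    candidate <- candidate & valid
  } else {
    candidate <- valid
  }
  idx <- which(candidate)
  k <- round(fraction * length(idx))
  if (k > 0L) {
    withr::with_seed(as.integer(seed), {
      hit <- if (k == length(idx)) idx else sample(idx, k)
    })
    valid[hit] <- FALSE
  }
  map$valid <- valid
  map
}
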