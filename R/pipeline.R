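# Pipeline orchestration: YAML-configured end-to-end runs with a manifest.

#' Read and validate a pipeline configuration
#'
#' A single YAML file with per-command sections drives the pipeline commands.
#' Top-level fields: `seed` (integer), `output_dir`, and optional sections
#' `simulate`, `build_normative`, `compare`, `deviate`. Missing required
#' fields are reported by name.
#'
#' @param path YAML config path.
#' @return validated config list, class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_keyed("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("seed", "output_dir")) {
    if (is.null(cfg[[field]]))
      stop_keyed("config is missing required field '%s'", field)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

write_manifest <- function(out_dir, command, cfg, extra = list()) {
  manifest <- c(list(command = command,
                     package = "retnorm",
                     version = as.character(utils::packageVersion("retnorm")),
                     seed = cfg$seed,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     config = unclass(cfg)),
                extra)
  path <- file.path(out_dir, sprintf("manifest-%s.json", command))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

ensure_outdir <- function(cfg, sub = NULL) {
  dir <- cfg$output_dir
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_keyed("cannot create output directory: %s", dir)
  if (!is.null(sub)) {
    dir <- file.path(dir, sub)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }
  dir
}

require_section <- function(cfg, name, fields) {
  sec <- cfg[[name]]
  if (is.null(sec)) stop_keyed("config is missing required field '%s'", name)
  for (f in fields)
    if (is.null(sec[[f]]))
      stop_keyed("config is missing required field '%s.%s'", name, f)
  sec
}

#' Simulate and write a synthetic cohort
#'
#' Samples `simulate$n_eyes` eyes per requested group/eye/age combination
#' from the packaged normative parameters and writes each eye as an
#' interface TIFF with sidecar, plus a cohort metadata CSV and a run
#' manifest.
#'
#' Config section `simulate`: `n_eyes` (required), and optional `groups`
#' (default `"WT"`), `eyes` (default `"OD"`), `ages` (default 1),
#' `between_eye_sd_scale`, `noise_sd_um`, `nasal_temporal_slope_um`,
#' `disc_distance_slope_um`, `layers`.
#'
#' @param cfg a `pipeline_config` (or path to one).
#' @return (invisibly) data.frame of written volumes.
#' @export
run_simulate <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  sec <- require_section(cfg, "simulate", "n_eyes")
  out <- ensure_outdir(cfg, "volumes")
  db_wt <- load_packaged("wt_whole_area")
  db_ad <- load_packaged("ad_whole_area")
  groups <- sec$groups %||% "WT"
  eyes <- sec$eyes %||% "OD"
  ages <- sec$ages %||% 1
  base_cfg <- sim_config(
    nasal_temporal_slope_um = sec$nasal_temporal_slope_um %||% 2,
    disc_distance_slope_um = sec$disc_distance_slope_um %||% -5,
    noise_sd_um = sec$noise_sd_um %||% 2)
  rows <- list()
  combo_id <- 0L
  for (g in groups) for (e in eyes) for (a in ages) {
    combo_id <- combo_id + 1L
    db <- if (g == "WT") db_wt else db_ad
    cohort <- sample_cohort(db, g, e, a, sec$n_eyes,
                            between_eye_sd_scale = sec$between_eye_sd_scale %||% 1,
                            seed = cfg$seed + combo_id,
                            layers = sec$layers %||% retina_layers(TRUE),
                            config_base = base_cfg)
    for (iset in cohort) {
      f <- file.path(out, paste0(iset$subject, ".tif"))
      write_interfaces(iset, f)
      rows <- c(rows, list(data.frame(subject = iset$subject, group = g,
                                      eye = e, age_months = a, file = f)))
    }
  }
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(out, "cohort.csv"), row.names = FALSE)
  write_manifest(cfg$output_dir, "simulate", cfg,
                 list(n_volumes = nrow(meta)))
  message(nrow(meta), " volumes written to ", out)
  invisible(meta)
}

# Full single-eye chain: interfaces -> thickness -> standardize -> validity
# -> blocks + whole-area mean, for the requested layers.
process_eye <- function(iset, layers, rules_db = NULL, robust_z = 6) {
  lapply(layers, function(l) {
    tm <- compute_thickness_map(iset, l)
    tm <- standardize_orientation(tm)
    upper <- if (is.null(rules_db)) Inf else
      tryCatch(default_upper_bound(rules_db, "WT", "combined", iset$age_months, l),
               error = function(e) Inf)
    tm <- apply_validity_criteria(tm, validity_rules(upper_um = upper,
                                                    robust_z_threshold = robust_z))
    wm <- tryCatch(whole_area_mean(tm), error = function(e) NA_real_)
    list(layer = l, grid = crop_and_block(tm), whole_mean = wm)
  })
}

#' Build a normative database from a directory of volumes
#'
#' Runs the full chain (thickness maps, orientation standardization,
#' validity criteria, block aggregation, whole-area means) over every volume
#' listed in `<input_dir>/cohort.csv` and writes the resulting database CSV
#' plus a per-block quality report (percentage of blocks removed by the 90%
#' rule, per block position).
#'
#' Config section `build_normative`: `input_dir` (with the `cohort.csv` and
#' TIFFs of [run_simulate()]); optional `layers`, `db_file`, `robust_z`.
#'
#' @param cfg a `pipeline_config` (or path).
#' @return (invisibly) the built `normative_db`.
#' @export
run_build_normative <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  sec <- require_section(cfg, "build_normative", "input_dir")
  meta_file <- file.path(sec$input_dir, "cohort.csv")
  if (!file.exists(meta_file))
    stop_keyed("no cohort metadata found at %s", meta_file)
  meta <- utils::read.csv(meta_file)
  if (nrow(meta) == 0L) stop("cohort metadata lists no volumes", call. = FALSE)
  layers <- sec$layers %||% retina_layers(include_trt = TRUE)
  grids <- list()
  wrows <- list()
  for (i in seq_len(nrow(meta))) {
    iset <- read_interfaces(meta$file[i])
    for (res in process_eye(iset, layers, robust_z = sec$robust_z %||% 6)) {
      grids <- c(grids, list(res$grid))
      wrows <- c(wrows, list(data.frame(
        subject = iset$subject, group = iset$group, eye = iset$eye,
        age_months = iset$age_months, layer = res$layer,
        mean_um = res$whole_mean)))
    }
  }
  whole <- do.call(rbind, wrows)
  whole <- whole[!is.na(whole$mean_um), ]
  db <- build_normative(grids, whole)
  out <- ensure_outdir(cfg)
  db_file <- file.path(out, sec$db_file %||% "normative_db.csv")
  write_normative_csv(db, db_file)
  bd <- block_grid_to_df(grids)
  qc <- stats::aggregate(retained ~ block, data = bd,
                         FUN = function(r) 100 * mean(!r))
  names(qc)[2] <- "removed_pct"
  utils::write.csv(qc, file.path(out, "qc_block_removal.csv"), row.names = FALSE)
  write_manifest(out, "build_normative", cfg,
                 list(n_volumes = nrow(meta), db_file = db_file))
  message("normative database with ", nrow(db), " cells written to ", db_file)
  invisible(db)
}

#' Compare two normative databases
#'
#' Writes a mean(sd) summary table per layer and age for each input and a
#' significance-tier matrix (layers x ages) from Welch t tests on the
#' whole-area cells.
#'
#' Config section `compare`: `db_a`, `db_b` (CSV paths, or the ids
#' `"wt_whole_area"`/`"ad_whole_area"` for the packaged tables); optional
#' `variant`, `eye`.
#'
#' @param cfg a `pipeline_config` (or path).
#' @return (invisibly) the tier-matrix data.frame.
#' @export
run_compare <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  sec <- require_section(cfg, "compare", c("db_a", "db_b"))
  load_db <- function(x) {
    if (x %in% c("wt_whole_area", "ad_whole_area")) load_packaged(x)
    else read_normative_csv(x)
  }
  db_a <- load_db(sec$db_a)
  db_b <- load_db(sec$db_b)
  eye <- sec$eye %||% "combined"
  wa <- db_a[db_a$region == "whole" & db_a$eye == eye, ]
  wb <- db_b[db_b$region == "whole" & db_b$eye == eye, ]
  layers <- intersect(unique(wa$layer), unique(wb$layer))
  ages <- intersect(unique(wa$age_months), unique(wb$age_months))
  if (!length(layers) || !length(ages))
    stop("inputs share no layers/ages: cannot align databases", call. = FALSE)
  if (!setequal(unique(wa$layer), unique(wb$layer)) ||
      !setequal(unique(wa$age_months), unique(wb$age_months)))
    stop("inputs cover different layers or ages: cannot align databases",
         call. = FALSE)
  rows <- list()
  for (l in layers) for (a in ages) {
    ca <- db_lookup(db_a, wa$group[1], eye, a, l)
    cb <- db_lookup(db_b, wb$group[1], eye, a, l)
    cmp <- two_sample_test(ca, cb, variant = sec$variant %||% "welch")
    rows <- c(rows, list(data.frame(
      layer = l, age_months = a,
      mean_a = ca$mean, sd_a = ca$sd, n_a = ca$n,
      mean_b = cb$mean, sd_b = cb$sd, n_b = cb$n,
      statistic = cmp$statistic, df = cmp$df, p = cmp$p, tier = cmp$tier)))
  }
  res <- do.call(rbind, rows)
  out <- ensure_outdir(cfg)
  utils::write.csv(res, file.path(out, "group_comparison.csv"), row.names = FALSE)
  tiers <- stats::reshape(res[c("layer", "age_months", "tier")],
                          idvar = "layer", timevar = "age_months",
                          direction = "wide")
  names(tiers) <- sub("^tier\\.", "age_", names(tiers))
  utils::write.csv(tiers, file.path(out, "tier_matrix.csv"), row.names = FALSE)
  write_manifest(out, "compare", cfg, list(n_tests = nrow(res)))
  invisible(res)
}

#' Score one eye against a normative database
#'
#' Processes one subject's volume through the thickness/block chain, scores
#' its blocks against the normative database, and writes the deviation CSV
#' and a rendered PNG.
#'
#' Config section `deviate`: `input_dir`, `db` (CSV path or packaged id) and
#' `layer`; optional `reference_group`.
#'
#' @param cfg a `pipeline_config` (or path).
#' @param subject subject id as listed in the cohort metadata.
#' @return (invisibly) the `deviation_map`.
#' @export
run_deviate <- function(cfg, subject) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  sec <- require_section(cfg, "deviate", c("input_dir", "db", "layer"))
  meta <- utils::read.csv(file.path(sec$input_dir, "cohort.csv"))
  hit <- meta$subject == subject
  if (!any(hit)) stop_keyed("unknown subject '%s'", subject)
  iset <- read_interfaces(meta$file[which(hit)[1]])
  db <- if (sec$db %in% c("wt_whole_area", "ad_whole_area"))
    load_packaged(sec$db) else read_normative_csv(sec$db)
  res <- process_eye(iset, sec$layer)[[1]]
  dm <- deviation_map(res$grid, db, group = sec$reference_group %||% "WT")
  out <- ensure_outdir(cfg)
  deviation_to_df(dm, file.path(out, sprintf("deviation-%s-%s.csv",
                                             subject, sec$layer)))
  png_file <- file.path(out, sprintf("deviation-%s-%s.png", subject, sec$layer))
  grDevices::png(png_file, width = 600, height = 600)
  plot(dm)
  grDevices::dev.off()
  write_manifest(out, "deviate", cfg, list(subject = subject))
  invisible(dm)
}
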