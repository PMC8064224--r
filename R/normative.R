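# Normative thickness databases: construction, packaged tables, queries.

db_columns <- c("group", "eye", "age_months", "layer", "region",
                "mean_um", "sd_um", "n")

new_normative_db <- function(df, provenance = "built") {
  stopifnot(all(db_columns %in% names(df)))
  df <- df[db_columns]
  if (any(df$sd_um < 0, na.rm = TRUE)) stop("cell sd must be >= 0", call. = FALSE)
  key <- do.call(paste, c(df[c("group", "eye", "age_months", "layer", "region")],
                          sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate normative cells", call. = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("normative_db", "data.frame"),
            provenance = provenance)
}

#' @export
print.normative_db <- function(x, ...) {
  cat(sprintf("<normative_db> %d cells (%s): groups {%s}, ages {%s} mo\n",
              nrow(x), attr(x, "provenance"),
              paste(unique(x$group), collapse = ", "),
              paste(sort(unique(x$age_months)), collapse = ", ")))
  NextMethod()
}

#' Look up a normative cell
#'
#' Returns the `(mean, sd, n)` cell for a `(group, eye, age, layer, region)`
#' key. When no cell exists for the requested eye, the eye-combined cell is
#' used (the packaged tables pool both eyes, having shown no left-right
#' difference).
#'
#' @param db a `normative_db`.
#' @param group,eye,age_months,layer key fields; `region` is `"whole"` or
#'   `"block1"`..`"block9"`.
#' @param region region key.
#' @return list with `mean`, `sd`, `n`.
#' @export
db_lookup <- function(db, group, eye, age_months, layer, region = "whole") {
  stopifnot(inherits(db, "normative_db"))
  hit <- db$group == group & db$age_months == age_months &
    db$layer == layer & db$region == region & db$eye == eye
  if (!any(hit) && eye != "combined")
    hit <- db$group == group & db$age_months == age_months &
      db$layer == layer & db$region == region & db$eye == "combined"
  if (!any(hit))
    stop_keyed("no normative cell for (group=%s, age=%s, layer=%s, region=%s)",
               group, as.character(age_months), layer, region)
  row <- db[which(hit)[1L], ]
  list(mean = row$mean_um, sd = row$sd_um, n = row$n)
}

#' Build a normative database from measured eyes
#'
#' Aggregates retained block means and whole-area means across eyes into
#' per-cell `(mean, sample sd, n)` summaries, keyed by group, eye, age,
#' layer and region. Cells are built per eye (OD, OS) and for both eyes
#' combined, treating eyes as independent samples. Only retained blocks
#' contribute to block cells; cells with fewer than two eyes are omitted
#' (with a message) since a one-eye sd is undefined.
#'
#' @param block_grids list of `block_grid` (possibly over several layers,
#'   ages and groups); may be `NULL`.
#' @param whole_means data.frame with columns `subject`, `group`, `eye`,
#'   `age_months`, `layer`, `mean_um` holding per-eye whole-area means; may
#'   be `NULL`.
#' @return a `normative_db` with provenance `"built"`.
#' @export
build_normative <- function(block_grids = NULL, whole_means = NULL) {
  rows <- list()
  if (!is.null(block_grids) && length(block_grids)) {
    bd <- block_grid_to_df(block_grids)
    bd <- bd[bd$retained & !is.na(bd$mean_um), ]
    bd$region <- sprintf("block%d", bd$block)
    rows <- c(rows, list(bd[c("group", "eye", "age_months", "layer", "region",
                              "mean_um")]))
  }
  if (!is.null(whole_means) && nrow(whole_means %||% data.frame())) {
    wm <- whole_means
    wm$region <- "whole"
    rows <- c(rows, list(wm[c("group", "eye", "age_months", "layer", "region",
                              "mean_um")]))
  }
  if (!length(rows)) {
    warning("no input eyes: returning an empty normative database", call. = FALSE)
    empty <- data.frame(group = character(), eye = character(),
                        age_months = numeric(), layer = character(),
                        region = character(), mean_um = numeric(),
                        sd_um = numeric(), n = integer())
    return(new_normative_db(empty))
  }
  long <- do.call(rbind, rows)
  combined <- long
  combined$eye <- "combined"
  long <- rbind(long, combined)
  agg <- stats::aggregate(mean_um ~ group + eye + age_months + layer + region,
                          data = long,
                          FUN = function(v) c(m = mean(v), s = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(agg[c("group", "eye", "age_months", "layer", "region")],
                    mean_um = agg$mean_um[, "m"],
                    sd_um = agg$mean_um[, "s"],
                    n = as.integer(agg$mean_um[, "n"]))
  small <- out$n < 2L
  if (any(small)) {
    message(sum(small), " cell(s) with n < 2 omitted")
    out <- out[!small, ]
  }
  new_normative_db(out, provenance = "built")
}

# md5 checksums of the packaged reference tables, fixed at packaging time.
PACKAGED_MD5 <- c(
  wt_whole_area = "b4f78929f7e3f9565cf967a624d64ede",
  ad_whole_area = "5e10fac220e9694fcfbce8cb453b5101",
  weights = "8e0c8e8ecbc757d34793cb033db05015"
)

packaged_path <- function(file) {
  p <- system.file("extdata", file, package = "retnorm")
  if (!nzchar(p)) stop_keyed("packaged file '%s' not found", file)
  p
}

#' Load a packaged reference table
#'
#' The package ships the published whole-area normative tables for the
#' C57BL6/129S wild-type (`"wt_whole_area"`) and 3xTg-AD (`"ad_whole_area"`)
#' cohorts at one to four months (nine layers/aggregates, both eyes
#' combined, printed to two decimals with the per-age N), and the body-weight
#' summary by group and age (`"weights"`). File integrity is checked against
#' an md5 recorded at packaging time.
#'
#' `"block_reference"` loads a per-block normative table from a user-supplied
#' CSV in the database dialect (see [read_normative_csv()]); no per-block
#' reference values are packaged.
#'
#' @param table_id one of `"wt_whole_area"`, `"ad_whole_area"`, `"weights"`,
#'   `"block_reference"`.
#' @param path CSV path, required for `"block_reference"` only.
#' @return a `normative_db` for the thickness tables, or a data.frame with
#'   columns `group`, `age_months`, `mean_g`, `sd_g`, `p_between_groups` for
#'   `"weights"`.
#' @export
#' @examples
#' db <- load_packaged("wt_whole_area")
#' db_lookup(db, "WT", "combined", 4, "TRT")
load_packaged <- function(table_id = c("wt_whole_area", "ad_whole_area",
                                       "weights", "block_reference"),
                          path = NULL) {
  table_id <- match.arg(table_id)
  if (table_id == "block_reference") {
    if (is.null(path))
      stop(paste("per-block reference values are not packaged;",
                 "supply `path` to a CSV in the normative database dialect"),
           call. = FALSE)
    return(read_normative_csv(path, provenance = "packaged"))
  }
  file <- switch(table_id,
                 wt_whole_area = "wt_whole_area_normative.csv",
                 ad_whole_area = "ad_whole_area_normative.csv",
                 weights = "weights_by_age.csv")
  p <- packaged_path(file)
  md5 <- unname(tools::md5sum(p))
  if (!identical(md5, unname(PACKAGED_MD5[[table_id]])))
    stop_keyed("integrity check failed for packaged table '%s'", table_id)
  if (table_id == "weights") {
    w <- utils::read.csv(p)
    pv <- utils::read.csv(packaged_path("weights_group_pvalues.csv"))
    w$p_between_groups <- pv$p[match(w$age_months, pv$age_months)]
    return(w)
  }
  raw <- utils::read.csv(p, check.names = FALSE)
  df <- data.frame(group = if (table_id == "wt_whole_area") "WT" else "3xTg-AD",
                   eye = "combined",
                   age_months = raw$age_months,
                   layer = raw$layer,
                   region = "whole",
                   mean_um = raw$mean_um,
                   sd_um = raw$sd_um,
                   n = as.integer(raw$n))
  new_normative_db(df, provenance = "packaged")
}

#' Sum of normative cell means across layers
#'
#' Adds the cell means of the requested layers for one `(group, eye, age,
#' region)` key, e.g. to form the photoreceptor/RPE outer-retina aggregate
#' IS + OS + RPE. Standard deviations are not combined, as between-layer
#' covariances are unknown.
#'
#' @param db a `normative_db`.
#' @param layers character vector of layer names.
#' @param group,age_months,region,eye cell key fields.
#' @return scalar sum of means, um.
#' @export
#' @examples
#' db <- load_packaged("wt_whole_area")
#' aggregate_cells(db, c("IS", "OS", "RPE"), "WT", 4)
aggregate_cells <- function(db, layers, group, age_months, region = "whole",
                            eye = "combined") {
  sum(vapply(layers, function(l)
    db_lookup(db, group, eye, age_months, l, region)$mean, numeric(1)))
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample two-sided KS test of a sample against a normal distribution.
#' By default the reference normal uses the sample's own mean and sd, as in
#' routine cohort normality screening; note that estimating the parameters
#' from the same sample makes the plain KS p-value conservative. The
#' `"lilliefors"` method applies the Lilliefors correction for exactly this
#' case. Fixed `mean`/`sd` can be supplied to test against known parameters.
#'
#' @param values numeric sample, `n >= 5`.
#' @param method `"ks"` (plain) or `"lilliefors"`.
#' @param mean,sd optional fixed reference parameters (plain KS only).
#' @return list with `statistic` and `p`.
#' @export
ks_normality <- function(values, method = c("ks", "lilliefors"),
                         mean = NULL, sd = NULL) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("need at least 5 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate (constant) sample: normality test undefined", call. = FALSE)
  if (method == "lilliefors") {
    if (!is.null(mean) || !is.null(sd))
      stop("fixed parameters apply to the plain KS method only", call. = FALSE)
    fit <- nortest::lillie.test(values)
    return(list(statistic = unname(fit$statistic), p = fit$p.value))
  }
  m <- mean %||% base::mean(values)
  s <- sd %||% stats::sd(values)
  fit <- suppressWarnings(stats::ks.test(values, "pnorm", m, s))
  list(statistic = unname(fit$statistic), p = fit$p.value)
}

#' Write / read a normative database as CSV
#'
#' Dialect: UTF-8, comma-separated, `.` decimal, columns `group`, `eye`,
#' `age_months`, `layer`, `region`, `mean_um`, `sd_um`, `n`. Numbers are
#' written with full precision (`format = "%.17g"` equivalent) so a
#' round-trip reproduces every cell exactly.
#'
#' @param db a `normative_db`.
#' @param path output/input CSV path.
#' @param provenance provenance tag for the loaded database.
#' @return `write_normative_csv` returns `path` invisibly;
#'   `read_normative_csv` returns a `normative_db`.
#' @export
write_normative_csv <- function(db, path) {
  stopifnot(inherits(db, "normative_db"))
  df <- as.data.frame(db)
  df$mean_um <- vapply(df$mean_um, function(v) sprintf("%.17g", v), character(1))
  df$sd_um <- vapply(df$sd_um, function(v) sprintf("%.17g", v), character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_normative_csv
#' @export
read_normative_csv <- function(path, provenance = "built") {
  if (!file.exists(path)) stop_keyed("database file not found: %s", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  new_normative_db(df, provenance = provenance)
}
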