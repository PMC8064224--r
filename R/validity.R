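# Per-value validity criteria and block aggregation.

#' Default validity rules for thickness values
#'
#' Builds the ordered list of per-position predicates applied by
#' [apply_validity_criteria()]: non-negativity, per-layer physiological
#' bounds, and a robust z-score rule flagging values far from the map's
#' median in MAD units (the MAD uses the usual 1.4826 normal-consistency
#' factor). The default upper bound is deliberately generous - three times a
#' reference mean for the layer - and configurable.
#'
#' @param lower_um,upper_um physiological bounds in um.
#' @param robust_z_threshold maximum allowed `|value - median| / MAD`;
#'   `Inf` disables the rule. If the MAD is zero (constant map) the rule
#'   passes everywhere.
#' @return list of predicate functions `f(values, valid) -> logical matrix`.
#' @export
validity_rules <- function(lower_um = 0, upper_um = Inf, robust_z_threshold = 6) {
  rules <- list(
    nonnegative = function(values, valid) values >= 0,
    bounds = function(values, valid) values >= lower_um & values <= upper_um
  )
  if (is.finite(robust_z_threshold)) {
    rules$robust_z <- function(values, valid) {
      med <- stats::median(values[valid])
      s <- stats::mad(values[valid])
      if (!is.finite(s) || s == 0) return(matrix(TRUE, nrow(values), ncol(values)))
      abs(values - med) / s <= robust_z_threshold
    }
  }
  rules
}

# Upper physiological bound derived from a normative database cell:
# 3x the age-matched whole-area mean.
default_upper_bound <- function(db, group, eye, age_months, layer) {
  3 * db_lookup(db, group, eye, age_months, layer, "whole")$mean
}

#' Apply validity criteria to a thickness map
#'
#' The map's validity mask becomes the conjunction of its current mask and
#' every rule's per-position outcome; rules only ever invalidate. Rules see
#' the mask as it was on entry (they are evaluated on the same input, not
#' chained), which keeps the result independent of rule order.
#'
#' @param map a `thickness_map`.
#' @param rules list of predicates as produced by [validity_rules()].
#' @return the map with an updated validity mask.
#' @export
apply_validity_criteria <- function(map, rules = validity_rules()) {
  stopifnot(inherits(map, "thickness_map"))
  if (length(rules) == 0L) {
    warning("empty rule list: validity mask unchanged", call. = FALSE)
    return(map)
  }
  valid0 <- map$valid
  out <- valid0
  for (rule in rules) out <- out & rule(map$values, valid0)
  map$valid <- out
  map
}

#' Crop and aggregate a thickness map into 3 x 3 blocks
#'
#' The 512 x 512 map is cropped centrally to 510 x 510 (one row and column
#' removed at each edge) and partitioned into nine 170 x 170 blocks, indexed
#' 1..9 row-major from the top-left of the standardized map. Each block's
#' mean is taken over its valid positions only, and a block is retained when
#' at least 90% of its 28,900 positions are valid - the boundary is
#' inclusive, and the comparison is done in integer arithmetic so that
#' exactly 90% retains.
#'
#' @param map a standardized `thickness_map`.
#' @param retention_threshold minimum valid fraction for block retention.
#' @return an object of class `block_grid`: list with `block_means` (3 x 3 um,
#'   `NA` where not retained or empty), `valid_counts` (3 x 3 integer),
#'   `block_valid` (3 x 3 logical) and inherited metadata.
#' @export
crop_and_block <- function(map, retention_threshold = 0.9) {
  stopifnot(inherits(map, "thickness_map"))
  if (!all(dim(map$values) == c(GRID_N, GRID_N)))
    stop_keyed("thickness grid must be %d x %d", GRID_N, GRID_N)
  if (map$orientation != "standardized")
    stop("map must be standardized before block aggregation", call. = FALSE)
  crop_idx <- 2:(GRID_N - 1L)
  vals <- map$values[crop_idx, crop_idx]
  valid <- map$valid[crop_idx, crop_idx]
  total <- BLOCK_N * BLOCK_N
  # threshold as an exact rational: retain iff valid_count / total >= p/q
  frac <- round(retention_threshold * 1e6)
  means <- matrix(NA_real_, 3L, 3L)
  counts <- matrix(0L, 3L, 3L)
  keep <- matrix(FALSE, 3L, 3L)
  for (b in 1:9) {
    bb <- block_bounds(b)
    v <- vals[bb$rows, bb$cols]
    ok <- valid[bb$rows, bb$cols]
    cnt <- sum(ok)
    br <- (b - 1L) %/% 3L + 1L
    bc <- (b - 1L) %% 3L + 1L
    counts[br, bc] <- cnt
    keep[br, bc] <- (cnt * 1e6 >= frac * total)
    if (cnt > 0L) means[br, bc] <- mean(v[ok])
  }
  means[!keep] <- NA_real_
  structure(list(
    block_means = means, valid_counts = counts, block_valid = keep,
    layer = map$layer, eye = map$eye, group = map$group,
    age_months = map$age_months, subject = map$subject
  ), class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat("<block_grid> ", x$layer, ", ", x$group, " ", x$eye, " age ",
      x$age_months, " mo, subject ", x$subject, "\n", sep = "")
  m <- x$block_means
  for (r in 1:3)
    cat(" ", paste(sprintf("%8s", ifelse(is.na(m[r, ]), "dropped",
                                         sprintf("%.2f", m[r, ]))),
                   collapse = " "), "\n")
  invisible(x)
}

#' Tidy per-block table from block grids
#'
#' @param grids a `block_grid` or list of them.
#' @return data.frame with columns `subject`, `group`, `eye`, `age_months`,
#'   `layer`, `block`, `mean_um`, `valid_count`, `retained`.
#' @export
block_grid_to_df <- function(grids) {
  if (inherits(grids, "block_grid")) grids <- list(grids)
  do.call(rbind, lapply(grids, function(g) {
    b <- 1:9
    br <- (b - 1L) %/% 3L + 1L
    bc <- (b - 1L) %% 3L + 1L
    data.frame(subject = g$subject, group = g$group, eye = g$eye,
               age_months = g$age_months, layer = g$layer, block = b,
               mean_um = g$block_means[cbind(br, bc)],
               valid_count = g$valid_counts[cbind(br, bc)],
               retained = g$block_valid[cbind(br, bc)])
  }))
}
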