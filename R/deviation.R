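# Normative deviation scoring of individual eyes.

#' Normative deviation score of a single thickness value
#'
#' Standardizes a thickness against a normative cell and returns the
#' two-sided tail probability of the reference normal generating a value at
#' least as far from its mean: `z = (thickness - mean)/sd`,
#' `p = 2 * (1 - Phi(|z|))`. The p-value is 1.00 at the normative mean and
#' decreases monotonically towards the tails; values below and above the
#' mean at the same distance receive the same p with opposite direction.
#'
#' @param thickness_um observed thickness, um.
#' @param cell normative cell: list with `mean`, `sd` (um), `sd > 0`.
#' @return list with `z`, `p`, `direction` (`"below"`, `"at"`, `"above"`).
#' @export
#' @examples
#' deviation_score(20, list(mean = 20, sd = 1))  # p = 1 at the mean
deviation_score <- function(thickness_um, cell) {
  if (!is.list(cell) || is.null(cell$mean) || is.null(cell$sd))
    stop("cell must provide mean and sd", call. = FALSE)
  if (!is.finite(cell$sd) || cell$sd <= 0)
    stop("degenerate reference: cell sd must be > 0", call. = FALSE)
  z <- (thickness_um - cell$mean) / cell$sd
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  direction <- if (z == 0) "at" else if (z < 0) "below" else "above"
  list(z = z, p = p, direction = direction)
}

#' Normative deviation map for one eye
#'
#' Scores each retained block of an eye's 3 x 3 block grid against the
#' matching normative cells, giving per-block signed z scores, two-sided
#' normative p-values and thinning/thickening directions. Blocks that failed
#' the 90% retention rule are marked invalid and not scored.
#'
#' @param grid a `block_grid` (standardized orientation).
#' @param db a `normative_db` with block cells for the grid's layer/age.
#' @param group reference group (default `"WT"`: deviations are read against
#'   the wild-type normative data).
#' @param eye reference eye key; `"combined"` (default) uses the pooled-eyes
#'   cells.
#' @return an object of class `deviation_map`: list of 3 x 3 matrices `z`,
#'   `p`, `thickness_um`, `valid`, character matrix `direction`, plus
#'   metadata.
#' @export
deviation_map <- function(grid, db, group = "WT", eye = "combined") {
  stopifnot(inherits(grid, "block_grid"), inherits(db, "normative_db"))
  z <- p <- matrix(NA_real_, 3L, 3L)
  direction <- matrix(NA_character_, 3L, 3L)
  for (b in 1:9) {
    br <- (b - 1L) %/% 3L + 1L
    bc <- (b - 1L) %% 3L + 1L
    if (!grid$block_valid[br, bc]) next
    cell <- db_lookup(db, group, eye, grid$age_months, grid$layer,
                      sprintf("block%d", b))
    s <- deviation_score(grid$block_means[br, bc], cell)
    z[br, bc] <- s$z
    p[br, bc] <- s$p
    direction[br, bc] <- s$direction
  }
  structure(list(z = z, p = p, direction = direction,
                 thickness_um = grid$block_means, valid = grid$block_valid,
                 layer = grid$layer, age_months = grid$age_months,
                 subject = grid$subject, reference_group = group),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  cat("<deviation_map> ", x$layer, ", subject ", x$subject, " vs ",
      x$reference_group, " normals, age ", x$age_months, " mo\n", sep = "")
  for (r in 1:3) {
    cells <- vapply(1:3, function(c) {
      if (!x$valid[r, c]) return("   n/a   ")
      sprintf("%6.1f p=%.2f", x$thickness_um[r, c], x$p[r, c])
    }, character(1))
    cat(" ", paste(cells, collapse = " | "), "\n")
  }
  invisible(x)
}

#' Color rendering specification of a deviation map
#'
#' Encodes the clinical reading convention: blue for thickness below the
#' normative average, red for above, with color intensity `1 - p` increasing
#' as the value becomes more extreme (white at the mean). Invalid blocks are
#' neutral gray. Each block carries its thickness (1 decimal) and p-value
#' (2 decimals) annotation.
#'
#' @param map a `deviation_map`.
#' @return data.frame with one row per block: `block`, `row`, `col`,
#'   `intensity`, `direction`, `color` (hex), `label`.
#' @export
render_deviation <- function(map) {
  stopifnot(inherits(map, "deviation_map"))
  out <- lapply(1:9, function(b) {
    r <- (b - 1L) %/% 3L + 1L
    c <- (b - 1L) %% 3L + 1L
    if (!map$valid[r, c] || is.na(map$p[r, c])) {
      return(data.frame(block = b, row = r, col = c, intensity = NA_real_,
                        direction = NA_character_, color = "#BDBDBD",
                        label = "n/a"))
    }
    i <- 1 - map$p[r, c]
    col <- switch(map$direction[r, c],
                  below = grDevices::rgb(1 - i, 1 - i, 1),
                  above = grDevices::rgb(1, 1 - i, 1 - i),
                  at = "#FFFFFF")
    data.frame(block = b, row = r, col = c, intensity = i,
               direction = map$direction[r, c], color = col,
               label = sprintf("%.1f\np=%.2f", map$thickness_um[r, c],
                               map$p[r, c]))
  })
  do.call(rbind, out)
}

#' Plot a deviation map
#'
#' Draws the 3 x 3 rendering of [render_deviation()] with base graphics.
#'
#' @param x a `deviation_map`.
#' @param main plot title.
#' @param ... ignored.
#' @return the rendering data.frame, invisibly.
#' @export
plot.deviation_map <- function(x, main = NULL, ...) {
  spec <- render_deviation(x)
  main <- main %||% sprintf("%s, subject %s vs %s normals",
                            x$layer, x$subject, x$reference_group)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 3), ylim = c(0, 3), asp = 1)
  graphics::title(main = main)
  for (i in seq_len(nrow(spec))) {
    r <- spec$row[i]; c <- spec$col[i]
    graphics::rect(c - 1, 3 - r, c, 4 - r, col = spec$color[i], border = "gray40")
    graphics::text(c - 0.5, 3.5 - r, gsub("\n", "\n", spec$label[i]), cex = 0.8)
  }
  invisible(spec)
}

#' Tidy export of a deviation map
#'
#' @param map a `deviation_map`.
#' @param path optional CSV output path.
#' @return data.frame with `block`, `thickness_um`, `z`, `p`, `direction`.
#' @export
deviation_to_df <- function(map, path = NULL) {
  stopifnot(inherits(map, "deviation_map"))
  b <- 1:9
  r <- (b - 1L) %/% 3L + 1L
  c <- (b - 1L) %% 3L + 1L
  df <- data.frame(subject = map$subject, layer = map$layer,
                   age_months = map$age_months, block = b,
                   thickness_um = map$thickness_um[cbind(r, c)],
                   z = map$z[cbind(r, c)], p = map$p[cbind(r, c)],
                   direction = map$direction[cbind(r, c)])
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
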