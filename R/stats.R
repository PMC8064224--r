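# Cross-sectional and longitudinal statistics.

#' Significance tier of a p-value
#'
#' Maps a p-value onto the fixed 5% / 1% / 0.1% reporting levels. Boundaries
#' are strict: `p = 0.05` is not significant.
#'
#' @param p probability in `[0, 1]`.
#' @return one of `"ns"`, `"5%"`, `"1%"`, `"0.1%"`.
#' @export
p_tier <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  if (p < 0.001) "0.1%" else if (p < 0.01) "1%" else if (p < 0.05) "5%" else "ns"
}

new_comparison_result <- function(statistic, df, p, extra = list()) {
  p <- min(max(p, 0), 1)
  structure(c(list(statistic = statistic, df = df, p = p, tier = p_tier(p)),
              extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  df <- if (length(x$df) == 2L)
    sprintf("df = (%.0f, %.0f)", x$df[1], x$df[2])
  else sprintf("df = %.2f", x$df)
  cat(sprintf("<comparison> stat = %.3f, %s, p = %.4g [%s]\n",
              x$statistic, df, x$p, x$tier))
  invisible(x)
}

as_summary_stats <- function(x, label) {
  if (is.numeric(x)) {
    if (length(x) < 2L) stop_keyed("sample '%s' needs n >= 2", label)
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
  } else if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    if (x$n < 2L) stop_keyed("summary '%s' needs n >= 2", label)
    x[c("mean", "sd", "n")]
  } else {
    stop_keyed("'%s' must be a numeric sample or a (mean, sd, n) summary", label)
  }
}

#' Two-sample t test, from raw samples or summary statistics
#'
#' Compares two independent groups with a two-sided t test, accepting either
#' raw numeric samples or `(mean, sd, n)` summaries (e.g. normative cells),
#' so published tables can be compared directly. The default is Welch's
#' unequal-variance test with Satterthwaite degrees of freedom; the pooled
#' Student variant is available for sensitivity checks.
#'
#' @param a,b numeric samples, or lists/cells with `mean`, `sd`, `n`.
#' @param variant `"welch"` or `"student"`.
#' @return a `comparison_result` with `statistic` (t), `df`, `p`, `tier`,
#'   and `mean_diff` (`a - b`).
#' @export
#' @examples
#' two_sample_test(list(mean = 20.62, sd = 0.61, n = 103),
#'                 list(mean = 18.96, sd = 0.73, n = 84))
two_sample_test <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  sa <- as_summary_stats(a, "a")
  sb <- as_summary_stats(b, "b")
  if (sa$sd == 0 && sb$sd == 0 && sa$mean == sb$mean)
    stop("both samples are constant and equal: t statistic undefined",
         call. = FALSE)
  if (variant == "welch") {
    va <- sa$sd^2 / sa$n
    vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  } else {
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / (sa$n + sb$n - 2)
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  }
  t <- (sa$mean - sb$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  new_comparison_result(t, df, p, list(mean_diff = sa$mean - sb$mean,
                                       variant = variant))
}

#' Nasal-temporal asymmetry test across eyes
#'
#' On standardized maps the nasal side is the right column of blocks
#' (3, 6, 9) and the temporal side the left column (1, 4, 7). For each eye
#' the contrast is the mean of its retained nasal-column block means minus
#' the mean of its retained temporal-column block means; a paired two-sided
#' t test is run on the per-eye contrasts.
#'
#' @param grids list of `block_grid` for one layer, standardized orientation.
#' @return a `comparison_result` with `mean_diff` (positive = nasal thicker)
#'   and `n_eyes`.
#' @export
asymmetry_test <- function(grids) {
  if (inherits(grids, "block_grid")) grids <- list(grids)
  diffs <- vapply(grids, function(g) {
    idx <- function(b) cbind((b - 1L) %/% 3L + 1L, (b - 1L) %% 3L + 1L)
    nas <- g$block_means[idx(NASAL_BLOCKS)]
    tem <- g$block_means[idx(TEMPORAL_BLOCKS)]
    nas <- nas[!is.na(nas)]
    tem <- tem[!is.na(tem)]
    if (!length(nas) || !length(tem)) return(NA_real_)
    mean(nas) - mean(tem)
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2L)
    stop("need at least 2 eyes with valid nasal and temporal blocks",
         call. = FALSE)
  fit <- stats::t.test(diffs)
  new_comparison_result(unname(fit$statistic), unname(fit$parameter),
                        fit$p.value,
                        list(mean_diff = mean(diffs), n_eyes = length(diffs)))
}

#' Complete-case longitudinal table
#'
#' Retains only eyes measured at all four monthly ages, as required by the
#' repeated-measures analysis, and reports how many were dropped.
#'
#' @param records data.frame with columns `subject`, `age_months`, `value`
#'   (one row per subject x age; `NA` values count as missing).
#' @param ages required time points.
#' @return an object of class `longitudinal_table`: list with `values`
#'   (complete-case subjects x ages matrix, rownames = subject), `ages`,
#'   and `n_dropped`.
#' @export
select_complete_cases <- function(records, ages = 1:4) {
  stopifnot(all(c("subject", "age_months", "value") %in% names(records)))
  subjects <- unique(records$subject)
  wide <- matrix(NA_real_, length(subjects), length(ages),
                 dimnames = list(subjects, paste0("m", ages)))
  for (i in seq_len(nrow(records))) {
    a <- match(records$age_months[i], ages)
    if (!is.na(a)) wide[as.character(records$subject[i]), a] <- records$value[i]
  }
  complete <- stats::complete.cases(wide)
  structure(list(values = wide[complete, , drop = FALSE], ages = ages,
                 n_dropped = sum(!complete)),
            class = "longitudinal_table")
}

as_long_matrix <- function(table) {
  y <- if (inherits(table, "longitudinal_table")) table$values else as.matrix(table)
  if (anyNA(y))
    stop("longitudinal table contains missing values; run select_complete_cases first",
         call. = FALSE)
  y
}

#' One-within-factor repeated-measures ANOVA
#'
#' Tests whether a thickness summary changes over the four monthly time
#' points, using the subject x time interaction as the error term:
#' `F = MS_time / MS_(subject x time)` with `(t - 1)` and `(n - 1)(t - 1)`
#' degrees of freedom. The uncorrected p-value is primary; the
#' Greenhouse-Geisser epsilon and adjusted p are reported alongside for
#' sphericity-sensitive reading.
#'
#' @param table a `longitudinal_table` or complete numeric matrix
#'   (subjects x time points), `>= 3` subjects.
#' @return list with `F`, `df_time`, `df_error`, `p`, `gg_epsilon`, `p_gg`
#'   and the sums of squares.
#' @export
ranova <- function(table) {
  y <- as_long_matrix(table)
  n <- nrow(y)
  t <- ncol(y)
  if (n < 3L) stop("need at least 3 complete-case subjects", call. = FALSE)
  if (t < 2L) stop("need at least 2 time points", call. = FALSE)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  time_means <- colMeans(y)
  ss_subj <- t * sum((subj_means - grand)^2)
  ss_time <- n * sum((time_means - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_subj - ss_time
  df_time <- t - 1
  df_err <- (n - 1) * (t - 1)
  scale <- max(ss_total, .Machine$double.eps)
  if (ss_time / scale < 1e-12) {
    # no time variation at all: report a null result rather than 0/0
    return(list(F = 0, df_time = df_time, df_error = df_err, p = 1,
                gg_epsilon = NA_real_, p_gg = 1,
                ss_time = ss_time, ss_error = ss_err, ss_subject = ss_subj))
  }
  if (ss_err / scale < 1e-12)
    stop("degenerate table: zero subject-by-time error (e.g. duplicated subjects)",
         call. = FALSE)
  F <- (ss_time / df_time) / (ss_err / df_err)
  p <- stats::pf(F, df_time, df_err, lower.tail = FALSE)
  eps <- gg_epsilon(y)
  p_gg <- stats::pf(F, df_time * eps, df_err * eps, lower.tail = FALSE)
  list(F = F, df_time = df_time, df_error = df_err, p = p,
       gg_epsilon = eps, p_gg = p_gg,
       ss_time = ss_time, ss_error = ss_err, ss_subject = ss_subj)
}

# Greenhouse-Geisser sphericity epsilon from the sample covariance of the
# subjects x time matrix.
gg_epsilon <- function(y) {
  S <- stats::cov(y)
  t <- ncol(S)
  num <- (t * (mean(diag(S)) - mean(S)))^2
  den <- (t - 1) * (sum(S^2) - 2 * t * sum(rowMeans(S)^2) + t^2 * mean(S)^2)
  if (den <= 0) return(1)
  min(max(num / den, 1 / (t - 1)), 1)
}

#' Tukey pairwise comparisons of the time-point means
#'
#' Tukey honest-significant-difference comparisons of all time-point pairs,
#' using the repeated-measures within-subject error term: for means
#' `m_j, m_k`, `q = |m_j - m_k| / sqrt(MS_error / n)` referred to the
#' studentized-range distribution with `t` means and the RANOVA error df.
#'
#' @param table a `longitudinal_table` or complete numeric matrix.
#' @return data.frame with one row per pair: `age_a`, `age_b`, `mean_diff`,
#'   `statistic` (q), `p`, `p_unadjusted` (the same contrast and error term
#'   without the multiplicity correction; never smaller than `p`), `tier`.
#' @export
tukey_pairwise <- function(table) {
  y <- as_long_matrix(table)
  ages <- if (inherits(table, "longitudinal_table")) table$ages else seq_len(ncol(y))
  fit <- ranova(table)
  if (fit$F == 0 && fit$ss_error == 0)
    stop("degenerate table: no within-subject variability", call. = FALSE)
  n <- nrow(y)
  t <- ncol(y)
  ms_err <- fit$ss_error / fit$df_error
  means <- colMeans(y)
  pairs <- utils::combn(t, 2)
  res <- apply(pairs, 2, function(jk) {
    d <- means[jk[1]] - means[jk[2]]
    q <- abs(d) / sqrt(ms_err / n)
    p <- stats::ptukey(q, nmeans = t, df = fit$df_error, lower.tail = FALSE)
    # same contrast and error term without the multiplicity correction
    p_un <- 2 * stats::pt(-q / sqrt(2), fit$df_error)
    c(d = d, q = q, p = p, p_un = p_un)
  })
  data.frame(age_a = ages[pairs[1, ]], age_b = ages[pairs[2, ]],
             mean_diff = res["d", ], statistic = res["q", ],
             p = res["p", ], p_unadjusted = res["p_un", ],
             tier = vapply(res["p", ], p_tier, character(1)))
}
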