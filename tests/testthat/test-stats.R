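# Group and longitudinal statistics.

test_that("significance tiers are a strict threshold function of p", {
  expect_identical(p_tier(0.5), "ns")
  expect_identical(p_tier(0.05), "ns")       # boundary is strict
  expect_identical(p_tier(0.049), "5%")
  expect_identical(p_tier(0.01), "5%")
  expect_identical(p_tier(0.0099), "1%")
  expect_identical(p_tier(0.001), "1%")
  expect_identical(p_tier(0.0001), "0.1%")
})

test_that("two-sample test agrees with stats::t.test on raw samples", {
  set.seed(42)
  a <- rnorm(25, 10, 2)
  b <- rnorm(31, 11, 3)
  ours <- two_sample_test(a, b)
  ref <- t.test(a, b)  # independent oracle (Welch)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  ref_s <- t.test(a, b, var.equal = TRUE)
  ours_s <- two_sample_test(a, b, variant = "student")
  expect_equal(ours_s$p, ref_s$p.value, tolerance = 1e-12)
  # summary-form input reproduces the raw-sample result exactly
  sa <- list(mean = mean(a), sd = sd(a), n = length(a))
  sb <- list(mean = mean(b), sd = sd(b), n = length(b))
  expect_equal(two_sample_test(sa, sb)$p, ours$p, tolerance = 1e-12)
})

test_that("identical samples give t = 0, p = 1; degenerate input errors", {
  x <- rnorm(10)
  res <- two_sample_test(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_identical(res$tier, "ns")
  expect_error(two_sample_test(list(mean = 1, sd = 0, n = 5),
                               list(mean = 1, sd = 0, n = 5)),
               "undefined")
})

test_that("Welch df never exceeds the pooled df, with equality when balanced", {
  set.seed(7)
  for (i in 1:20) {
    na <- sample(3:40, 1); nb <- sample(3:40, 1)
    res <- two_sample_test(rnorm(na), rnorm(nb, 0, runif(1, 0.2, 3)))
    expect_lte(res$df, na + nb - 2 + 1e-9)
  }
  bal <- two_sample_test(list(mean = 0, sd = 2, n = 15),
                         list(mean = 1, sd = 2, n = 15))
  expect_equal(bal$df, 28, tolerance = 1e-12)
})

test_that("published INL summaries at four months separate at the 0.1% tier", {
  wt <- db_lookup(load_packaged("wt_whole_area"), "WT", "combined", 4, "INL")
  ad <- db_lookup(load_packaged("ad_whole_area"), "3xTg-AD", "combined", 4, "INL")
  res <- two_sample_test(wt, ad)
  expect_equal(res$statistic, 16.6, tolerance = 0.01)
  expect_identical(res$tier, "0.1%")
})

test_that("asymmetry contrast detects a nasal-thicker cohort and errors on one eye", {
  set.seed(88)
  grids <- lapply(1:30, function(i)
    make_grid(matrix(200 + rnorm(9, 0, 0.5), 3, 3) +
                matrix(rep(c(-1, 0, 1), each = 3), 3, 3),
              subject = sprintf("e%02d", i)))
  res <- asymmetry_test(grids)
  expect_gt(res$mean_diff, 0)
  expect_identical(res$tier, "0.1%")
  expect_error(asymmetry_test(grids[1]), "at least 2 eyes")
})

test_that("asymmetry test keeps its nominal size under the symmetric null", {
  set.seed(303)
  rej <- replicate(500, {
    grids <- lapply(1:12, function(i) make_grid(matrix(rnorm(9, 200, 1), 3, 3)))
    asymmetry_test(grids)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("asymmetry detected on generated maps with the default gradient", {
  db <- load_packaged("wt_whole_area")
  cohort <- sample_cohort(db, "WT", "OD", 1, n_eyes = 12, seed = 55,
                          between_eye_sd_scale = 0,
                          config_base = sim_config(nasal_temporal_slope_um = 2,
                                                   noise_sd = 2))
  grids <- lapply(cohort, function(i)
    crop_and_block(standardize_orientation(compute_thickness_map(i, "TRT"))))
  res <- asymmetry_test(grids)
  expect_gt(res$mean_diff, 0)
  expect_true(res$tier != "ns")
})

test_that("complete-case selection keeps only four-age subjects", {
  rec <- data.frame(subject = rep(c("a", "b", "c"), each = 4),
                    age_months = rep(1:4, 3),
                    value = rnorm(12))
  rec <- rec[-7, ]  # subject b loses age 3
  tab <- select_complete_cases(rec)
  expect_identical(rownames(tab$values), c("a", "c"))
  expect_identical(tab$n_dropped, 1L)
  full <- select_complete_cases(data.frame(subject = rep("a", 4),
                                           age_months = 1:4, value = 1:4))
  expect_identical(full$n_dropped, 0L)
  empty <- select_complete_cases(data.frame(subject = character(),
                                            age_months = numeric(),
                                            value = numeric()))
  expect_identical(nrow(empty$values), 0L)
  expect_identical(empty$n_dropped, 0L)
})

test_that("repeated-measures ANOVA matches brute-force sums of squares", {
  y <- matrix(c(10, 12, 11, 13,
                9, 11, 12, 12,
                11, 13, 13, 15), 3, 4, byrow = TRUE)
  fit <- ranova(y)
  # brute force on the 12 values
  grand <- mean(y)
  ss_time <- 3 * sum((colMeans(y) - grand)^2)
  ss_subj <- 4 * sum((rowMeans(y) - grand)^2)
  ss_err <- sum((y - grand)^2) - ss_time - ss_subj
  F_expected <- (ss_time / 3) / (ss_err / 6)
  expect_equal(fit$F, F_expected, tolerance = 1e-12)
  expect_identical(c(fit$df_time, fit$df_error), c(3, 6))
  expect_equal(fit$p, pf(F_expected, 3, 6, lower.tail = FALSE), tolerance = 1e-12)
  # independent oracle: aov with a subject error stratum
  d <- data.frame(y = as.vector(y),
                  subj = factor(rep(1:3, 4)), time = factor(rep(1:4, each = 3)))
  ref <- summary(aov(y ~ time + Error(subj/time), data = d))
  ref_tab <- ref[["Error: subj:time"]][[1]]
  expect_equal(fit$F, ref_tab["time", "F value"], tolerance = 1e-9)
  expect_equal(fit$p, ref_tab["time", "Pr(>F)"], tolerance = 1e-9)
})

test_that("ranova handles constant-over-time and degenerate tables", {
  const <- matrix(rep(c(5, 7, 9), 4), 3, 4)
  fit <- ranova(const)
  expect_equal(fit$F, 0)
  expect_equal(fit$p, 1)
  dup <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4)  # one subject duplicated
  expect_error(ranova(dup), "degenerate")
  expect_error(ranova(matrix(1:8, 2, 4)), "at least 3")
  with_na <- matrix(rnorm(12), 3, 4); with_na[2, 3] <- NA
  expect_error(ranova(with_na), "missing")
})

test_that("ranova holds its nominal type-I error under the null", {
  set.seed(2024)
  rej <- replicate(1000, {
    y <- matrix(rnorm(30 * 4, 200, 3), 30, 4) + rnorm(30, 0, 2)  # subject effect
    ranova(y)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("Greenhouse-Geisser epsilon is bounded and softens the p-value", {
  set.seed(31)
  y <- matrix(rnorm(20 * 4), 20, 4)
  y[, 4] <- y[, 4] * 3 + y[, 3]       # break sphericity
  y <- sweep(y, 2, c(0, 0.5, 1, 2), `+`)  # real time effect, F > 1
  fit <- ranova(y)
  expect_gt(fit$F, 1)
  expect_gte(fit$gg_epsilon, 1 / 3)
  expect_lte(fit$gg_epsilon, 1)
  expect_gte(fit$p_gg, fit$p)
})

test_that("Tukey pairwise contrasts behave across null and shifted designs", {
  set.seed(99)
  y_null <- matrix(rnorm(30 * 4, 100, 1), 30, 4)
  tk <- tukey_pairwise(y_null)
  expect_identical(nrow(tk), 6L)
  shifted <- y_null
  err_sd <- sqrt(ranova(y_null)$ss_error / ranova(y_null)$df_error)
  shifted[, 2] <- shifted[, 2] + 10 * err_sd
  tk2 <- tukey_pairwise(shifted)
  involving2 <- tk2$age_a == 2 | tk2$age_b == 2
  expect_true(all(tk2$tier[involving2] == "0.1%"))
  # Tukey correction never reports a smaller p than the unadjusted contrast
  expect_true(all(tk2$p >= tk2$p_unadjusted - 1e-12))
})

test_that("equal time-point means yield no significant Tukey pair", {
  set.seed(17)
  base <- matrix(rnorm(12 * 4, 50, 1), 12, 4)
  centered <- sweep(base, 2, colMeans(base)) + 50  # identical column means
  tk <- tukey_pairwise(centered)
  expect_true(all(tk$tier == "ns"))
  expect_true(all(abs(tk$mean_diff) < 1e-9))
})
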