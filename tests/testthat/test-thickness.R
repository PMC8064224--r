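# Thickness maps, orientation, validity, block aggregation.

test_that("thickness is the interface distance scaled by the axial pitch", {
  iset <- generate_interfaces(sim_config(noise_sd = 0, seed = 2))
  # overwrite with a known depth difference: 146.2857 px -> 200.00 um
  iset$surfaces[, , 1] <- 100
  iset$surfaces[, , 9] <- 100 + 146.2857
  trt <- compute_thickness_map(iset, "TRT")
  expect_equal(trt$values[40, 400], 146.2857 * 1400 / 1024, tolerance = 1e-12)
  expect_equal(round(trt$values[1, 1], 2), 200.00)
  # coincident boundaries give zero thickness
  iset$surfaces[, , 2] <- iset$surfaces[, , 1]
  expect_true(all(compute_thickness_map(iset, "RNFL-GCL")$values == 0))
  expect_error(compute_thickness_map(iset, "GCL"), "unknown layer")
})

test_that("the eight layer maps telescope exactly to the TRT map", {
  iset <- generate_interfaces(sim_config(noise_sd = 3, seed = 8))
  acc <- matrix(0, 512, 512)
  for (l in retina_layers()) acc <- acc + compute_thickness_map(iset, l)$values
  trt <- compute_thickness_map(iset, "TRT")$values
  expect_equal(acc, trt, tolerance = 1e-9)
})

test_that("orientation standardization mirrors OS only and is idempotent", {
  od <- make_map(matrix(runif(512 * 512), 512, 512), orientation = "native",
                 eye = "OD")
  expect_identical(standardize_orientation(od)$values, od$values)
  os_vals <- matrix(runif(512 * 512), 512, 512)
  os <- make_map(os_vals, orientation = "native", eye = "OS")
  std <- standardize_orientation(os)
  expect_identical(std$values[, 512], os_vals[, 1])
  expect_identical(std$values[, 512:1], os_vals)
  expect_message(again <- standardize_orientation(std), "already standardized")
  expect_identical(again$values, std$values)
})

test_that("validity rules invalidate out-of-range and outlier positions", {
  vals <- matrix(100, 512, 512)
  vals[3, 7] <- -1
  map <- apply_validity_criteria(make_map(vals),
                                 validity_rules(robust_z_threshold = Inf))
  expect_false(map$valid[3, 7])
  expect_identical(sum(!map$valid), 1L)
  # a 5,000-pixel patch at 10x the typical value trips the robust-z rule
  vals2 <- matrix(rnorm(512 * 512, 100, 1), 512, 512)
  vals2[1:50, 1:100] <- 1000
  map2 <- apply_validity_criteria(make_map(vals2), validity_rules())
  med <- median(vals2)
  expect_gt(abs(1000 - med) / mad(vals2), 6)  # oracle on the toy map
  expect_true(all(!map2$valid[1:50, 1:100]))
  expect_true(mean(map2$valid) > 0.95)
  expect_warning(apply_validity_criteria(make_map(100), list()), "empty rule")
})

test_that("block aggregation reproduces brute-force 170x170 averages", {
  grad <- outer(seq_len(512), seq_len(512), function(r, c) 0.3 * r + 0.7 * c)
  grid <- crop_and_block(make_map(grad))
  crop <- grad[2:511, 2:511]
  for (b in 1:9) {
    bb <- retnorm:::block_bounds(b)
    expected <- mean(crop[bb$rows, bb$cols])  # brute force
    expect_equal(grid$block_means[(b - 1) %/% 3 + 1, (b - 1) %% 3 + 1],
                 expected, tolerance = 1e-12)
  }
  expect_true(all(grid$block_valid))
  expect_true(all(grid$valid_counts == 28900L))
})

test_that("the 90% retention rule is inclusive at the boundary", {
  for (pct in c(89, 90, 91)) {
    map <- make_map(50)
    b5 <- retnorm:::block_bounds_full(5)
    n_invalid <- round((1 - pct / 100) * 28900)
    bad <- arrayInd(seq_len(n_invalid), c(170, 170))
    map$valid[cbind(b5$rows[bad[, 1]], b5$cols[bad[, 2]])] <- FALSE
    grid <- crop_and_block(map)
    expect_identical(grid$block_valid[2, 2], pct >= 90)
  }
})

test_that("constant maps propagate through blocks and whole-area means", {
  grid <- crop_and_block(make_map(123.4))
  expect_true(all(abs(grid$block_means - 123.4) < 1e-12))
  expect_equal(whole_area_mean(make_map(123.4)), 123.4)
  half <- make_map(cbind(matrix(10, 512, 256), matrix(30, 512, 256)))
  expect_equal(whole_area_mean(half), 20)
})

test_that("whole-area mean fails on mostly- or fully-invalid maps", {
  map <- make_map(100)
  map$valid[, 1:300] <- FALSE
  expect_error(whole_area_mean(map), "valid")
  map$valid[] <- FALSE
  expect_error(whole_area_mean(map), "no valid")
  native <- make_map(100, orientation = "native")
  expect_error(whole_area_mean(native), "standardized")
  expect_error(crop_and_block(native), "standardized")
})

test_that("with full validity, block means average to the cropped-map mean", {
  vals <- matrix(rnorm(512 * 512, 150, 4), 512, 512)
  grid <- crop_and_block(make_map(vals))
  expect_equal(mean(grid$block_means), mean(vals[2:511, 2:511]),
               tolerance = 1e-9)
})

test_that("radial profile bins by disc distance and sees the decline", {
  expect_true(all(abs(radial_profile(make_map(77))$mean_um - 77) < 1e-12))
  # two-bin oracle on a step function of disc distance
  d <- sqrt(outer((seq_len(512) - 512.5)^2, (seq_len(512) - 256.5)^2, `+`))
  step <- ifelse(d <= median(d), 10, 20)
  prof <- radial_profile(make_map(step), n_bins = 2)
  expect_equal(nrow(prof), 2L)
  expect_lt(prof$mean_um[1], prof$mean_um[2])
  # generated decline with distance: strictly decreasing bin means at noise 0
  iset <- generate_interfaces(sim_config(noise_sd = 0, disc_distance_slope_um = -8,
                                         nasal_temporal_slope_um = 0, seed = 4))
  tm <- standardize_orientation(compute_thickness_map(iset, "TRT"))
  prof2 <- radial_profile(tm, n_bins = 8)
  expect_true(all(diff(prof2$mean_um) < 0))
  expect_error(radial_profile(tm, disc_centre = c(NA, 1)), "finite")
  expect_error(radial_profile(tm, n_bins = 1), "n_bins")
})
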