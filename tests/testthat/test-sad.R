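# The volume-denominator cases are checked against brute-force enumeration;
# the cylinder denominator (the calibration default) must integrate to 100.

test_that("delta fluence concentrates SAD at its depth layer", {
  v <- array(0, c(64, 64, 64))
  v[32, 32, 6] <- 3.7   # voxel center (31.5, 31.5), inside the ROI; z layer 5
  for (den in c("volume", "cylinder")) {
    p <- compute_sad_profile(v, denominator = den)
    expect_equal(p$sad_pct[6], 100)
    expect_equal(sum(p$sad_pct), 100)
  }
})

test_that("uniform fluence matches the brute-force voxel-in-disk count", {
  v <- array(1, c(64, 64, 64))
  p <- compute_sad_profile(v, denominator = "volume")
  # independent enumeration over the 64 x 64 plane
  count <- 0L
  for (i in 1:64) for (j in 1:64) {
    if ((i - 0.5 - 32)^2 + (j - 0.5 - 32)^2 <= 100) count <- count + 1L
  }
  expect_equal(p$sad_pct, rep(100 * count / 64^3, 64))
  pc <- compute_sad_profile(v, denominator = "cylinder")
  expect_equal(pc$sad_pct, rep(100 / 64, 64))
})

test_that("two equal point masses split SAD 50/50 under the volume reference", {
  v <- array(0, c(64, 64, 64))
  v[32, 32, 4] <- 2   # inside ROI, depth layer 3
  v[2, 2, 4] <- 2     # far outside ROI, same depth
  p <- compute_sad_profile(v, denominator = "volume")
  expect_equal(p$sad_pct[4], 50)
  # cylinder reference only sees the ROI mass
  pc <- compute_sad_profile(v, denominator = "cylinder")
  expect_equal(pc$sad_pct[4], 100)
})

test_that("SAD rejects degenerate volumes and is scale invariant", {
  expect_error(compute_sad_profile(array(0, c(8, 8, 8))), "all-zero")
  expect_error(compute_sad_profile(array(-1, c(8, 8, 8))), "non-negative")
  set.seed(42)
  v <- array(stats::rexp(16^3), c(16, 16, 16))
  p1 <- compute_sad_profile(v)
  p2 <- compute_sad_profile(7.3 * v)
  expect_equal(p1$sad_pct, p2$sad_pct)
})

test_that("SAD of a real fluence volume is a proper depth distribution", {
  sim <- ref_sim()
  p_cyl <- compute_sad_profile(sim$fluence)
  expect_equal(sum(p_cyl$sad_pct), 100, tolerance = 1e-9)
  expect_true(all(p_cyl$sad_pct >= 0))
  p_vol <- compute_sad_profile(sim$fluence, denominator = "volume")
  expect_lte(sum(p_vol$sad_pct), 100)
  expect_true(all(p_vol$sad_pct <= 100))
})

test_that("mean profile across heads is the unweighted per-depth average", {
  mk <- function(sds, vals) {
    out <- data.frame(depth_mm = seq_along(vals) - 1, sad_pct = vals)
    attr(out, "sds") <- sds
    class(out) <- c("sad_profile", "data.frame")
    out
  }
  one <- mk(19, c(1, 2, 3))
  expect_equal(mean_sad_across_heads(list(one))$sad_pct, c(1, 2, 3))
  two <- mean_sad_across_heads(list(mk(19, c(2, 2, 2)), mk(19, c(4, 6, 2))))
  expect_equal(two$sad_pct, c(3, 4, 2))
  expect_error(mean_sad_across_heads(list(mk(19, 1:3), mk(21, 1:3))),
               "same sds")
})

test_that("box statistics follow the interpolated-quantile convention", {
  b <- sad_box_stats(1:8)
  expect_equal(b$median, 4.5)
  expect_equal(b$q1, 2.75)
  expect_equal(b$q3, 6.25)
  expect_length(b$outliers, 0)

  flat <- sad_box_stats(rep(2, 6))
  expect_equal(flat$q3 - flat$q1, 0)
  expect_length(flat$outliers, 0)

  out <- sad_box_stats(c(rep(1, 7), 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 1)

  expect_error(sad_box_stats(1:3), "at least 4")
})

test_that("path-length histograms report per-bin mean weights", {
  one <- pathlength_histogram(data.frame(weight = 0.5, path_mm = 30), n_bins = 1)
  expect_equal(one$mean_weight, 0.5)
  expect_equal(one$count, 1L)

  two <- pathlength_histogram(
    data.frame(weight = c(0.2, 0.4), path_mm = c(10, 50)), n_bins = 2)
  expect_equal(two$mean_weight, c(0.2, 0.4))
  expect_equal(two$breaks, c(10, 30, 50))

  expect_error(pathlength_histogram(data.frame(weight = numeric(),
                                               path_mm = numeric())),
               "no detected")
})

test_that("detected mean path length grows with separation", {
  ph <- build_phantom(8, 6.8, 5.55)
  near <- run_simulation(ph, sds = 8, n_photons = 4e4, seed = 21)
  far <- run_simulation(ph, sds = 16, n_photons = 4e4, seed = 22)
  expect_gt(nrow(near$detected), 5)
  expect_gt(nrow(far$detected), 5)
  expect_gt(mean(far$detected$path_mm), mean(near$detected$path_mm))
})
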