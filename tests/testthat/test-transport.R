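test_that("simulations are bit-reproducible under a fixed seed", {
  ph <- build_phantom(8, 6.8, 5.55)
  a <- run_simulation(ph, sds = 21, n_photons = 3000, seed = 99)
  b <- run_simulation(ph, sds = 21, n_photons = 3000, seed = 99)
  expect_identical(a$fluence$values, b$fluence$values)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$detected, b$detected)
  c <- run_simulation(ph, sds = 21, n_photons = 3000, seed = 100)
  expect_false(identical(a$fluence$values, c$fluence$values))
})

test_that("source and detector flank the plane center at sds/2", {
  ph <- build_phantom(8, 6.8, 5.55)
  sim <- run_simulation(ph, sds = 5, n_photons = 10, seed = 1)
  expect_equal(sim$config$source_xy, c(29.5, 32))
  expect_equal(sim$config$detector_xy, c(34.5, 32))
  expect_error(run_simulation(ph, sds = 70, n_photons = 10, seed = 1),
               "domain")
})

test_that("energy ledger closes and roulette residual balances exactly", {
  sim <- ref_sim()   # head #1, sds 29, 1e5 photons
  l <- sim$ledger
  # exact bookkeeping identity including the roulette adjustments
  expect_equal(l$launched + l$roulette_residual, l$absorbed + l$escaped,
               tolerance = 1e-9)
  # statistical closure: roulette is unbiased
  expect_lt(abs(l$launched - l$absorbed - l$escaped) / l$launched, 0.005)
  expect_lte(l$detected, l$escaped)
  expect_true(all(sim$fluence$values >= 0))
  expect_true(all(is.finite(sim$fluence$values)))
  expect_true(all(sim$detected$weight > 0 & sim$detected$weight <= 1))
  expect_true(all(sim$detected$path_mm > 0))
})

test_that("ballistic limit: pure absorber deposits along a single column", {
  ph <- build_phantom(10, 10, 10,
                      optical_properties = uniform_props(1, 0, 0, 1))
  sim <- run_simulation(ph, sds = 10, n_photons = 2000, seed = 5,
                        half_angle = 1e-9)
  v <- sim$fluence$values
  src <- sim$config$source_xy
  ix <- floor(src[1]) + 1; iy <- floor(src[2]) + 1
  expect_gt(sum(v[ix, iy, ]), 0)
  off <- v; off[ix, iy, ] <- 0
  expect_equal(sum(off), 0)
  # everything is eventually absorbed
  expect_equal(sim$ledger$absorbed + sim$ledger$escaped, 2000,
               tolerance = 1e-9)
})

test_that("Beer-Lambert limit: log-fluence slope recovers -mu_a within 2%", {
  ph <- build_phantom(10, 10, 10,
                      optical_properties = uniform_props(0.1, 0, 0, 1))
  sim <- run_simulation(ph, sds = 10, n_photons = 1e5, seed = 31,
                        half_angle = 1e-9)
  v <- sim$fluence$values
  col <- vapply(1:50, function(z) sum(v[, , z]), numeric(1))
  z_mid <- (1:50) - 0.5
  fit <- stats::lm(log(col) ~ z_mid)
  expect_equal(unname(stats::coef(fit)[2]), -0.1, tolerance = 0.02)
})

test_that("low-scattering CSF-like medium carries light deeper than scalp", {
  csf_ph <- build_phantom(10, 10, 10,
                          optical_properties = uniform_props(0.004, 0.3, 0, 1.33))
  scl_ph <- build_phantom(10, 10, 10,
                          optical_properties = uniform_props(0.016, 19, 0.9, 1.6))
  a <- run_simulation(csf_ph, sds = 20, n_photons = 5000, seed = 77)
  b <- run_simulation(scl_ph, sds = 20, n_photons = 5000, seed = 77)
  frac_deep <- function(s) {
    v <- s$fluence$values
    sum(v[, , 21:64]) / sum(v)
  }
  expect_gt(frac_deep(a), frac_deep(b))
})

test_that("fluence decays with distance from the source in shell averages", {
  sim <- ref_sim()
  v <- sim$fluence$values
  src <- sim$config$source_xy
  d <- dim(v)
  xs <- (seq_len(d[1]) - 0.5); ys <- (seq_len(d[2]) - 0.5); zs <- (seq_len(d[3]) - 0.5)
  r <- sqrt(outer(outer((xs - src[1])^2, (ys - src[2])^2, "+"), zs^2, "+"))
  shells <- findInterval(r, seq(0, 30, by = 3))
  means <- vapply(1:8, function(k) mean(v[shells == k]), numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("detected weight is symmetric under source-detector exchange", {
  ph <- build_phantom(8, 6.8, 5.55)
  nm <- ph$layers$name
  props <- ph$props
  args <- list(
    z_upper = ph$z_boundaries,
    mu_a = vapply(props[nm], function(p) p$mu_a, numeric(1)),
    mu_s = vapply(props[nm], function(p) p$mu_s, numeric(1)),
    g = vapply(props[nm], function(p) p$g, numeric(1)),
    n_idx = vapply(props[nm], function(p) p$n, numeric(1)),
    n_void = 1, domain_shape = ph$domain_shape, voxel_size = 1,
    half_angle_deg = 70, det_radius = 1.5,
    n_photons = 5e4, roulette_threshold = 1e-4, roulette_survival = 0.1,
    entry_refraction = 0L)
  fwd <- do.call(fnirscal:::.mc_run_cpp, c(args, list(
    src_x = 27, src_y = 32, det_x = 37, det_y = 32, seed = 404)))
  rev <- do.call(fnirscal:::.mc_run_cpp, c(args, list(
    src_x = 37, src_y = 32, det_x = 27, det_y = 32, seed = 405)))
  se <- function(r) sqrt(sum(r$det_weight^2))
  expect_gt(length(fwd$det_weight), 0)
  expect_lt(abs(fwd$detected - rev$detected),
            3 * sqrt(se(fwd)^2 + se(rev)^2))
})
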