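# Synthetic surrogates with known closed-form inverses exercise the
# inversion logic independently of the Monte Carlo pipeline.

fit_known_surface <- function(f) {
  gr <- expand.grid(sds = seq(19, 39, by = 2), depth = 10:20)
  gr$sad <- f(gr$sds, gr$depth)
  sad_surrogate(sad ~ sds + depth, gr, kind = "gpr")
}

test_that("separation recommendation inverts a known monotone surface", {
  # SAD = (sds - 19)/4 %, depth-independent: level L crossed at 19 + 4 L
  m <- fit_known_surface(function(s, d) (s - 19) / 4)
  rep <- sds_for_depth(m, depth = 15)
  expect_equal(rep$recommended_mm[rep$level_pct == 2], 27.0, tolerance = 0.05)
  expect_equal(rep$recommended_mm[rep$level_pct == 4], 35.0, tolerance = 0.05)
  # max SAD on [19, 39] is 5: level 6 is out of reach
  expect_false(rep$feasible[rep$level_pct == 6])
  expect_true(is.na(rep$recommended_mm[rep$level_pct == 6]))

  expect_error(sds_for_depth(m, depth = 25), "\\[10, 20\\]")
  expect_error(sds_for_depth(m, depth = 15, levels = 0), "levels")
})

test_that("depth recommendation returns the deepest depth meeting the level", {
  # SAD = 30 - depth % at any separation: level L met down to depth 30 - L
  m <- fit_known_surface(function(s, d) 30 - d)
  rep <- depth_for_sds(m, sds = 29, levels = 12, level_bounds = c(1, 20))
  expect_equal(rep$recommended_mm, 18.0, tolerance = 0.05)
  # a level met everywhere in [10, 20] reports the domain bottom
  all_ok <- depth_for_sds(m, sds = 29, levels = 5)
  expect_equal(all_ok$recommended_mm, 20.0)
  # an unobtainable level is infeasible
  none <- depth_for_sds(m, sds = 29, levels = 22, level_bounds = c(1, 25))
  expect_false(none$feasible)

  expect_error(depth_for_sds(m, sds = 45), "\\[19, 39\\]")
  expect_error(depth_for_sds(m, sds = 29, levels = 0), "levels")
})

test_that("feasibility reflects the surrogate maximum over separations", {
  # max SAD (s - 19)/3.9 = 5.13% at s = 39: level 5 in reach, level 6 not
  m <- fit_known_surface(function(s, d) (s - 19) / 3.9)
  expect_true(feasibility(m, depth = 14, level = 5))
  expect_false(feasibility(m, depth = 14, level = 6))
  expect_error(feasibility(m, depth = 9, level = 1), "\\[10, 20\\]")
})

test_that("feasible levels are downward closed and reports are well-formed", {
  m <- fit_known_surface(function(s, d) (s - 19) / 4 + 0.02 * (20 - d))
  rep <- sds_for_depth(m, depth = 12)
  f <- rep$feasible
  # once a level is infeasible, all higher levels are infeasible
  expect_true(all(diff(as.integer(f)) <= 0))
  ok <- rep$recommended_mm[rep$feasible]
  expect_true(all(ok >= 19 & ok <= 39))
  # 0.1 mm resolution
  expect_equal(ok, round(ok, 1))
})

test_that("recommended separations invert back to the requested level", {
  m <- fit_known_surface(function(s, d) (s - 19) / 4 + 0.05 * (15 - d))
  for (depth in c(10.5, 14.8, 19.2)) {
    rep <- sds_for_depth(m, depth = depth)
    for (i in which(rep$feasible)) {
      nd <- data.frame(sds = rep$recommended_mm[i], depth = depth)
      expect_lt(abs(predict(m, nd) - rep$level_pct[i]), 0.05)
    }
  }
})

test_that("calibration reports print and export as CSV", {
  m <- fit_known_surface(function(s, d) (s - 19) / 4)
  rep <- sds_for_depth(m, depth = 15)
  expect_output(print(rep), "sds_from_depth")
  f <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(rep, f)
  back <- utils::read.csv(f)
  expect_equal(back$level_pct, rep$level_pct)
  expect_equal(back$feasible, rep$feasible)

  fs <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(m, fs, sds = seq(19, 39, 5), depths = c(10, 15, 20))
  surf <- utils::read.csv(fs)
  expect_named(surf, c("sds_mm", "depth_mm", "sad_pct"))
  expect_equal(nrow(surf), 15L)
})
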