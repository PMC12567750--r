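test_that("dataset assembly builds the 121-row standardized grid", {
  profs <- synthetic_mean_profiles()
  ds <- assemble_sad_dataset(profs)
  expect_equal(nrow(ds), 121L)
  expect_equal(sort(unique(ds$sds)), seq(19, 39, by = 2))
  expect_equal(sort(unique(ds$depth)), 10:20)
  # depths outside the 10-20 mm calibration band are not included
  expect_false(any(ds$depth < 10 | ds$depth > 20))

  # stored standardization constants reproduce z-scored columns
  ctr <- attr(ds, "center"); scl <- attr(ds, "scale")
  zs <- scale(as.data.frame(ds)[c("sds", "depth", "sad")])
  expect_equal(unname((ds$sad - ctr["sad"]) / scl["sad"]), unname(zs[, "sad"]))
  expect_equal(mean((ds$sds - ctr["sds"]) / scl["sds"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd((ds$depth - ctr["depth"]) / scl["depth"]), 1,
               tolerance = 1e-12)

  expect_error(assemble_sad_dataset(profs[-3]), "missing mean SAD")
})

test_that("standardization round-trips to machine precision", {
  ds <- assemble_sad_dataset(synthetic_mean_profiles())
  ctr <- attr(ds, "center"); scl <- attr(ds, "scale")
  x <- ds$sad
  expect_equal((x - ctr["sad"]) / scl["sad"] * scl["sad"] + ctr["sad"],
               x, ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("adjusted R-squared matches hand computations and guards", {
  expect_equal(adjusted_r2(1:5, 1:5), 1)
  # SSE = 0.08, SST = 10 -> R2 = 0.992, adjusted = 1 - 0.008 * 4/2 = 0.984
  expect_equal(adjusted_r2(1:5, c(1.1, 1.9, 3.2, 3.9, 5.1)), 0.984)
  # predicting the mean: R2 = 0, adjusted negative
  expect_equal(adjusted_r2(1:5, rep(3, 5)), 1 - 4 / 2)
  expect_error(adjusted_r2(1:3, 1:3), "n > p")
  expect_error(adjusted_r2(rep(2, 5), rep(2, 5)), "constant")
})

test_that("GPR recovers a noiseless smooth surface to high precision", {
  dat <- smooth_surface_data()
  m <- sad_surrogate(sad ~ sds + depth, dat, kind = "gpr")
  pred <- predict(m, dat)
  expect_lt(max(abs(pred - dat$sad)), 1e-3)
  expect_gt(m$train_adj_r2, 0.999999)

  # interpolation contract: training value within 2 posterior sd (plus a
  # floor for near-noiseless fits)
  pr <- predict(m, dat[17, ], se.fit = TRUE)
  expect_lt(abs(pr$fit - dat$sad[17]), 2 * pr$se.fit + 1e-3)

  # off-grid prediction stays close to the generating surface mid-domain
  nd <- data.frame(sds = 30, depth = 15.5)
  expect_equal(predict(m, nd), 0.01 * 30 * (20 - 15.5), tolerance = 1e-2)
})

test_that("SVR fits the smooth surface and stays below GPR accuracy", {
  dat <- smooth_surface_data()
  sv <- sad_surrogate(sad ~ sds + depth, dat, kind = "svr")
  r2 <- 1 - sum((dat$sad - predict(sv, dat))^2) /
    sum((dat$sad - mean(dat$sad))^2)
  expect_gt(r2, 0.99)
  gp <- sad_surrogate(sad ~ sds + depth, dat, kind = "gpr")
  expect_lte(sv$train_adj_r2, gp$train_adj_r2)
  # degenerate response is rejected
  flat <- dat; flat$sad <- 5
  expect_error(sad_surrogate(sad ~ sds + depth, flat, kind = "svr"),
               "zero variance|interquartile")
})

test_that("GPR posterior mean agrees with an independent implementation", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  X <- as.matrix(expand.grid(x1 = seq(-1, 1, 0.5), x2 = seq(-1, 1, 0.5)))
  y <- sin(X[, 1]) + 0.5 * cos(2 * X[, 2])
  ls <- c(1, 1); sf2 <- 1; sn2 <- 0.01
  K <- fnirscal:::gpr_kernel(X, X, ls, sf2)
  L <- chol(K + diag(sn2, nrow(X)))
  core <- list(ls = ls, sf2 = sf2, sn2 = sn2, L = L,
               alpha = backsolve(L, forwardsolve(t(L), y)), X = X, y = y)
  Xnew <- as.matrix(expand.grid(x1 = c(-0.7, 0.3), x2 = c(-0.2, 0.8)))
  ours <- fnirscal:::gpr_predict_core(core, Xnew, se = TRUE)

  # kernlab rbfdot: exp(-sigma |x - x'|^2) == our kernel for sigma = 1/(2 l^2)
  kl <- kernlab::gausspr(X, y, kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * ls[1]^2)),
                         var = sn2, scaled = FALSE)
  expect_equal(ours$mean, as.numeric(kernlab::predict(kl, Xnew)),
               tolerance = 1e-6)
  expect_true(all(ours$sd >= 0))
})

test_that("LOOCV mechanics: finite scores, permutation invariance, gap", {
  # three collinear points: finite score over 3 folds
  toy <- data.frame(sds = c(19, 29, 39), depth = c(10, 15, 20),
                    sad = c(1, 2, 3))
  cv <- loocv(toy, kind = "gpr")
  expect_equal(cv$n_folds, 3L)
  expect_true(is.finite(cv$adjusted_r2))

  set.seed(8)
  dat <- smooth_surface_data(sds = seq(19, 39, by = 4), depths = seq(10, 20, 2.5))
  dat$sad <- dat$sad + stats::rnorm(nrow(dat), sd = 0.02)
  cv1 <- loocv(dat, kind = "gpr")
  cv2 <- loocv(dat[sample(nrow(dat)), ], kind = "gpr")
  expect_equal(cv1$adjusted_r2, cv2$adjusted_r2, tolerance = 1e-8)

  # held-out score does not beat the training fit on the same data
  m <- sad_surrogate(sad ~ sds + depth, dat, kind = "gpr")
  expect_lte(cv1$adjusted_r2, m$train_adj_r2 + 1e-8)
})

test_that("surrogate model methods expose the usual modelling surface", {
  dat <- smooth_surface_data()
  m <- sad_surrogate(sad ~ sds + depth, dat, kind = "gpr")
  expect_s3_class(m, "sad_surrogate")
  expect_named(coef(m), c("length_scale_sds", "length_scale_depth",
                          "signal_sd", "noise_sd"))
  expect_equal(residuals(m), dat$sad - fitted(m))
  expect_output(print(m), "GPR")
  sm <- summary(m)
  expect_output(print(sm), "adjusted R")
  draws <- simulate(m, nsim = 3, seed = 1,
                    newdata = data.frame(sds = c(25, 33), depth = c(12, 18)))
  expect_equal(dim(draws), c(2L, 3L))
  expect_error(predict(m, data.frame(sds = 30)), "missing predictor")

  sv <- sad_surrogate(sad ~ sds + depth, dat, kind = "svr")
  expect_named(coef(sv), c("kernel_scale", "cost", "epsilon"))
  expect_error(predict(sv, dat, se.fit = TRUE), "GPR")
  expect_error(simulate(sv), "GPR")
})

test_that("surrogate JSON persistence reproduces predictions", {
  dat <- smooth_surface_data()
  m <- sad_surrogate(sad ~ sds + depth, dat, kind = "gpr")
  f <- withr::local_tempfile(fileext = ".json")
  write_surrogate_json(m, f)
  m2 <- read_surrogate_json(f)
  nd <- data.frame(sds = c(20, 30, 38), depth = c(11, 15, 19))
  expect_equal(predict(m2, nd), predict(m, nd), tolerance = 1e-8)
})
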