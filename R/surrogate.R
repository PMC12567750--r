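#' Assemble the SAD calibration dataset
#'
#' Builds the training table for the sensitivity surrogate from cross-head
#' mean SAD profiles: one row per (separation, depth) cell, with separations
#' 19-39 mm in 2 mm steps and depths restricted to the cortical target range
#' 10-20 mm (11 x 11 = 121 rows on the default grid). Per-column
#' standardization constants (mean/sd for both inputs and the output) are
#' computed and stored with the dataset; models are fitted on the
#' standardized values.
#'
#' @param mean_profiles List of `sad_profile` objects (one per separation,
#'   typically from [mean_sad_across_heads()]).
#' @param sds Required separations in mm (default `seq(19, 39, by = 2)`); an
#'   error is raised if any is missing from `mean_profiles`.
#' @param depths Depth grid in mm (default `10:20`).
#' @return Object of class `sad_dataset`: data frame with columns `sds`,
#'   `depth`, `sad`, and attributes `center` and `scale` (named length-3
#'   vectors).
#' @export
assemble_sad_dataset <- function(mean_profiles, sds = seq(19, 39, by = 2),
                                 depths = 10:20) {
  have <- vapply(mean_profiles, function(p) as.numeric(attr(p, "sds")),
                 numeric(1))
  missing_sds <- setdiff(sds, have)
  if (length(missing_sds))
    stop("missing mean SAD profile(s) for sds = ",
         paste(missing_sds, collapse = ", "), " mm")
  rows <- lapply(sds, function(s) {
    p <- mean_profiles[[which(have == s)[1]]]
    idx <- match(depths, p$depth_mm)
    if (anyNA(idx))
      stop("profile at sds ", s, " lacks depth(s) ",
           paste(depths[is.na(idx)], collapse = ", "), " mm")
    data.frame(sds = s, depth = depths, sad = p$sad_pct[idx])
  })
  df <- do.call(rbind, rows)
  as_sad_dataset(df)
}

#' Mark a data frame of (sds, depth, sad) rows as a calibration dataset
#'
#' Computes and attaches the per-column standardization constants.
#'
#' @param df Data frame with numeric columns `sds`, `depth`, `sad`.
#' @return A `sad_dataset`.
#' @export
as_sad_dataset <- function(df) {
  stopifnot(all(c("sds", "depth", "sad") %in% names(df)))
  cols <- c("sds", "depth", "sad")
  center <- vapply(df[cols], mean, numeric(1))
  scale <- vapply(df[cols], stats::sd, numeric(1))
  if (any(scale == 0))
    stop("degenerate dataset: column(s) ",
         paste(cols[scale == 0], collapse = ", "), " have zero variance")
  structure(df[cols], center = center, scale = scale,
            class = c("sad_dataset", "data.frame"))
}

standardize_cols <- function(df, center, scale) {
  out <- df
  for (nm in names(center))
    if (nm %in% names(out)) out[[nm]] <- (out[[nm]] - center[nm]) / scale[nm]
  out
}

# ---- Gaussian process internals (squared-exponential ARD kernel) ----------

gpr_kernel <- function(X1, X2, ls, sf2) {
  d2 <- matrix(0, nrow(X1), nrow(X2))
  for (k in seq_len(ncol(X1)))
    d2 <- d2 + outer(X1[, k], X2[, k], "-")^2 / ls[k]^2
  sf2 * exp(-0.5 * d2)
}

# Cholesky with escalating jitter; the kernel matrix of near-duplicate
# inputs is numerically singular without it
gpr_chol <- function(K, jitter = 1e-8) {
  for (j in jitter * 10^(0:6)) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) {
      if (j > jitter)
        message("gpr: kernel matrix required extra jitter (", j, ")")
      return(L)
    }
  }
  stop("gpr: kernel matrix is singular even with jitter")
}

gpr_nll <- function(theta, X, y) {
  ls <- exp(theta[1:2]); sf2 <- exp(2 * theta[3]); sn2 <- exp(2 * theta[4])
  K <- gpr_kernel(X, X, ls, sf2) + diag(sn2, nrow(X))
  L <- tryCatch(chol(K + diag(1e-8, nrow(X))), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(L))) +
               0.5 * length(y) * log(2 * pi))
}

# Marginal-likelihood hyperparameter fit with a fixed, deterministic set of
# restarts (no RNG: reproducibility by construction).
fit_gpr_core <- function(X, y) {
  starts <- expand.grid(log_l = log(c(0.3, 1, 3)),
                        log_sn = log(c(0.3, 0.01)))
  lower <- c(log(1e-2), log(1e-2), log(1e-3), log(1e-6))
  upper <- c(log(1e2), log(1e2), log(1e3), log(10))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- c(starts$log_l[i], starts$log_l[i], 0, starts$log_sn[i])
    fit <- tryCatch(
      stats::optim(th0, gpr_nll, X = X, y = y, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("gpr: hyperparameter optimisation failed")
  th <- best$par
  ls <- exp(th[1:2]); sf2 <- exp(2 * th[3]); sn2 <- exp(2 * th[4])
  K <- gpr_kernel(X, X, ls, sf2) + diag(sn2, nrow(X))
  L <- gpr_chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  list(ls = ls, sf2 = sf2, sn2 = sn2, L = L, alpha = alpha,
       nll = best$value, X = X, y = y)
}

gpr_predict_core <- function(core, Xnew, se = FALSE) {
  Ks <- gpr_kernel(Xnew, core$X, core$ls, core$sf2)
  mu <- as.numeric(Ks %*% core$alpha)
  if (!se) return(list(mean = mu))
  v <- forwardsolve(t(core$L), t(Ks))
  var <- pmax(0, core$sf2 + core$sn2 - colSums(v^2))
  list(mean = mu, sd = sqrt(var))
}

# ---- The user-facing surrogate model --------------------------------------

#' Fit a sensitivity-at-depth surrogate model
#'
#' Fits a regression surrogate of SAD (%) over source-detector separation
#' and cortical depth, either a Gaussian process (squared-exponential ARD
#' kernel plus noise, hyperparameters by maximum marginal likelihood over a
#' fixed deterministic set of restarts) or an epsilon-SVR with RBF kernel
#' (kernel scale from the median pairwise distance; box constraint
#' `IQR(y)/1.349`; epsilon `IQR(y)/13.49`). Inputs and output are z-score
#' standardized before fitting; predictions are returned on the original
#' percentage scale.
#'
#' @param formula Model formula; the default and canonical form is
#'   `sad ~ sds + depth` (response and exactly two numeric predictors).
#' @param data A [as_sad_dataset()]/[assemble_sad_dataset()] object or any
#'   data frame with the formula's variables.
#' @param kind `"gpr"` (default) or `"svr"`.
#' @return Object of class `sad_surrogate` with methods [print], [summary],
#'   [coef], [predict], [fitted], [residuals], [plot] and (for GPR)
#'   [simulate].
#' @examples
#' grid <- expand.grid(sds = seq(19, 39, 2), depth = 10:20)
#' grid$sad <- 0.01 * grid$sds * (20 - grid$depth)
#' m <- sad_surrogate(sad ~ sds + depth, grid, kind = "gpr")
#' predict(m, data.frame(sds = 30, depth = 15))
#' @export
sad_surrogate <- function(formula = sad ~ sds + depth, data,
                          kind = c("gpr", "svr")) {
  kind <- match.arg(kind)
  mf <- stats::model.frame(formula, as.data.frame(data))
  if (ncol(mf) != 3L)
    stop("formula must have a response and exactly two predictors")
  yname <- names(mf)[1]
  xnames <- names(mf)[2:3]
  if (nrow(mf) < 2L)
    stop("too few rows to fit a surrogate")
  center <- vapply(mf, mean, numeric(1))
  scale <- vapply(mf, stats::sd, numeric(1))
  if (any(scale == 0))
    stop("degenerate data: zero variance in ",
         paste(names(mf)[scale == 0], collapse = ", "))
  Xs <- as.matrix(sweep(sweep(mf[xnames], 2, center[xnames]), 2,
                        scale[xnames], "/"))
  ys <- (mf[[yname]] - center[yname]) / scale[yname]

  if (kind == "gpr") {
    core <- fit_gpr_core(Xs, ys)
  } else {
    dists <- stats::dist(Xs)
    ks <- stats::median(dists)
    iqr_y <- stats::IQR(ys)
    if (iqr_y == 0)
      stop("svr: degenerate response (zero interquartile range)")
    core <- list(
      kernel_scale = ks, cost = iqr_y / 1.349, epsilon = iqr_y / 13.49,
      model = e1071::svm(x = Xs, y = ys, type = "eps-regression",
                         kernel = "radial", gamma = 1 / (2 * ks^2),
                         cost = iqr_y / 1.349, epsilon = iqr_y / 13.49,
                         scale = FALSE)
    )
  }
  obj <- structure(list(
    kind = kind, core = core, formula = formula,
    yname = yname, xnames = xnames,
    center = center, scale = scale,
    data = mf, n = nrow(mf)
  ), class = "sad_surrogate")
  obj$train_adj_r2 <- tryCatch(adjusted_r2(mf[[yname]], fitted(obj), p = 2),
                               error = function(e) NA_real_)
  obj
}

#' Predict from a fitted sensitivity surrogate
#'
#' @param object A [sad_surrogate()] fit.
#' @param newdata Data frame containing the predictor columns (defaults to
#'   the training data).
#' @param se.fit For GPR, also return the posterior standard deviation.
#' @param ... Unused.
#' @return Numeric vector of predicted SAD (%), or a list with `fit` and
#'   `se.fit` when `se.fit = TRUE`.
#' @export
predict.sad_surrogate <- function(object, newdata = NULL, se.fit = FALSE,
                                  ...) {
  if (is.null(newdata)) newdata <- object$data
  miss <- setdiff(object$xnames, names(newdata))
  if (length(miss))
    stop("newdata is missing predictor(s): ", paste(miss, collapse = ", "))
  Xs <- as.matrix(sweep(sweep(newdata[object$xnames], 2,
                              object$center[object$xnames]), 2,
                        object$scale[object$xnames], "/"))
  ysc <- object$scale[[object$yname]]
  yc <- object$center[[object$yname]]
  if (object$kind == "gpr") {
    pr <- gpr_predict_core(object$core, Xs, se = se.fit)
    fit <- pr$mean * ysc + yc
    if (se.fit) return(list(fit = fit, se.fit = pr$sd * ysc))
    return(fit)
  }
  if (se.fit)
    stop("se.fit is only available for the GPR surrogate")
  as.numeric(stats::predict(object$core$model, Xs)) * ysc + yc
}

#' @export
fitted.sad_surrogate <- function(object, ...) {
  predict(object, object$data)
}

#' @export
residuals.sad_surrogate <- function(object, ...) {
  object$data[[object$yname]] - fitted(object)
}

#' @export
coef.sad_surrogate <- function(object, ...) {
  if (object$kind == "gpr") {
    ysc <- object$scale[[object$yname]]
    c(length_scale_sds = object$core$ls[1],
      length_scale_depth = object$core$ls[2],
      signal_sd = sqrt(object$core$sf2) * ysc,
      noise_sd = sqrt(object$core$sn2) * ysc)
  } else {
    c(kernel_scale = object$core$kernel_scale,
      cost = object$core$cost, epsilon = object$core$epsilon)
  }
}

#' @export
print.sad_surrogate <- function(x, ...) {
  cat(sprintf("SAD surrogate (%s), %d training rows\n",
              toupper(x$kind), x$n))
  cat(sprintf("  %s over (%s); training adjusted R^2 = %.6f\n",
              x$yname, paste(x$xnames, collapse = ", "), x$train_adj_r2))
  co <- coef(x)
  cat("  ", paste(sprintf("%s = %.4g", names(co), co), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.sad_surrogate <- function(object, ...) {
  res <- residuals(object)
  out <- list(kind = object$kind, n = object$n, coef = coef(object),
              train_adj_r2 = object$train_adj_r2,
              rmse = sqrt(mean(res^2)), max_abs_resid = max(abs(res)))
  class(out) <- "summary.sad_surrogate"
  out
}

#' @export
print.summary.sad_surrogate <- function(x, ...) {
  cat(sprintf("SAD surrogate summary (%s)\n", toupper(x$kind)))
  cat(sprintf("  n = %d, training adjusted R^2 = %.6f\n", x$n, x$train_adj_r2))
  cat(sprintf("  RMSE = %.4g %%, max |residual| = %.4g %%\n",
              x$rmse, x$max_abs_resid))
  cat("  ", paste(sprintf("%s = %.4g", names(x$coef), x$coef),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Draw from the GPR posterior over the SAD surface
#'
#' @param object A GPR [sad_surrogate()] fit.
#' @param nsim Number of posterior draws.
#' @param seed Optional seed.
#' @param newdata Points at which to draw (default: training inputs).
#' @param ... Unused.
#' @return Matrix `nrow(newdata) x nsim` of SAD draws (%).
#' @export
simulate.sad_surrogate <- function(object, nsim = 1, seed = NULL,
                                   newdata = NULL, ...) {
  if (object$kind != "gpr")
    stop("posterior simulation is only available for the GPR surrogate")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$data
  Xs <- as.matrix(sweep(sweep(newdata[object$xnames], 2,
                              object$center[object$xnames]), 2,
                        object$scale[object$xnames], "/"))
  core <- object$core
  Ks <- gpr_kernel(Xs, core$X, core$ls, core$sf2)
  mu <- as.numeric(Ks %*% core$alpha)
  v <- forwardsolve(t(core$L), t(Ks))
  Kpp <- gpr_kernel(Xs, Xs, core$ls, core$sf2) + diag(core$sn2, nrow(Xs))
  S <- Kpp - crossprod(v)
  Ls <- gpr_chol((S + t(S)) / 2)
  draws <- mu + t(Ls) %*% matrix(stats::rnorm(nrow(Xs) * nsim), nrow(Xs))
  draws * object$scale[[object$yname]] + object$center[[object$yname]]
}

#' Plot the fitted SAD surface
#'
#' Filled-contour view of predicted SAD over the (separation, depth) domain,
#' with the training points overlaid.
#'
#' @param x A [sad_surrogate()] fit.
#' @param sds_range,depth_range Plot domain, mm.
#' @param n_grid Grid resolution per axis.
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.sad_surrogate <- function(x, sds_range = c(19, 39),
                               depth_range = c(10, 20), n_grid = 60, ...) {
  s <- seq(sds_range[1], sds_range[2], length.out = n_grid)
  d <- seq(depth_range[1], depth_range[2], length.out = n_grid)
  gr <- expand.grid(s, d)
  names(gr) <- x$xnames
  z <- matrix(predict(x, gr), n_grid, n_grid)
  graphics::filled.contour(
    s, d, z, xlab = "source-detector separation (mm)",
    ylab = "depth (mm)",
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::points(x$data[[x$xnames[1]]], x$data[[x$xnames[2]]],
                       pch = 16, cex = 0.4)
    }, ...)
  invisible(NULL)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` with `p` predictors; the surrogate
#' uses `p = 2` (separation and depth).
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @param p Number of predictors (default 2).
#' @return Adjusted R-squared (can be negative for models worse than the
#'   mean).
#' @examples
#' adjusted_r2(1:5, c(1.1, 1.9, 3.2, 3.9, 5.1))  # 0.984
#' @export
adjusted_r2 <- function(y, y_hat, p = 2) {
  n <- length(y)
  stopifnot(length(y_hat) == n)
  if (n <= p + 1)
    stop("adjusted R^2 needs n > p + 1 (n = ", n, ", p = ", p, ")")
  sse <- sum((y - y_hat)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("adjusted R^2 undefined for constant y")
  r2 <- 1 - sse / sst
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Leave-one-out cross-validation of a surrogate
#'
#' Refits the surrogate n times, each excluding one row, and scores the
#' held-out predictions with the adjusted R-squared (p = 2). For n <= p + 1,
#' where the adjustment denominator vanishes, the unadjusted R-squared is
#' reported instead.
#'
#' @param data Data frame with columns `sds`, `depth`, `sad` (or matching
#'   the formula).
#' @param kind `"gpr"` or `"svr"`.
#' @param formula Model formula (default `sad ~ sds + depth`).
#' @return Object of class `loocv_result`: list with `y`, `y_hat` (held-out
#'   predictions in row order), `adjusted_r2` and `n_folds`.
#' @export
loocv <- function(data, kind = c("gpr", "svr"),
                  formula = sad ~ sds + depth) {
  kind <- match.arg(kind)
  df <- as.data.frame(data)
  n <- nrow(df)
  if (n < 3L) stop("LOOCV needs at least 3 rows")
  yname <- all.vars(formula)[1]
  y_hat <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      sad_surrogate(formula, df[-i, , drop = FALSE], kind = kind),
      error = function(e) stop("LOOCV fold ", i, " failed: ",
                               conditionMessage(e)))
    y_hat[i] <- predict(fit, df[i, , drop = FALSE])
  }
  y <- df[[yname]]
  score <- if (n > 3) {
    adjusted_r2(y, y_hat, p = 2)
  } else {
    1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)
  }
  structure(list(y = y, y_hat = y_hat, adjusted_r2 = score, n_folds = n),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV over %d folds: adjusted R^2 = %.6f\n",
              x$n_folds, x$adjusted_r2))
  invisible(x)
}

#' Persist a surrogate model as JSON
#'
#' Stores the model kind, fitted hyperparameters (on the standardized
#' scale), standardization constants and the training rows.
#' [read_surrogate_json()] rebuilds the model from the stored
#' hyperparameters without re-optimising, so the round trip reproduces
#' predictions to JSON number precision.
#'
#' @param model A [sad_surrogate()] fit.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_surrogate_json <- function(model, file) {
  core_params <- if (model$kind == "gpr") {
    list(ls = model$core$ls, sf2 = model$core$sf2, sn2 = model$core$sn2)
  } else {
    list(kernel_scale = model$core$kernel_scale, cost = model$core$cost,
         epsilon = model$core$epsilon)
  }
  payload <- list(
    kind = model$kind,
    yname = model$yname, xnames = model$xnames,
    center = as.list(model$center), scale = as.list(model$scale),
    hyperparameters = core_params,
    training = model$data
  )
  # I(17) significant digits: doubles survive the JSON round trip exactly,
  # which matters because near-interpolating kernels amplify tiny
  # hyperparameter perturbations
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_surrogate_json
#' @export
read_surrogate_json <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  df <- as.data.frame(payload$training)
  yname <- payload$yname
  xnames <- payload$xnames
  center <- unlist(payload$center)[c(xnames, yname)]
  scale <- unlist(payload$scale)[c(xnames, yname)]
  hp <- payload$hyperparameters
  Xs <- as.matrix(sweep(sweep(df[xnames], 2, center[xnames]), 2,
                        scale[xnames], "/"))
  ys <- (df[[yname]] - center[[yname]]) / scale[[yname]]
  core <- if (payload$kind == "gpr") {
    ls <- unlist(hp$ls)
    K <- gpr_kernel(Xs, Xs, ls, hp$sf2) + diag(hp$sn2, nrow(Xs))
    L <- gpr_chol(K)
    list(ls = ls, sf2 = hp$sf2, sn2 = hp$sn2, L = L,
         alpha = backsolve(L, forwardsolve(t(L), ys)),
         nll = NA_real_, X = Xs, y = ys)
  } else {
    list(kernel_scale = hp$kernel_scale, cost = hp$cost,
         epsilon = hp$epsilon,
         model = e1071::svm(x = Xs, y = ys, type = "eps-regression",
                            kernel = "radial",
                            gamma = 1 / (2 * hp$kernel_scale^2),
                            cost = hp$cost, epsilon = hp$epsilon,
                            scale = FALSE))
  }
  obj <- structure(list(
    kind = payload$kind, core = core,
    formula = stats::reformulate(xnames, response = yname),
    yname = yname, xnames = xnames,
    center = center, scale = scale,
    data = df[c(yname, xnames)], n = nrow(df)
  ), class = "sad_surrogate")
  obj$train_adj_r2 <- tryCatch(adjusted_r2(df[[yname]], fitted(obj), p = 2),
                               error = function(e) NA_real_)
  obj
}
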