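#' @keywords internal
check_levels <- function(levels, level_bounds = c(1, 6)) {
  if (!length(levels) || any(!is.finite(levels)) ||
      any(levels < level_bounds[1]) || any(levels > level_bounds[2]))
    stop("SAD levels must lie in [", level_bounds[1], ", ",
         level_bounds[2], "] percent")
  sort(unique(levels))
}

predict_sad <- function(model, sds, depth) {
  nd <- data.frame(sds, depth)
  names(nd) <- model$xnames
  predict(model, nd)
}

# refine a bracketing interval [lo, hi] where f crosses `target` to tol
bisect_crossing <- function(f, lo, hi, target, tol = 0.01) {
  flo <- f(lo) - target
  fhi <- f(hi) - target
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid) - target
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Recommend source-detector separations for a target depth
#'
#' Inverts the fitted SAD surrogate at a fixed cortical depth: for each
#' requested sensitivity level L (%), the predicted SAD(sds, depth) curve is
#' scanned on a 0.1 mm separation grid over `[19, 39]` mm, the smallest
#' crossing of SAD = L is refined by bisection to 0.01 mm, and the result is
#' reported at 0.1 mm precision. A level is infeasible when the predicted
#' SAD never reaches it anywhere on the grid. For a GPR surrogate the
#' posterior standard deviation at each recommendation is attached as
#' advisory uncertainty.
#'
#' @param model A [sad_surrogate()] fit.
#' @param depth Target cortical depth in mm, within `[10, 20]`.
#' @param levels SAD thresholds in percent (default `1:6`).
#' @param sds_range Separation search interval in mm (default `c(19, 39)`).
#' @param level_bounds Allowed range for requested levels (default
#'   `c(1, 6)`, the span the tool is calibrated for).
#' @return Object of class `calibration_report`: data frame with columns
#'   `level_pct`, `recommended_mm` (NA when infeasible), `feasible`, and for
#'   GPR `sad_sd_pct`; query details in attributes.
#' @export
sds_for_depth <- function(model, depth, levels = 1:6,
                          sds_range = c(19, 39), level_bounds = c(1, 6)) {
  stopifnot(inherits(model, "sad_surrogate"))
  if (!is.finite(depth) || depth < 10 || depth > 20)
    stop("depth must lie in [10, 20] mm (got ", depth, ")")
  levels <- check_levels(levels, level_bounds)
  grid <- seq(sds_range[1], sds_range[2], by = 0.1)
  sad <- predict_sad(model, grid, depth)
  f <- function(s) predict_sad(model, s, depth)
  rec <- vapply(levels, function(L) {
    if (max(sad) < L) return(NA_real_)
    at <- which(sad >= L)
    first <- at[1]
    if (first == 1) return(grid[1])  # already above the level at the left edge
    round(bisect_crossing(f, grid[first - 1], grid[first], L), 1)
  }, numeric(1))
  report <- data.frame(level_pct = levels, recommended_mm = rec,
                       feasible = !is.na(rec))
  if (model$kind == "gpr") {
    report$sad_sd_pct <- vapply(seq_along(levels), function(i) {
      if (is.na(rec[i])) return(NA_real_)
      nd <- data.frame(rec[i], depth); names(nd) <- model$xnames
      predict(model, nd, se.fit = TRUE)$se.fit
    }, numeric(1))
  }
  structure(report, mode = "sds_from_depth", value = depth,
            sds_range = sds_range,
            class = c("calibration_report", "data.frame"))
}

#' Deepest achievable depth for a given separation
#'
#' For each sensitivity level L (%), reports the deepest depth in
#' `[10, 20]` mm (0.1 mm grid, bisection-refined) at which the predicted
#' SAD at the given separation still reaches L; infeasible when no depth
#' qualifies. "Deepest depth still achieving the level" matches the tool's
#' purpose of guaranteeing sensitivity down to a target structure.
#'
#' @param model A [sad_surrogate()] fit.
#' @param sds Source-detector separation in mm, within `[19, 39]`.
#' @param levels SAD thresholds in percent (default `1:6`).
#' @param depth_range Depth search interval in mm (default `c(10, 20)`).
#' @param level_bounds Allowed range for requested levels (default `c(1, 6)`).
#' @return A `calibration_report` (see [sds_for_depth()]).
#' @export
depth_for_sds <- function(model, sds, levels = 1:6,
                          depth_range = c(10, 20), level_bounds = c(1, 6)) {
  stopifnot(inherits(model, "sad_surrogate"))
  if (!is.finite(sds) || sds < 19 || sds > 39)
    stop("sds must lie in [19, 39] mm (got ", sds, ")")
  levels <- check_levels(levels, level_bounds)
  grid <- seq(depth_range[1], depth_range[2], by = 0.1)
  sad <- predict_sad(model, sds, grid)
  f <- function(d) predict_sad(model, sds, d)
  rec <- vapply(levels, function(L) {
    ok <- which(sad >= L)
    if (!length(ok)) return(NA_real_)
    last <- ok[length(ok)]
    if (last == length(grid)) return(grid[length(grid)])
    round(bisect_crossing(f, grid[last], grid[last + 1], L), 1)
  }, numeric(1))
  report <- data.frame(level_pct = levels, recommended_mm = rec,
                       feasible = !is.na(rec))
  if (model$kind == "gpr") {
    report$sad_sd_pct <- vapply(seq_along(levels), function(i) {
      if (is.na(rec[i])) return(NA_real_)
      nd <- data.frame(sds, rec[i]); names(nd) <- model$xnames
      predict(model, nd, se.fit = TRUE)$se.fit
    }, numeric(1))
  }
  structure(report, mode = "depth_from_sds", value = sds,
            depth_range = depth_range,
            class = c("calibration_report", "data.frame"))
}

#' Is a sensitivity level achievable at a depth?
#'
#' TRUE when the maximum predicted SAD over the separation grid at the given
#' depth reaches the level.
#'
#' @param model A [sad_surrogate()] fit.
#' @param depth Depth in mm, within `[10, 20]`.
#' @param level SAD threshold in percent.
#' @param sds_range Separation search interval (default `c(19, 39)`).
#' @return Logical scalar.
#' @export
feasibility <- function(model, depth, level, sds_range = c(19, 39)) {
  stopifnot(inherits(model, "sad_surrogate"))
  if (!is.finite(depth) || depth < 10 || depth > 20)
    stop("depth must lie in [10, 20] mm (got ", depth, ")")
  grid <- seq(sds_range[1], sds_range[2], by = 0.1)
  max(predict_sad(model, grid, depth)) >= level
}

#' @export
print.calibration_report <- function(x, ...) {
  mode <- attr(x, "mode")
  what <- if (identical(mode, "sds_from_depth")) "separation" else "depth"
  cat(sprintf("Calibration report (%s, input %.1f mm): recommended %s per SAD level\n",
              mode, attr(x, "value"), what))
  df <- as.data.frame(x)
  df$recommended_mm <- ifelse(df$feasible, sprintf("%.1f", df$recommended_mm),
                              "-")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a calibration report as CSV
#'
#' Columns `level_pct,recommended_mm,feasible`; infeasible levels have an
#' empty `recommended_mm`.
#'
#' @param report A `calibration_report`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_calibration_csv <- function(report, file) {
  df <- as.data.frame(report)[c("level_pct", "recommended_mm", "feasible")]
  utils::write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Export the predicted SAD surface as a CSV grid
#'
#' Long-format table of predicted SAD over a (separation, depth) grid for
#' external surface plotting.
#'
#' @param model A [sad_surrogate()] fit.
#' @param file Output path.
#' @param sds Separation grid (mm).
#' @param depths Depth grid (mm).
#' @return `file`, invisibly.
#' @export
write_surface_csv <- function(model, file, sds = seq(19, 39, by = 0.5),
                              depths = seq(10, 20, by = 0.25)) {
  gr <- expand.grid(sds_mm = sds, depth_mm = depths)
  gr$sad_pct <- predict_sad(model, gr$sds_mm, gr$depth_mm)
  utils::write.csv(gr, file, row.names = FALSE)
  invisible(file)
}
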