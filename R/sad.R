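#' Depth-resolved sensitivity (SAD) profile from a fluence volume
#'
#' For each 1-voxel depth layer z, sums fluence over voxels whose in-plane
#' center lies within `roi_radius` of the source-detector midpoint and
#' expresses it as a percentage of a reference fluence:
#' \deqn{SAD(z) = 100 \cdot \frac{\sum_{(x,y) \in R_z} \Phi_{x,y,z}}
#'                               {\sum \Phi}}
#' where \eqn{R_z} is the circular region of interest at depth z.
#'
#' The reference (denominator) can be the fluence inside the ROI *cylinder*
#' (the same disk at every depth; the default) or the fluence of the entire
#' volume. Under the cylinder reference the profile sums to exactly 100 and
#' describes how the sensitivity under the probe midpoint is distributed
#' over depth; this is the normalization under which sensitivity at a fixed
#' depth grows with source-detector separation, the behaviour on which the
#' calibration rests. Under the volume reference the profile sums to the
#' (typically small) percentage of total fluence lying under the midpoint,
#' and is dominated by the source position rather than the probe geometry.
#'
#' @param fluence A `fluence_volume` from [run_simulation()], or a plain
#'   non-negative 3-D array (voxel size then taken as 1 mm).
#' @param midpoint_xy Source-detector midpoint in mm; defaults to the plane
#'   center recorded in the volume metadata, else the geometric center.
#' @param roi_radius ROI radius in mm (default 10).
#' @param head,sds Optional identifiers stored in the profile.
#' @param denominator `"cylinder"` (default) or `"volume"`, see Details.
#' @return Object of class `sad_profile`: data frame with columns `depth_mm`
#'   (lower edge of each depth layer) and `sad_pct`, plus `head`/`sds`
#'   attributes.
#' @export
compute_sad_profile <- function(fluence, midpoint_xy = NULL, roi_radius = 10,
                                head = NA, sds = NA,
                                denominator = c("cylinder", "volume")) {
  denominator <- match.arg(denominator)
  if (inherits(fluence, "fluence_volume")) {
    vals <- fluence$values
    vox <- fluence$voxel_size
    if (is.null(midpoint_xy) && !is.null(fluence$meta$sds))
      midpoint_xy <- c(dim(vals)[1], dim(vals)[2]) * vox / 2
    if (is.na(sds) && !is.null(fluence$meta$sds)) sds <- fluence$meta$sds
  } else {
    vals <- fluence
    vox <- 1
  }
  stopifnot(length(dim(vals)) == 3L, roi_radius > 0)
  if (any(vals < 0)) stop("fluence must be non-negative")
  total <- sum(vals)
  if (total <= 0)
    stop("all-zero fluence volume: SAD is undefined")
  d <- dim(vals)
  if (is.null(midpoint_xy)) midpoint_xy <- c(d[1], d[2]) * vox / 2
  xc <- (seq_len(d[1]) - 0.5) * vox
  yc <- (seq_len(d[2]) - 0.5) * vox
  in_roi <- outer(xc, yc, function(x, y)
    (x - midpoint_xy[1])^2 + (y - midpoint_xy[2])^2 <= roi_radius^2)
  roi_sum <- vapply(seq_len(d[3]), function(z) sum(vals[, , z][in_roi]),
                    numeric(1))
  ref <- if (denominator == "cylinder") sum(roi_sum) else total
  if (ref <= 0)
    stop("no fluence inside the ROI cylinder: SAD is undefined")
  out <- data.frame(depth_mm = (seq_len(d[3]) - 1) * vox,
                    sad_pct = 100 * roi_sum / ref)
  attr(out, "head") <- head
  attr(out, "sds") <- sds
  attr(out, "roi_radius") <- roi_radius
  class(out) <- c("sad_profile", "data.frame")
  out
}

#' Mean SAD profile across heads at one separation
#'
#' Unweighted arithmetic mean of SAD per depth over a set of profiles that
#' share the same source-detector separation; the cross-head mean curve is
#' what the surrogate model is trained on.
#'
#' @param profiles List of `sad_profile` objects with identical `sds`.
#' @return A `sad_profile` with `head = "mean"`.
#' @export
mean_sad_across_heads <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  sds <- vapply(profiles, function(p) as.numeric(attr(p, "sds")), numeric(1))
  if (length(unique(sds)) != 1L)
    stop("all profiles must share the same sds (got: ",
         paste(unique(sds), collapse = ", "), ")")
  depths <- profiles[[1]]$depth_mm
  for (p in profiles) stopifnot(identical(p$depth_mm, depths))
  sad <- rowMeans(vapply(profiles, function(p) p$sad_pct,
                         numeric(length(depths))))
  out <- data.frame(depth_mm = depths, sad_pct = sad)
  attr(out, "head") <- "mean"
  attr(out, "sds") <- sds[1]
  class(out) <- c("sad_profile", "data.frame")
  out
}

#' Box-plot statistics for SAD values across heads
#'
#' Median and quartiles use the linear-interpolation quantile convention
#' (`stats::quantile` type 7); whiskers extend to the most extreme data
#' points within 1.5 IQR of the quartiles, and anything beyond is flagged
#' as an outlier.
#'
#' @param values Numeric vector of SAD percentages across heads at one
#'   (depth, sds) cell; at least 4 values.
#' @return Object of class `box_stats`: list with `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
sad_box_stats <- function(values) {
  if (length(values) < 4L)
    stop("need at least 4 values for box statistics")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(values[inside]),
    whisker_high = max(values[inside]),
    outliers = values[!inside]
  ), class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("median %.4g [q1 %.4g, q3 %.4g], whiskers [%.4g, %.4g]",
              x$median, x$q1, x$q3, x$whisker_low, x$whisker_high))
  if (length(x$outliers))
    cat(", outliers:", paste(signif(x$outliers, 4), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Histogram of detected photon weight versus path length
#'
#' Bins detected packets by total path length (uniform bins spanning the
#' observed range) and reports the mean exit weight per bin. Weighted-packet
#' simulations report weights, not unweighted counts.
#'
#' @param detected Data frame with columns `weight` and `path_mm` (as
#'   returned by [run_simulation()]).
#' @param n_bins Number of bins (default 20).
#' @return Object of class `pathlength_histogram`: list with `breaks` (bin
#'   edges, mm), `mean_weight` (per-bin mean weight, NA for empty bins) and
#'   `count` (packets per bin).
#' @export
pathlength_histogram <- function(detected, n_bins = 20) {
  if (nrow(detected) < 1L)
    stop("no detected photons: cannot build a path-length histogram")
  stopifnot(n_bins >= 1)
  rng <- range(detected$path_mm)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(detected$path_mm, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mw <- rep(NA_real_, n_bins)
  cnt <- integer(n_bins)
  for (b in unique(bin)) {
    sel <- bin == b
    mw[b] <- mean(detected$weight[sel])
    cnt[b] <- sum(sel)
  }
  structure(list(breaks = breaks, mean_weight = mw, count = cnt),
            class = "pathlength_histogram")
}

#' Write/read SAD profiles as a long-format CSV table
#'
#' Columns: `head,sds_mm,depth_mm,sad_pct`.
#'
#' @param profiles A list of `sad_profile` objects, or a data frame already
#'   in long format.
#' @param file Path.
#' @return `write_sad_table`: `file` invisibly. `read_sad_table`: the long
#'   data frame.
#' @export
write_sad_table <- function(profiles, file) {
  if (is.data.frame(profiles)) {
    df <- profiles
  } else {
    df <- do.call(rbind, lapply(profiles, function(p) {
      data.frame(head = as.character(attr(p, "head")),
                 sds_mm = as.numeric(attr(p, "sds")),
                 depth_mm = p$depth_mm, sad_pct = p$sad_pct)
    }))
  }
  stopifnot(all(c("head", "sds_mm", "depth_mm", "sad_pct") %in% names(df)))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sad_table
#' @export
read_sad_table <- function(file) {
  df <- tryCatch(utils::read.csv(file, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse SAD table '", file,
                                          "': ", conditionMessage(e)))
  needed <- c("head", "sds_mm", "depth_mm", "sad_pct")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("SAD table '", file, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  for (cl in needed[-1]) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("SAD table '", file, "': non-numeric '", cl, "' at data line ",
           bad[1])
    df[[cl]] <- v
  }
  df[needed]
}

#' Plot SAD-versus-depth curves with vertical staggering
#'
#' Draws one curve per separation; each successive curve is shifted up by
#' `stagger` percentage points so overlapping profiles stay readable.
#'
#' @param profiles List of `sad_profile` objects (typically cross-head means
#'   at increasing sds).
#' @param stagger Vertical shift between successive curves, percentage
#'   points (default 2).
#' @param max_depth Truncate the depth axis, mm (default 30).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_sad_profiles <- function(profiles, stagger = 2, max_depth = 30, ...) {
  stopifnot(length(profiles) >= 1)
  keep <- profiles[[1]]$depth_mm <= max_depth
  depths <- profiles[[1]]$depth_mm[keep]
  mat <- vapply(seq_along(profiles), function(i)
    profiles[[i]]$sad_pct[keep] + (i - 1) * stagger, numeric(sum(keep)))
  cols <- grDevices::colorRampPalette(c("mistyrose", "red4"))(length(profiles))
  graphics::matplot(depths, mat, type = "l", lty = 1, col = cols,
                    xlab = "depth (mm)",
                    ylab = sprintf("SAD (%%), staggered by %g", stagger), ...)
  invisible(NULL)
}
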