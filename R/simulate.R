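#' Run a Monte Carlo photon transport simulation
#'
#' Launches weighted photon packets from a cone source on the scalp surface,
#' propagates them through the layered phantom (exponential step lengths,
#' Henyey-Greenstein scattering, Fresnel reflection/refraction at slab
#' interfaces, Russian roulette termination), and tallies a fluence volume
#' (accumulated weight x path length per voxel) together with the photons
#' exiting through a surface detector disk.
#'
#' Source and detector are placed symmetrically about the center of the
#' surface plane: source at `(cx - sds/2, cy)`, detector at
#' `(cx + sds/2, cy)`, so their midpoint is the plane center. Results are
#' reproducible for a given `seed`: each photon uses its own deterministic
#' RNG substream, so tallies do not depend on batching.
#'
#' @param phantom A [build_phantom()] object.
#' @param sds Source-detector separation in mm. Must fit inside the domain.
#' @param n_photons Number of photon packets (default 1e5; increase for
#'   production-quality fluence maps).
#' @param seed Integer root seed (required: simulations are reproducible by
#'   contract).
#' @param half_angle Source cone half-angle, degrees (default 70).
#' @param detector_radius Detector disk radius on the surface, mm (default
#'   1.5, a typical fNIRS detector aperture).
#' @param roulette_threshold Packet weight below which Russian roulette is
#'   played (default 1e-4).
#' @param roulette_survival Roulette survival probability (default 0.1);
#'   survivors have their weight divided by this, keeping the scheme unbiased.
#' @param launch `"internal"` (default): packets start just inside the scalp
#'   with the cone sampled in tissue and no specular entry loss.
#'   `"above_surface"`: the cone is emitted in the void above the head and
#'   refracted through the void-scalp interface (specular reflections never
#'   enter). The choice barely affects depth-sensitivity profiles --
#'   directionality is forgotten within about one transport mean free path --
#'   but is exposed for studying launch-convention sensitivity.
#' @return An object of class `mc_result`: list with `fluence` (a
#'   `fluence_volume`), `detected` (data frame of per-photon exit weight,
#'   total path length in mm, and exit x/y in mm), `ledger` (an
#'   `energy_ledger`), and `config`.
#' @export
run_simulation <- function(phantom, sds, n_photons = 1e5, seed,
                           half_angle = 70, detector_radius = 1.5,
                           roulette_threshold = 1e-4,
                           roulette_survival = 0.1,
                           launch = c("internal", "above_surface")) {
  launch <- match.arg(launch)
  stopifnot(inherits(phantom, "head_phantom"))
  if (missing(seed) || !is.finite(seed))
    stop("a finite integer 'seed' is required for reproducible simulations")
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (half_angle <= 0 || half_angle > 90)
    stop("half_angle must be in (0, 90] degrees")
  if (detector_radius <= 0) stop("detector_radius must be positive")
  extent_x <- phantom$domain_shape[1] * phantom$voxel_size
  extent_y <- phantom$domain_shape[2] * phantom$voxel_size
  if (!is.finite(sds) || sds <= 0 || sds >= extent_x)
    stop("sds (", sds, " mm) must be positive and smaller than the domain ",
         "extent (", extent_x, " mm)")
  cx <- extent_x / 2
  cy <- extent_y / 2
  src <- c(cx - sds / 2, cy)
  det <- c(cx + sds / 2, cy)

  nm <- phantom$layers$name
  props <- phantom$props
  raw <- .mc_run_cpp(
    z_upper = phantom$z_boundaries,
    mu_a = vapply(props[nm], function(p) p$mu_a, numeric(1)),
    mu_s = vapply(props[nm], function(p) p$mu_s, numeric(1)),
    g = vapply(props[nm], function(p) p$g, numeric(1)),
    n_idx = vapply(props[nm], function(p) p$n, numeric(1)),
    n_void = props$void$n,
    domain_shape = phantom$domain_shape,
    voxel_size = phantom$voxel_size,
    src_x = src[1], src_y = src[2], half_angle_deg = half_angle,
    det_x = det[1], det_y = det[2], det_radius = detector_radius,
    n_photons = n_photons, seed = seed,
    roulette_threshold = roulette_threshold,
    roulette_survival = roulette_survival,
    entry_refraction = as.integer(launch == "above_surface")
  )

  config <- list(
    sds = sds, n_photons = n_photons, seed = as.integer(seed),
    half_angle = half_angle, detector_radius = detector_radius,
    roulette_threshold = roulette_threshold,
    roulette_survival = roulette_survival, launch = launch,
    source_xy = src, detector_xy = det,
    domain_shape = phantom$domain_shape, voxel_size = phantom$voxel_size,
    thicknesses = stats::setNames(phantom$layers$thickness, nm)
  )
  fluence <- structure(
    list(values = raw$fluence, voxel_size = phantom$voxel_size, meta = config),
    class = "fluence_volume"
  )
  ledger <- structure(
    list(launched = raw$launched, absorbed = raw$absorbed,
         escaped = raw$escaped, detected = raw$detected,
         roulette_residual = raw$roulette_residual),
    class = "energy_ledger"
  )
  detected <- data.frame(
    weight = raw$det_weight, path_mm = raw$det_path,
    x_mm = raw$det_x, y_mm = raw$det_y
  )
  structure(list(fluence = fluence, detected = detected,
                 ledger = ledger, config = config),
            class = "mc_result")
}

#' @export
print.energy_ledger <- function(x, ...) {
  gap <- x$launched - x$absorbed - x$escaped
  cat(sprintf(
    "Energy ledger: launched %.6g | absorbed %.6g | escaped %.6g (detected %.6g)\n",
    x$launched, x$absorbed, x$escaped, x$detected))
  cat(sprintf("  closure gap %.3g (%.4f%% of launched); roulette residual %.3g\n",
              gap, 100 * abs(gap) / x$launched, x$roulette_residual))
  invisible(x)
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo run: sds = %g mm, %g photons, seed %d\n",
              x$config$sds, x$config$n_photons, x$config$seed))
  cat(sprintf("  detected %d packets, total weight %.4g\n",
              nrow(x$detected), x$ledger$detected))
  print(x$ledger)
  invisible(x)
}

#' @export
print.fluence_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Fluence volume %d x %d x %d @ %g mm (total %.4g)\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$values)))
  invisible(x)
}

#' Export a fluence volume as NIfTI-1 with a JSON sidecar
#'
#' Writes the 3-D fluence tally as a NIfTI-1 image (1 mm isotropic by
#' default) plus a `.json` sidecar holding the simulation configuration.
#' Requires the RNifti package.
#'
#' @param fluence A `fluence_volume` from [run_simulation()].
#' @param file Output path ending in `.nii` or `.nii.gz`.
#' @return `file`, invisibly.
#' @export
write_fluence_nifti <- function(fluence, file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("write_fluence_nifti requires the RNifti package")
  img <- RNifti::asNifti(fluence$values, pixdim = rep(fluence$voxel_size, 3))
  RNifti::writeNifti(img, file)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", file)
  jsonlite::write_json(fluence$meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Read a fluence volume written by [write_fluence_nifti()]
#' @param file NIfTI path; the JSON sidecar is read from the matching name.
#' @return A `fluence_volume`.
#' @export
read_fluence_nifti <- function(file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_fluence_nifti requires the RNifti package")
  img <- RNifti::readNifti(file)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", file)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  vox <- RNifti::pixdim(img)[1]
  structure(list(values = array(as.numeric(img), dim = dim(img)),
                 voxel_size = vox, meta = meta),
            class = "fluence_volume")
}

#' Export detected photon records as JSON Lines
#'
#' One JSON object per detected packet with exit `weight`, total `path_mm`
#' and exit `x_mm`/`y_mm`.
#'
#' @param detected Data frame of detected records from [run_simulation()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_detected_jsonl <- function(detected, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(detected))) {
    writeLines(jsonlite::toJSON(as.list(detected[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(file)
}
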