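#' Default tissue optical properties at 735 nm
#'
#' Returns the absorption coefficient (`mu_a`, mm^-1), scattering coefficient
#' (`mu_s`, mm^-1), Henyey-Greenstein anisotropy factor (`g`) and refractive
#' index (`n`) for each medium of the layered head model: `void`,
#' `scalp_muscle`, `cranium`, `csf` and `brain`. Values are literature optical
#' properties for near-infrared light at 735 nm.
#'
#' @param file Optional path to a JSON file mapping layer name to
#'   `{mu_a, mu_s, g, n}`; defaults to the table shipped with the package.
#' @return A named list of lists, one entry per medium, each with elements
#'   `mu_a`, `mu_s`, `g`, `n`.
#' @examples
#' props <- default_optical_properties()
#' props$csf$mu_s   # 0.3 mm^-1: CSF scatters weakly
#' @export
default_optical_properties <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "optical_properties.json",
                        package = "fnirscal", mustWork = TRUE)
  }
  props <- jsonlite::read_json(file, simplifyVector = FALSE)
  for (nm in names(props)) {
    p <- props[[nm]]
    stopifnot(all(c("mu_a", "mu_s", "g", "n") %in% names(p)))
    validate_optical_properties(p, nm)
  }
  props
}

validate_optical_properties <- function(p, name = "layer") {
  if (p$mu_a < 0 || p$mu_s < 0)
    stop("optical properties for '", name, "': mu_a and mu_s must be >= 0")
  if (p$g <= -1 || p$g >= 1)
    stop("optical properties for '", name, "': g must lie in (-1, 1)")
  if (p$n < 1)
    stop("optical properties for '", name, "': refractive index must be >= 1")
  invisible(p)
}

#' Tissue layer order of the slab head model
#' @keywords internal
TISSUE_LAYERS <- c("scalp_muscle", "cranium", "csf", "brain")

#' Build a layered slab head phantom
#'
#' Constructs a planar four-layer head model (scalp-muscle, cranium, CSF,
#' brain, stacked along +z from the outer surface at z = 0) on a voxel tally
#' grid. Layer boundaries are kept continuous along z: they are *not* snapped
#' to the voxel grid, so sub-voxel CSF layers (e.g. 0.68 mm) are represented
#' exactly. The voxel grid is used only to accumulate fluence.
#'
#' @param scalp_mm,cranium_mm,csf_mm Layer thicknesses in mm; all must be
#'   positive. Brain fills the remaining z-extent of the domain.
#' @param domain_shape Integer vector of voxels per axis (default `c(64, 64, 64)`).
#' @param voxel_size Voxel edge length in mm (default 1).
#' @param optical_properties Named list as returned by
#'   [default_optical_properties()].
#' @return An object of class `head_phantom`: a list with `layers` (data frame
#'   of name/thickness), `props`, `domain_shape`, `voxel_size`, and
#'   `z_boundaries` (cumulative interface depths in mm, including the domain
#'   bottom).
#' @examples
#' ph <- build_phantom(8, 6.8, 5.55)       # cadaveric head #1
#' ph$layers$thickness[4]                   # brain: 43.65 mm
#' @export
build_phantom <- function(scalp_mm, cranium_mm, csf_mm,
                          domain_shape = c(64L, 64L, 64L),
                          voxel_size = 1,
                          optical_properties = default_optical_properties()) {
  th <- c(scalp_mm, cranium_mm, csf_mm)
  if (any(!is.finite(th)) || any(th <= 0))
    stop("layer thicknesses must be positive and finite")
  if (length(domain_shape) != 3L || any(domain_shape < 1))
    stop("domain_shape must be three positive voxel counts")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  z_extent <- domain_shape[3] * voxel_size
  if (sum(th) >= z_extent)
    stop("scalp + cranium + CSF (", sum(th),
         " mm) must be smaller than the domain z-extent (", z_extent, " mm)")
  brain_mm <- z_extent - sum(th)
  layers <- data.frame(
    name = TISSUE_LAYERS,
    thickness = c(th, brain_mm),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      layers = layers,
      props = optical_properties,
      domain_shape = as.integer(domain_shape),
      voxel_size = voxel_size,
      z_boundaries = cumsum(layers$thickness)
    ),
    class = "head_phantom"
  )
}

#' @export
print.head_phantom <- function(x, ...) {
  cat("Layered head phantom (", paste(x$domain_shape, collapse = " x "),
      " voxels @ ", x$voxel_size, " mm)\n", sep = "")
  df <- x$layers
  df$z_from <- c(0, head(x$z_boundaries, -1))
  df$z_to <- x$z_boundaries
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tissue layer containing a given depth
#'
#' Depth intervals are half-open, `[lower, upper)`: a point exactly on an
#' interface belongs to the deeper layer.
#'
#' @param phantom A [build_phantom()] object.
#' @param z_mm Depth in mm from the outer scalp surface (0 <= z < z-extent).
#' @return Layer name, one of `"scalp_muscle"`, `"cranium"`, `"csf"`, `"brain"`.
#' @examples
#' ph <- build_phantom(8, 6.8, 5.55)
#' layer_at_depth(ph, 8)      # "cranium": boundary point goes to deeper layer
#' @export
layer_at_depth <- function(phantom, z_mm) {
  stopifnot(inherits(phantom, "head_phantom"), length(z_mm) == 1L)
  z_extent <- phantom$domain_shape[3] * phantom$voxel_size
  if (!is.finite(z_mm) || z_mm < 0 || z_mm >= z_extent)
    stop("depth ", z_mm, " mm is outside the domain [0, ", z_extent, ") mm")
  idx <- findInterval(z_mm, c(0, phantom$z_boundaries),
                      left.open = FALSE, rightmost.closed = FALSE)
  phantom$layers$name[idx]
}

#' Packaged cadaveric head layer thicknesses
#'
#' Loads the table of scalp-muscle, cranium and CSF thicknesses (mm) measured
#' by MRI on eight cadaveric heads, used to parameterise the packaged slab
#' phantoms.
#'
#' @param file Optional CSV path with header
#'   `head,scalp_muscle_mm,cranium_mm,csf_mm`; defaults to the packaged table.
#' @return Data frame with columns `head`, `scalp_muscle_mm`, `cranium_mm`,
#'   `csf_mm`.
#' @export
head_thicknesses <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "head_thicknesses.csv",
                        package = "fnirscal", mustWork = TRUE)
  }
  read_thickness_table(file)
}

#' Read a layer-thickness table
#'
#' @param file CSV with header `head,scalp_muscle_mm,cranium_mm,csf_mm`.
#' @return Validated data frame.
#' @export
read_thickness_table <- function(file) {
  df <- tryCatch(
    utils::read.csv(file, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse thickness table '", file, "': ",
                             conditionMessage(e))
  )
  needed <- c("head", "scalp_muscle_mm", "cranium_mm", "csf_mm")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("thickness table '", file, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  num_cols <- needed[-1]
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop("thickness table '", file, "': non-positive or non-numeric '",
           cl, "' at data line ", bad[1])
    df[[cl]] <- v
  }
  df[needed]
}

#' Per-layer mean and standard deviation of head thicknesses
#'
#' Summarises a multi-head thickness table: arithmetic mean and sample (n-1)
#' standard deviation per layer, including the derived brain thickness
#' (domain z-extent minus the superficial layers). Values are rounded to two
#' decimals for reporting.
#'
#' @param table Data frame as from [head_thicknesses()].
#' @param z_extent_mm Domain depth used to derive brain thickness (default 64).
#' @param digits Rounding for the report (default 2).
#' @return Data frame with columns `layer`, `mean`, `sd`.
#' @examples
#' thickness_summary(head_thicknesses())
#' @export
thickness_summary <- function(table, z_extent_mm = 64, digits = 2) {
  needed <- c("scalp_muscle_mm", "cranium_mm", "csf_mm")
  stopifnot(all(needed %in% names(table)))
  if (nrow(table) < 2L)
    stop("need at least 2 heads to compute a sample standard deviation")
  brain <- z_extent_mm - rowSums(table[needed])
  m <- cbind(table[needed], brain_mm = brain)
  # half-up reporting rounding (a mean like 44.635 prints as 44.64, not the
  # banker's/floating-point 44.63)
  round_half_up <- function(x, d) round(x + sign(x) * 1e-9, d)
  data.frame(
    layer = c("scalp_muscle", "cranium", "csf", "brain"),
    mean = round_half_up(vapply(m, mean, numeric(1)), digits),
    sd = round_half_up(vapply(m, stats::sd, numeric(1)), digits),
    row.names = NULL
  )
}

#' Export a phantom label volume as NIfTI-1
#'
#' Writes a voxel label volume (1 = scalp-muscle ... 4 = brain, assigned by
#' the layer containing each voxel center) for visualisation in standard
#' neuroimaging viewers. Requires the RNifti package.
#'
#' @param phantom A [build_phantom()] object.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @return `file`, invisibly.
#' @export
write_phantom_nifti <- function(phantom, file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("write_phantom_nifti requires the RNifti package")
  dm <- phantom$domain_shape
  zc <- (seq_len(dm[3]) - 0.5) * phantom$voxel_size
  lab <- findInterval(zc, c(0, phantom$z_boundaries),
                      left.open = FALSE, rightmost.closed = FALSE)
  vol <- aperm(array(rep(lab, each = dm[1] * dm[2]), dim = dm), c(1, 2, 3))
  img <- RNifti::asNifti(vol, pixdim = rep(phantom$voxel_size, 3))
  RNifti::writeNifti(img, file)
  invisible(file)
}
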