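#' Sample photon launch directions from a cone source
#'
#' Directions are uniform over the spherical cap of the given half-angle
#' about the +z axis, emulating the divergence of an fNIRS LED. The mean
#' z-component over the cap is (1 + cos(half_angle)) / 2.
#'
#' @param n Number of directions.
#' @param half_angle Cone half-angle in degrees, in `[0, 90]`.
#' @return An `n x 3` matrix of unit vectors.
#' @export
sample_cone_direction <- function(n, half_angle = 70) {
  if (half_angle < 0 || half_angle > 90)
    stop("half_angle must be in [0, 90] degrees")
  cos_max <- cos(half_angle * pi / 180)
  cz <- 1 - stats::runif(n) * (1 - cos_max)
  sz <- sqrt(pmax(0, 1 - cz^2))
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(x = sz * cos(phi), y = sz * sin(phi), z = cz)
}

#' Sample free path lengths between interaction events
#'
#' Exponential step lengths `s = -log(U) / mu_t` with `U ~ Uniform(0, 1]`,
#' the standard Beer-Lambert sampling for a medium with total attenuation
#' `mu_t = mu_a + mu_s`.
#'
#' @param n Number of draws.
#' @param mu_t Total attenuation coefficient, mm^-1; must be positive. A
#'   non-scattering, non-absorbing region (void) has no interaction events:
#'   callers must use straight-line transport there instead.
#' @return Numeric vector of lengths in mm.
#' @export
sample_step_length <- function(n, mu_t) {
  if (!is.finite(mu_t) || mu_t <= 0)
    stop("mu_t must be positive; use straight-line transport in void regions")
  stats::rexp(n, rate = mu_t)
}

#' Sample scattering angle cosines from the Henyey-Greenstein phase function
#'
#' Standard inverse-CDF sampling. For `g = 0` the cosine is uniform on
#' `[-1, 1]` (isotropic); otherwise
#' `cos(theta) = (1 + g^2 - ((1 - g^2) / (1 - g + 2 g U))^2) / (2 g)`.
#' The first moment is `E[cos(theta)] = g`. Azimuth is sampled uniformly by
#' the caller.
#'
#' @param n Number of draws.
#' @param g Anisotropy factor, strictly inside `(-1, 1)`.
#' @return Numeric vector of cosines in `[-1, 1]`.
#' @export
sample_hg_cos <- function(n, g) {
  if (!is.finite(g) || abs(g) >= 1)
    stop("anisotropy factor g must satisfy |g| < 1")
  u <- stats::runif(n)
  if (g == 0) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  ct <- (1 + g^2 - f^2) / (2 * g)
  pmin(1, pmax(-1, ct))
}

#' Unpolarized Fresnel reflectance and refraction at a planar interface
#'
#' Computes the unpolarized Fresnel power reflectance for a ray crossing from
#' refractive index `n1` into `n2` with incidence cosine `cos_incident`
#' (measured from the interface normal). Beyond the critical angle the ray is
#' totally internally reflected (`R = 1`).
#'
#' @param n1,n2 Refractive indices (>= 1; vacuum/void is 1).
#' @param cos_incident Cosine of the incidence angle, in `(0, 1]`.
#' @return A list with `R` (reflectance in `[0, 1]`), `tir` (logical,
#'   total internal reflection), and `cos_transmit` (cosine of the refraction
#'   angle, `NA` under TIR).
#' @examples
#' fresnel_interface(1.6, 1.56, 1)$R   # ~1.6e-4 at normal incidence
#' @export
fresnel_interface <- function(n1, n2, cos_incident) {
  stopifnot(n1 > 0, n2 > 0,
            cos_incident > 0, cos_incident <= 1)
  if (n1 == n2)
    return(list(R = 0, tir = FALSE, cos_transmit = cos_incident))
  sin_i <- sqrt(1 - cos_incident^2)
  sin_t <- n1 / n2 * sin_i
  if (sin_t >= 1)
    return(list(R = 1, tir = TRUE, cos_transmit = NA_real_))
  cos_t <- sqrt(1 - sin_t^2)
  rs <- (n1 * cos_incident - n2 * cos_t) / (n1 * cos_incident + n2 * cos_t)
  rp <- (n1 * cos_t - n2 * cos_incident) / (n1 * cos_t + n2 * cos_incident)
  list(R = (rs^2 + rp^2) / 2, tir = FALSE, cos_transmit = cos_t)
}
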