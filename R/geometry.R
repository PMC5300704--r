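#' Helix geometry of a flagellar filament
#'
#' The flagellar filament is a helix; fluorescence images record only its 2D
#' projection onto the focal plane.  A `helix_geometry` object holds the two
#' constants that define the helix: radius and pitch.  The defaults are the
#' literature values for *Vibrio alginolyticus* polar flagella (radius
#' 0.16 um, pitch 1.5 um).
#'
#' @param radius_nm Helix radius r in nm (>= 0; 0 gives a straight filament).
#' @param pitch_nm Helix pitch c in nm (> 0), the axial rise per turn.
#' @return An object of class `helix_geometry`.
#' @examples
#' geom <- helix_geometry()
#' arc_length_3d(geom, 1500)
#' @export
helix_geometry <- function(radius_nm = 160, pitch_nm = 1500) {
  if (!is.numeric(radius_nm) || length(radius_nm) != 1L || radius_nm < 0)
    stop("'radius_nm' must be a single non-negative number")
  if (!is.numeric(pitch_nm) || length(pitch_nm) != 1L || pitch_nm <= 0)
    stop("'pitch_nm' must be a single positive number")
  structure(list(radius_nm = radius_nm, pitch_nm = pitch_nm),
            class = "helix_geometry")
}

#' @export
print.helix_geometry <- function(x, ...) {
  cat(sprintf("Helical filament: radius %g nm, pitch %g nm\n",
              x$radius_nm, x$pitch_nm))
  invisible(x)
}

#' 3D arc length of a helical filament
#'
#' For a helix x = r sin(2*pi*z/c), y = r cos(2*pi*z/c) of axial extent z,
#' the arc length is sqrt((2*pi*r*z/c)^2 + z^2): the helix is a straight
#' line on the unrolled cylinder, so length is exactly linear in z.
#'
#' @param geom A [helix_geometry()].
#' @param z Axial extent in nm (vectorised, each >= 0).
#' @return Arc length(s) in nm; always >= z.
#' @examples
#' arc_length_3d(helix_geometry(160, 1500), 1500)  # one full turn
#' @export
arc_length_3d <- function(geom, z) {
  stopifnot(inherits(geom, "helix_geometry"))
  if (any(z < 0)) stop("'z' must be non-negative")
  sqrt((2 * pi * geom$radius_nm * z / geom$pitch_nm)^2 + z^2)
}

#' 2D projected arc length of a helical filament
#'
#' The image-plane projection of the helix is the plane curve
#' x = r sin(2*pi*z/c) traced against z, whose arc length
#' integral(0..z) sqrt(1 + ((2*pi*r/c) cos(2*pi*z'/c))^2) dz' has no closed
#' form and is evaluated by adaptive quadrature.
#'
#' @inheritParams arc_length_3d
#' @param rel.tol Relative quadrature tolerance.
#' @return Projected arc length(s) in nm; lies between z and
#'   [arc_length_3d()].
#' @export
arc_length_2d <- function(geom, z, rel.tol = 1e-8) {
  stopifnot(inherits(geom, "helix_geometry"))
  if (any(z < 0)) stop("'z' must be non-negative")
  a <- 2 * pi * geom$radius_nm / geom$pitch_nm
  w <- 2 * pi / geom$pitch_nm
  integrand <- function(zz) sqrt(1 + (a * cos(w * zz))^2)
  vapply(z, function(zi) {
    if (zi == 0) return(0)
    stats::integrate(integrand, 0, zi, rel.tol = rel.tol,
                     subdivisions = 200L + 10L * ceiling(zi / geom$pitch_nm)
                     )$value
  }, numeric(1))
}

#' Projection-correction factor from 2D to 3D length
#'
#' Samples axial positions uniformly on (0, z_max], computes the pair
#' (L2D, L3D) at each, and returns the least-squares slope through the
#' origin.  Because both lengths are exactly linear in whole turns, the
#' slope is insensitive to the sampling range; for the default *Vibrio*
#' helix (r = 160 nm, c = 1500 nm) it is 1.09.
#'
#' @inheritParams arc_length_3d
#' @param z_max Upper end of the sampled axial range in nm (> 0).
#' @param n_points Number of sample points (>= 2).
#' @return The dimensionless slope L3D/L2D (>= 1).
#' @examples
#' projection_correction_factor(helix_geometry(160, 1500))
#' @export
projection_correction_factor <- function(geom, z_max = 10000, n_points = 100) {
  stopifnot(inherits(geom, "helix_geometry"))
  if (z_max <= 0) stop("'z_max' must be positive")
  if (n_points < 2) stop("'n_points' must be at least 2")
  z <- seq(0, z_max, length.out = n_points + 1L)[-1L]  # exclude z = 0
  l2 <- arc_length_2d(geom, z)
  l3 <- arc_length_3d(geom, z)
  sum(l2 * l3) / sum(l2 * l2)
}

#' Convert a projected 2D length to a 3D filament length
#'
#' @param L2D Measured projected length(s) in nm (>= 0).
#' @param factor Correction slope from [projection_correction_factor()]
#'   (>= 1); default 1.09, the value for the *Vibrio* helix.
#' @return Corrected 3D length(s) in nm.
#' @export
correct_2d_to_3d <- function(L2D, factor = 1.09) {
  if (any(L2D < 0)) stop("'L2D' must be non-negative")
  if (any(factor < 1)) stop("'factor' must be >= 1")
  factor * L2D
}
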