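#' Detector geometry
#'
#' Describes a flat area detector with its beam geometry.  The lab frame
#' places the direct beam along +z, the detector fast axis along lab x and
#' the slow axis along lab y, with the detector plane perpendicular to the
#' beam at `distance`.  All photometric corrections and the pixel-to-q
#' mapping derive from this object.
#'
#' @param distance crystal-to-detector distance (mm)
#' @param pixel_size edge length of a square pixel (mm)
#' @param n_fast,n_slow number of pixels along the fast and slow axes
#' @param beam_center direct-beam position in (fast, slow) pixel units
#' @param wavelength X-ray wavelength (Angstrom)
#' @param polarization_fraction fraction of the beam intensity polarized
#'   with the electric field in the plane perpendicular to
#'   `polarization_plane_normal`; 0.5 corresponds to an unpolarized beam
#' @param polarization_plane_normal unit lab-frame normal of the
#'   polarization plane (the plane spanned by the beam and the dominant
#'   electric-field direction)
#' @param rotation_axis unit lab-frame spindle axis
#' @return an object of class `detector_geometry`
#' @export
detector_geometry <- function(distance, pixel_size, n_fast, n_slow,
                              beam_center, wavelength,
                              polarization_fraction = 0.5,
                              polarization_plane_normal = c(0, 1, 0),
                              rotation_axis = c(1, 0, 0)) {
  stopifnot_scalar_pos(distance, "distance")
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot_scalar_pos(wavelength, "wavelength")
  if (polarization_fraction < 0 || polarization_fraction > 1)
    stop("polarization_fraction must lie in [0, 1]")
  if (abs(vnorm(polarization_plane_normal) - 1) > 1e-10)
    stop("polarization_plane_normal must be unit length")
  if (abs(vnorm(rotation_axis) - 1) > 1e-10)
    stop("rotation_axis must be unit length")
  structure(list(distance = distance, pixel_size = pixel_size,
                 n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
                 beam_center = as.numeric(beam_center),
                 wavelength = wavelength,
                 polarization_fraction = polarization_fraction,
                 polarization_plane_normal = as.numeric(polarization_plane_normal),
                 rotation_axis = as.numeric(rotation_axis)),
            class = "detector_geometry")
}

#' Crystal setting: unit cell, symmetry, orientation
#'
#' @param cell numeric length 6 (a, b, c in Angstrom; angles in degrees)
#' @param spacegroup space-group label (see [spacegroup_ops()])
#' @param orientation optional 3x3 setting matrix mapping a Miller-index
#'   column to the Cartesian q vector (A^-1, q = 2*pi*s convention) at
#'   spindle angle zero; defaults to the cell-aligned matrix whose columns
#'   are the reciprocal-cell vectors times 2*pi
#' @return object of class `crystal_frame`
#' @export
crystal_frame <- function(cell, spacegroup = "P1", orientation = NULL) {
  check_cell(cell)
  ops <- spacegroup_ops(spacegroup)
  if (is.null(orientation)) orientation <- default_orientation(cell)
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3, 3)) || abs(det(orientation)) < 1e-12)
    stop("orientation must be a non-singular 3x3 matrix")
  structure(list(cell = as.numeric(cell), spacegroup = ops$label,
                 orientation = orientation, ops = ops),
            class = "crystal_frame")
}

#' A single rotation-series frame
#'
#' @param pixels numeric matrix of counts, dimensions `n_fast` x `n_slow`
#' @param valid_mask logical matrix congruent with `pixels`; FALSE marks
#'   pixels excluded from all downstream statistics
#' @param phi_start start of the oscillation interval (degrees)
#' @param phi_width oscillation width (degrees), positive
#' @param scale_factor per-image scale; intensities are divided by it
#' @return object of class `diffraction_frame`
#' @export
diffraction_frame <- function(pixels, valid_mask = NULL, phi_start = 0,
                              phi_width = 1, scale_factor = 1) {
  pixels <- as.matrix(pixels)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (!all(dim(valid_mask) == dim(pixels)))
    stop("pixels and valid_mask must have congruent shapes")
  if (phi_width <= 0) stop("phi_width must be positive")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  structure(list(pixels = pixels, valid_mask = valid_mask,
                 phi_start = phi_start, phi_width = phi_width,
                 scale_factor = scale_factor),
            class = "diffraction_frame")
}

phi_mid <- function(frame) frame$phi_start + frame$phi_width / 2

# Lab-frame scattering vectors for pixel coordinate vectors (fast, slow).
# Returns an n x 3 matrix; q = (2*pi/lambda) * (s_hat - b_hat).
pixel_q_lab <- function(fast, slow, geometry) {
  x <- (fast - geometry$beam_center[1]) * geometry$pixel_size
  y <- (slow - geometry$beam_center[2]) * geometry$pixel_size
  z <- geometry$distance
  r <- sqrt(x^2 + y^2 + z^2)
  k <- 2 * pi / geometry$wavelength
  cbind(k * x / r, k * y / r, k * (z / r - 1), deparse.level = 0)
}

#' Map detector pixels to reciprocal space
#'
#' Computes the scattering vector of each pixel in the crystal-fixed frame
#' at the given spindle angle: the lab-frame q is rotated back by `-phi`
#' about the rotation axis, so that Miller indices follow directly from the
#' setting matrix.  `|q|` equals `4*pi*sin(theta)/wavelength` and is
#' independent of `phi`.
#'
#' @param pixel numeric length-2 (fast, slow) or an n x 2 matrix of pixel
#'   coordinates
#' @param geometry a [detector_geometry()]
#' @param crystal optional [crystal_frame()]; not needed for the q vector
#'   itself and accepted for interface symmetry
#' @param phi spindle angle in degrees (use the frame's mid-oscillation
#'   angle when mapping whole frames)
#' @return n x 3 matrix of q vectors (A^-1)
#' @export
pixel_to_q <- function(pixel, geometry, crystal = NULL, phi = 0) {
  pm <- if (is.matrix(pixel)) pixel else matrix(pixel, ncol = 2)
  if (any(pm[, 1] < 0.5 | pm[, 1] > geometry$n_fast + 0.5 |
          pm[, 2] < 0.5 | pm[, 2] > geometry$n_slow + 0.5))
    stop("pixel out of detector bounds")
  qlab <- pixel_q_lab(pm[, 1], pm[, 2], geometry)
  R <- rotation_about_axis(geometry$rotation_axis, -phi * pi / 180)
  qlab %*% t(R)
}

#' Predicted detector pixel for a crystal-frame q vector
#'
#' Inverse of [pixel_to_q()] for vectors lying on the Ewald sphere of the
#' frame at spindle angle `phi`.  Used for spot prediction round trips.
#'
#' @param q n x 3 matrix of crystal-frame q vectors (A^-1)
#' @inheritParams pixel_to_q
#' @return n x 2 matrix of (fast, slow) pixel coordinates; NA for vectors
#'   that do not intersect the detector (or scatter backwards)
#' @export
q_to_pixel <- function(q, geometry, phi = 0) {
  qm <- if (is.matrix(q)) q else matrix(q, ncol = 3)
  R <- rotation_about_axis(geometry$rotation_axis, phi * pi / 180)
  qlab <- qm %*% t(R)
  k <- 2 * pi / geometry$wavelength
  s <- sweep(qlab / k, 2, c(0, 0, 1), "+")  # scattered unit vectors
  bad <- s[, 3] <= 1e-9
  t_fac <- geometry$distance / s[, 3]
  fast <- s[, 1] * t_fac / geometry$pixel_size + geometry$beam_center[1]
  slow <- s[, 2] * t_fac / geometry$pixel_size + geometry$beam_center[2]
  out <- cbind(fast, slow, deparse.level = 0)
  out[bad, ] <- NA_real_
  out
}

#' Polarization correction factor
#'
#' Kahn-style polarization factor for a beam with intensity fraction
#' `polarization_fraction` whose electric field lies in the polarization
#' plane.  Observed intensities are divided by the returned factor, which
#' equals 1 for forward scattering and reduces to the Thomson
#' `(1 + cos^2 2theta)/2` for an unpolarized beam.
#'
#' @param q n x 3 matrix of crystal-frame q vectors
#' @param geometry a [detector_geometry()]
#' @param phi spindle angle (degrees) at which the q vectors were measured
#' @return numeric vector of factors in (0, 1]
#' @export
polarization_correction <- function(q, geometry, phi = 0) {
  qm <- if (is.matrix(q)) q else matrix(q, ncol = 3)
  R <- rotation_about_axis(geometry$rotation_axis, phi * pi / 180)
  qlab <- qm %*% t(R)
  k <- 2 * pi / geometry$wavelength
  s <- sweep(qlab / k, 2, c(0, 0, 1), "+")
  n2 <- unit(geometry$polarization_plane_normal)       # out-of-plane E
  e1 <- unit(pracma_cross(n2, c(0, 0, 1)))             # in-plane E
  p <- geometry$polarization_fraction
  p * (1 - (s %*% e1)[, 1]^2) + (1 - p) * (1 - (s %*% n2)[, 1]^2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Solid-angle correction factor
#'
#' Ratio of the solid angle subtended by a pixel to that of an on-axis
#' pixel; `cos^3 psi` for a flat detector normal to the beam.  Observed
#' intensities are divided by the returned factor.
#'
#' @param pixel length-2 vector or n x 2 matrix of (fast, slow) coordinates
#' @param geometry a [detector_geometry()]
#' @return numeric vector of factors in (0, 1]
#' @export
solid_angle_correction <- function(pixel, geometry) {
  pm <- if (is.matrix(pixel)) pixel else matrix(pixel, ncol = 2)
  x <- (pm[, 1] - geometry$beam_center[1]) * geometry$pixel_size
  y <- (pm[, 2] - geometry$beam_center[2]) * geometry$pixel_size
  cospsi <- geometry$distance / sqrt(x^2 + y^2 + geometry$distance^2)
  cospsi^3
}

#' Apply the per-image scale factor
#'
#' Divides the pixel intensities by the frame's scale factor (mask and
#' oscillation metadata unchanged) and resets the stored factor to 1 so
#' the operation is idempotent.
#'
#' @param frame a [diffraction_frame()]
#' @return rescaled `diffraction_frame`
#' @export
apply_frame_scale <- function(frame) {
  if (frame$scale_factor <= 0) stop("scale_factor must be positive")
  frame$pixels <- frame$pixels / frame$scale_factor
  frame$scale_factor <- 1
  frame
}

# Photometric correction of a whole frame: divide by polarization and
# solid-angle factors (no Lorentz factor anywhere in the pipeline).
correct_frame_photometric <- function(frame, geometry) {
  px <- pixel_grid(geometry)
  qc <- pixel_to_q(px, geometry, phi = phi_mid(frame))
  P <- polarization_correction(qc, geometry, phi = phi_mid(frame))
  Om <- solid_angle_correction(px, geometry)
  frame$pixels <- frame$pixels / matrix(P * Om, geometry$n_fast, geometry$n_slow)
  frame
}

# All pixel-center coordinates of a detector, fast index varying fastest.
pixel_grid <- function(geometry) {
  cbind(rep(seq_len(geometry$n_fast), times = geometry$n_slow),
        rep(seq_len(geometry$n_slow), each = geometry$n_fast))
}

# |q| for every pixel of a geometry (phi-independent).
pixel_qabs <- function(geometry) {
  q <- pixel_q_lab(pixel_grid(geometry)[, 1], pixel_grid(geometry)[, 2],
                   geometry)
  matrix(sqrt(rowSums(q^2)), geometry$n_fast, geometry$n_slow)
}
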