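test_that("pixel_to_q fixes the q = 2*pi/d convention and is phi-consistent", {
  g <- detector_geometry(100, 0.2, 256, 256, c(128.5, 128.5), 0.9795)
  # beam-center pixel maps to the origin of reciprocal space at any phi
  for (phi in c(0, 37, 90))
    expect_equal(as.vector(pixel_to_q(c(128.5, 128.5), g, phi = phi)),
                 c(0, 0, 0), tolerance = 1e-12)
  # a pixel at the scattering angle of a 4.8 A spacing sits at ~1.31 A^-1,
  # the position of the amorphous-oil contaminant ring
  th <- asin(0.9795 / (2 * 4.8))
  r <- 100 * tan(2 * th)
  q <- pixel_to_q(c(128.5 + r / 0.2, 128.5), g)
  expect_equal(sqrt(sum(q^2)), 2 * pi / 4.8, tolerance = 1e-6)
  expect_equal(round(sqrt(sum(q^2)), 1), 1.3)
  # rotation changes direction, never the modulus
  q90 <- pixel_to_q(c(128.5 + r / 0.2, 128.5), g, phi = 90)
  expect_equal(sqrt(sum(q90^2)), sqrt(sum(q^2)), tolerance = 1e-10)
  expect_gt(max(abs(q90 - q)), 1e-3)
  expect_error(pixel_to_q(c(0, 10), g), "bounds")
})

test_that("every pixel q obeys the Ewald bound and round-trips to its pixel", {
  g <- tiny_geom(32)
  px <- diffusemap:::pixel_grid(g)
  for (phi in c(0, 23)) {
    q <- pixel_to_q(px, g, phi = phi)
    expect_true(all(sqrt(rowSums(q^2)) <= 4 * pi / g$wavelength + 1e-12))
    back <- q_to_pixel(q, g, phi = phi)
    expect_equal(back, px, tolerance = 1e-9, ignore_attr = TRUE)
    # and q -> pixel -> q closes within 1e-6 A^-1
    q2 <- pixel_to_q(back, g, phi = phi)
    expect_lt(max(abs(q2 - q)), 1e-6)
  }
})

test_that("polarization factor matches the Thomson limits", {
  g <- detector_geometry(100, 0.2, 256, 256, c(128.5, 128.5), 1.0,
                         polarization_fraction = 0.5)
  expect_equal(polarization_correction(matrix(0, 1, 3), g), 1)
  # unpolarized beam, scattering in the polarization plane at 2theta:
  # P = (1 + cos^2 2theta)/2, so 0.5 at 90 degrees
  k <- 2 * pi
  for (tth in c(30, 60, 90) * pi / 180) {
    s <- c(sin(tth), 0, cos(tth))
    q <- k * (s - c(0, 0, 1))
    expect_equal(polarization_correction(matrix(q, 1, 3), g),
                 (1 + cos(tth)^2) / 2, tolerance = 1e-12)
  }
  # fully polarized beam, scattering perpendicular to the polarization
  # plane: no dipole projection loss at any angle
  gp <- detector_geometry(100, 0.2, 256, 256, c(128.5, 128.5), 1.0,
                          polarization_fraction = 1)
  for (tth in c(30, 60, 90) * pi / 180) {
    s <- c(0, sin(tth), cos(tth))
    q <- k * (s - c(0, 0, 1))
    expect_equal(polarization_correction(matrix(q, 1, 3), gp), 1,
                 tolerance = 1e-12)
  }
})

test_that("solid-angle factor is cos^3 psi, 1 on axis, strictly decreasing", {
  g <- tiny_geom(64)
  expect_equal(solid_angle_correction(g$beam_center, g), 1)
  offs <- seq(0, 25, by = 5)
  f <- solid_angle_correction(cbind(g$beam_center[1] + offs,
                                    g$beam_center[2]), g)
  psi <- atan(offs * g$pixel_size / g$distance)
  expect_equal(f, cos(psi)^3, tolerance = 1e-12)
  expect_true(all(diff(f) < 0))
})

test_that("frame scaling divides intensities and nothing else", {
  fr <- diffraction_frame(matrix(10, 4, 4), phi_start = 3, phi_width = 0.5,
                          scale_factor = 2)
  out <- apply_frame_scale(fr)
  expect_equal(out$pixels, matrix(5, 4, 4))
  expect_equal(out$valid_mask, fr$valid_mask)
  expect_equal(out$phi_start, 3)
  # two frames differing only by a global factor coincide after scaling
  fr2 <- diffraction_frame(matrix(30, 4, 4), scale_factor = 6)
  expect_equal(apply_frame_scale(fr2)$pixels, out$pixels)
  expect_error(diffraction_frame(matrix(1, 2, 2), scale_factor = 0),
               "positive")
})

test_that("corrected intensities contain only polarization, solid angle and scale", {
  # no Lorentz factor anywhere: correcting a frame of ones must give
  # exactly 1 / (P * Omega * scale)
  g <- tiny_geom(16)
  fr <- diffraction_frame(matrix(1, 16, 16), phi_start = 0, phi_width = 2,
                          scale_factor = 1.7)
  out <- apply_frame_scale(diffusemap:::correct_frame_photometric(fr, g))
  px <- diffusemap:::pixel_grid(g)
  qc <- pixel_to_q(px, g, phi = 1)
  P <- polarization_correction(qc, g, phi = 1)
  Om <- solid_angle_correction(px, g)
  expect_equal(as.vector(out$pixels), 1 / (P * Om * 1.7), tolerance = 1e-12)
})

test_that("space-group operator tables are closed groups of the right order", {
  sizes <- c(P1 = 1, P212121 = 4, P4222 = 8, P6322 = 12)
  for (sg in names(sizes)) {
    ops <- spacegroup_ops(sg)
    expect_length(ops$recip, sizes[[sg]])
    expect_true(diffusemap:::ops_closed(ops$recip))
    expect_length(laue_group(ops$recip), 2 * sizes[[sg]])
  }
  expect_error(spacegroup_ops("P321"), "unsupported")
})

test_that("reciprocal basis inverts the real basis; symmetry rotations are orthogonal", {
  cells <- list(c(24, 26, 30, 90, 90, 90),
                c(61.3, 61.3, 128.7, 90, 90, 90),
                c(161.3, 161.3, 139.4, 90, 90, 120))
  sgs <- c("P212121", "P4222", "P6322")
  for (i in seq_along(cells)) {
    A <- real_basis(cells[[i]])
    B <- reciprocal_basis(cells[[i]])
    expect_equal(t(B) %*% A, diag(3), tolerance = 1e-12)
    cr <- crystal_frame(cells[[i]], sgs[i])
    for (M in cr$ops$recip) {
      R <- diffusemap:::op_cartesian(cr, M)
      expect_equal(t(R) %*% R, diag(3), tolerance = 1e-9)
    }
  }
})
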