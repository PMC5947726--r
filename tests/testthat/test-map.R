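test_that("voxel statistics: mean, sample-sd SNR, undefined singletons", {
  # a far, tiny detector puts every pixel into the origin voxel
  g <- detector_geometry(1e5, 0.05, 3, 1, c(2, 1), 1.0)
  cr <- p1_crystal()
  fr <- diffraction_frame(matrix(c(1, 2, 3), 3, 1))
  mp <- accumulate(list(fr), g, cr, grid_extent = 2, oversampling = 3)
  v <- which(mp$n_obs == 3)
  expect_length(v, 1)
  expect_equal(mp$intensity[v], 2)
  expect_equal(mp$snr[v], 2 / sd(c(1, 2, 3)))  # mean / sample sd = 2
  # single observation: defined intensity, undefined SNR
  g1 <- detector_geometry(1e5, 0.05, 1, 1, c(1, 1), 1.0)
  mp1 <- accumulate(list(diffraction_frame(matrix(5, 1, 1))), g1, cr, 2, 3)
  v1 <- which(mp1$n_obs == 1)
  expect_equal(mp1$intensity[v1], 5)
  expect_true(is.na(mp1$snr[v1]))
})

test_that("n_obs is conserved: accepted pixels = merged + dropped", {
  sc <- default_scenario(poisson = FALSE, bragg = FALSE, background = FALSE,
                         jitter = 0, n_frames = 4)
  mp <- accumulate(sc$frames, sc$geom, sc$crystal, 8, 3)
  total <- sum(vapply(sc$frames, function(f) sum(f$valid_mask), 0))
  expect_equal(sum(mp$n_obs) + attr(mp, "dropped"), total)
})

test_that("symmetrization averages orbits with n_obs weights, idempotently", {
  cr <- p1_crystal()
  gr <- map_grid(cr, 2, 3)
  idx <- diffusemap:::trip_to_index(gr, rbind(c(2, 1, 3), c(-2, -1, -3)))
  intens <- rep(NA_real_, nrow(gr$hkl))
  nobs <- rep(0L, nrow(gr$hkl))
  intens[idx] <- c(4, 6); nobs[idx] <- c(1L, 1L)
  mp <- diffuse_map(gr, intens, n_obs = nobs)
  s1 <- symmetrize(mp)
  expect_equal(s1$intensity[idx], c(5, 5))       # equal-weight Friedel mean
  expect_equal(s1$multiplicity[idx], c(2, 2))
  s2 <- symmetrize(s1)
  expect_equal(s2$intensity, s1$intensity)       # idempotent
  # n_obs-weighted variant
  nobs[idx] <- c(1L, 3L)
  sw <- symmetrize(diffuse_map(gr, intens, n_obs = nobs))
  expect_equal(sw$intensity[idx], c(5.5, 5.5))
})

test_that("symmetry_cc is 1 for symmetric maps and drops with noise", {
  cr <- ortho_crystal()
  gr <- map_grid(cr, 3, 3)
  m <- flat_toy(5, cr, seed = 2)
  tsym <- symmetrized_molecular_transform(m, gr)
  mp <- diffuse_map(gr, tsym$intensity, n_obs = rep(1L, nrow(gr$hkl)))
  expect_equal(symmetry_cc(mp, "both"), 1, tolerance = 1e-12)
  expect_equal(symmetry_cc(mp, "friedel"), 1, tolerance = 1e-12)
  noisy <- with_voxel_noise(mp, snr = 0.05, seed = 9)  # noise >> signal
  expect_lt(symmetry_cc(noisy, "both"), 0.2)
  # error with too few defined pairs
  sparse <- diffuse_map(gr, rep(NA_real_, nrow(gr$hkl)))
  expect_error(symmetry_cc(sparse), "pairs")
})

test_that("radial-average subtraction zeroes shells and ignores radial additions", {
  cr <- p1_crystal()
  gr <- map_grid(cr, 3, 3)
  radial <- exp(-gr$qabs)
  out <- subtract_radial_average(diffuse_map(gr, radial))
  expect_lt(max(abs(out$intensity)), 1e-2 * max(radial))
  m <- flat_toy(4, cr, seed = 5)
  base <- symmetrized_molecular_transform(m, gr)$intensity
  a1 <- subtract_radial_average(diffuse_map(gr, base))$intensity
  # the radial estimate is interpolated between shells, so a smooth
  # radial addition cancels up to the interpolation error
  a2 <- subtract_radial_average(diffuse_map(gr, base + 5 * radial + 3))$intensity
  expect_lt(max(abs(a1 - a2)), 0.01 * diff(range(base)))
  # shell means of the output are small relative to the input scale;
  # with interpolated (not piecewise-constant) radial subtraction they
  # vanish only approximately on sparse toy shells
  sm <- diffusemap:::shell_means(diffuse_map(gr, a1))
  expect_lt(max(abs(sm$means), na.rm = TRUE), 0.05 * diff(range(base)))
})

test_that("positivity offset shifts without changing correlations", {
  cr <- p1_crystal()
  gr <- map_grid(cr, 2, 3)
  v <- sin(seq_len(nrow(gr$hkl))) * 2 - 1   # min near -3
  mp <- positivity_offset(diffuse_map(gr, v))
  expect_gt(min(mp$intensity), 0)
  expect_equal(attr(mp, "offset"), -min(v) + 1e-6 * diff(range(v)))
  other <- cos(seq_len(nrow(gr$hkl)))
  expect_equal(weighted_cc(mp$intensity, other),
               weighted_cc(v, other), tolerance = 1e-9)
})

test_that("maps survive a CSV + JSON round trip", {
  cr <- ortho_crystal()
  gr <- map_grid(cr, 2, 3)
  m <- flat_toy(4, cr, seed = 11)
  mp <- predict_rigid_translations(m, gr, 0.5)
  mp$n_obs <- rep(2L, nrow(gr$hkl))
  pref <- file.path(tempdir(), "map_rt")
  write_map(mp, pref)
  back <- read_map(pref)
  expect_equal(back$intensity, mp$intensity, tolerance = 1e-12)
  expect_equal(back$grid$crystal$cell, cr$cell)
})
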