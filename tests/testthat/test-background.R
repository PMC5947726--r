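test_that("radial profiles are masked means over |q| bins", {
  qa <- matrix(seq(0.1, 2, length.out = 400), 20, 20)
  fr <- diffraction_frame(matrix(7, 20, 20))
  p <- radial_profile(fr, qa, n_bins = 10)
  expect_true(all(p$intensity[p$n_pixels > 0] == 7))
  # image equal to |q| reproduces the bin centers
  fr2 <- diffraction_frame(qa)
  p2 <- radial_profile(fr2, qa, n_bins = 20)
  ok <- p2$n_pixels > 0
  expect_equal(p2$intensity[ok], p2$q_centers[ok], tolerance = 0.05)
  # masked pixels are excluded
  vm <- matrix(TRUE, 20, 20); vm[3, 3] <- FALSE
  px <- matrix(7, 20, 20); px[3, 3] <- 1000
  p3 <- radial_profile(diffraction_frame(px, vm), qa, n_bins = 10)
  expect_true(all(p3$intensity[p3$n_pixels > 0] == 7))
})

test_that("background fit recovers generating coefficients", {
  q <- seq(0.3, 2, length.out = 100)
  prof <- structure(list(q_centers = q, intensity = 2 * q^2 + 1,
                         n_pixels = rep(10, 100)), class = "radial_profile")
  fit <- fit_reference_background(prof, synthetic_reference_profile,
                                  fit_range = c(0.63, 1.88))
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(fit$c, 1, tolerance = 1e-6)
  expect_equal(fit$m, 0, tolerance = 1e-6)
  # a profile that IS the reference: m ~ 1, q0 ~ 0, polynomial ~ 0
  prof2 <- structure(list(q_centers = q,
                          intensity = synthetic_reference_profile(q),
                          n_pixels = rep(10, 100)), class = "radial_profile")
  fit2 <- fit_reference_background(prof2, synthetic_reference_profile)
  expect_equal(fit2$m, 1, tolerance = 1e-3)
  expect_lt(abs(fit2$q0), 1e-3)
  expect_lt(max(abs(c(fit2$a, fit2$b, fit2$c))), 1e-3)
  # the golden-section best-so-far residual never increases
  expect_true(all(diff(fit2$trace) <= 1e-12))
})

test_that("a planted reference shift of 0.007 is recovered", {
  q <- seq(0.3, 2, length.out = 150)
  y <- 3 * q^2 - q + 2 +
    1.4 * synthetic_reference_profile(q - 0.007)
  prof <- structure(list(q_centers = q, intensity = y,
                         n_pixels = rep(10, 150)), class = "radial_profile")
  fit <- fit_reference_background(prof, synthetic_reference_profile)
  expect_equal(fit$q0, 0.007, tolerance = 1e-3)
  expect_equal(fit$m, 1.4, tolerance = 1e-2)
})

test_that("PCA residual correction removes planted inter-frame variance", {
  q <- seq(0.1, 2, length.out = 80)
  base <- 50 * exp(-((q - 1) / 0.5)^2)
  mk <- function(y) structure(list(q_centers = q, intensity = y,
                                   n_pixels = rep(5, 80)),
                              class = "radial_profile")
  # identical frames: zero correction everywhere
  same <- lapply(1:6, function(i) mk(base))
  out0 <- pca_residual_correction(same, 2)
  expect_lt(max(abs(out0$background)), 1e-8)
  # one frame with an added Gaussian bump: the first component isolates it
  bump <- 20 * exp(-((q - 1.3) / 0.1)^2)
  profs <- c(lapply(1:5, function(i) mk(base)), list(mk(base + bump)))
  out <- pca_residual_correction(profs, 1)
  corrected <- do.call(rbind, lapply(profs, `[[`, "intensity")) -
    out$background
  expect_lt(max(apply(corrected, 2, sd)), 1e-6)
  expect_gt(abs(cor(out$background[6, ], bump)), 0.999)
  # validation errors
  expect_error(pca_residual_correction(profs, 6), "smaller")
  # zero components is a no-op
  outz <- pca_residual_correction(profs, 0)
  expect_true(all(outz$background == 0))
})

test_that("the shipped reference table is usable as a reference profile", {
  path <- system.file("extdata", "synthetic_amorphous_reference.txt",
                      package = "diffusemap")
  tab <- read.table(path)
  f <- diffusemap:::reference_fun(as.matrix(tab))
  q <- seq(0.3, 2, by = 0.05)
  expect_equal(f(q), synthetic_reference_profile(q), tolerance = 1e-3)
})

test_that("pipeline background stages only act radially", {
  # a per-frame radial correction never changes anisotropy at fixed |q|:
  # two pixels at the same |q| receive the same correction
  sc <- default_scenario(poisson = FALSE, bragg = FALSE, n_frames = 4)
  qa <- diffusemap:::pixel_qabs(sc$geom)
  profs <- lapply(sc$frames, radial_profile, qabs = qa, n_bins = 50)
  pca <- pca_residual_correction(profs, 2)
  fr <- sc$frames[[1]]
  corr <- fr$pixels - diffusemap:::subtract_radial_background(
    fr, qa, pca$q_centers, pca$background[1, ])$pixels
  # pixels mirrored across the beam center share |q| exactly, so their
  # corrections must be identical
  n <- nrow(corr)
  expect_equal(corr, corr[n:1, ], tolerance = 1e-12)
  expect_equal(corr, corr[, n:1], tolerance = 1e-12)
})
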