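#' Radial intensity profile of a frame
#'
#' Mean intensity of valid pixels in equal-width |q| bins.  Bins without
#' pixels are returned as NA and excluded from all downstream fits.
#'
#' @param frame a [diffraction_frame()]
#' @param qabs matrix of per-pixel |q| values
#' @param n_bins number of radial bins
#' @param q_range optional c(lo, hi) binning range; defaults to the range
#'   of `qabs`
#' @return object of class `radial_profile`: `q_centers`, `intensity`,
#'   `n_pixels`
#' @export
radial_profile <- function(frame, qabs, n_bins = 100, q_range = NULL) {
  rng <- q_range %||% range(qabs)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(qabs, br, all.inside = TRUE), 1L), n_bins)
  sel <- frame$valid_mask & is.finite(frame$pixels)
  mu <- group_means(frame$pixels[sel], bin[sel], n_bins)
  cnt <- tabulate(bin[sel], n_bins)
  structure(list(q_centers = (br[-1] + br[-length(br)]) / 2,
                 intensity = mu, n_pixels = cnt),
            class = "radial_profile")
}

#' Synthetic amorphous reference profile
#'
#' A smooth stand-in for the scattering profile of an amorphous coating
#' oil: a broad peak centered at 1.3 inverse Angstrom over a wide shoulder.
#' A measured reference (two-column table of |q| and intensity) can be
#' used anywhere this function is accepted; a tabulated copy of this
#' synthetic profile ships as
#' `system.file("extdata", "synthetic_amorphous_reference.txt",
#' package = "diffusemap")`.
#'
#' @param q |q| values (A^-1)
#' @return non-negative profile values (arbitrary units, peak 1)
#' @export
synthetic_reference_profile <- function(q) {
  exp(-(q - 1.3)^2 / (2 * 0.12^2)) + 0.25 * exp(-(q - 1.1)^2 / (2 * 0.45^2))
}

reference_fun <- function(reference) {
  if (is.function(reference)) return(reference)
  if (inherits(reference, "radial_profile"))
    return(function(q) interp_clamped(reference$q_centers,
                                      reference$intensity, q))
  if (is.matrix(reference) || is.data.frame(reference)) {
    tab <- as.matrix(reference)
    return(function(q) interp_clamped(tab[, 1], tab[, 2], q))
  }
  stop("reference must be a function, radial_profile or two-column table")
}

#' Fit a polynomial-plus-reference background to a radial profile
#'
#' Models the radial intensity in `fit_range` as
#' `a q^2 + b q + c + m * I_ref(q - q0)`: linear least squares in
#' `(a, b, c, m)` with a golden-section search over the reference shift
#' `q0`.  The best-so-far residual is non-increasing over the search.  A
#' negative reference scale is clamped to `m = 0` (pure polynomial).
#'
#' @param profile a [radial_profile()]
#' @param reference reference profile: function of |q|, a
#'   `radial_profile`, or a two-column table
#' @param fit_range c(q_lo, q_hi) in A^-1
#' @param q0_range search interval for the shift (A^-1)
#' @return object of class `background_fit` with coefficients `a`, `b`,
#'   `c`, `m`, `q0`, the fit `residual`, the search `trace`, and
#'   `component(q)`, the scaled shifted reference to subtract
#' @export
fit_reference_background <- function(profile, reference,
                                     fit_range = c(0.63, 1.88),
                                     q0_range = c(-0.05, 0.05)) {
  ref <- reference_fun(reference)
  sel <- is.finite(profile$intensity) &
    profile$q_centers >= fit_range[1] & profile$q_centers <= fit_range[2]
  if (sum(sel) < 5)
    stop("fewer defined profile bins than fit parameters in fit_range")
  q <- profile$q_centers[sel]; y <- profile$intensity[sel]
  fit_at <- function(q0) {
    X <- cbind(q^2, q, 1, ref(q - q0))
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, 4))
    if (any(is.na(cf)) || cf[4] < 0) {
      X <- X[, 1:3, drop = FALSE]
      cf <- c(qr.coef(qr(X), y), 0)
    }
    res <- sum((y - X %*% cf[seq_len(ncol(X))])^2)
    list(coef = cf, residual = res)
  }
  gs <- golden_section(function(q0) fit_at(q0)$residual,
                       q0_range[1], q0_range[2], tol = 1e-5)
  best <- fit_at(gs$minimum)
  cf <- unname(best$coef)
  structure(list(a = cf[1], b = cf[2], c = cf[3], m = cf[4],
                 q0 = gs$minimum, residual = best$residual,
                 trace = gs$trace,
                 component = local({
                   m <- cf[4]; q0 <- gs$minimum
                   function(qq) m * ref(qq - q0)
                 })),
            class = "background_fit")
}

#' Remove the largest variance components between radial profiles
#'
#' Standard (mean-centered) principal-component analysis of the per-frame
#' radial profiles; the per-frame background is the reconstruction of the
#' frame's deviation from the mean profile using the first `n_components`
#' components (scores times loadings).  Subtracting it equalizes the
#' radially symmetric scattering across the rotation range while leaving
#' anisotropic structure at fixed |q| untouched.
#'
#' @param profiles list of [radial_profile()]s on a common |q| grid
#' @param n_components number of components to remove (0 disables)
#' @return list with `components` (bins x k loadings), `eigenvalues`
#'   (component variances), `projections` (frames x k scores),
#'   `background` (frames x bins matrix to subtract), `q_centers`
#' @export
pca_residual_correction <- function(profiles, n_components = 2) {
  if (length(profiles) < 2) stop("need at least 2 frames")
  if (n_components >= length(profiles))
    stop("n_components must be smaller than the number of frames")
  qc <- profiles[[1]]$q_centers
  X <- do.call(rbind, lapply(profiles, function(p) {
    stopifnot(isTRUE(all.equal(p$q_centers, qc)))
    p$intensity
  }))
  ok <- colSums(!is.finite(X)) == 0
  bg <- matrix(0, nrow(X), ncol(X))
  if (n_components == 0 || sum(ok) < 2) {
    return(list(components = matrix(0, ncol(X), 0), eigenvalues = numeric(0),
                projections = matrix(0, nrow(X), 0), background = bg,
                q_centers = qc))
  }
  pc <- prcomp(X[, ok, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  ld <- pc$rotation[, seq_len(k), drop = FALSE]
  bg[, ok] <- sc %*% t(ld)
  comps <- matrix(NA_real_, ncol(X), k)
  comps[ok, ] <- ld
  list(components = comps, eigenvalues = pc$sdev[seq_len(k)]^2,
       projections = sc, background = bg, q_centers = qc)
}

# Subtract a per-frame radial background (values on q_centers) from all
# pixels of a frame by linear interpolation in |q|.
subtract_radial_background <- function(frame, qabs, q_centers, bg_values) {
  ok <- is.finite(bg_values)
  if (!any(ok)) return(frame)
  corr <- interp_clamped(q_centers[ok], bg_values[ok], as.vector(qabs))
  frame$pixels <- frame$pixels - matrix(corr, nrow(qabs), ncol(qabs))
  frame
}
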