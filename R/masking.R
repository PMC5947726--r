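#' Bragg-peak masking configuration
#'
#' @param window square window edge (pixels) for local outlier statistics
#' @param local_sigma_cut mask a predicted pixel when its intensity
#'   exceeds the neighborhood mean by this many standard deviations
#' @param radial_mad_cut robust cut (in raw median-absolute-deviation
#'   units, no normality factor) for the per-resolution-shell filter
#' @param contaminated_region_mad_cut tighter cut applied inside
#'   `contaminated_region`
#' @param contaminated_region optional logical matrix (detector shaped)
#'   marking a region with known non-Bragg contamination
#' @param hkl_tolerance fractional Miller-index distance (per axis)
#'   defining the predicted-reflection footprint
#' @param n_shells resolution shells for the radial filter
#' @param n_phi_samples spindle positions sampled across the oscillation
#'   when predicting reflections
#' @return list of class `mask_config`
#' @export
mask_config <- function(window = 30, local_sigma_cut = 3,
                        radial_mad_cut = 5, contaminated_region_mad_cut = 2.5,
                        contaminated_region = NULL, hkl_tolerance = 0.25,
                        n_shells = 100, n_phi_samples = 5) {
  if (window < 3) stop("window must be at least 3 pixels")
  if (local_sigma_cut <= 0 || radial_mad_cut <= 0 ||
      contaminated_region_mad_cut <= 0)
    stop("all cuts must be positive")
  structure(list(window = as.integer(window),
                 local_sigma_cut = local_sigma_cut,
                 radial_mad_cut = radial_mad_cut,
                 contaminated_region_mad_cut = contaminated_region_mad_cut,
                 contaminated_region = contaminated_region,
                 hkl_tolerance = hkl_tolerance,
                 n_shells = as.integer(n_shells),
                 n_phi_samples = as.integer(n_phi_samples)),
            class = "mask_config")
}

# Fractional Miller indices of every pixel at a given spindle angle.
frame_hkl <- function(geometry, crystal, phi) {
  qc <- pixel_to_q(pixel_grid(geometry), geometry, phi = phi)
  qc %*% t(solve(crystal$orientation))
}

#' Predict Bragg-affected pixels for a frame
#'
#' A pixel is predicted to be spanned by a reflection if, at any of the
#' sampled spindle angles across the frame's oscillation, its fractional
#' Miller index lies strictly within `hkl_tolerance` of an integer along
#' every axis.  Zero tolerance gives the empty set; the predicted region
#' grows monotonically with the tolerance.
#'
#' @param frame a [diffraction_frame()]
#' @param geometry a [detector_geometry()]
#' @param crystal a [crystal_frame()]
#' @param config a [mask_config()]
#' @return logical matrix (detector shaped): TRUE where a reflection is
#'   predicted
#' @export
predict_spot_pixels <- function(frame, geometry, crystal,
                                config = mask_config()) {
  tol <- config$hkl_tolerance
  pred <- matrix(FALSE, geometry$n_fast, geometry$n_slow)
  if (tol <= 0) return(pred)
  phis <- seq(frame$phi_start, frame$phi_start + frame$phi_width,
              length.out = config$n_phi_samples)
  for (phi in phis) {
    hkl <- frame_hkl(geometry, crystal, phi)
    d <- abs(hkl - round(hkl))
    pred <- pred | matrix(d[, 1] < tol & d[, 2] < tol & d[, 3] < tol,
                          geometry$n_fast, geometry$n_slow)
  }
  pred
}

# Box-filter mean/sd/count over an inclusion mask, window truncated at the
# detector edges, via 2D summed-area tables.
box_stats <- function(vals, include, window) {
  nf <- nrow(vals); ns <- ncol(vals)
  v <- vals; v[!include] <- 0
  c1 <- include * 1
  sa <- function(m) {
    m <- apply(m, 2, cumsum)
    t(apply(m, 1, cumsum))
  }
  S <- sa(v); S2 <- sa(v^2); C <- sa(c1)
  lo <- -((window - 1L) %/% 2L); hi <- window %/% 2L
  r1 <- pmax(seq_len(nf) + lo - 1L, 0L); r2 <- pmin(seq_len(nf) + hi, nf)
  cl <- pmax(seq_len(ns) + lo - 1L, 0L); ch <- pmin(seq_len(ns) + hi, ns)
  pick <- function(M) {
    Mp <- rbind(0, cbind(0, M))  # 1-padded for zero-row/col access
    Mp[1 + r2, 1 + ch, drop = FALSE] - Mp[1 + r1, 1 + ch, drop = FALSE] -
      Mp[1 + r2, 1 + cl, drop = FALSE] + Mp[1 + r1, 1 + cl, drop = FALSE]
  }
  n <- pick(C); s <- pick(S); s2 <- pick(S2)
  mean <- ifelse(n > 0, s / n, NA_real_)
  varr <- ifelse(n > 1, pmax(s2 - n * mean^2, 0) / (n - 1), 0)
  list(mean = mean, sd = sqrt(varr), n = n)
}

#' Mask predicted Bragg pixels that are local outliers
#'
#' A predicted pixel is masked when its intensity exceeds the mean of the
#' valid, non-predicted pixels in the surrounding window by more than
#' `local_sigma_cut` standard deviations (strict inequality).  Windows are
#' truncated at detector edges; a predicted pixel whose window holds no
#' non-predicted valid pixel is masked unconditionally.  Masked pixels are
#' dropped, never replaced.  Idempotent for a fixed predicted set.
#'
#' @inheritParams predict_spot_pixels
#' @param spot_pixels logical matrix from [predict_spot_pixels()]
#' @return the frame with `valid_mask` updated
#' @export
mask_local_outliers <- function(frame, spot_pixels, config = mask_config()) {
  prior <- frame_stat_mask(frame)
  include <- prior & !spot_pixels
  st <- box_stats(frame$pixels, include, config$window)
  thresh <- st$mean + config$local_sigma_cut * st$sd
  bad <- spot_pixels & prior & (st$n == 0 | frame$pixels > thresh)
  bad[is.na(bad)] <- FALSE
  set_outliers(frame, bad)
}

#' Mask radial outliers per resolution shell
#'
#' Pixels whose intensity exceeds the shell median by more than
#' `radial_mad_cut` raw median absolute deviations are masked
#' (`contaminated_region_mad_cut` inside the configured contaminated
#' region).  Shells with fewer than 10 valid pixels are skipped with a
#' warning.  Statistics are computed over the union of currently valid
#' and previously outlier-masked pixels, which makes the operation
#' idempotent.
#'
#' @inheritParams predict_spot_pixels
#' @param qabs matrix of per-pixel |q| (see internal `pixel_qabs`)
#' @return the frame with `valid_mask` updated
#' @export
mask_radial_outliers <- function(frame, qabs, config = mask_config()) {
  prior <- frame_stat_mask(frame)
  rng <- range(qabs)
  br <- seq(rng[1], rng[2], length.out = config$n_shells + 1)
  bin <- pmin(pmax(findInterval(qabs, br, all.inside = TRUE), 1L),
              config$n_shells)
  cut <- matrix(config$radial_mad_cut, nrow(qabs), ncol(qabs))
  if (!is.null(config$contaminated_region))
    cut[config$contaminated_region] <- config$contaminated_region_mad_cut
  bad <- matrix(FALSE, nrow(qabs), ncol(qabs))
  skipped <- 0L
  for (s in seq_len(config$n_shells)) {
    sel <- bin == s & prior
    if (sum(sel) == 0) next
    if (sum(sel) < 10) { skipped <- skipped + 1L; next }
    v <- frame$pixels[sel]
    med <- median(v)
    madv <- median(abs(v - med))
    bad[sel] <- v > med + cut[sel] * madv
  }
  if (skipped > 0)
    warning(skipped, " resolution shell(s) with < 10 valid pixels skipped")
  set_outliers(frame, bad & prior)
}

# Pixels eligible for outlier statistics: valid now, or removed earlier by
# an outlier mask (keeps repeated applications exactly idempotent).
frame_stat_mask <- function(frame) {
  frame$valid_mask | (frame$outlier_mask %||% matrix(FALSE,
                                                     nrow(frame$pixels),
                                                     ncol(frame$pixels)))
}

set_outliers <- function(frame, bad) {
  om <- frame$outlier_mask %||% matrix(FALSE, nrow(frame$pixels),
                                       ncol(frame$pixels))
  frame$outlier_mask <- om | bad
  frame$valid_mask <- frame_stat_mask(frame) & !frame$outlier_mask
  frame
}
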