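#' Full reconstruction pipeline: corrected frames to symmetrized map
#'
#' Applies, in order: photometric corrections (division by polarization
#' and solid-angle factors; no Lorentz factor), per-frame scale factors,
#' Bragg masking (spot prediction + local outliers + radial MAD filter),
#' per-frame background removal (optional reference-profile fit plus PCA
#' of radial profiles), then merges pixels into an oversampled map,
#' symmetrizes, subtracts the radial average and applies the positivity
#' offset.  Individual stages can be disabled to study their effect on
#' the internal consistency of the map.
#'
#' @param frames list of [diffraction_frame()]s
#' @param geometry a [detector_geometry()]
#' @param crystal a [crystal_frame()]
#' @param grid_extent,oversampling grid parameters
#' @param corrections logical flags: `scale`, `mask`, `background`
#'   (photometric correction is always applied)
#' @param mask_cfg a [mask_config()]
#' @param background_opts list: `n_components` (PCA components to remove,
#'   default 2), `n_bins`, `reference` (profile function or table; NULL
#'   skips the reference fit), `fit_range`, `q0_range`
#' @param symmetrize,radial_subtract,positivity enable the map-space
#'   post-processing stages
#' @return list with `map` (final [diffuse_map()]), `map_unsym` (merged,
#'   pre-symmetrization), `background_fits`, `pca`, `masked_fraction`
#' @export
reconstruct_map <- function(frames, geometry, crystal, grid_extent = 8,
                            oversampling = 3,
                            corrections = list(scale = TRUE, mask = TRUE,
                                               background = TRUE),
                            mask_cfg = mask_config(),
                            background_opts = list(),
                            symmetrize = TRUE, radial_subtract = TRUE,
                            positivity = TRUE) {
  qabs_m <- pixel_qabs(geometry)
  bo <- utils::modifyList(list(n_components = 2, n_bins = 100,
                               reference = NULL, fit_range = c(0.63, 1.88),
                               q0_range = c(-0.05, 0.05)), background_opts)
  frames <- lapply(frames, correct_frame_photometric, geometry = geometry)
  if (isTRUE(corrections$scale))
    frames <- lapply(frames, apply_frame_scale)
  n_masked <- 0L
  if (isTRUE(corrections$mask)) {
    frames <- lapply(frames, function(fr) {
      spots <- predict_spot_pixels(fr, geometry, crystal, mask_cfg)
      fr <- mask_local_outliers(fr, spots, mask_cfg)
      fr <- suppressWarnings(mask_radial_outliers(fr, qabs_m, mask_cfg))
      fr
    })
    n_masked <- sum(vapply(frames, function(fr) sum(fr$outlier_mask), 0))
  }
  bg_fits <- NULL; pca <- NULL
  if (isTRUE(corrections$background)) {
    if (!is.null(bo$reference)) {
      bg_fits <- lapply(frames, function(fr) {
        prof <- radial_profile(fr, qabs_m, n_bins = bo$n_bins)
        tryCatch(fit_reference_background(prof, bo$reference,
                                          fit_range = bo$fit_range,
                                          q0_range = bo$q0_range),
                 error = function(e) NULL)
      })
      frames <- Map(function(fr, fit) {
        if (is.null(fit)) return(fr)
        fr$pixels <- fr$pixels - matrix(fit$component(as.vector(qabs_m)),
                                        nrow(qabs_m), ncol(qabs_m))
        fr
      }, frames, bg_fits)
    }
    if (bo$n_components > 0 && length(frames) > bo$n_components) {
      profs <- lapply(frames, radial_profile, qabs = qabs_m,
                      n_bins = bo$n_bins)
      pca <- pca_residual_correction(profs, n_components = bo$n_components)
      frames <- Map(function(fr, i) {
        subtract_radial_background(fr, qabs_m, pca$q_centers,
                                   pca$background[i, ])
      }, frames, seq_along(frames))
    }
  }
  map_unsym <- accumulate(frames, geometry, crystal, grid_extent,
                          oversampling)
  map <- map_unsym
  if (symmetrize) map <- symmetrize(map)
  if (radial_subtract) map <- subtract_radial_average(map)
  if (positivity) map <- positivity_offset(map)
  npx <- length(frames) * geometry$n_fast * geometry$n_slow
  list(map = map, map_unsym = map_unsym, background_fits = bg_fits,
       pca = pca, masked_fraction = n_masked / npx)
}
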