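#' Diffuse scattering map container
#'
#' A `diffuse_map` binds per-voxel statistics to a [map_grid()]: mean
#' intensity, number of contributing pixel observations, symmetry
#' multiplicity and signal-to-noise ratio.  Voxels with no observations
#' carry NA intensity and are excluded from all downstream statistics.
#'
#' @param grid a [map_grid()]
#' @param intensity numeric vector of per-voxel intensities (NA undefined)
#' @param n_obs integer vector of contributing pixels per voxel
#' @param multiplicity symmetry-equivalents averaged per voxel
#' @param snr per-voxel signal-to-noise ratio
#' @return object of class `diffuse_map`
#' @export
diffuse_map <- function(grid, intensity, n_obs = NULL, multiplicity = NULL,
                        snr = NULL) {
  nv <- n_voxels(grid)
  stopifnot(length(intensity) == nv)
  if (!is.null(n_obs)) stopifnot(length(n_obs) == nv, all(n_obs >= 0))
  structure(list(grid = grid, intensity = as.numeric(intensity),
                 n_obs = n_obs, multiplicity = multiplicity, snr = snr),
            class = "diffuse_map")
}

#' @export
print.diffuse_map <- function(x, ...) {
  nd <- sum(is.finite(x$intensity))
  cat(sprintf("diffuse_map: %d^3 voxels (extent %d, oversampling %d), %d defined (%.1f%%)\n",
              x$grid$n_axis, x$grid$grid_extent, x$grid$oversampling,
              nd, 100 * nd / n_voxels(x$grid)))
  invisible(x)
}

defined_voxels <- function(map) is.finite(map$intensity)

#' Merge corrected frames into a reciprocal-space map
#'
#' Every valid pixel is mapped to its fractional Miller index at the
#' frame's mid-oscillation angle and assigned to the nearest grid node;
#' voxel intensity is the mean of the contributing pixels, and the voxel
#' SNR is mean / sample standard deviation (undefined for fewer than two
#' observations).  Pixels falling outside the grid are dropped and
#' counted in the `dropped` attribute.
#'
#' @param frames list of corrected, masked [diffraction_frame()]s
#' @param geometry a [detector_geometry()]
#' @param crystal a [crystal_frame()]
#' @param grid_extent,oversampling grid parameters (see [map_grid()])
#' @return a [diffuse_map()] with attribute `dropped`
#' @export
accumulate <- function(frames, geometry, crystal, grid_extent = 8,
                       oversampling = 3) {
  grid <- map_grid(crystal, grid_extent, oversampling)
  nv <- n_voxels(grid)
  Oinv <- solve(crystal$orientation)
  px <- pixel_grid(geometry)
  sums <- numeric(nv); sums2 <- numeric(nv); cnt <- numeric(nv)
  dropped <- 0L
  for (fr in frames) {
    qc <- pixel_to_q(px, geometry, phi = phi_mid(fr))
    hkl <- qc %*% t(Oinv)
    idx <- hkl_to_index(grid, hkl)
    val <- as.vector(fr$pixels)
    keep <- as.vector(fr$valid_mask) & is.finite(val)
    dropped <- dropped + sum(keep & is.na(idx))
    keep <- keep & !is.na(idx)
    if (!any(keep)) next
    id <- idx[keep]; v <- val[keep]
    s <- rowsum(cbind(v, v^2, 1), id)
    at <- as.integer(rownames(s))
    sums[at] <- sums[at] + s[, 1]
    sums2[at] <- sums2[at] + s[, 2]
    cnt[at] <- cnt[at] + s[, 3]
  }
  intensity <- ifelse(cnt > 0, sums / cnt, NA_real_)
  varr <- ifelse(cnt > 1, (sums2 - cnt * (sums / cnt)^2) / (cnt - 1), NA_real_)
  varr[varr < 0] <- 0
  snr <- ifelse(cnt > 1 & varr > 0, intensity / sqrt(varr), NA_real_)
  out <- diffuse_map(grid, intensity, n_obs = as.integer(cnt), snr = snr)
  attr(out, "dropped") <- dropped
  out
}

# Orbit labels of every voxel under the grid's Laue group (canonical key).
laue_orbits <- function(grid) {
  m <- grid$grid_extent * grid$oversampling
  canon <- rep(Inf, n_voxels(grid))
  for (M in grid$laue) {
    tt <- grid$trips %*% t(M)
    canon <- pmin(canon, trip_key(tt, m))
  }
  match(canon, unique(canon))
}

#' Average Laue- and Friedel-equivalent voxels
#'
#' Each orbit under the Laue group (space-group rotations combined with
#' Friedel inversion) is assigned the n_obs-weighted mean of its defined
#' members; multiplicity records how many defined members were averaged.
#' Idempotent.
#'
#' @param map an unsymmetrized [diffuse_map()]
#' @return symmetrized `diffuse_map`
#' @export
symmetrize <- function(map) {
  grid <- map$grid
  orb <- laue_orbits(grid)
  def <- defined_voxels(map)
  w <- if (!is.null(map$n_obs)) pmax(map$n_obs, 0) else rep(1, length(orb))
  w[!def] <- 0
  iv <- ifelse(def, map$intensity, 0)
  wsum <- rowsum(w, orb)
  isum <- rowsum(w * iv, orb)
  msum <- rowsum(as.numeric(def), orb)
  keys <- as.integer(rownames(wsum))
  mean_orb <- rep(NA_real_, max(orb))
  mult_orb <- rep(0, max(orb))
  ok <- wsum[, 1] > 0
  mean_orb[keys[ok]] <- isum[ok, 1] / wsum[ok, 1]
  mult_orb[keys] <- msum[, 1]
  out <- map
  out$intensity <- mean_orb[orb]
  out$multiplicity <- mult_orb[orb]
  out
}

# Voxel pairs related by a set of symmetry operators, each unordered pair
# counted once.  op_set selects Friedel inversion, the proper Laue
# rotations, or the full Laue group.
symmetry_pairs <- function(grid, op_set = c("friedel", "laue", "both")) {
  op_set <- match.arg(op_set)
  ident <- diag(3)
  ops <- switch(op_set,
    friedel = list(-diag(3)),
    laue = Filter(function(M) !all(M == ident) && !all(M == -ident),
                  lapply(grid$crystal$ops$recip, identity)),
    both = Filter(function(M) !all(M == ident), grid$laue))
  m <- grid$grid_extent * grid$oversampling
  a <- integer(0); b <- integer(0)
  for (M in ops) {
    tt <- grid$trips %*% t(M)
    pidx <- trip_to_index(grid, tt)
    v <- seq_len(n_voxels(grid))
    keep <- !is.na(pidx) & v < pidx
    a <- c(a, v[keep]); b <- c(b, pidx[keep])
  }
  # drop duplicate pairs reached through different operators
  key <- as.numeric(a) * (n_voxels(grid) + 1) + as.numeric(b)
  dup <- duplicated(key)
  cbind(a[!dup], b[!dup])
}

#' Correlation between symmetry-related voxels
#'
#' Pearson correlation between the intensities of voxel pairs related by
#' Friedel inversion, the proper Laue rotations, or both, each unordered
#' pair counted once.  Apply to an unsymmetrized map; apply after
#' [subtract_radial_average()] for the anisotropic-signal variant.
#'
#' @param map a [diffuse_map()]
#' @param op_set "friedel", "laue" or "both"
#' @return Pearson correlation coefficient
#' @export
symmetry_cc <- function(map, op_set = c("friedel", "laue", "both")) {
  pr <- symmetry_pairs(map$grid, op_set)
  x <- map$intensity[pr[, 1]]; y <- map$intensity[pr[, 2]]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10) stop("fewer than 10 defined symmetry-related pairs")
  stats::cor(x[ok], y[ok])
}

# Shell means of a map's defined voxels over n equal-width |q| shells.
# The interpolation abscissa of each shell is the mean |q| of its defined
# voxels (less biased than the geometric bin center for partial shells).
shell_means <- function(map, n_shells = 100) {
  q <- map$grid$qabs
  def <- defined_voxels(map)
  rng <- range(q)
  br <- seq(rng[1], rng[2], length.out = n_shells + 1)
  bin <- pmin(pmax(findInterval(q, br, all.inside = TRUE), 1L), n_shells)
  mu <- group_means(map$intensity[def], bin[def], n_shells)
  qc <- group_means(q[def], bin[def], n_shells)
  fallback <- (br[-1] + br[-length(br)]) / 2
  qc[!is.finite(qc)] <- fallback[!is.finite(qc)]
  list(centers = qc, means = mu)
}

#' Subtract the interpolated radial average from a map
#'
#' Shell means (100 equal-width shells in |q| by default) are linearly
#' interpolated at each voxel's |q| and subtracted, isolating the
#' anisotropic component of the signal.  Adding any radially symmetric
#' function to a map leaves the result unchanged.
#'
#' @param map a [diffuse_map()]
#' @param n_shells number of resolution shells
#' @return `diffuse_map` with shell means approximately zero
#' @export
subtract_radial_average <- function(map, n_shells = 100) {
  sh <- shell_means(map, n_shells)
  bg <- interp_clamped(sh$centers, sh$means, map$grid$qabs)
  map$intensity <- map$intensity - bg
  map
}

#' Shift a map so every defined intensity is positive
#'
#' Adds `-min + eps` with `eps` equal to 1e-6 of the dynamic range.
#' Correlation against any other map is unchanged by the shift.
#'
#' @param map a [diffuse_map()]
#' @return shifted `diffuse_map` with attribute `offset`
#' @export
positivity_offset <- function(map) {
  def <- defined_voxels(map)
  lo <- min(map$intensity[def]); hi <- max(map$intensity[def])
  eps <- 1e-6 * if (hi > lo) (hi - lo) else 1
  off <- -lo + eps
  map$intensity <- map$intensity + off
  attr(map, "offset") <- off
  map
}

#' Write a diffuse map as CSV with a JSON sidecar
#'
#' The CSV holds one row per defined voxel (fractional h, k, l, intensity,
#' n_obs, multiplicity, snr); the sidecar records the cell, space group,
#' grid parameters and summary statistics so the map can be rebuilt.
#'
#' @param map a [diffuse_map()]
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`
#' @export
write_map <- function(map, prefix) {
  def <- defined_voxels(map)
  df <- data.frame(h = map$grid$hkl[def, 1], k = map$grid$hkl[def, 2],
                   l = map$grid$hkl[def, 3],
                   intensity = map$intensity[def],
                   n_obs = (map$n_obs %||% rep(NA, length(def)))[def],
                   multiplicity = (map$multiplicity %||% rep(NA, length(def)))[def],
                   snr = (map$snr %||% rep(NA, length(def)))[def])
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(cell = map$grid$crystal$cell,
               spacegroup = map$grid$crystal$spacegroup,
               orientation = map$grid$crystal$orientation,
               grid_extent = map$grid$grid_extent,
               oversampling = map$grid$oversampling,
               n_defined = sum(def),
               intensity_range = range(map$intensity[def]))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a diffuse map written by [write_map()]
#'
#' @param prefix path prefix used when writing
#' @return a [diffuse_map()]
#' @export
read_map <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  crystal <- crystal_frame(side$cell, side$spacegroup,
                           orientation = matrix(unlist(side$orientation), 3, 3))
  grid <- map_grid(crystal, side$grid_extent, side$oversampling)
  df <- read.csv(paste0(prefix, ".csv"))
  idx <- hkl_to_index(grid, as.matrix(df[, c("h", "k", "l")]))
  intensity <- rep(NA_real_, n_voxels(grid))
  intensity[idx] <- df$intensity
  n_obs <- rep(0L, n_voxels(grid)); n_obs[idx] <- ifelse(is.na(df$n_obs), 1L, df$n_obs)
  mult <- rep(NA_real_, n_voxels(grid)); mult[idx] <- df$multiplicity
  snr <- rep(NA_real_, n_voxels(grid)); snr[idx] <- df$snr
  diffuse_map(grid, intensity, n_obs = n_obs, multiplicity = mult, snr = snr)
}
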