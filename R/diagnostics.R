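#' Speckle and correlation-length diagnostics
#'
#' Disorder whose correlations cross unit-cell boundaries concentrates
#' diffuse intensity at reciprocal-lattice nodes ("speckles" or halos).
#' Two complementary diagnostics quantify this: the fall-off of intensity
#' with distance `dq` from the nearest node, compared against the
#' single-phonon `1/dq^2` and the liquid-like-motions
#' `8 pi gamma^3 / (1 + gamma^2 dq^2)^2` forms; and peaks of the map's
#' real-space autocorrelation at unit-cell translation vectors.
#'
#' @name diagnostics
NULL

# Cartesian distance of every voxel to its nearest integral-hkl node.
voxel_dq <- function(grid) {
  frac <- grid$hkl - round(grid$hkl)
  sqrt(rowSums((frac %*% t(grid$crystal$orientation))^2))
}

min_node_spacing <- function(grid) {
  min(sqrt(colSums(grid$crystal$orientation^2)))
}

#' Intensity fall-off around reciprocal-lattice nodes
#'
#' Bins defined voxels by resolution shell and by distance `dq` to the
#' nearest integral Miller index, recording the median intensity per
#' (shell, dq) cell, normalized so the `dq = 0` bin of each shell equals
#' one.  The `dq` bin width defaults to one tenth of the smallest
#' reciprocal-cell spacing and bins extend to half that spacing.
#'
#' @param map a [diffuse_map()] (oversampling >= 5 recommended; a warning
#'   is issued below that)
#' @param n_shells number of resolution shells
#' @return object of class `falloff_profile` with matrices
#'   `median_intensity` (normalized), `dq_mean`, `counts` (shells x bins),
#'   plus `dq_centers`, `shell_centers`
#' @export
deltaq_profile <- function(map, n_shells = 20) {
  grid <- map$grid
  if (grid$oversampling < 5)
    warning("oversampling below 5 under-resolves the dq profile")
  dq <- voxel_dq(grid)
  spacing <- min_node_spacing(grid)
  width <- spacing / 10
  n_dq <- ceiling((spacing / 2) / width)
  def <- defined_voxels(map) & dq <= spacing / 2 + 1e-12
  shell_br <- seq(min(grid$qabs[def]), max(grid$qabs[def]) * (1 + 1e-12),
                  length.out = n_shells + 1)
  shell <- pmin(pmax(findInterval(grid$qabs, shell_br, all.inside = TRUE), 1L),
                n_shells)
  dqbin <- pmin(floor(dq / width) + 1L, n_dq)
  med <- matrix(NA_real_, n_shells, n_dq)
  dqm <- matrix(NA_real_, n_shells, n_dq)
  cnt <- matrix(0L, n_shells, n_dq)
  idx <- (shell - 1L) * n_dq + dqbin
  sp <- split(which(def), idx[def])
  for (nm in names(sp)) {
    v <- sp[[nm]]
    i <- (as.integer(nm) - 1L) %/% n_dq + 1L
    j <- (as.integer(nm) - 1L) %% n_dq + 1L
    med[i, j] <- median(map$intensity[v])
    dqm[i, j] <- mean(dq[v])
    cnt[i, j] <- length(v)
  }
  norm <- med / med[, 1]
  structure(list(median_intensity = norm, raw_median = med, dq_mean = dqm,
                 counts = cnt,
                 dq_centers = (seq_len(n_dq) - 0.5) * width,
                 shell_centers = (shell_br[-1] + shell_br[-length(shell_br)]) / 2,
                 spacing = spacing),
            class = "falloff_profile")
}

#' Lowest resolution shell with enough defined dq bins to fit
#'
#' Toy-scale maps can leave the very lowest shells with too few voxels
#' off the lattice nodes; fits then use the lowest shell that has at
#' least `min_bins` defined bins at dq > 0.
#'
#' @param profile a [deltaq_profile()] result
#' @param min_bins minimum defined dq > 0 bins
#' @return shell index
#' @export
first_usable_shell <- function(profile, min_bins = 4, min_nodes = 20) {
  for (s in seq_len(nrow(profile$median_intensity))) {
    ok <- is.finite(profile$median_intensity[s, -1]) &
      profile$counts[s, -1] > 0
    if (sum(ok) >= min_bins && profile$counts[s, 1] >= min_nodes) return(s)
  }
  stop("no shell with ", min_bins, " defined dq bins and ", min_nodes,
       " lattice nodes")
}

#' Fit phonon and liquid-like-motions forms to a fall-off profile
#'
#' Least-squares fits of `a / dq^2 + c` (single-phonon prediction) and
#' `A * 8 pi gamma^3 / (1 + gamma^2 dq^2)^2 + c` (liquid-like motions
#' kernel) to the normalized profile of one resolution shell.  Both forms
#' carry the same additive floor `c`, absorbing the near-constant
#' contribution of uncorrelated disorder and of tails from neighboring
#' lattice nodes, which would otherwise bias the kernel width.  The
#' `dq = 0` bin (where the phonon form diverges) anchors only the kernel
#' fit; residuals are reported over the `dq > 0` bins both forms share.
#' Fitted amplitudes scale linearly with the profile; `gamma` is
#' scale-invariant.
#'
#' @param profile a [deltaq_profile()] result
#' @param shell_index resolution shell to fit (1 = lowest resolution)
#' @param gamma_range search interval for the correlation length (A)
#' @return list with elements `phonon` (amplitude, residual) and `llm`
#'   (gamma, amplitude, residual)
#' @export
fit_falloff <- function(profile, shell_index = 1,
                        gamma_range = c(0.5, 1000)) {
  y_all <- profile$median_intensity[shell_index, ]
  x_all <- profile$dq_mean[shell_index, ]
  n_all <- profile$counts[shell_index, ]
  def <- is.finite(y_all) & is.finite(x_all) & n_all > 0
  pos <- def & x_all > 0
  if (sum(pos) < 4) stop("fewer than 4 defined dq bins in shell")
  xp <- x_all[pos]; yp <- y_all[pos]
  Xp <- cbind(1 / xp^2, 1)
  cfp <- qr.coef(qr(Xp), yp)
  phonon_res <- sum((yp - Xp %*% cfp)^2)
  x0 <- x_all[def]; y0 <- y_all[def]
  llm_fit <- function(gamma) {
    X <- cbind(llm_kernel(x0, gamma), 1)
    cf <- qr.coef(qr(X), y0)
    list(coef = cf, rss = sum((y0 - X %*% cf)^2))
  }
  opt <- optimize(function(lg) llm_fit(exp(lg))$rss, log(gamma_range))
  gamma <- exp(opt$minimum)
  cfl <- llm_fit(gamma)$coef
  llm_res <- sum((yp - (cfl[1] * llm_kernel(xp, gamma) + cfl[2]))^2)
  list(phonon = list(amplitude = cfp[1], offset = cfp[2],
                     residual = phonon_res),
       llm = list(gamma = gamma, amplitude = cfl[1], offset = cfl[2],
                  residual = llm_res),
       n_bins = sum(pos))
}

#' Real-space autocorrelation of a diffuse map
#'
#' Fourier transform of the intensity map with any recorded positivity
#' offset removed; undefined voxels are
#' zero-filled and the filled fraction reported.  The result is
#' origin-normalized to 1 and centrosymmetric, sampled on a real-space
#' grid spanning `oversampling` unit cells per axis.
#'
#' @param map a [diffuse_map()]
#' @return object of class `autocorr_map`: `values` (3D array with the
#'   origin at the center index), `spacing_frac` (grid step in fractional
#'   unit cells), `cell`, `oversampling`, `fill_fraction`
#' @export
autocorrelation <- function(map) {
  grid <- map$grid
  n <- grid$n_axis
  def <- defined_voxels(map)
  off <- attr(map, "offset") %||% 0   # undo positivity_offset, if applied
  v <- map$intensity - off
  v[!def] <- 0
  arr <- array(v, c(n, n, n))
  # move the h=0 node (center index, n odd) to position 1 for the DFT
  ctr0 <- (n + 1L) %/% 2L
  ord <- c(ctr0:n, seq_len(ctr0 - 1L))
  arr <- arr[ord, ord, ord]
  P <- Re(stats::fft(arr))
  # shift real-space origin back to the center index
  inv <- order(ord)
  P <- P[inv, inv, inv]
  ctr_val <- P[ctr0, ctr0, ctr0]
  # radial-average-subtracted maps can have a near-zero origin sum; fall
  # back to the maximum magnitude so normalization stays well defined
  if (abs(ctr_val) < 1e-8 * max(abs(P))) ctr_val <- max(abs(P))
  structure(list(values = P / ctr_val,
                 spacing_frac = grid$oversampling / n,
                 cell = grid$crystal$cell,
                 oversampling = grid$oversampling,
                 n_axis = n,
                 fill_fraction = mean(!def)),
            class = "autocorr_map")
}

# Trilinear interpolation of a 3D array at a (possibly fractional) index.
trilinear <- function(arr, pos) {
  d <- dim(arr)
  if (any(pos < 1) || any(pos > d)) return(NA_real_)
  lo <- pmin(floor(pos), d - 1); f <- pos - lo
  acc <- 0
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    w <- (if (i) f[1] else 1 - f[1]) * (if (j) f[2] else 1 - f[2]) *
      (if (k) f[3] else 1 - f[3])
    acc <- acc + w * arr[lo[1] + i, lo[2] + j, lo[3] + k]
  }
  acc
}

#' Autocorrelation peaks at unit-cell translations
#'
#' Evaluates the autocorrelation at the six +-primitive-cell translations
#' and compares each against the median of a surrounding shell of grid
#' points (fractional radius 0.15-0.35 of a cell); a peak is flagged when
#' it exceeds the background median by more than three raw median
#' absolute deviations.  Peaks at cell translations indicate correlations
#' crossing unit-cell boundaries.
#'
#' @param acorr an [autocorrelation()] result
#' @return data.frame with one row per translation: direction, value,
#'   background, mad, flagged, in_grid
#' @export
lattice_peak_report <- function(acorr) {
  n <- acorr$n_axis
  ctr <- (n + 1) / 2
  step <- acorr$spacing_frac
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  ax <- (seq_len(n) - ctr) * step
  out <- data.frame(direction = c("+a", "-a", "+b", "-b", "+c", "-c"),
                    value = NA_real_, background = NA_real_,
                    mad = NA_real_, flagged = FALSE, in_grid = FALSE)
  for (r in seq_len(nrow(dirs))) {
    p <- dirs[r, ]
    pos <- p / step + ctr
    if (any(pos < 1) || any(pos > n)) next
    out$in_grid[r] <- TRUE
    out$value[r] <- trilinear(acorr$values, pos)
    dist <- sqrt(outer(outer((ax - p[1])^2, (ax - p[2])^2, "+"),
                       (ax - p[3])^2, "+"))
    shell <- acorr$values[dist >= 0.15 & dist <= 0.35]
    bg <- median(shell)
    madv <- median(abs(shell - bg))
    out$background[r] <- bg
    out$mad[r] <- madv
    out$flagged[r] <- out$value[r] > bg + 3 * madv
  }
  out
}
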