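#' Synthetic crystals, disorder-ensemble oracles and rendered images
#'
#' Everything the pipeline consumes can be generated with known ground
#' truth: toy atomic models placed in one asymmetric unit, brute-force
#' sampled disorder ensembles whose structure-factor variance serves as an
#' independent oracle for the analytic predictions, and rotation-series
#' images carrying Bragg spots, diffuse signal from a known map, radial
#' backgrounds, a shifted reference-profile contaminant, per-frame scale
#' jitter and Poisson noise.  All generators are deterministic given their
#' seed.
#'
#' @name synthetic-data
NULL

#' Specification for a toy crystal
#'
#' @param n_atoms number of atoms in the asymmetric unit
#' @param cell unit cell (length 6)
#' @param spacegroup space-group label
#' @param elements element palette sampled uniformly ("X" for constant
#'   form factors)
#' @param b_range range of isotropic B factors (A^2)
#' @param box fractional-coordinate bounds (lo, hi) of the placement box,
#'   kept inside one asymmetric unit
#' @param min_dist minimum interatomic distance (Angstrom)
#' @param seed placement seed
#' @return list of class `toy_crystal_spec`
#' @export
toy_crystal_spec <- function(n_atoms = 8, cell = c(24, 26, 30, 90, 90, 90),
                             spacegroup = "P212121",
                             elements = c("C", "N", "O"),
                             b_range = c(10, 20), box = c(0.08, 0.38),
                             min_dist = 1.5, seed = 1) {
  structure(list(n_atoms = n_atoms, cell = cell, spacegroup = spacegroup,
                 elements = elements, b_range = b_range, box = box,
                 min_dist = min_dist, seed = seed),
            class = "toy_crystal_spec")
}

#' Generate a toy atomic model from a specification
#'
#' Atoms are placed uniformly in the fractional box with rejection
#' sampling to honor the minimum interatomic distance; deterministic
#' given the spec's seed.
#'
#' @param spec a [toy_crystal_spec()]
#' @return an [atomic_model()]
#' @export
make_toy_crystal <- function(spec) {
  A <- real_basis(spec$cell)
  local_seed(spec$seed, {
    frac <- matrix(NA_real_, spec$n_atoms, 3)
    xyz <- matrix(NA_real_, spec$n_atoms, 3)
    for (i in seq_len(spec$n_atoms)) {
      placed <- FALSE
      for (try in seq_len(1000)) {
        f <- runif(3, spec$box[1], spec$box[2])
        x <- as.vector(A %*% f)
        if (i == 1 || min(sqrt(rowSums(sweep(xyz[seq_len(i - 1), , drop = FALSE],
                                             2, x)^2))) >= spec$min_dist) {
          frac[i, ] <- f; xyz[i, ] <- x; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not satisfy min_dist after 1000 tries; shrink n_atoms ",
             "or enlarge the box")
    }
    atomic_model(element = sample(spec$elements, spec$n_atoms, replace = TRUE),
                 xyz = xyz,
                 occupancy = 1,
                 b = runif(spec$n_atoms, spec$b_range[1], spec$b_range[2]),
                 cell = spec$cell, spacegroup = spec$spacegroup)
  })
}

#' Explicit-ensemble oracle for diffuse scattering
#'
#' Realizes a disorder model by sampling explicit perturbed copies of the
#' structure and computing the variance of their structure factors,
#' `<|F_k|^2> - |<F_k>|^2`, orientation-symmetrized on the grid.  This is
#' the brute-force reference against which the analytic predictions are
#' validated.
#'
#' Supported disorder tags: `rbt` (sigma), `rbr` (sigma_rot), `llm`
#' (sigma, gamma; exponentially correlated Gaussian displacements,
#' optionally over a supercell of molecules), `ensemble` (states,
#' weights; `exhaustive = TRUE` enumerates states instead of sampling),
#' and `gaussian` (explicit per-axis covariance matrix `vmat`).
#'
#' @param model an [atomic_model()] (the asymmetric-unit / molecule model)
#' @param config list with `disorder` (tagged list as above), `n_samples`,
#'   `seed`, and optional `supercell = c(na, nb, nc)`
#' @param grid a [map_grid()]
#' @return a [diffuse_map()]
#' @export
oracle_diffuse_map <- function(model, config, grid) {
  dis <- config$disorder
  n <- config$n_samples %||% 20000
  if (n < 100) stop("n_samples must be >= 100")
  seed <- config$seed %||% 7
  type <- dis$type
  if (is.null(type)) stop("config$disorder$type missing")
  zero_amp <- switch(type,
    rbt = isTRUE(dis$sigma == 0), rbr = isTRUE(dis$sigma_rot == 0),
    llm = isTRUE(dis$sigma == 0), gaussian = all(dis$vmat == 0),
    FALSE)
  if (zero_amp) return(diffuse_map(grid, numeric(n_voxels(grid))))
  switch(type,
    rbt = {
      na <- nrow(model$xyz)
      coords <- local_seed(seed, {
        d <- matrix(rnorm(3 * n, 0, dis$sigma), n, 3)
        arr <- array(0, c(na, 3, n))
        for (s in seq_len(n))
          arr[, , s] <- sweep(model$xyz, 2, d[s, ], "+")
        arr
      })
      ensemble_variance_map(model, grid, coords)
    },
    rbr = predict_rigid_rotations(model, grid, dis$sigma_rot,
                                  n_samples = n, seed = seed),
    llm = {
      sc <- config$supercell %||% c(1, 1, 1)
      mdl <- replicate_supercell(model, sc)
      D <- as.matrix(stats::dist(mdl$xyz))
      C <- dis$sigma^2 * exp(-D / dis$gamma)
      out <- sample_gaussian_ensemble(mdl, grid, C, n, seed)
      out$intensity <- out$intensity / prod(sc)
      out
    },
    gaussian = sample_gaussian_ensemble(model, grid, as.matrix(dis$vmat),
                                        n, seed),
    ensemble = {
      states <- dis$states; w <- dis$weights
      if (isTRUE(dis$exhaustive)) {
        vals <- numeric(n_voxels(grid))
        for (R in orientation_ops(grid)) {
          Qr <- grid$Q %*% t(R)
          Fs <- lapply(states, sf_at, Q = Qr, qabs = grid$qabs)
          sumI <- Reduce(`+`, Map(function(F, wi) wi * Mod(F)^2, Fs, w))
          sumF <- Reduce(`+`, Map(function(F, wi) wi * F, Fs, w))
          vals <- vals + pmax(sumI - Mod(sumF)^2, 0)
        }
        diffuse_map(grid, vals)
      } else {
        pick <- local_seed(seed, sample.int(length(states), n, replace = TRUE,
                                            prob = w))
        na <- nrow(states[[1]]$xyz)
        arr <- array(0, c(na, 3, n))
        for (s in seq_len(n)) arr[, , s] <- states[[pick[s]]]$xyz
        ensemble_variance_map(states[[1]], grid, arr)
      }
    },
    stop("unsupported disorder tag '", type, "'"))
}

# Replicate a molecule over a supercell of unit-cell translations
# (correlations in the sampled ensemble then cross cell boundaries).
replicate_supercell <- function(model, sc) {
  if (all(sc == 1)) return(model)
  A <- real_basis(model$cell)
  shifts <- as.matrix(expand.grid(seq_len(sc[1]) - 1, seq_len(sc[2]) - 1,
                                  seq_len(sc[3]) - 1))
  xyz <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i)
    sweep(model$xyz, 2, as.vector(A %*% shifts[i, ]), "+")))
  atomic_model(element = rep(model$element, nrow(shifts)), xyz = xyz,
               occupancy = rep(model$occupancy, nrow(shifts)),
               b = rep(model$b, nrow(shifts)),
               cell = model$cell, spacegroup = "P1")
}

# Sample displacements u ~ N(0, C) independently per axis (per-axis
# covariance C, A^2) and return the ensemble-variance map.
sample_gaussian_ensemble <- function(model, grid, C, n, seed) {
  na <- nrow(model$xyz)
  stopifnot(nrow(C) == na)
  L <- t(chol(C + diag(1e-10, na)))
  coords <- local_seed(seed, {
    arr <- array(0, c(na, 3, n))
    for (s in seq_len(n)) {
      u <- L %*% matrix(rnorm(3 * na), na, 3)
      arr[, , s] <- model$xyz + u
    }
    arr
  })
  ensemble_variance_map(model, grid, coords)
}

#' Image-simulation configuration
#'
#' @param geometry a [detector_geometry()]
#' @param crystal a [crystal_frame()]
#' @param n_frames number of rotation frames
#' @param phi_start starting spindle angle (degrees)
#' @param phi_width oscillation per frame (degrees)
#' @param diffuse_scale multiplier applied to the input map's intensities
#' @param bragg_scale multiplier for Bragg-spot intensities (0 disables)
#' @param background optional function of |q| giving the isotropic
#'   background level per pixel; a two-argument function `f(q, frame)`
#'   gives frame-dependent backgrounds
#' @param contaminant optional list(ref = function, m = per-frame scales,
#'   q0 = per-frame shifts) adding `m * ref(|q| - q0)` per pixel
#' @param scale_jitter standard deviation of log-normal per-frame scale
#'   fluctuations (0 disables)
#' @param poisson apply Poisson counting noise
#' @param seed RNG seed
#' @param bragg_tol fractional-index radius within which a reflection
#'   contributes intensity to a pixel
#' @param bragg_sigma Gaussian footprint width in fractional-index units
#' @param spot_core_tol fractional-index radius defining "core" pixels
#'   recorded in the ground-truth sidecar
#' @param n_phi_samples spindle samples per frame (matches spot
#'   prediction)
#' @return list of class `image_sim_config`
#' @export
image_sim_config <- function(geometry, crystal, n_frames = 36,
                             phi_start = 0, phi_width = 5,
                             diffuse_scale = 1, bragg_scale = 0,
                             background = NULL, contaminant = NULL,
                             scale_jitter = 0, poisson = FALSE, seed = 1,
                             bragg_tol = 0.12, bragg_sigma = 0.05,
                             spot_core_tol = 0.08, n_phi_samples = 5) {
  stopifnot(diffuse_scale >= 0, bragg_scale >= 0, scale_jitter >= 0)
  structure(as.list(environment()), class = "image_sim_config")
}

#' Render rotation-series diffraction images from a known map
#'
#' Projects the grid intensities onto the pixels each frame observes
#' (nearest-voxel lookup at the mid-oscillation angle), adds
#' Debye-Waller-damped Bragg spots at predicted reflections with Gaussian
#' footprints, an isotropic background, a shifted reference-profile
#' contaminant, per-frame scale fluctuations, the polarization and
#' solid-angle attenuation that the reconstruction pipeline later
#' removes, and optional Poisson noise.
#'
#' @param map_diffuse a [diffuse_map()] providing the diffuse ground truth
#' @param model an [atomic_model()] for the Bragg structure factors
#' @param config an [image_sim_config()]
#' @return list with `frames` (list of [diffraction_frame()]s) and
#'   `truth` (ground-truth sidecar: the input map, per-frame scales,
#'   contaminant parameters, spot-core masks, config)
#' @export
render_images <- function(map_diffuse, model, config) {
  geom <- config$geometry
  crystal <- config$crystal
  grid <- map_diffuse$grid
  Oinv <- solve(crystal$orientation)
  px <- pixel_grid(geom)
  qabs_m <- pixel_qabs(geom)
  if (max(grid$qabs) < max(qabs_m) * 0.5)
    stop("map grid does not cover the detector's q range; enlarge grid_extent")
  P_om <- NULL
  # Bragg intensities at integral nodes, with per-atom B damping
  icell <- NULL
  if (config$bragg_scale > 0) {
    cellm <- if (model$spacegroup == "P1") model else expand_symmetry(model)
    E <- grid$grid_extent
    hs <- as.matrix(expand.grid(-E:E, -E:E, -E:E))
    Qh <- hs %*% t(crystal$orientation)
    qa <- sqrt(rowSums(Qh^2))
    fe <- felem_for(cellm$element, qa)
    # per-atom form factors with per-atom B damping on the amplitude
    fat <- fe$felem[, fe$idx + 1, drop = FALSE] *
      exp(-outer(qa^2, cellm$b) / (16 * pi^2))
    Fh <- cpp_sf_grid(Qh, cellm$xyz, fat,
                      seq_len(nrow(cellm$xyz)) - 1L, cellm$occupancy)
    icell <- array(Mod(Fh)^2, rep(2 * E + 1, 3))
  }
  scales <- local_seed(config$seed,
                       exp(rnorm(config$n_frames, 0, config$scale_jitter)))
  m_vec <- q0_vec <- rep(0, config$n_frames)
  if (!is.null(config$contaminant)) {
    m_vec <- rep_len(config$contaminant$m, config$n_frames)
    q0_vec <- rep_len(config$contaminant$q0 %||% 0, config$n_frames)
  }
  frames <- vector("list", config$n_frames)
  cores <- vector("list", config$n_frames)
  E <- grid$grid_extent
  for (fidx in seq_len(config$n_frames)) {
    phi0 <- config$phi_start + (fidx - 1) * config$phi_width
    phim <- phi0 + config$phi_width / 2
    qc <- pixel_to_q(px, geom, phi = phim)
    hkl <- qc %*% t(Oinv)
    vidx <- hkl_to_index(grid, hkl)
    dif <- rep(0, nrow(px))
    ok <- !is.na(vidx)
    mv <- map_diffuse$intensity[vidx[ok]]
    mv[!is.finite(mv)] <- 0
    dif[ok] <- config$diffuse_scale * mv
    sig <- dif
    core <- rep(FALSE, nrow(px))
    if (config$bragg_scale > 0) {
      # Bragg recorded at the mid-oscillation orientation only: the
      # Gaussian fall-off with the mid-slice fractional-index distance
      # emulates partiality, so symmetry-equivalent reflections recorded
      # at different spindle angles carry different partial intensities
      hr <- round(hkl)
      d2 <- rowSums((hkl - hr)^2)
      hit <- d2 < config$bragg_tol^2 & rowSums(abs(hr) <= E) == 3
      bragg <- rep(0, nrow(px))
      if (any(hit)) {
        ih <- hr[hit, , drop = FALSE] + E + 1
        iv <- icell[cbind(ih[, 1], ih[, 2], ih[, 3])]
        bragg[hit] <- config$bragg_scale * iv *
          exp(-d2[hit] / (2 * config$bragg_sigma^2))
      }
      sig <- sig + bragg
      # a core pixel is one whose planted Bragg intensity dominates the
      # local non-Bragg signal by >= 10x
      core <- d2 < config$spot_core_tol^2 & bragg >= 10 * pmax(dif, 1e-12)
    }
    qa <- as.vector(qabs_m)
    if (!is.null(config$background)) {
      # per-frame backgrounds (solvent/beam fluctuation) take (q, frame)
      sig <- sig + if (length(formals(config$background)) >= 2)
        config$background(qa, fidx) else config$background(qa)
    }
    if (m_vec[fidx] != 0 && !is.null(config$contaminant))
      sig <- sig + m_vec[fidx] * config$contaminant$ref(qa - q0_vec[fidx])
    if (is.null(P_om)) {
      Pc <- polarization_correction(qc, geom, phi = phim)
      Om <- solid_angle_correction(px, geom)
      P_om <- Pc * Om  # phi-independent up to spindle symmetry; recompute is cheap
    }
    sig <- sig * P_om * scales[fidx]
    if (config$poisson)
      sig <- local_seed(config$seed + 1000 + fidx,
                        rpois(length(sig), pmax(sig, 0)))
    frames[[fidx]] <- diffraction_frame(matrix(sig, geom$n_fast, geom$n_slow),
                                        phi_start = phi0,
                                        phi_width = config$phi_width,
                                        scale_factor = scales[fidx])
    cores[[fidx]] <- matrix(core, geom$n_fast, geom$n_slow)
  }
  list(frames = frames,
       truth = list(map = map_diffuse, scales = scales, m = m_vec,
                    q0 = q0_vec, spot_cores = cores, config = config))
}
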