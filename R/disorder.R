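#' Disorder models for diffuse scattering prediction
#'
#' All predictions share two ingredients: the molecular transform
#' `F(q) = sum_i occ_i f_i(|q|) exp(i q . r_i)` of the asymmetric-unit
#' model (no B-factor damping; each disorder model applies its own
#' displacement statistics), and the incoherent orientation sum over the
#' crystallographic rotations of the unit cell.  Predicted maps are
#' consequently invariant under the Laue group and Friedel inversion, and
#' non-negative before radial-average subtraction.
#'
#' @name disorder-models
NULL

# Orientation (proper rotation) operators of a grid's crystal, as
# Cartesian matrices acting on q.
orientation_ops <- function(grid) {
  lapply(grid$crystal$ops$recip, function(M) op_cartesian(grid$crystal, M))
}

sf_at <- function(model, Q, qabs) {
  fe <- felem_for(model$element, qabs)
  cpp_sf_grid(Q, model$xyz, fe$felem, fe$idx, model$occupancy)
}

#' Molecular transform of an atomic model on a map grid
#'
#' @param model an [atomic_model()]
#' @param grid a [map_grid()]
#' @return object of class `complex_transform`: the grid plus the complex
#'   amplitude F(q) at every node
#' @export
molecular_transform <- function(model, grid) {
  F <- sf_at(model, grid$Q, grid$qabs)
  structure(list(grid = grid, F = F), class = "complex_transform")
}

#' Orientation-symmetrized squared molecular transform
#'
#' `sum_ops |F(R_op q)|^2`: the incoherent sum of the single-molecule
#' transform over its crystallographic orientations, which is the basis of
#' every asymmetric-unit-confined disorder model.
#'
#' @inheritParams molecular_transform
#' @return a [diffuse_map()]
#' @export
symmetrized_molecular_transform <- function(model, grid) {
  vals <- numeric(n_voxels(grid))
  for (R in orientation_ops(grid)) {
    F <- sf_at(model, grid$Q %*% t(R), grid$qabs)
    vals <- vals + Mod(F)^2
  }
  diffuse_map(grid, vals)
}

#' Rigid-body translational disorder
#'
#' The whole asymmetric unit translates with an isotropic Gaussian of
#' standard deviation `sigma` per axis.  The diffuse intensity is the
#' symmetrized molecular transform scaled by the complement of the
#' Debye-Waller factor:
#' `I_D(q) = T_sym(q) * (1 - exp(-sigma^2 |q|^2))` with `B = 8 pi^2 sigma^2`.
#'
#' @inheritParams molecular_transform
#' @param sigma isotropic displacement (Angstrom), non-negative
#' @return a [diffuse_map()]
#' @export
predict_rigid_translations <- function(model, grid, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  tsym <- symmetrized_molecular_transform(model, grid)
  tsym$intensity <- tsym$intensity * (1 - exp(-sigma^2 * grid$qabs^2))
  tsym
}

#' Rigid-body rotational disorder (Monte Carlo)
#'
#' The asymmetric unit rotates as a unit about its centroid around a
#' random, isotropically oriented axis with a normally distributed angle
#' (standard deviation `sigma_rot` degrees).  The diffuse intensity is the
#' ensemble variance of the rotated structure factors,
#' `<|F_k|^2> - |<F_k>|^2`, orientation-symmetrized.
#'
#' @inheritParams molecular_transform
#' @param sigma_rot rotation-angle standard deviation (degrees)
#' @param n_samples Monte Carlo sample count (>= 100)
#' @param seed RNG seed for the rotation ensemble
#' @return a [diffuse_map()]
#' @export
predict_rigid_rotations <- function(model, grid, sigma_rot, n_samples = 2000,
                                    seed = 1) {
  if (sigma_rot < 0) stop("sigma_rot must be non-negative")
  if (sigma_rot == 0) return(diffuse_map(grid, numeric(n_voxels(grid))))
  if (n_samples < 100) stop("n_samples must be >= 100")
  na <- nrow(model$xyz)
  ctr <- colMeans(model$xyz)
  centered <- sweep(model$xyz, 2, ctr)
  coords <- local_seed(seed, {
    arr <- array(0, c(na, 3, n_samples))
    for (s in seq_len(n_samples)) {
      ax <- rnorm(3)
      ang <- rnorm(1, 0, sigma_rot * pi / 180)
      R <- rotation_about_axis(ax, ang)
      arr[, , s] <- sweep(centered %*% t(R), 2, ctr, "+")
    }
    arr
  })
  ensemble_variance_map(model, grid, coords)
}

# Variance of structure factors over an explicit coordinate ensemble,
# summed over the crystal's orientation operators.  Uses the lattice
# factorization of the grid (per-axis complex exponentials) for speed.
ensemble_variance_map <- function(model, grid, coords) {
  fe <- felem_for(model$element, grid$qabs)
  vals <- numeric(n_voxels(grid))
  m <- grid$grid_extent * grid$oversampling
  for (R in orientation_ops(grid)) {
    M <- R %*% grid$crystal$orientation / grid$oversampling
    acc <- cpp_sf_ensemble_lattice(m, M, coords, fe$felem, fe$idx,
                                   model$occupancy)
    mI <- acc$sum_I / acc$n
    mF2 <- (acc$sum_re / acc$n)^2 + (acc$sum_im / acc$n)^2
    vals <- vals + pmax(mI - mF2, 0)
  }
  diffuse_map(grid, vals)
}

#' Liquid-like motions reciprocal-space kernel
#'
#' `Gamma_gamma(dq) = 8 pi gamma^3 / (1 + gamma^2 dq^2)^2`, the
#' three-dimensional Fourier transform of the exponential correlation
#' decay `exp(-r/gamma)`; normalized so `(2 pi)^-3 integral Gamma d^3q = 1`.
#'
#' @param dq distance(s) in reciprocal space (A^-1)
#' @param gamma correlation length (Angstrom), positive
#' @return kernel density values
#' @export
llm_kernel <- function(dq, gamma) {
  if (gamma <= 0) stop("gamma must be positive")
  8 * pi * gamma^3 / (1 + gamma^2 * dq^2)^2
}

# Discrete LLM kernel on the grid's node lattice, truncated where it falls
# below `rel_tol` of its peak and normalized to unit sum so that the
# delta-kernel (large gamma) limit reproduces the unconvolved basis.
llm_kernel_array <- function(grid, gamma, rel_tol = 1e-4) {
  O <- grid$crystal$orientation
  step <- sqrt(colSums(O^2)) / grid$oversampling   # q step per axis index
  dq_max <- sqrt(1 / sqrt(rel_tol) - 1) / gamma
  half_max <- sqrt(sqrt(2) - 1) / gamma
  if (any(ceiling(half_max / step) > grid$n_axis - 1))
    stop("LLM kernel support exceeds the grid; enlarge grid_extent ",
         "or increase gamma")
  # broad tails are truncated at the grid span (the unit-sum
  # normalization keeps the truncated kernel a proper smoothing kernel)
  r <- pmin(pmax(ceiling(dq_max / step), 1L), grid$n_axis - 1L)
  ax <- lapply(r, function(k) seq.int(-k, k))
  offs <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  qoff <- (offs / grid$oversampling) %*% t(O)
  vals <- llm_kernel(sqrt(rowSums(qoff^2)), gamma)
  vals[vals < rel_tol * llm_kernel(0, gamma)] <- 0
  ker <- array(vals / sum(vals), dim = 2 * r + 1)
  ker
}

# Zero-padded FFT convolution of a 3D array with a centered kernel.
convolve3 <- function(x, ker) {
  dx <- dim(x); dk <- dim(ker); r <- (dk - 1) %/% 2
  dp <- dx + dk - 1L
  X <- array(0, dp); X[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  K <- array(0, dp); K[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- ker
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / prod(dp)
  full[r[1] + seq_len(dx[1]), r[2] + seq_len(dx[2]), r[3] + seq_len(dx[3])]
}

# Unit-cell (crystal) transform intensity concentrated at integral Miller
# indices: |F_cell|^2 at nodes where all three indices are integral, zero
# elsewhere on the oversampled grid.
crystal_transform_nodes <- function(model, grid) {
  cellm <- if (model$spacegroup == "P1") model else expand_symmetry(model)
  at_node <- rowSums(grid$trips %% grid$oversampling == 0) == 3
  vals <- numeric(n_voxels(grid))
  Q <- grid$Q[at_node, , drop = FALSE]
  F <- sf_at(cellm, Q, sqrt(rowSums(Q^2)))
  vals[at_node] <- Mod(F)^2
  vals
}

#' Liquid-like motions diffuse scattering
#'
#' Displacement correlations decay exponentially with interatomic distance
#' (`exp(-r/gamma)`, isotropic amplitude `sigma`).  In the one-phonon
#' approximation the diffuse intensity is
#' `I_D(q) = sigma^2 |q|^2 exp(-sigma^2 |q|^2) * [I_basis (x) Gamma_gamma](q)`,
#' a grid convolution of the basis intensity with the reciprocal kernel.
#' The confined variant uses the symmetrized molecular transform as basis
#' (correlations limited to the asymmetric unit); the extended
#' (conventional) variant uses the crystal transform, nonzero only at
#' integral Miller indices, so correlations cross unit-cell boundaries and
#' produce speckles centered on reciprocal-lattice nodes.
#'
#' @inheritParams molecular_transform
#' @param sigma displacement amplitude (Angstrom), positive
#' @param gamma correlation length (Angstrom), positive
#' @param extended FALSE for the asymmetric-unit-confined variant, TRUE
#'   for the intermolecular (crystal-transform) variant
#' @return a [diffuse_map()]
#' @export
predict_llm <- function(model, grid, sigma, gamma, extended = FALSE) {
  if (sigma <= 0 || gamma <= 0) stop("sigma and gamma must be positive")
  basis_fun <- if (extended) {
    function(g) crystal_transform_nodes(model, g)
  } else {
    function(g) symmetrized_molecular_transform(model, g)$intensity
  }
  conv <- llm_convolve(basis_fun, grid, gamma)
  x <- sigma^2 * grid$qabs^2
  diffuse_map(grid, x * exp(-x) * conv)
}

# Convolve a basis intensity with the LLM kernel.  The basis is evaluated
# on a grid enlarged by the kernel radius so that voxels near the edge of
# the target grid see true (not zero-padded) basis values; the result is
# cropped back.  `basis_fun(grid2)` must return intensities on any grid
# sharing the crystal and oversampling.
llm_convolve <- function(basis_fun, grid, gamma) {
  ker <- llm_kernel_array(grid, gamma)
  r <- (dim(ker) - 1L) %/% 2L
  extra <- ceiling(max(r) / grid$oversampling)
  grid2 <- if (extra > 0)
    map_grid(grid$crystal, grid$grid_extent + extra, grid$oversampling)
  else grid
  n2 <- grid2$n_axis
  basis <- basis_fun(grid2)
  conv2 <- convolve3(array(basis, c(n2, n2, n2)), ker)
  off <- extra * grid$oversampling
  sel <- off + seq_len(grid$n_axis)
  as.vector(conv2[sel, sel, sel])
}

#' Discrete conformational-ensemble diffuse scattering
#'
#' For probability-weighted states with structure factors `F_s`, the
#' diffuse intensity is the weighted variance
#' `I_D(q) = sum_s w_s |F_s|^2 - |sum_s w_s F_s|^2`,
#' orientation-symmetrized.  Two-state models reduce to
#' `w1 w2 |F_1 - F_2|^2`.
#'
#' @param states list of [atomic_model()]s on a common cell
#' @param weights state probabilities, non-negative, summing to 1
#' @param grid a [map_grid()]
#' @return a [diffuse_map()]
#' @export
predict_ensemble <- function(states, weights, grid) {
  if (length(states) != length(weights) || length(states) < 2)
    stop("need >= 2 states with matching weights")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  vals <- numeric(n_voxels(grid))
  for (R in orientation_ops(grid)) {
    Qr <- grid$Q %*% t(R)
    sumI <- numeric(n_voxels(grid))
    sumF <- complex(real = numeric(n_voxels(grid)))
    for (s in seq_along(states)) {
      F <- sf_at(states[[s]], Qr, grid$qabs)
      sumI <- sumI + weights[s] * Mod(F)^2
      sumF <- sumF + weights[s] * F
    }
    vals <- vals + pmax(sumI - Mod(sumF)^2, 0)
  }
  diffuse_map(grid, vals)
}

#' Elastic-network displacement covariances
#'
#' Builds a Gaussian network on all atoms with a uniform spring constant
#' for pairs within `cutoff`, takes the pseudo-inverse of the network
#' Laplacian as the raw (isotropic, per-axis) covariance, and rescales per
#' atom so the implied B factors reproduce `b_targets`:
#' `V_ij <- s_i s_j V_ij` with `s_i = sqrt(B_i / (8 pi^2 V_ii_raw))`.
#'
#' @param model an [atomic_model()]
#' @param cutoff interaction distance (Angstrom)
#' @param b_targets per-atom B factors to renormalize against (defaults to
#'   the model's B column)
#' @return object of class `covariance_model` with the per-axis covariance
#'   matrix `vmat` (A^2); blocks are `v_ij * I3`
#' @export
build_enm_covariance <- function(model, cutoff = 10.5, b_targets = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  b_targets <- b_targets %||% model$b
  n <- nrow(model$xyz)
  D <- as.matrix(stats::dist(model$xyz))
  A <- (D <= cutoff) & (D > 0)
  comp <- connected_components(A)
  if (max(comp) > 1)
    stop("elastic network is disconnected at cutoff ", cutoff, ": ",
         max(comp), " components of sizes ",
         paste(tabulate(comp), collapse = ", "))
  L <- -1 * A
  diag(L) <- rowSums(A)
  eg <- eigen(L, symmetric = TRUE)
  keep <- eg$values > 1e-9 * max(eg$values)
  Linv <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
  s <- sqrt(b_targets / (8 * pi^2 * diag(Linv)))
  vmat <- Linv * outer(s, s)
  structure(list(vmat = vmat, cutoff = cutoff, b = b_targets),
            class = "covariance_model")
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diffuse scattering from a general Gaussian covariance model
#'
#' For small Gaussian displacements with per-pair covariances
#' `V_ij = v_ij I3`, the diffuse intensity is
#' `I_D(q) = sum_ij f_i f_j exp(-q^2(v_ii + v_jj)/2) (exp(q^2 v_ij) - 1)
#' cos(q . r_ij)`, orientation-symmetrized.  With `linear = TRUE` the
#' `exp(x) - 1` factor is replaced by `x` (one-phonon linearization).
#'
#' @inheritParams molecular_transform
#' @param covariance a [build_enm_covariance()] result, or any
#'   `covariance_model`-like list with an n x n `vmat`
#' @param linear use the linearized correlation factor
#' @return a [diffuse_map()]
#' @export
predict_gaussian_disorder <- function(model, grid, covariance,
                                      linear = FALSE) {
  vmat <- as.matrix(covariance$vmat %||% covariance)
  stopifnot(nrow(vmat) == nrow(model$xyz))
  fe <- felem_for(model$element, grid$qabs)
  vals <- numeric(n_voxels(grid))
  for (R in orientation_ops(grid)) {
    Qr <- grid$Q %*% t(R)
    vals <- vals + cpp_gaussian_diffuse(Qr, grid$qabs^2, model$xyz,
                                        fe$felem, fe$idx, model$occupancy,
                                        vmat, linear)
  }
  vals[vals < 0 & vals > -1e-9 * max(abs(vals))] <- 0
  diffuse_map(grid, vals)
}
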