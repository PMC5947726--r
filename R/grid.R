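#' Oversampled reciprocal-space grid
#'
#' Nodes sit at fractional Miller indices i/os for integer i in
#' `[-grid_extent*os, grid_extent*os]` along each axis, so that with odd
#' oversampling every integral Miller index coincides with a node.  The
#' grid carries the Cartesian q vector and |q| of every node, the crystal
#' it belongs to, and the Laue group used for symmetrization.
#'
#' @param crystal a [crystal_frame()]
#' @param grid_extent maximum |h|, |k|, |l| covered (integer)
#' @param oversampling odd integer number of nodes per Miller index step
#' @return object of class `map_grid`
#' @export
map_grid <- function(crystal, grid_extent = 8, oversampling = 3) {
  if (oversampling %% 2 != 1 || oversampling < 1)
    stop("oversampling must be an odd positive integer")
  os <- as.integer(oversampling)
  E <- as.integer(grid_extent)
  m <- E * os
  ax <- seq.int(-m, m)
  n <- length(ax)
  trips <- cbind(rep(ax, times = n * n),
                 rep(rep(ax, each = n), times = n),
                 rep(ax, each = n * n))
  hkl <- trips / os
  Q <- hkl %*% t(crystal$orientation)
  structure(list(crystal = crystal, oversampling = os, grid_extent = E,
                 n_axis = n, trips = trips, hkl = hkl, Q = Q,
                 qabs = sqrt(rowSums(Q^2)),
                 laue = laue_group(crystal$ops$recip)),
            class = "map_grid")
}

n_voxels <- function(grid) nrow(grid$hkl)

# Nearest-node linear indices for fractional Miller indices (n x 3).
# Assignment is floor(x + 0.5) with exact half-distance ties resolved to
# the lexicographically smaller node; rows outside the grid give NA.
hkl_to_index <- function(grid, hkl) {
  m <- grid$grid_extent * grid$oversampling
  x <- hkl * grid$oversampling
  nidx <- floor(x + 0.5)
  tie <- (x + 0.5) == nidx
  nidx[tie] <- nidx[tie] - 1
  out <- rep(NA_integer_, nrow(hkl))
  ok <- rowSums(abs(nidx) <= m) == 3
  n <- grid$n_axis
  out[ok] <- 1L + (nidx[ok, 1] + m) + n * ((nidx[ok, 2] + m) +
                                             n * (nidx[ok, 3] + m))
  out
}

# Linear indices for integer node triples (kernel units, n x 3); NA when
# outside the grid.
trip_to_index <- function(grid, trips) {
  m <- grid$grid_extent * grid$oversampling
  n <- grid$n_axis
  ok <- rowSums(abs(trips) <= m) == 3
  out <- rep(NA_integer_, nrow(trips))
  out[ok] <- 1L + (trips[ok, 1] + m) + n * ((trips[ok, 2] + m) +
                                              n * (trips[ok, 3] + m))
  out
}

# Encode transformed integer triples as scalar keys for orbit bookkeeping.
# The key space covers indices beyond the grid so hexagonal operators that
# map nodes outside the cube still receive consistent keys.
trip_key <- function(trips, m) {
  K <- 4 * m + 3
  off <- 2 * m + 1
  (as.numeric(trips[, 1]) + off) * K * K +
    (as.numeric(trips[, 2]) + off) * K +
    (as.numeric(trips[, 3]) + off)
}

# Cartesian rotation matrix realizing a reciprocal-space integer operator
# on q vectors: q' = R q corresponds to h' = M h.
op_cartesian <- function(crystal, M) {
  O <- crystal$orientation
  O %*% M %*% solve(O)
}
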