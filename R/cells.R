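#' Unit-cell algebra and space-group operator tables
#'
#' The package supports the point groups needed for the crystal systems it
#' targets: triclinic P1, orthorhombic P212121 (Laue class mmm), tetragonal
#' P4222 (4/mmm) and hexagonal P6322 (6/mmm).  Operators are stored as
#' real-space rotation parts `W` with translation parts `w` (fractional),
#' plus the corresponding reciprocal-space integer rotations acting on
#' (h,k,l) column vectors.
#'
#' @name cell-algebra
NULL

#' Real-space basis matrix of a unit cell
#'
#' Columns are the Cartesian cell vectors a, b, c (standard PDB
#' orthogonalization: a along x, b in the xy plane).
#'
#' @param cell numeric length-6: a, b, c (Angstrom), alpha, beta, gamma
#'   (degrees)
#' @return 3x3 matrix with cell vectors as columns
#' @export
real_basis <- function(cell) {
  check_cell(cell)
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  av <- c(a, 0, 0)
  bv <- c(b * cos(ga), b * sin(ga), 0)
  cx <- c * cos(be)
  cy <- c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(c^2 - cx^2 - cy^2, 0))
  cbind(av, bv, c(cx, cy, cz), deparse.level = 0)
}

#' Reciprocal-space basis (no 2*pi factor)
#'
#' Columns are a*, b*, c* in inverse Angstrom such that
#' `t(reciprocal_basis(cell)) %*% real_basis(cell)` is the identity.
#'
#' @inheritParams real_basis
#' @export
reciprocal_basis <- function(cell) {
  t(solve(real_basis(cell)))
}

#' Default orientation matrix for a crystal at spindle angle zero
#'
#' Maps a Miller-index column (h,k,l) to the Cartesian scattering vector q
#' in inverse Angstrom, using the q = 2*pi*s convention (|q| = 2*pi/d).
#' Columns are the reciprocal-cell vectors scaled by 2*pi.
#'
#' @inheritParams real_basis
#' @export
default_orientation <- function(cell) {
  2 * pi * reciprocal_basis(cell)
}

check_cell <- function(cell) {
  if (length(cell) != 6 || any(!is.finite(cell)))
    stop("cell must be numeric length 6: a, b, c, alpha, beta, gamma")
  if (any(cell[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  invisible(cell)
}

# Parse "x+1/2,-y,z" style triplets into (W, w).
parse_symop <- function(s) {
  parts <- strsplit(gsub(" ", "", s), ",")[[1]]
  stopifnot(length(parts) == 3L)
  W <- matrix(0, 3, 3)
  w <- numeric(3)
  for (i in 1:3) {
    p <- parts[i]
    for (j in 1:3) {
      v <- c("x", "y", "z")[j]
      if (grepl(paste0("-", v), p, fixed = TRUE)) W[i, j] <- -1
      else if (grepl(v, p, fixed = TRUE)) W[i, j] <- 1
    }
    frac <- regmatches(p, regexpr("[-+]?[0-9]+/[0-9]+", p))
    if (length(frac) == 1L) {
      nm <- as.numeric(strsplit(gsub("\\+", "", frac), "/")[[1]])
      w[i] <- nm[1] / nm[2]
    }
  }
  list(W = W, w = w %% 1)
}

symop_tables <- list(
  P1 = c("x,y,z"),
  P212121 = c("x,y,z",
              "-x+1/2,-y,z+1/2",
              "-x,y+1/2,-z+1/2",
              "x+1/2,-y+1/2,-z"),
  P4222 = c("x,y,z", "-x,-y,z",
            "-y,x,z+1/2", "y,-x,z+1/2",
            "-x,y,-z", "x,-y,-z",
            "y,x,-z+1/2", "-y,-x,-z+1/2"),
  P6322 = c("x,y,z", "-y,x-y,z", "-x+y,-x,z",
            "-x,-y,z+1/2", "y,-x+y,z+1/2", "x-y,x,z+1/2",
            "y,x,-z", "x-y,-y,-z", "-x,-x+y,-z",
            "-y,-x,-z+1/2", "-x+y,y,-z+1/2", "x,x-y,-z+1/2")
)

#' Space-group operators for the supported groups
#'
#' @param label one of "P1", "P212121", "P4222", "P6322"
#' @return list with `label`, `W` (list of real-space rotation parts),
#'   `w` (translations, fractional), and `recip` (list of integer matrices
#'   acting on Miller-index columns)
#' @export
spacegroup_ops <- function(label) {
  label <- gsub("[ ()_]", "", label)
  if (!label %in% names(symop_tables))
    stop("unsupported space group '", label, "'; supported: ",
         paste(names(symop_tables), collapse = ", "))
  ops <- lapply(symop_tables[[label]], parse_symop)
  W <- lapply(ops, `[[`, "W")
  w <- lapply(ops, `[[`, "w")
  # Reciprocal-space action on column (h,k,l): h' = t(solve(W)) h gives the
  # operator under which |F| is invariant; entries are integers.
  recip <- lapply(W, function(m) round(t(solve(m))))
  stopifnot(ops_closed(recip))
  list(label = label, W = W, w = w, recip = recip)
}

op_key <- function(m) paste(as.integer(round(m)), collapse = ",")

# Verify a set of integer matrices is closed under composition.
ops_closed <- function(mats) {
  keys <- vapply(mats, op_key, "")
  for (a in mats) for (b in mats)
    if (!op_key(a %*% b) %in% keys) return(FALSE)
  TRUE
}

#' Laue group (rotations plus Friedel inversion) from rotation parts
#'
#' Closes the supplied reciprocal-space rotations under composition with
#' the inversion -I, yielding the point group of diffraction intensities.
#'
#' @param recip list of integer 3x3 matrices acting on (h,k,l)
#' @return list of integer matrices forming the Laue group
#' @export
laue_group <- function(recip) {
  mats <- c(recip, lapply(recip, function(m) -m))
  keys <- vapply(mats, op_key, "")
  mats <- mats[!duplicated(keys)]
  # close under composition (the seeds are groups, one pass suffices; loop
  # defensively anyway)
  repeat {
    keys <- vapply(mats, op_key, "")
    extra <- list()
    for (a in mats) for (b in mats) {
      p <- a %*% b
      k <- op_key(p)
      if (!k %in% keys && !k %in% names(extra)) extra[[k]] <- p
    }
    if (length(extra) == 0L) break
    mats <- c(mats, unname(extra))
  }
  mats
}
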