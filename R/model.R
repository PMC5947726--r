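#' Atomic coordinate model
#'
#' A minimal container for an asymmetric-unit model: atoms with element,
#' Cartesian coordinates, occupancy and isotropic B factor, in a unit cell
#' with space-group symmetry.  Disorder predictions apply their own
#' displacement statistics, so the stored B factors enter only where a
#' model explicitly renormalizes against them (elastic network) or damps
#' Bragg intensities (image rendering).
#'
#' @param element character vector of element symbols ("X" for constant
#'   form factor 1)
#' @param xyz n x 3 Cartesian coordinates (Angstrom)
#' @param occupancy occupancies in `[0, 1]` (recycled)
#' @param b isotropic B factors in A^2 (recycled)
#' @param cell unit cell, numeric length 6
#' @param spacegroup space-group label (see [spacegroup_ops()])
#' @return object of class `atomic_model`
#' @export
atomic_model <- function(element, xyz, occupancy = 1, b = 10,
                         cell, spacegroup = "P1") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (ncol(xyz) != 3 || any(!is.finite(xyz)))
    stop("xyz must be a finite n x 3 matrix")
  occupancy <- rep_len(occupancy, n)
  b <- rep_len(b, n)
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancies must lie in [0, 1]")
  if (any(b < 0)) stop("B factors must be non-negative")
  check_cell(cell)
  ops <- spacegroup_ops(spacegroup)
  structure(list(element = as.character(element), xyz = xyz,
                 occupancy = occupancy, b = b, cell = as.numeric(cell),
                 spacegroup = ops$label, ops = ops),
            class = "atomic_model")
}

#' Expand an asymmetric unit to the full unit cell
#'
#' Applies every space-group operator (rotation plus translation, in
#' fractional coordinates) to the model's atoms and returns a new P1
#' model containing all symmetry copies.
#'
#' @param model an [atomic_model()]
#' @return `atomic_model` in P1 holding all unit-cell atoms
#' @export
expand_symmetry <- function(model) {
  A <- real_basis(model$cell)
  frac <- t(solve(A) %*% t(model$xyz))
  ops <- model$ops
  pieces <- lapply(seq_along(ops$W), function(i) {
    fr <- t(ops$W[[i]] %*% t(frac)) +
      matrix(ops$w[[i]], nrow(frac), 3, byrow = TRUE)
    t(A %*% t(fr))
  })
  atomic_model(element = rep(model$element, length(ops$W)),
               xyz = do.call(rbind, pieces),
               occupancy = rep(model$occupancy, length(ops$W)),
               b = rep(model$b, length(ops$W)),
               cell = model$cell, spacegroup = "P1")
}

#' Read a PDB-format coordinate file
#'
#' Parses ATOM/HETATM records (element from columns 77-78, falling back to
#' the atom name), CRYST1 for the unit cell and space group.  Occupancy and
#' B-factor columns are honored.
#'
#' @param path path to a PDB file
#' @param spacegroup optional override of the CRYST1 space-group label
#' @return an [atomic_model()]
#' @export
read_pdb <- function(path, spacegroup = NULL) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0) stop("no CRYST1 record in ", path)
  cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                       substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                       substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  sg <- spacegroup %||% gsub(" ", "", substr(cr[1], 56, 66))
  at <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  if (length(at) == 0) stop("no atom records in ", path)
  num <- function(a, b) as.numeric(substr(at, a, b))
  elem <- trimws(substr(at, 77, 78))
  fallback <- trimws(substr(at, 13, 14))
  elem[elem == ""] <- substr(fallback[elem == ""], 1, 1)
  atomic_model(element = elem,
               xyz = cbind(num(31, 38), num(39, 46), num(47, 54)),
               occupancy = num(55, 60), b = num(61, 66),
               cell = cell, spacegroup = sg)
}

#' Write a minimal PDB file for an atomic model
#'
#' @param model an [atomic_model()]
#' @param path output path
#' @export
write_pdb <- function(model, path) {
  cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                model$cell[1], model$cell[2], model$cell[3],
                model$cell[4], model$cell[5], model$cell[6],
                model$spacegroup)
  n <- nrow(model$xyz)
  at <- sprintf(
    "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), substr(model$element, 1, 2), seq_len(n),
    model$xyz[, 1], model$xyz[, 2], model$xyz[, 3],
    model$occupancy, model$b, model$element)
  writeLines(c(cr, at, "END"), path)
  invisible(path)
}

#' Convert a Wilson B factor to an isotropic displacement
#'
#' `sigma = sqrt(B / (8 * pi^2))`, the standard deviation per axis of the
#' Gaussian positional spread implied by an isotropic B factor.
#'
#' @param B isotropic B factor(s) in A^2, non-negative
#' @return displacement sigma in Angstrom
#' @export
wilson_b_to_sigma <- function(B) {
  if (any(B < 0)) stop("B must be non-negative")
  sqrt(B / (8 * pi^2))
}
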