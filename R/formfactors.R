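#' Atomic X-ray form factors
#'
#' Four-Gaussian (Cromer-Mann-type) parameterizations for the elements
#' common in protein models, evaluated as a function of
#' `s = sin(theta)/lambda = |q|/(4*pi)`:
#' `f(s) = sum_i a_i exp(-b_i s^2) + c`.
#' The pseudo-element `"X"` has a constant form factor of 1 and is used by
#' toy models where a flat scatterer keeps closed-form oracles simple.
#'
#' @name form-factors
NULL

cromer_mann <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

#' Evaluate the form factor of an element
#'
#' @param element element symbol ("H", "C", "N", "O", "P", "S") or "X" for
#'   a constant factor of 1
#' @param qabs scattering-vector magnitudes |q| in A^-1 (q = 2*pi*s)
#' @return numeric vector of form-factor values (electrons)
#' @export
form_factor <- function(element, qabs) {
  if (element == "X") return(rep(1, length(qabs)))
  cf <- cromer_mann[[element]]
  if (is.null(cf)) stop("unknown element '", element, "'")
  s2 <- (qabs / (4 * pi))^2
  out <- rep(cf$c, length(qabs))
  for (i in 1:4) out <- out + cf$a[i] * exp(-cf$b[i] * s2)
  out
}

# n_vox x n_elem matrix of form factors for the distinct elements of a
# model evaluated on a grid's |q|, plus the 0-based column index per atom.
felem_for <- function(elements, qabs) {
  uel <- unique(elements)
  fm <- vapply(uel, function(e) form_factor(e, qabs), numeric(length(qabs)))
  fm <- matrix(fm, nrow = length(qabs), dimnames = NULL)
  list(felem = fm, idx = match(elements, uel) - 1L)
}
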