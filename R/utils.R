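#' @useDynLib diffusemap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median mad rnorm rpois runif sd prcomp optimize setNames
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("zero vector cannot be normalized")
  x / n
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula for a right-handed rotation by `angle` (radians)
#' about the unit vector `axis`.
#'
#' @param axis unit 3-vector
#' @param angle rotation angle in radians
#' @return 3x3 rotation matrix
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Golden-section minimization on an interval
#'
#' Minimizes a univariate function; returns the minimizer, the minimum and
#' the trace of best-so-far objective values (non-increasing by
#' construction), which downstream code uses to assert that the shift
#' search never worsens the residual.
#'
#' @keywords internal
golden_section <- function(f, lower, upper, tol = 1e-6, max_iter = 200) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  trace <- min(f1, f2)
  it <- 0L
  while (abs(b - a) > tol && it < max_iter) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
    trace <- c(trace, min(tail(trace, 1L), f1, f2))
    it <- it + 1L
  }
  x <- if (f1 < f2) c1 else c2
  list(minimum = x, objective = min(f1, f2), trace = trace)
}

# Linear interpolation with end clamping; x must be sorted increasing.
interp_clamped <- function(x, y, xout) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least two defined points to interpolate")
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# Evaluate an expression with a temporary RNG seed, restoring any
# pre-existing RNG state afterwards so generators are bit-reproducible
# without clobbering the caller's stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Robust per-group mean via rowsum on a numeric vector.
group_means <- function(values, group, n_groups) {
  sums <- rowsum(values, group)
  cnts <- rowsum(rep(1, length(values)), group)
  idx <- as.integer(rownames(sums))
  out <- rep(NA_real_, n_groups)
  out[idx] <- sums / cnts
  out
}
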