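#' Compare predicted and experimental maps; optimize disorder parameters
#'
#' Agreement between maps is scored by the Pearson correlation over
#' co-defined voxels, with each voxel downweighted by its symmetry
#' multiplicity (weight `1/m`; `1/sqrt(m)` available).  Best-fit disorder
#' parameters are found by scanning a coarse grid and refining once at a
#' ten-fold finer step around the maximum.
#'
#' @name model-fitting
NULL

map_vals <- function(x) if (inherits(x, "diffuse_map")) x$intensity else as.numeric(x)

#' Weighted Pearson correlation between two maps
#'
#' @param map_a,map_b [diffuse_map()]s or numeric vectors of equal length
#' @param weights per-voxel weights; defaults to `1/multiplicity` of the
#'   first map carrying a multiplicity, else 1
#' @return correlation coefficient in `[-1, 1]`
#' @export
weighted_cc <- function(map_a, map_b, weights = NULL) {
  a <- map_vals(map_a); b <- map_vals(map_b)
  stopifnot(length(a) == length(b))
  if (is.null(weights)) {
    m <- if (inherits(map_a, "diffuse_map") && !is.null(map_a$multiplicity))
      map_a$multiplicity
    else if (inherits(map_b, "diffuse_map") && !is.null(map_b$multiplicity))
      map_b$multiplicity
    weights <- if (is.null(m)) rep(1, length(a)) else 1 / pmax(m, 1)
  }
  ok <- is.finite(a) & is.finite(b) & is.finite(weights) & weights > 0
  if (sum(ok) < 10) stop("fewer than 10 co-defined voxels")
  w <- weights[ok] / sum(weights[ok])
  x <- a[ok]; y <- b[ok]
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop("zero weighted variance")
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Least-squares scale and platform between maps
#'
#' Finds `(scale, platform)` minimizing
#' `sum w (scale * pred + platform - exp)^2`; the correlation coefficient
#' is unchanged by this affine transform.
#'
#' @param predicted,experimental maps or numeric vectors
#' @param weights per-voxel weights (default as in [weighted_cc()])
#' @return list with `scale` and `platform`
#' @export
scale_to_experiment <- function(predicted, experimental, weights = NULL) {
  p <- map_vals(predicted); e <- map_vals(experimental)
  if (is.null(weights)) {
    m <- if (inherits(experimental, "diffuse_map") &&
             !is.null(experimental$multiplicity)) experimental$multiplicity
    weights <- if (is.null(m)) rep(1, length(p)) else 1 / pmax(m, 1)
  }
  ok <- is.finite(p) & is.finite(e) & is.finite(weights) & weights > 0
  if (sum(ok) < 2) stop("fewer than 2 co-defined voxels")
  w <- weights[ok]; p <- p[ok]; e <- e[ok]
  mp <- sum(w * p) / sum(w); me <- sum(w * e) / sum(w)
  vp <- sum(w * (p - mp)^2)
  if (vp == 0) stop("degenerate (constant) predicted map")
  sc <- sum(w * (p - mp) * (e - me)) / vp
  list(scale = sc, platform = me - sc * mp)
}

#' Build a cached predictor closure for a disorder model
#'
#' Returns `function(params)` mapping a named parameter list to the
#' predicted intensity vector on `grid`.  Basis transforms and per-gamma
#' kernel convolutions are cached inside the closure, so reusing one
#' predictor across many [scan_parameters()] calls (e.g. over noise
#' replicates) avoids recomputing them.
#'
#' @param model_spec list with `type` ("rbt", "llm", "llm_ext", "rbr") and
#'   `model` (an [atomic_model()])
#' @param grid a [map_grid()]
#' @return prediction closure
#' @export
make_predictor <- function(model_spec, grid) {
  type <- model_spec$type
  env <- new.env(parent = emptyenv())
  base <- NULL
  if (type == "rbt")
    base <- symmetrized_molecular_transform(model_spec$model, grid)$intensity
  basis_fun <- if (type == "llm") {
    function(g) {
      key <- sprintf("b%d", g$grid_extent)
      if (is.null(env[[key]]))
        env[[key]] <- symmetrized_molecular_transform(model_spec$model,
                                                      g)$intensity
      env[[key]]
    }
  } else if (type == "llm_ext") {
    function(g) {
      key <- sprintf("b%d", g$grid_extent)
      if (is.null(env[[key]]))
        env[[key]] <- crystal_transform_nodes(model_spec$model, g)
      env[[key]]
    }
  }
  get_conv <- function(gamma) {
    key <- sprintf("g%.8g", gamma)
    if (is.null(env[[key]]))
      env[[key]] <- llm_convolve(basis_fun, grid, gamma)
    env[[key]]
  }
  function(p) {
    vals <- switch(type,
      rbt = base * (1 - exp(-p[["sigma"]]^2 * grid$qabs^2)),
      llm = ,
      llm_ext = {
        x <- p[["sigma"]]^2 * grid$qabs^2
        x * exp(-x) * get_conv(p[["gamma"]])
      },
      rbr = predict_rigid_rotations(model_spec$model, grid, p[["sigma_rot"]],
                                    n_samples = model_spec$n_samples %||% 2000,
                                    seed = model_spec$seed %||% 1)$intensity,
      stop("unsupported model type '", type, "'"))
    vals
  }
}

#' Scan disorder parameters to maximize the weighted correlation
#'
#' Evaluates the multiplicity-weighted correlation between the (radial
#' average-subtracted) model prediction and the experimental map at every
#' point of a coarse parameter grid, then refines each parameter once at
#' a ten-fold finer step around the maximum (coordinate-wise, in the
#' order the axes are given).  Ties break toward smaller parameter
#' values.  Failed predictions (e.g. an LLM kernel wider than the grid)
#' are recorded and skipped.
#'
#' When the same model is fitted against many experimental replicates,
#' build the predictor once with [make_predictor()] and pass it in
#' `model_spec$predictor`; cached basis convolutions are then shared
#' across calls.
#'
#' @param experimental a radial-average-subtracted [diffuse_map()]
#' @param model_spec list with `type` ("rbt", "llm", "llm_ext", "rbr"),
#'   `model` (an [atomic_model()]), optional `n_samples`/`seed` for Monte
#'   Carlo models, and optionally a prebuilt `predictor`
#' @param scan_grid named list of parameter vectors, e.g.
#'   `list(sigma = seq(0.05, 1.5, 0.05))` or
#'   `list(sigma = ..., gamma = ...)`
#' @param weights optional per-voxel weights (default `1/multiplicity`)
#' @param refine run the fine refinement pass
#' @return object of class `fit_result`: `model_tag`, `best_params`,
#'   `cc`, `scale`, `platform`, `scan_table`
#' @export
scan_parameters <- function(experimental, model_spec, scan_grid,
                            weights = NULL, refine = TRUE) {
  if (!length(scan_grid) || !all(lengths(scan_grid) > 0))
    stop("scan_grid must contain at least one point")
  grid <- experimental$grid
  predictor <- model_spec$predictor %||% make_predictor(model_spec, grid)
  # precomputed radial-average machinery (hot path of the scan)
  n_shells <- 100
  rng <- range(grid$qabs)
  br <- seq(rng[1], rng[2], length.out = n_shells + 1)
  bin <- pmin(pmax(findInterval(grid$qabs, br, all.inside = TRUE), 1L),
              n_shells)
  centers <- (br[-1] + br[-length(br)]) / 2
  radial_sub <- function(vals) {
    mu <- group_means(vals, bin, n_shells)
    vals - interp_clamped(centers, mu, grid$qabs)
  }
  eval_tab <- function(tab) {
    cc <- rep(NA_real_, nrow(tab))
    for (i in seq_len(nrow(tab))) {
      vals <- tryCatch(predictor(as.list(tab[i, , drop = FALSE])),
                       error = function(e) NULL)
      if (is.null(vals)) next
      cc[i] <- weighted_cc(experimental, radial_sub(vals), weights = weights)
    }
    tab$cc <- cc
    tab
  }
  coarse <- expand.grid(scan_grid, KEEP.OUT.ATTRS = FALSE)
  coarse <- coarse[do.call(order, coarse), , drop = FALSE]
  tab <- eval_tab(coarse)
  scan_table <- tab
  if (all(is.na(tab$cc))) stop("all scan points failed")
  best <- tab[which.max(tab$cc), , drop = FALSE]
  if (refine) {
    for (nm in names(scan_grid)) {
      ax <- sort(unique(scan_grid[[nm]]))
      p <- best[[nm]]
      i <- which.min(abs(ax - p))
      lo <- if (i > 1) ax[i - 1] else ax[i]
      hi <- if (i < length(ax)) ax[i + 1] else ax[i]
      if (lo == hi) next
      fine <- best[rep(1, 21), setdiff(names(best), "cc"), drop = FALSE]
      fine[[nm]] <- seq(lo, hi, by = (hi - lo) / 20)
      fine <- eval_tab(fine)
      scan_table <- rbind(scan_table, fine)
      if (any(is.finite(fine$cc)) &&
          max(fine$cc, na.rm = TRUE) >= best$cc)
        best <- fine[which.max(fine$cc), , drop = FALSE]
    }
  }
  bp <- as.list(best[setdiff(names(best), "cc")])
  pred <- predictor(bp)
  sp <- scale_to_experiment(radial_sub(pred), experimental, weights = weights)
  structure(list(model_tag = model_spec$type, best_params = bp,
                 cc = best$cc, scale = sp$scale, platform = sp$platform,
                 scan_table = scan_table),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: cc = %.4f at %s (scale %.4g, platform %.4g)\n",
              x$model_tag, x$cc,
              paste(names(x$best_params),
                    signif(unlist(x$best_params), 4),
                    sep = " = ", collapse = ", "),
              x$scale, x$platform))
  invisible(x)
}
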