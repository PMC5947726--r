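# Shared toy fixtures.  Everything is generated in code from fixed seeds;
# heavier scenario builders live in the tests that use them.

tiny_geom <- function(n = 64, distance = 60, pixel = 0.3, lambda = 1.0) {
  detector_geometry(distance, pixel, n, n, c(n / 2 + 0.5, n / 2 + 0.5),
                    lambda)
}

ortho_crystal <- function(cell = c(24, 26, 30, 90, 90, 90),
                          sg = "P212121") {
  crystal_frame(cell, sg)
}

p1_crystal <- function(cell = c(20, 22, 24, 90, 90, 90)) {
  crystal_frame(cell, "P1")
}

flat_toy <- function(n_atoms = 5, crystal = p1_crystal(), seed = 3,
                     box = c(0.08, 0.38)) {
  make_toy_crystal(toy_crystal_spec(n_atoms = n_atoms, cell = crystal$cell,
                                    spacegroup = crystal$spacegroup,
                                    elements = "X", box = box, seed = seed))
}

anis <- function(map) subtract_radial_average(map)$intensity

# multiplicative per-voxel noise at a given signal-to-noise ratio
with_voxel_noise <- function(map, snr, seed) {
  map$intensity <- local_seed_test(seed, {
    map$intensity * (1 + stats::rnorm(length(map$intensity)) / snr)
  })
  map
}

local_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# default rendered scenario shared by round-trip / acceptance tests
default_scenario <- function(poisson = TRUE, bragg = TRUE, background = TRUE,
                             jitter = 0.15, n_frames = 36, seed = 7) {
  geom <- tiny_geom(128)
  cr <- ortho_crystal()
  m <- make_toy_crystal(toy_crystal_spec(n_atoms = 12, cell = cr$cell,
                                         spacegroup = "P212121", seed = 5))
  gr <- map_grid(cr, 8, 3)
  truth <- predict_rigid_translations(m, gr, 0.6)
  ds <- 100 / stats::median(truth$intensity[truth$intensity > 0])
  bgfun <- NULL
  cont <- NULL
  if (background) {
    pars <- local_seed_test(42, list(a1 = 150 * (1 + 0.4 * rnorm(n_frames)),
                                     a2 = 50 * (1 + 0.4 * rnorm(n_frames)),
                                     m = 60 * abs(rnorm(n_frames, 1, 0.3)),
                                     q0 = rnorm(n_frames, 0.007, 0.003)))
    bgfun <- function(q, i) pars$a1[i] * exp(-((q - 1.0) / 0.5)^2) + pars$a2[i]
    cont <- list(ref = synthetic_reference_profile, m = pars$m, q0 = pars$q0)
  }
  cfg <- image_sim_config(geom, cr, n_frames = n_frames, phi_width = 5,
                          diffuse_scale = ds,
                          bragg_scale = if (bragg) ds * 30 else 0,
                          background = bgfun, contaminant = cont,
                          scale_jitter = jitter, poisson = poisson,
                          seed = seed)
  ri <- render_images(truth, m, cfg)
  # truth on the rendered photon scale
  truth_scaled <- truth
  truth_scaled$intensity <- truth_scaled$intensity * ds
  list(geom = geom, crystal = cr, model = m, grid = gr, truth = truth_scaled,
       diffuse_scale = ds, frames = ri$frames, truth_sidecar = ri$truth,
       config = cfg)
}
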