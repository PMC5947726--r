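test_that("toy crystals are deterministic and respect their constraints", {
  spec <- toy_crystal_spec(n_atoms = 8, seed = 4)
  m1 <- make_toy_crystal(spec)
  m2 <- make_toy_crystal(spec)
  expect_identical(m1, m2)
  expect_gt(min(dist(m1$xyz)), 1.5 - 1e-12)
  expect_equal(nrow(m1$xyz), 8)
  # single atom in P1
  one <- make_toy_crystal(toy_crystal_spec(n_atoms = 1, spacegroup = "P1",
                                           cell = c(20, 20, 20, 90, 90, 90)))
  expect_equal(nrow(one$xyz), 1)
  # P212121 generates four symmetry copies per unit cell
  expect_equal(nrow(expand_symmetry(m1)$xyz), 32)
  # impossible packing fails with a clear error
  expect_error(make_toy_crystal(toy_crystal_spec(n_atoms = 100,
                                                 box = c(0.2, 0.22))),
               "min_dist")
})

test_that("symmetry expansion keeps copies apart and preserves elements", {
  m <- make_toy_crystal(toy_crystal_spec(n_atoms = 6, seed = 2))
  full <- expand_symmetry(m)
  expect_equal(full$spacegroup, "P1")
  expect_equal(full$element, rep(m$element, 4))
  expect_gt(min(dist(full$xyz)), 0.5)   # no collapsing copies
})

test_that("oracle maps: zero disorder gives zero; exhaustive ensembles are exact", {
  cr <- p1_crystal()
  gr <- map_grid(cr, 2, 3)
  m <- flat_toy(4, cr, seed = 3)
  z <- oracle_diffuse_map(m, list(disorder = list(type = "rbt", sigma = 0),
                                  n_samples = 100), gr)
  expect_equal(z$intensity, numeric(nrow(gr$hkl)))
  m2 <- m; m2$xyz[1, ] <- m2$xyz[1, ] + c(0.8, 0, 0.4)
  w <- c(0.55, 0.45)
  orc <- oracle_diffuse_map(m, list(disorder = list(
    type = "ensemble", states = list(m, m2), weights = w,
    exhaustive = TRUE)), gr)
  expect_equal(orc$intensity, predict_ensemble(list(m, m2), w, gr)$intensity,
               tolerance = 1e-12)
  expect_error(oracle_diffuse_map(m, list(disorder = list(type = "phonon"),
                                          n_samples = 100), gr),
               "unsupported")
  expect_error(oracle_diffuse_map(m, list(disorder = list(type = "rbt",
                                                          sigma = 1),
                                          n_samples = 10), gr), ">= 100")
})

test_that("rendering is reproducible and the noiseless round trip is exact", {
  sc1 <- default_scenario(poisson = FALSE, bragg = FALSE, background = FALSE,
                          jitter = 0, n_frames = 4)
  sc2 <- default_scenario(poisson = FALSE, bragg = FALSE, background = FALSE,
                          jitter = 0, n_frames = 4)
  expect_identical(sc1$frames[[2]]$pixels, sc2$frames[[2]]$pixels)
  mp <- accumulate(lapply(sc1$frames, diffusemap:::correct_frame_photometric,
                          geometry = sc1$geom), sc1$geom, sc1$crystal, 8, 3)
  def <- is.finite(mp$intensity)
  rel <- abs(mp$intensity[def] - sc1$truth$intensity[def]) /
    pmax(abs(sc1$truth$intensity[def]), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("frame stacks and configs survive text round trips", {
  sc <- default_scenario(poisson = TRUE, n_frames = 2)
  dir <- file.path(tempdir(), "framestack")
  write_frames(sc$frames, dir)
  back <- read_frames(dir)
  expect_equal(back[[1]]$pixels, sc$frames[[1]]$pixels, tolerance = 1e-6)
  expect_equal(back[[2]]$phi_start, sc$frames[[2]]$phi_start)
  expect_equal(back[[2]]$scale_factor, sc$frames[[2]]$scale_factor,
               tolerance = 1e-6)
  cfgp <- file.path(tempdir(), "cfg.json")
  write_config(sc$geom, sc$crystal, cfgp)
  cfg <- read_config(cfgp)
  expect_equal(cfg$geometry$distance, sc$geom$distance)
  expect_equal(cfg$crystal$cell, sc$crystal$cell)
  expect_equal(cfg$crystal$orientation, sc$crystal$orientation,
               tolerance = 1e-12)
})

test_that("PDB files round-trip an atomic model", {
  m <- make_toy_crystal(toy_crystal_spec(n_atoms = 5, seed = 12,
                                         elements = c("C", "N", "O", "S")))
  path <- file.path(tempdir(), "toy.pdb")
  write_pdb(m, path)
  back <- read_pdb(path)
  expect_equal(back$xyz, m$xyz, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$element, m$element)
  expect_equal(back$cell, m$cell, tolerance = 1e-3)
  expect_equal(back$spacegroup, "P212121")
  expect_equal(back$b, m$b, tolerance = 0.01)
})
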