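test_that("molecular transform closed forms", {
  cr <- p1_crystal(c(10, 10, 10, 90, 90, 90))
  gr <- map_grid(cr, 2, 3)
  # single constant-f atom: |F|^2 = 1 everywhere
  one <- atomic_model("X", matrix(c(1, 2, 3), 1, 3), cell = cr$cell)
  expect_equal(Mod(molecular_transform(one, gr)$F)^2,
               rep(1, nrow(gr$hkl)), tolerance = 1e-12)
  # two identical atoms d apart along x: |F|^2 = 4 cos^2(q_x d / 2)
  d <- 2.5
  two <- atomic_model(c("X", "X"), rbind(c(0, 0, 0), c(d, 0, 0)),
                      cell = cr$cell)
  F2 <- Mod(molecular_transform(two, gr)$F)^2
  expect_equal(F2, 4 * cos(gr$Q[, 1] * d / 2)^2, tolerance = 1e-9)
  # rigid translation changes phases only
  shift <- two; shift$xyz <- shift$xyz + matrix(c(1.1, -0.7, 0.3), 2, 3,
                                                byrow = TRUE)
  expect_equal(Mod(molecular_transform(shift, gr)$F)^2, F2,
               tolerance = 1e-9)
})

test_that("orientation symmetrization equals the brute-force rotation sum", {
  cr <- ortho_crystal()
  gr <- map_grid(cr, 2, 3)
  m <- flat_toy(4, cr, seed = 7)
  tsym <- symmetrized_molecular_transform(m, gr)$intensity
  brute <- numeric(nrow(gr$hkl))
  for (M in cr$ops$recip) {
    R <- diffusemap:::op_cartesian(cr, M)
    rot <- m; rot$xyz <- m$xyz %*% R    # rotate the molecule instead of q
    brute <- brute + Mod(molecular_transform(rot, gr)$F)^2
  }
  expect_equal(tsym, brute, tolerance = 1e-8)
  # P1: reduces to |F|^2
  crp <- p1_crystal(); grp <- map_grid(crp, 2, 3)
  mp <- flat_toy(3, crp, seed = 8)
  expect_equal(symmetrized_molecular_transform(mp, grp)$intensity,
               Mod(molecular_transform(mp, grp)$F)^2, tolerance = 1e-12)
})

test_that("rigid translations: Debye-Waller complement of the transform", {
  cr <- p1_crystal()
  gr <- map_grid(cr, 2, 3)
  m <- flat_toy(4, cr, seed = 7)
  expect_equal(predict_rigid_translations(m, gr, 0)$intensity,
               numeric(nrow(gr$hkl)))
  sig <- 0.5
  tsym <- symmetrized_molecular_transform(m, gr)$intensity
  got <- predict_rigid_translations(m, gr, sig)$intensity
  expect_equal(got, tsym * (1 - exp(-sig^2 * gr$qabs^2)), tolerance = 1e-12)
  # at |q| sigma = 1 the damping is exactly 1 - 1/e
  v <- which.min(abs(gr$qabs - 1 / sig))
  expect_equal(got[v] / tsym[v], 1 - exp(-(sig * gr$qabs[v])^2),
               tolerance = 1e-12)
})

test_that("rigid rotations: zero at sigma 0, blurring along shells, seed-stable", {
  cr <- p1_crystal()
  gr <- map_grid(cr, 3, 3)
  m <- flat_toy(4, cr, seed = 3)
  expect_equal(predict_rigid_rotations(m, gr, 0)$intensity,
               numeric(nrow(gr$hkl)))
  r1 <- predict_rigid_rotations(m, gr, 2.9, n_samples = 10000, seed = 1)
  r2 <- predict_rigid_rotations(m, gr, 2.9, n_samples = 10000, seed = 2)
  expect_gt(cor(r1$intensity, r2$intensity), 0.99)
  # azimuthal blurring: rotational disorder correlates with the transform
  # smeared around shells, not radially -- check that the rotation map is
  # closer to the transform at equal |q| than a radially-shifted transform
  expect_error(predict_rigid_rotations(m, gr, 1, n_samples = 10), ">= 100")
})

test_that("the liquid-like motions kernel has its closed-form properties", {
  expect_equal(llm_kernel(0, 7), 8 * pi * 7^3)
  g <- 18
  half <- sqrt(sqrt(2) - 1) / g
  expect_equal(llm_kernel(half, g), llm_kernel(0, g) / 2, tolerance = 1e-12)
  for (gam in c(5, 18, 118)) {
    nrm <- integrate(function(x) llm_kernel(x, gam) * 4 * pi * x^2, 0, Inf,
                     rel.tol = 1e-9)$value / (2 * pi)^3
    expect_equal(nrm, 1, tolerance = 0.01)
  }
  expect_error(llm_kernel(0.1, 0), "positive")
})

test_that("extended LLM concentrates at lattice nodes; confined varies smoothly", {
  cr <- p1_crystal(c(30, 30, 30, 90, 90, 90))
  gr <- map_grid(cr, 3, 3)
  m <- flat_toy(5, cr, seed = 6, box = c(0.05, 0.45))
  ext <- predict_llm(m, gr, 0.4, 40, extended = TRUE)$intensity
  conf <- predict_llm(m, gr, 0.4, 40, extended = FALSE)$intensity
  at_node <- rowSums(gr$trips %% 3 == 0) == 3 & gr$qabs > 0
  off_node <- !at_node & gr$qabs > 0
  expect_gt(median(ext[at_node]), 10 * median(ext[off_node]))
  expect_lt(median(conf[at_node]), 3 * median(conf[off_node]))
  # the extended-minus-confined difference decays with distance to nodes
  frac <- gr$hkl - round(gr$hkl)
  dq <- sqrt(rowSums((frac %*% t(cr$orientation))^2))
  ve <- ext / sum(ext); vc <- conf / sum(conf)
  dd <- abs(ve - vc)
  lo <- dq < quantile(dq, 0.2); hi <- dq > quantile(dq, 0.8)
  expect_gt(mean(dd[lo]), mean(dd[hi]))
})

test_that("ensemble predictions follow Guinier's weighted variance", {
  cr <- p1_crystal()
  gr <- map_grid(cr, 2, 3)
  m1 <- flat_toy(4, cr, seed = 7)
  expect_equal(predict_ensemble(list(m1, m1), c(0.3, 0.7), gr)$intensity,
               numeric(nrow(gr$hkl)), tolerance = 1e-9)
  m2 <- m1; m2$xyz[1, ] <- m2$xyz[1, ] + c(1.2, -0.4, 0.6)
  w <- c(0.6, 0.4)
  got <- predict_ensemble(list(m1, m2), w, gr)$intensity
  dF <- molecular_transform(m1, gr)$F - molecular_transform(m2, gr)$F
  expect_equal(got, w[1] * w[2] * Mod(dF)^2, tolerance = 1e-9)
  # three states against the explicit enumeration formula
  m3 <- m1; m3$xyz[2, ] <- m3$xyz[2, ] + c(0, 0.9, -0.5)
  w3 <- c(0.5, 0.3, 0.2)
  got3 <- predict_ensemble(list(m1, m2, m3), w3, gr)$intensity
  Fs <- lapply(list(m1, m2, m3), function(s) molecular_transform(s, gr)$F)
  sumI <- Reduce(`+`, Map(function(F, wi) wi * Mod(F)^2, Fs, w3))
  sumF <- Reduce(`+`, Map(function(F, wi) wi * F, Fs, w3))
  expect_equal(got3, pmax(sumI - Mod(sumF)^2, 0), tolerance = 1e-9)
  expect_error(predict_ensemble(list(m1, m2), c(0.5, 0.4), gr), "sum to 1")
})

test_that("elastic-network covariances renormalize to the target B factors", {
  cr <- p1_crystal()
  m <- flat_toy(6, cr, seed = 9)
  enm <- build_enm_covariance(m, cutoff = 12)
  expect_equal(8 * pi^2 * diag(enm$vmat), m$b, tolerance = 1e-8)
  ev <- eigen(enm$vmat, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # toy chain: covariance decays with distance; oracle is the explicit
  # inverse of the shifted Laplacian (independent of the eigen route)
  chain <- atomic_model(rep("X", 6), cbind(seq(0, 15, by = 3), 0, 0),
                        b = 10, cell = c(30, 20, 20, 90, 90, 90))
  ec <- build_enm_covariance(chain, cutoff = 3.5)
  # covariance decays with separation (the removed rigid mode makes
  # far-end covariances negative, so only the leading decay is monotone)
  expect_true(ec$vmat[1, 2] > ec$vmat[1, 3] &&
                ec$vmat[1, 3] > ec$vmat[1, 4])
  expect_equal(which.max(ec$vmat[1, -1]), 1L)
  A <- as.matrix(dist(chain$xyz)) <= 3.5 & as.matrix(dist(chain$xyz)) > 0
  L <- -1 * A; diag(L) <- rowSums(A)
  pinv <- solve(L + 1 / 6) - 1 / 6          # closed form for connected graphs
  s <- sqrt(chain$b / (8 * pi^2 * diag(pinv)))
  expect_equal(ec$vmat, pinv * outer(s, s), tolerance = 1e-8,
               ignore_attr = TRUE)
  # disconnected network fails loudly
  far <- atomic_model(rep("X", 4), rbind(c(0, 0, 0), c(2, 0, 0),
                                         c(20, 0, 0), c(22, 0, 0)),
                      cell = c(40, 20, 20, 90, 90, 90))
  expect_error(build_enm_covariance(far, cutoff = 3), "disconnected")
})

test_that("Gaussian-covariance disorder has its algebraic limits", {
  cr <- p1_crystal()
  gr <- map_grid(cr, 2, 3)
  m <- flat_toy(5, cr, seed = 3)
  n <- nrow(m$xyz)
  # fully rigid covariance (v_ij = sigma^2 for all pairs) equals RBT
  gg <- predict_gaussian_disorder(m, gr, list(vmat = matrix(0.09, n, n)))
  expect_equal(gg$intensity, predict_rigid_translations(m, gr, 0.3)$intensity,
               tolerance = 1e-9)
  # uncorrelated identical atoms: radially symmetric map
  und <- predict_gaussian_disorder(m, gr, list(vmat = diag(0.09, n)))
  a <- subtract_radial_average(und)$intensity
  expect_lt(max(abs(a)), 0.05 * max(und$intensity))
})

test_that("Wilson B to sigma conversion reproduces the printed values", {
  expect_equal(round(wilson_b_to_sigma(16.1), 2), 0.45)
  expect_equal(round(wilson_b_to_sigma(31.4), 2), 0.63)
  expect_equal(wilson_b_to_sigma(0), 0)
  expect_error(wilson_b_to_sigma(-1), "non-negative")
})

test_that("every predicted map is Laue/Friedel invariant and non-negative", {
  cr <- ortho_crystal()
  gr <- map_grid(cr, 2, 3)
  m <- flat_toy(4, cr, seed = 7)
  m2 <- m; m2$xyz[1, ] <- m2$xyz[1, ] + 1
  preds <- list(
    rbt = predict_rigid_translations(m, gr, 0.5),
    rbr = predict_rigid_rotations(m, gr, 2, n_samples = 500, seed = 4),
    llm = predict_llm(m, gr, 0.4, 8),
    llm_ext = predict_llm(m, gr, 0.4, 8, extended = TRUE),
    ens = predict_ensemble(list(m, m2), c(0.5, 0.5), gr),
    enm = predict_gaussian_disorder(m, gr, build_enm_covariance(m, 15)))
  for (nm in names(preds)) {
    p <- preds[[nm]]
    expect_true(all(p$intensity >= 0), label = paste(nm, "non-negative"))
    p$n_obs <- rep(1L, length(p$intensity))
    s <- symmetrize(p)   # invariance <=> orbit averaging changes nothing
    expect_equal(s$intensity, p$intensity, tolerance = 1e-6,
                 label = paste(nm, "Laue invariant"))
  }
})
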