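# Spline potentials and the hybrid energy.

make_onehot_restraints <- function(ref, floor_p = 1e-6) {
  oracle_geometry(ref, oracle_config(temperature = 0))
}

test_that("spline curves reproduce their knot values at bin centers", {
  hp <- fix_hairpin16()
  restr <- oracle_geometry(hp$beads, oracle_config(temperature = 1))
  pot <- build_geometry_potential(restr)
  for (term in c("dist_PP", "dih_CNNC")) {
    tm <- pot$terms[[term]]
    centers <- tm$x1 + tm$h * (0:(tm$n - 1))
    v <- spline_curve(pot, term, 1, 5, centers)
    expect_equal(v, tm$Y[1 + 4 * 16, ], tolerance = 1e-9)
  }
})

test_that("uniform distance restraints give a flat zero potential", {
  pot <- build_geometry_potential(uniform_restraints(4))
  grid <- seq(2.5, 29.5, length.out = 200)
  expect_lt(max(abs(spline_curve(pot, "dist_PP", 1, 2, grid))), 1e-9)
  # and the dihedral curve is flat too (uniform-reference centering)
  gridth <- seq(-pi, pi, length.out = 200)
  expect_lt(max(abs(spline_curve(pot, "dih_PCCP", 1, 2, gridth))), 1e-9)
})

test_that("one-hot restraints place spline minima at the true bin", {
  hp <- fix_hairpin16()
  restr <- make_onehot_restraints(hp$beads)
  pot <- build_geometry_potential(restr)
  labels <- geometry_labels(hp$beads)
  spec <- geometry_bin_spec()
  set.seed(41)
  for (term in GEOMETRY_TERMS) {
    sp <- spec[[term]]
    tm <- pot$terms[[term]]
    checked <- 0
    for (trial in 1:30) {
      i <- sample(16, 1); j <- sample(16, 1)
      if (i == j) next
      b <- labels[[term]][i, j]
      first <- if (sp$kind == "distance") 2L else 1L
      if (is.na(b) || b < first || b >= first + sp$n_content) next
      bc <- b - first + 1L
      center <- tm$x1 + (bc - 1) * tm$h
      grid <- if (sp$kind == "distance")
        seq(sp$lo, sp$hi, length.out = 10000)
      else seq(-pi, pi, length.out = 10000)
      v <- spline_curve(pot, term, i, j, grid)
      xmin <- grid[which.min(v)]
      dist_off <- if (sp$kind == "dihedral")
        min(abs(xmin - center), 2 * pi - abs(xmin - center))
      else abs(xmin - center)
      expect_lt(dist_off, tm$h / 2)
      checked <- checked + 1
      if (checked >= 3) break
    }
    expect_gte(checked, 1)
  }
})

test_that("dihedral splines are exactly periodic", {
  hp <- fix_hairpin16()
  pot <- build_geometry_potential(
    oracle_geometry(hp$beads, oracle_config(temperature = 1)))
  for (term in c("dih_PCCP", "dih_CNNC", "dih_PNNP")) {
    v <- spline_curve(pot, term, 2, 9, c(-pi, pi))
    expect_equal(v[1], v[2], tolerance = 1e-9)
  }
})

test_that("uniform restraints give zero energy for any conformation", {
  hp <- fix_hairpin16()
  pot <- build_geometry_potential(uniform_restraints(16))
  expect_lt(abs(energy_geo(hp$beads, pot)$value), 1e-6 * 6)
  pert <- perturb_structure(hp$beads, 4, seed = 2)
  expect_lt(abs(energy_geo(pert, pot)$value), 1e-6 * 6)
})

test_that("the reference conformation sits near the restraint optimum", {
  hp <- fix_hairpin16()
  pot <- build_geometry_potential(
    oracle_geometry(hp$beads, oracle_config(temperature = 0.5)))
  e_ref <- energy_geo(hp$beads, pot)$value
  for (seed in 1:5)
    expect_gt(energy_geo(perturb_structure(hp$beads, 3, seed = seed),
                         pot)$value, e_ref)
})

test_that("geometry energy gradient matches finite differences", {
  hp4 <- make_reference("hairpin", stem = 1, loop = 2, seed = 5)  # L = 4
  pot <- build_geometry_potential(
    oracle_geometry(hp4$beads, oracle_config(temperature = 1)))
  s <- perturb_structure(hp4$beads, 1, seed = 6)
  res <- energy_geo(s, pot, grad = TRUE)
  h <- 1e-6
  set.seed(43)
  for (probe in 1:8) {
    i <- sample(4, 1); a <- sample(3, 1); x <- sample(3, 1)
    sp <- s; sp$coords[i, a, x] <- sp$coords[i, a, x] + h
    sm <- s; sm$coords[i, a, x] <- sm$coords[i, a, x] - h
    fd <- (energy_geo(sp, pot)$value - energy_geo(sm, pot)$value) / (2 * h)
    expect_equal(res$g_beads[i, a, x], fd, tolerance = 1e-4)
  }
})

test_that("e2e energy: identity case, K-linearity, brute force", {
  hp <- fix_hairpin16()
  fs <- fix_true_frames()
  one <- e2e_prediction(list(fs))
  n_terms <- 16 * 48
  expect_equal(energy_e2e(fs, one, hp$sequence)$value,
               n_terms * sqrt(1e-3), tolerance = 1e-9)
  # K identical predictions scale the energy K-fold
  conf <- frames_from_structure(perturb_structure(hp$beads, 2, seed = 7),
                                fix_templates(), hp$sequence)
  e1 <- energy_e2e(conf, one, hp$sequence)$value
  e3 <- energy_e2e(conf, e2e_prediction(list(fs, fs, fs)),
                   hp$sequence)$value
  expect_equal(e3, 3 * e1, tolerance = 1e-9)
  # 2-residue brute force (sum reduction, K = 1)
  tmpl <- fix_templates()
  seq2 <- c("G", "C")
  predf <- frame_set(list(rotvec_to_matrix(c(0.1, 0.2, 0)), diag(3)),
                     rbind(c(0, 0, 0), c(3, 4, 0)))
  conf2 <- frame_set(list(diag(3), rotvec_to_matrix(c(0, 0, 0.4))),
                     rbind(c(0.5, 0, 0), c(3, 3, 1)))
  atoms <- rbind(tmpl$G$local_coords, tmpl$C$local_coords)
  res_of <- rep(1:2, each = 3)
  brute <- 0
  for (i in 1:2) for (j in 1:6) {
    fj_c <- frame_set_get(conf2, res_of[j])
    fj_p <- frame_set_get(predf, res_of[j])
    xc <- frame_apply(fj_c, atoms[j, , drop = FALSE])
    xp <- frame_apply(fj_p, atoms[j, , drop = FALSE])
    lc <- frame_apply(frame_invert(frame_set_get(conf2, i)), xc)
    lp <- frame_apply(frame_invert(frame_set_get(predf, i)), xp)
    brute <- brute + min(30, sqrt(sum((lc - lp)^2) + 1e-3))
  }
  expect_equal(energy_e2e(conf2, e2e_prediction(list(predf)), seq2)$value,
               brute, tolerance = 1e-10)
})

test_that("hybrid energy is the unweighted sum of available components", {
  hp <- fix_hairpin16()
  fs <- fix_true_frames()
  preds <- oracle_e2e(hp$beads, oracle_config(replicas = 2, seed = 9))
  pot <- build_geometry_potential(
    oracle_geometry(hp$beads, oracle_config(temperature = 1)))
  conf <- frames_from_structure(perturb_structure(hp$beads, 1, seed = 8),
                                fix_templates(), hp$sequence)
  eg <- energy_hybrid(conf, hp$sequence, potentials = pot)
  ee <- energy_hybrid(conf, hp$sequence, preds = preds)
  eh <- energy_hybrid(conf, hp$sequence, preds = preds, potentials = pot)
  beads <- beads_from_frames(conf, hp$sequence)
  expect_equal(eg, energy_geo(beads, pot)$value, tolerance = 1e-12)
  expect_equal(ee, energy_e2e(conf, preds, hp$sequence)$value,
               tolerance = 1e-12)
  expect_equal(eh, eg + ee, tolerance = 1e-9)
  expect_error(energy_hybrid(conf, hp$sequence), "absent")
})

test_that("energy decreases along the negative gradient", {
  hp <- fix_hairpin16()
  pot <- build_geometry_potential(
    oracle_geometry(hp$beads, oracle_config(temperature = 0.5)))
  s <- perturb_structure(hp$beads, 3, seed = 10)
  res <- energy_geo(s, pot, grad = TRUE)
  g <- res$g_beads
  step <- 1e-4 / max(abs(g))
  s2 <- s; s2$coords <- s$coords - step * g
  expect_lt(energy_geo(s2, pot)$value, res$value)
})
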