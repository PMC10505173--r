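# Geometric substrate: ideal helices, templates, rigid frames, mirrors.

test_that("ideal duplex stems have exact helical symmetry", {
  seq16 <- strsplit("ACGUACGUACGUACGU", "")[[1]]
  pairs <- lapply(1:8, function(i) c(i, 17 - i))
  h <- build_ideal_helix(seq16, pairs)
  expect_equal(h$beads$L, 16)
  P <- bead_atom(h$beads, "P")
  dPP <- sqrt(rowSums((P[2:8, ] - P[1:7, ])^2))
  # all intra-strand steps equal a single stem-geometry constant
  expect_lt(diff(range(dPP)), 1e-9)
  # independent oracle: explicit rotation-about-axis construction,
  # d^2 = 2 r^2 (1 - cos twist) + rise^2 with r the P radius
  units <- rnaforge:::.aform_units()
  r <- sqrt(sum(units$A["P", 1:2]^2))
  oracle <- sqrt(2 * r^2 * (1 - cos(32.7 * pi / 180)) + 2.548^2)
  expect_equal(dPP[1], oracle, tolerance = 1e-9)
})

test_that("single unpaired nucleotide builds with finite coordinates", {
  h <- build_ideal_helix("A", list())
  expect_equal(h$beads$L, 1)
  expect_true(all(is.finite(h$beads$coords)))
})

test_that("hairpin stems superpose exactly onto a bare duplex stem", {
  hp <- fix_hairpin16()
  d6 <- build_ideal_helix(strsplit("GGGGGGCCCCCC", "")[[1]],
                          lapply(1:6, function(i) c(i, 13 - i)))
  expect_equal(hp$beads$L, 16)
  stem_idx <- c(1:6, 11:16)
  a <- do.call(rbind, lapply(stem_idx, function(i)
    matrix(hp$beads$coords[i, , ], 3, 3)))
  b <- do.call(rbind, lapply(1:12, function(i)
    matrix(d6$beads$coords[i, , ], 3, 3)))
  expect_lt(attr(kabsch_frame(a, b), "rmsd"), 1e-6)
})

test_that("crossing pairs are rejected naming the offenders", {
  seq16 <- strsplit("ACGUACGUACGUACGU", "")[[1]]
  expect_error(build_ideal_helix(seq16, list(c(1, 8), c(4, 12))),
               "crossing pairs \\(1,8\\) and \\(4,12\\)")
})

test_that("templates are centered, aliased and distance-preserving", {
  tmpl <- fix_templates()
  for (b in c("A", "U", "G", "C"))
    expect_lt(max(abs(colMeans(tmpl[[b]]$local_coords))), 1e-9)
  expect_equal(tmpl[["N"]]$local_coords, tmpl[["U"]]$local_coords)
  # rigid transforms preserve the triad's internal distances
  units <- rnaforge:::.aform_units()
  triad <- rnaforge:::.unit_beads(units$G, "G")
  expect_equal(as.numeric(dist(tmpl$G$local_coords)),
               as.numeric(dist(triad)), tolerance = 1e-9)
})

test_that("frame_from_beads recovers exact rigid placements", {
  tmpl <- fix_templates()
  f0 <- frame_from_beads(tmpl$A$local_coords, tmpl$A)
  expect_equal(f0$R, diag(3), tolerance = 1e-8)
  expect_equal(f0$t, c(0, 0, 0), tolerance = 1e-8)
  expect_lt(attr(f0, "rmsd"), 1e-9)
  g <- random_rigid(4)
  obs <- frame_apply(g, tmpl$A$local_coords)
  f <- frame_from_beads(obs, tmpl$A)
  expect_equal(f$R, g$R, tolerance = 1e-8)
  expect_equal(f$t, g$t, tolerance = 1e-8)
  # template re-projection reproduces the observation exactly
  expect_equal(frame_apply(f, tmpl$A$local_coords), obs,
               tolerance = 1e-8)
})

test_that("frame_from_beads matches a dense rotation-grid minimizer", {
  tmpl <- fix_templates()
  g0 <- random_rigid(11)
  set.seed(12)
  obs <- frame_apply(g0, tmpl$A$local_coords) + matrix(rnorm(9, 0, 0.1), 3)
  fit <- frame_from_beads(obs, tmpl$A)
  # brute force: scan rotations around the noise-free pose on a grid
  step <- 2 * pi / 180
  grid <- expand.grid(a = seq(-3, 3) * step, b = seq(-3, 3) * step,
                      c = seq(-3, 3) * step)
  loc <- tmpl$A$local_coords
  ctr_l <- colMeans(loc); ctr_o <- colMeans(obs)
  best <- Inf; bestR <- NULL
  for (r in seq_len(nrow(grid))) {
    R <- g0$R %*% rotvec_to_matrix(as.numeric(grid[r, ]))
    fitted <- sweep(sweep(loc, 2, ctr_l) %*% t(R), 2, ctr_o, "+")
    err <- sum((fitted - obs)^2)
    if (err < best) { best <- err; bestR <- R }
  }
  ang <- acos(pmin(1, (sum(diag(t(bestR) %*% fit$R)) - 1) / 2))
  expect_lt(ang, step * sqrt(3))       # within grid resolution
})

test_that("degenerate bead triads raise an error", {
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  tmpl <- fix_templates()
  expect_error(frame_from_beads(collinear, tmpl$A), "degenerate")
})

test_that("frame algebra: identity, inverse, composition", {
  expect_equal(frame_invert(frame_identity())$R, diag(3))
  f <- random_rigid(5)
  g <- random_rigid(6)
  h <- random_rigid(7)
  set.seed(8)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(frame_apply(frame_invert(f), frame_apply(f, x)), x,
               tolerance = 1e-10)
  cid <- frame_compose(f, frame_invert(f))
  expect_equal(cid$R, diag(3), tolerance = 1e-10)
  expect_equal(cid$t, c(0, 0, 0), tolerance = 1e-10)
  # associativity and the action property
  lhs <- frame_compose(frame_compose(f, g), h)
  rhs <- frame_compose(f, frame_compose(g, h))
  expect_equal(lhs$R, rhs$R, tolerance = 1e-12)
  expect_equal(lhs$t, rhs$t, tolerance = 1e-10)
  expect_equal(frame_apply(frame_compose(f, g), x),
               frame_apply(f, frame_apply(g, x)), tolerance = 1e-10)
})

test_that("every constructed frame is a proper rotation", {
  expect_error(rigid_frame(diag(c(1, 1, -1)), c(0, 0, 0)), "proper")
  hp <- fix_hairpin16()
  fs <- frames_from_structure(hp$beads, fix_templates(), hp$sequence)
  for (i in seq_len(fs$L))
    expect_equal(det(matrix(fs$R[i, , ], 3, 3)), 1, tolerance = 1e-6)
})

test_that("frame_from_beads is left-equivariant", {
  tmpl <- fix_templates()
  set.seed(21)
  for (rep in 1:5) {
    obs <- tmpl$G$local_coords + matrix(rnorm(9, 0, 0.3), 3)
    g <- random_rigid(rep * 13)
    f1 <- frame_from_beads(frame_apply(g, obs), tmpl$G)
    f2 <- frame_compose(g, frame_from_beads(obs, tmpl$G))
    expect_equal(f1$R, f2$R, tolerance = 1e-8)
    expect_equal(f1$t, f2$t, tolerance = 1e-8)
  }
})

test_that("mirroring is an involution preserving distances, negating dihedrals", {
  hp <- fix_hairpin16()
  m <- mirror_structure(hp$beads)
  expect_equal(mirror_structure(m)$coords, hp$beads$coords)
  expect_equal(pairwise_distances(m, "P"), pairwise_distances(hp$beads, "P"))
  set.seed(31)
  for (rep in 1:10) {
    ij <- sample(16, 2)
    th0 <- pair_dihedral(hp$beads, ij[1], ij[2], "PCCP")
    th1 <- pair_dihedral(m, ij[1], ij[2], "PCCP")
    expect_equal(th1, -th0, tolerance = 1e-10)
  }
})
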