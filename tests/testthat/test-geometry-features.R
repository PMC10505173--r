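# Pairwise geometry measurement and discretization.

test_that("pairwise distances match constructions and the helix oracle", {
  coords <- array(0, c(2, 3, 3))
  coords[2, , ] <- matrix(rep(c(5, 0, 0), 3), 3, 3, byrow = TRUE)
  coords[1, 2, ] <- c(0, 1, 0); coords[1, 3, ] <- c(0, 0, 1)
  coords[2, 2, ] <- coords[2, 2, ] + c(0, 1, 0)
  coords[2, 3, ] <- coords[2, 3, ] + c(0, 0, 1)
  s <- bead_structure(coords)
  d <- pairwise_distances(s, "P")
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), c(0, 0))
  hp <- fix_hairpin16()
  expect_equal(pairwise_distances(mirror_structure(hp$beads), "C4'"),
               pairwise_distances(hp$beads, "C4'"))
  # duplex distances vs the explicit helical construction
  seq16 <- strsplit("ACGUACGUACGUACGU", "")[[1]]
  h <- build_ideal_helix(seq16, lapply(1:8, function(i) c(i, 17 - i)))
  units <- rnaforge:::.aform_units()
  d <- pairwise_distances(h$beads, "P")
  p1 <- units$A["P", ]
  twist <- 32.7 * pi / 180
  for (k in 1:5) {
    pk <- rnaforge:::rot_z(k * twist) %*% p1 + c(0, 0, k * 2.548)
    expect_equal(d[1, 1 + k], sqrt(sum((p1 - pk)^2)), tolerance = 1e-9)
  }
})

test_that("pair dihedrals follow the signed IUPAC convention", {
  mk <- function(p1, p2, p3, p4) {
    coords <- array(0, c(2, 3, 3))
    coords[1, 1, ] <- p1; coords[1, 2, ] <- p2
    coords[2, 2, ] <- p3; coords[2, 1, ] <- p4
    coords[1, 3, ] <- c(9, 9, 9); coords[2, 3, ] <- c(-9, 9, 9)
    bead_structure(coords)
  }
  # cis (same side) -> 0; trans -> pi
  cis <- mk(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))
  expect_equal(abs(pair_dihedral(cis, 1, 2, "PCCP")), 0, tolerance = 1e-12)
  trans <- mk(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0))
  expect_equal(abs(pair_dihedral(trans, 1, 2, "PCCP")), pi,
               tolerance = 1e-12)
  expect_error(pair_dihedral(cis, 1, 1, "PCCP"), "differ")
  # mirror negation on random pairs of a real structure
  hp <- fix_hairpin16()
  m <- mirror_structure(hp$beads)
  set.seed(9)
  for (scheme in c("PCCP", "CNNC", "PNNP")) {
    ij <- sample(16, 2)
    expect_equal(pair_dihedral(m, ij[1], ij[2], scheme),
                 -pair_dihedral(hp$beads, ij[1], ij[2], scheme),
                 tolerance = 1e-10)
  }
  # symmetry theta(i,j) = theta(j,i) for these quadruples
  th <- pairwise_dihedrals(hp$beads, "PCCP")
  expect_equal(th, t(th), tolerance = 1e-10)
})

test_that("distance discretization follows the stated bin layout", {
  spec <- geometry_bin_spec()
  expect_equal(discretize(1.9, spec, "dist_PP"), 1L)
  expect_equal(discretize(30.5, spec, "dist_PP"), 58L)   # > 30 A bin
  expect_equal(discretize(2.0, spec, "dist_PP"), 2L)     # first content bin
  # closed-form index arithmetic at an interior boundary value
  w <- (30 - 2) / 56
  expect_equal(discretize(16.0, spec, "dist_PP"),
               1L + 1L + as.integer(floor((16 - 2) / w)))
  # boundary scan: every edge starts its own bin (half-open left edges)
  edges <- 2 + w * (0:55)
  expect_equal(discretize(edges + 1e-9, spec, "dist_PP"), as.integer(2:57))
  expect_equal(discretize(edges - 1e-9, spec, "dist_PP"),
               as.integer(1:56))
})

test_that("dense grids partition into exactly 58/46/34 bins", {
  spec <- geometry_bin_spec()
  cases <- list(dist_PP = 58L, dist_CC = 46L, dist_NN = 34L)
  for (term in names(cases)) {
    sp <- spec[[term]]
    grid <- seq(0.5, sp$hi + 3, by = 0.001)
    idx <- discretize(grid, spec, term)
    expect_equal(sort(unique(idx)), seq_len(cases[[term]]))
    # half-open partition: indices are monotone along the grid
    expect_true(all(diff(idx) >= 0))
    # occupancy widths of interior bins are uniform
    counts <- table(idx)[as.character(2:(cases[[term]] - 1L))]
    expect_lt(diff(range(counts)), 2)
  }
})

test_that("dihedral binning wraps and honors the beyond-M gate", {
  spec <- geometry_bin_spec()
  eps <- 1e-6
  expect_equal(discretize(-pi + eps, spec, "dih_PCCP"), 1L)
  expect_equal(discretize(pi - eps, spec, "dih_PCCP"), 36L)
  expect_equal(discretize(pi, spec, "dih_PCCP"), 36L)    # +pi wraps down
  # gate: any angle with a long virtual bond lands in the extra bin
  expect_equal(discretize(0.3, spec, "dih_PCCP", gate_lengths = 25),
               37L)
  expect_equal(discretize(0.3, spec, "dih_CNNC", gate_lengths = 17.9),
               as.integer(1 + floor((0.3 + pi) / (2 * pi / 36))))
  expect_equal(discretize(NA_real_, spec, "dih_PNNP", gate_lengths = 5),
               37L)
})

test_that("mirror reflection maps content dihedral bins to 37 - b", {
  hp <- fix_hairpin20()
  lab <- geometry_labels(hp$beads)
  labm <- geometry_labels(mirror_structure(hp$beads))
  for (term in c("dih_PCCP", "dih_CNNC", "dih_PNNP")) {
    a <- lab[[term]]; b <- labm[[term]]
    sel <- !is.na(a) & a <= 36 & !is.na(b) & b <= 36
    # reflected bin index (modulo exact boundary hits, none expected here)
    expect_true(mean(b[sel] == 37L - a[sel]) > 0.98)
  }
  # distance labels are mirror-invariant
  expect_equal(lab$dist_PP, labm$dist_PP)
})

test_that("geometry labels stay within each term's bin count", {
  hp <- fix_hairpin20()
  lab <- geometry_labels(hp$beads)
  spec <- geometry_bin_spec()
  for (term in names(lab)) {
    expect_true(all(is.na(diag(lab[[term]]))))
    expect_true(all(lab[[term]][!is.na(lab[[term]])] <=
                      spec[[term]]$n_total))
  }
})
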