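# Model-quality metrics.

test_that("superposition RMSD: identity, rigid copies, grid oracle", {
  hp <- fix_hairpin16()
  expect_equal(p_rmsd(hp$beads, hp$beads), 0, tolerance = 1e-10)
  g <- random_rigid(3, trans_sd = 8)
  expect_lt(p_rmsd(bead_transform(g, hp$beads), hp$beads), 1e-8)
  expect_equal(p_rmsd(hp$beads, bead_transform(g, hp$beads)),
               p_rmsd(bead_transform(g, hp$beads), hp$beads),
               tolerance = 1e-9)
  # 3-point instance against a dense rotation-grid minimum
  set.seed(4)
  a <- matrix(rnorm(9), 3)
  b <- matrix(rnorm(9), 3)
  fit <- superpose_rmsd(a, b)
  step <- 6 * pi / 180
  best <- Inf
  ca <- colMeans(a); cb <- colMeans(b)
  for (ax in seq(-pi, pi, by = step))
    for (ay in seq(-pi / 2, pi / 2, by = step))
      for (az in seq(-pi, pi, by = step)) {
        R <- rnaforge:::rot_z(az) %*% rnaforge:::rot_y(ay) %*%
          rnaforge:::rot_x(ax)
        fitd <- sweep(sweep(a, 2, ca) %*% t(R), 2, cb, "+")
        best <- min(best, sqrt(mean(rowSums((fitd - b)^2))))
      }
  expect_lte(as.numeric(fit), best + 1e-9)
  expect_lt(abs(as.numeric(fit) - best), 0.1)
  expect_error(superpose_rmsd(a, b[1:2, ]), "length mismatch")
})

test_that("TM-score: identity, bounded contribution, symmetry, invariance", {
  hp <- fix_hairpin20()
  expect_equal(tm_score(hp$beads, hp$beads), 1.0, tolerance = 1e-9)
  # one residue displaced to (effective) infinity contributes ~0
  far <- hp$beads
  far$coords[20, , ] <- far$coords[20, , ] + 1e5
  tm_far <- tm_score(far, hp$beads)
  expect_lt(abs(tm_far - 19 / 20), 0.02)
  # symmetry and rigid invariance
  p <- perturb_structure(hp$beads, 3, seed = 5)
  expect_equal(tm_score(p, hp$beads), tm_score(hp$beads, p),
               tolerance = 1e-6)
  g <- random_rigid(6, trans_sd = 12)
  expect_equal(tm_score(bead_transform(g, p), hp$beads),
               tm_score(p, hp$beads), tolerance = 1e-6)
})

test_that("TM-score matches a brute-force superposition search", {
  hp <- fix_hairpin20()
  p <- perturb_structure(hp$beads, 2.5, seed = 9)
  tm <- tm_score(p, hp$beads)
  # oracle: coarse rotation grid, then local refinement of the best cell
  xa <- bead_atom(p, "P"); xb <- bead_atom(hp$beads, "P")
  d0 <- rnaforge:::tm_d0(20)
  ca <- colMeans(xa); cb <- colMeans(xb)
  tm_of <- function(par) {
    R <- rotvec_to_matrix(par[1:3])
    fit <- sweep(sweep(xa, 2, ca) %*% t(R), 2, cb + par[4:6], "+")
    mean(1 / (1 + rowSums((fit - xb)^2) / d0^2))
  }
  best <- -Inf; bestp <- NULL
  for (ax in seq(-pi, pi, length.out = 13))
    for (ay in seq(-pi / 2, pi / 2, length.out = 7))
      for (az in seq(-pi, pi, length.out = 13)) {
        w <- matrix_to_rotvec(rnaforge:::rot_z(az) %*%
                                rnaforge:::rot_y(ay) %*%
                                rnaforge:::rot_x(ax))
        v <- tm_of(c(w, 0, 0, 0))
        if (v > best) { best <- v; bestp <- c(w, 0, 0, 0) }
      }
  ref <- stats::optim(bestp, function(p) -tm_of(p),
                      control = list(maxit = 2000, reltol = 1e-12))
  oracle <- -ref$value
  expect_lt(abs(tm - oracle), 0.005)
})

test_that("INF: perfect, disjoint, and enumerated confusion cases", {
  ref <- interaction_set(wc = list(c(1, 6), c(2, 5)), L = 6)
  expect_equal(inf_score(ref, ref)$inf[1], 1.0)
  # disjoint non-empty sets score <= 0
  pred_dis <- interaction_set(wc = list(c(1, 4), c(3, 6)), L = 6)
  expect_lte(inf_score(ref, pred_dis)$inf[1], 0)
  # brute-force confusion over all C(6,2) pairs
  pred <- interaction_set(wc = list(c(1, 6), c(3, 4)), L = 6)
  out <- inf_score(ref, pred)
  row <- out[out$category == "wc", ]
  univ <- utils::combn(6, 2)
  inref <- function(i, j) (i == 1 & j == 6) | (i == 2 & j == 5)
  inpred <- function(i, j) (i == 1 & j == 6) | (i == 3 & j == 4)
  tp <- fp <- fn <- tn <- 0
  for (k in seq_len(ncol(univ))) {
    i <- univ[1, k]; j <- univ[2, k]
    r <- inref(i, j); p <- inpred(i, j)
    tp <- tp + (r && p); fp <- fp + (!r && p)
    fn <- fn + (r && !p); tn <- tn + (!r && !p)
  }
  expect_equal(unname(c(row$tp, row$fp, row$fn, row$tn)),
               c(tp, fp, fn, tn))
  mcc <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(row$inf, mcc, tolerance = 1e-12)
  # empty reference category reports NA
  expect_true(is.na(out$inf[out$category == "nwc"]))
})

test_that("deformation index arithmetic", {
  expect_equal(di_score(2.0, 1.0), 2.0)
  expect_equal(di_score(2.0, 0.5), 4.0)
  expect_equal(di_score(0, 0.7), 0)
  expect_warning(expect_true(is.na(di_score(2, 0))), "undefined")
})

test_that("handedness separates targets from mirror images", {
  hp <- fix_hairpin16()
  expect_equal(handedness(hp$beads, hp$beads, hp$ss), 1.0)
  expect_equal(handedness(mirror_structure(hp$beads), hp$beads, hp$ss),
               0.0)
  dx <- fix_duplex8()
  expect_equal(handedness(dx$beads, dx$beads, dx$ss), 1.0)
  expect_equal(handedness(mirror_structure(dx$beads), dx$beads, dx$ss),
               0.0)
})

test_that("handedness ties count as not-closer", {
  # flat zig-zag: all C4' pseudotorsions exactly 0 -> tau_target = 0,
  # every comparison is a tie and the score is 0, not NA
  L <- 6
  coords <- array(0, c(L, 3, 3))
  for (i in 1:L) {
    base <- c(i * 3, (i %% 2), 0)
    coords[i, 1, ] <- base + c(0, 0, 1)
    coords[i, 2, ] <- base
    coords[i, 3, ] <- base + c(0, 1, 0)
  }
  s <- bead_structure(coords)
  ss <- secondary_structure(list(c(2, 5), c(3, 4)), L)
  expect_equal(handedness(s, s, ss), 0.0)
})

test_that("clash estimate: clean helix, coincident atoms, 5-clash fixture", {
  dx <- fix_duplex8()
  expect_equal(clash_estimate(dx$full_atom)$n_clashes, 0)
  two <- full_atom_structure(c("C1'", "C1'"), c(1, 2), c("A", "A"),
                             rbind(c(0, 0, 0), c(0.1, 0, 0)))
  expect_gte(clash_estimate(two)$n_clashes, 1)
  # exactly 5 overlapping pairs built by construction: members 2 A
  # apart (C-C overlap 1.4), pairs isolated by 20 A
  n <- 10
  xyz <- matrix(0, n, 3)
  for (k in 1:5) {
    xyz[2 * k - 1, ] <- c(20 * k, 0, 0)
    xyz[2 * k, ] <- c(20 * k + 2, 0, 0)
  }
  fx <- full_atom_structure(rep("C1'", n), 1:n, rep("A", n), xyz)
  est <- clash_estimate(fx)
  expect_equal(est$n_clashes, 5)
  expect_equal(est$per_1000, 5 / n * 1000)
})

test_that("geometric WC detection recovers the reference pairing", {
  hp <- fix_hairpin16()
  det <- detect_wc_pairs(hp$full_atom)
  expect_setequal(vapply(det$wc, paste, character(1), collapse = "-"),
                  vapply(hp$ss$pair_table, paste, character(1),
                         collapse = "-"))
  inf <- inf_score(interaction_set(wc = hp$ss$pair_table, L = 16), det)
  expect_equal(inf$inf[inf$category == "wc"], 1.0)
})

test_that("score_model assembles the metric table", {
  hp <- fix_hairpin16()
  g <- random_rigid(14, trans_sd = 6)
  rigid_copy <- bead_transform(g, hp$beads)
  tab <- score_model(rigid_copy, hp$beads, ss = hp$ss,
                     ref_interactions = interaction_set(
                       wc = hp$ss$pair_table, L = 16),
                     pred_interactions = detect_wc_pairs(
                       reconstruct_full_atom(rigid_copy, hp$sequence,
                                             hp$ss)))
  expect_true(all(c("rmsd_p", "tm_score", "inf_all", "di",
                    "handedness") %in% names(tab)))
  expect_lt(tab$rmsd_p, 1e-6)
  expect_equal(tab$tm_score, 1.0, tolerance = 1e-6)
  expect_equal(tab$inf_all, 1.0)
  expect_equal(tab$handedness, 1.0)
  expect_lt(tab$di, 1e-6)
  # a mildly perturbed model stays within sane metric ranges
  p <- perturb_structure(hp$beads, 1, seed = 3)
  tab2 <- score_model(p, hp$beads, ss = hp$ss)
  expect_lt(tab2$rmsd_p, 1.2)
  expect_true(tab2$tm_score > 0 && tab2$tm_score < 1)
  expect_gte(tab2$handedness, 0.5)
})
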