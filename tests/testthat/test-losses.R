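# Training objectives: FAPE, distance and geometry cross-entropies.

test_that("FAPE of identical frame sets is sqrt(eps) per term", {
  hp <- fix_hairpin16()
  fs <- fix_true_frames()
  expect_equal(fape_loss(fs, fs, hp$sequence), sqrt(1e-3),
               tolerance = 1e-12)
})

test_that("FAPE is invariant to global rigid motion of either side", {
  hp <- fix_hairpin16()
  fs <- fix_true_frames()
  pert <- frames_from_structure(perturb_structure(hp$beads, 2, seed = 4),
                                fix_templates(), hp$sequence)
  base <- fape_loss(pert, fs, hp$sequence)
  for (seed in 1:3) {
    g <- random_rigid(seed, trans_sd = 10)
    expect_equal(fape_loss(frame_set_transform(g, pert), fs, hp$sequence),
                 base, tolerance = 1e-8)
    expect_equal(fape_loss(pert, frame_set_transform(g, fs), hp$sequence),
                 base, tolerance = 1e-8)
  }
})

test_that("FAPE detects reflection of a chiral helix", {
  hp <- fix_hairpin16()
  fs <- fix_true_frames()
  fsm <- frames_from_structure(mirror_structure(hp$beads),
                               fix_templates(), hp$sequence)
  expect_gt(fape_loss(fsm, fs, hp$sequence),
            10 * fape_loss(fs, fs, hp$sequence))
})

test_that("two-residue FAPE equals a hand-enumerated double sum", {
  tmpl <- fix_templates()
  seqc <- c("A", "U")
  mkfs <- function(f1, f2) frame_set(list(f1$R, f2$R), rbind(f1$t, f2$t))
  pred <- mkfs(rigid_frame(rotvec_to_matrix(c(0.2, 0, 0)), c(1, 0, 0)),
               rigid_frame(rotvec_to_matrix(c(0, 0.3, 0)), c(0, 5, 0)))
  true <- mkfs(frame_identity(),
               rigid_frame(diag(3), c(0, 6, 1)))
  d_cut <- 30; eps <- 1e-3
  # brute force over the 2 frames x (2 residues * 3 atoms) terms
  atoms <- rbind(tmpl$A$local_coords, tmpl$U$local_coords)
  res_of <- rep(1:2, each = 3)
  total <- 0
  for (i in 1:2) for (j in 1:6) {
    fp <- frame_set_get(pred, res_of[j]); ft <- frame_set_get(true, res_of[j])
    xg_p <- as.numeric(frame_apply(fp, atoms[j, , drop = FALSE]))
    xg_t <- as.numeric(frame_apply(ft, atoms[j, , drop = FALSE]))
    ip <- frame_set_get(pred, i); it <- frame_set_get(true, i)
    lp <- as.numeric(frame_apply(frame_invert(ip),
                                 matrix(xg_p, 1)))
    lt <- as.numeric(frame_apply(frame_invert(it),
                                 matrix(xg_t, 1)))
    total <- total + min(d_cut, sqrt(sum((lp - lt)^2) + eps))
  }
  expect_equal(fape_loss(pred, true, seqc), total / 12, tolerance = 1e-12)
})

test_that("FAPE clamps at d_cut (saturation)", {
  tmpl <- fix_templates()
  seqc <- c("A", "U")
  true <- frame_set(list(diag(3), diag(3)),
                    rbind(c(0, 0, 0), c(0, 6, 0)))
  far1 <- frame_set(list(diag(3), diag(3)),
                    rbind(c(0, 0, 0), c(500, 6, 0)))
  far2 <- frame_set(list(diag(3), diag(3)),
                    rbind(c(0, 0, 0), c(900, 6, 0)))
  expect_equal(fape_loss(far1, true, seqc), fape_loss(far2, true, seqc),
               tolerance = 1e-12)
})

test_that("FAPE gradient matches finite differences", {
  hp <- fix_hairpin16()
  tmpl <- fix_templates()
  fs <- fix_true_frames()
  ta <- rnaforge:::.template_atoms(hp$sequence, tmpl)
  set.seed(17)
  w0 <- matrix(rnorm(48, 0, 0.4), 16, 3)
  t0 <- fs$t + matrix(rnorm(48, 0, 0.8), 16, 3)
  mkfs <- function(w, t) {
    R <- array(0, c(16, 3, 3))
    for (i in 1:16) R[i, , ] <- rotvec_to_matrix(w[i, ])
    frame_set(R, t)
  }
  en <- function(w, t)
    rnaforge:::fape_core(mkfs(w, t), fs, ta, 30, 1e-3, "mean")$value
  res <- rnaforge:::fape_core(mkfs(w0, t0), fs, ta, 30, 1e-3, "mean",
                              grad = TRUE)
  h <- 1e-6
  for (probe in list(c(1, 2), c(9, 1), c(16, 3))) {
    i <- probe[1]; k <- probe[2]
    gw <- rnaforge:::rotvec_grad(w0[i, ], matrix(res$gR[i, , ], 3, 3))
    wp <- w0; wp[i, k] <- wp[i, k] + h
    wm <- w0; wm[i, k] <- wm[i, k] - h
    fd <- (en(wp, t0) - en(wm, t0)) / (2 * h)
    expect_equal(gw[k], fd, tolerance = 1e-5)
    tp <- t0; tp[i, k] <- tp[i, k] + h
    tm <- t0; tm[i, k] <- tm[i, k] - h
    fd <- (en(w0, tp) - en(w0, tm)) / (2 * h)
    expect_equal(res$gt[i, k], fd, tolerance = 1e-5)
  }
})

test_that("distance cross-entropy matches closed forms and brute force", {
  L <- 3
  dm <- matrix(c(0, 10, 21, 10, 0, 33, 21, 33, 0), 3, 3)
  # one-hot correct prediction: near-zero loss
  lab <- discretize(dm, ndist_bin_spec(), "dist_N38")
  p <- array(1e-13, c(L, L, 38))
  for (i in 1:L) for (j in 1:L) p[i, j, lab[i, j]] <- 1 - 37e-13
  expect_lt(distance_ce(p, dm), 1e-8)
  # uniform prediction: L(L-1) log 38
  pu <- array(1 / 38, c(L, L, 38))
  expect_equal(distance_ce(pu, dm), L * (L - 1) * log(38),
               tolerance = 1e-10)
  # random case vs explicit nested loop
  set.seed(23)
  pr <- array(stats::runif(L * L * 38), c(L, L, 38))
  for (i in 1:L) for (j in 1:L) pr[i, j, ] <- pr[i, j, ] / sum(pr[i, j, ])
  brute <- 0
  for (i in 1:L) for (j in 1:L) {
    if (i == j) next
    for (b in 1:38) brute <- brute -
      (b == lab[i, j]) * log(pr[i, j, b])
  }
  expect_equal(distance_ce(pr, dm), brute, tolerance = 1e-10)
  # non-normalized probabilities are rejected
  expect_error(distance_ce(pr * 1.01, dm), "sum to 1")
})

test_that("geometry cross-entropy weights and brute force agree", {
  hp3 <- bead_structure(fix_hairpin16()$beads$coords[1:3, , , drop = FALSE],
                        sequence = fix_hairpin16()$sequence[1:3])
  labels <- geometry_labels(hp3)
  spec <- geometry_bin_spec()
  set.seed(29)
  pred <- list()
  for (term in names(spec)) {
    B <- spec[[term]]$n_total
    a <- array(stats::runif(3 * 3 * B), c(3, 3, B))
    for (i in 1:3) for (j in 1:3) a[i, j, ] <- a[i, j, ] / sum(a[i, j, ])
    pred[[term]] <- a
  }
  brute <- 0
  for (term in names(spec)) {
    w <- if (startsWith(term, "dist")) 1.0 else 0.5
    for (i in 1:3) for (j in 1:3) {
      if (i == j || is.na(labels[[term]][i, j])) next
      brute <- brute - w * log(pred[[term]][i, j, labels[[term]][i, j]])
    }
  }
  expect_equal(geometry_ce(pred, labels), brute, tolerance = 1e-10)
  # linearity probe: changing only the dihedral tensors moves the total
  # by 0.5 x the change in unweighted dihedral cross-entropy
  unweighted_dih <- function(p) {
    ce <- 0
    for (term in c("dih_PCCP", "dih_CNNC", "dih_PNNP"))
      for (i in 1:3) for (j in 1:3) {
        if (i == j || is.na(labels[[term]][i, j])) next
        ce <- ce - log(p[[term]][i, j, labels[[term]][i, j]])
      }
    ce
  }
  pred2 <- pred
  set.seed(31)
  for (term in c("dih_PCCP", "dih_CNNC", "dih_PNNP")) {
    B <- spec[[term]]$n_total
    a <- array(stats::runif(3 * 3 * B), c(3, 3, B))
    for (i in 1:3) for (j in 1:3) a[i, j, ] <- a[i, j, ] / sum(a[i, j, ])
    pred2[[term]] <- a
  }
  delta_total <- geometry_ce(pred2, labels) - geometry_ce(pred, labels)
  delta_dih <- unweighted_dih(pred2) - unweighted_dih(pred)
  expect_equal(delta_total, 0.5 * delta_dih, tolerance = 1e-10)
  expect_error(geometry_ce(pred[-1], labels), "missing term")
})

test_that("all-correct one-hot geometry prediction gives near-zero loss", {
  hp3 <- bead_structure(fix_hairpin16()$beads$coords[1:3, , , drop = FALSE],
                        sequence = fix_hairpin16()$sequence[1:3])
  labels <- geometry_labels(hp3)
  spec <- geometry_bin_spec()
  pred <- list()
  for (term in names(spec)) {
    B <- spec[[term]]$n_total
    a <- array(1e-13, c(3, 3, B))
    for (i in 1:3) for (j in 1:3) {
      b <- labels[[term]][i, j]
      if (is.na(b)) b <- 1L
      a[i, j, b] <- 1 - (B - 1) * 1e-13
    }
    pred[[term]] <- a
  }
  expect_lt(geometry_ce(pred, labels), 1e-8)
})

test_that("the end-to-end total applies the stated weights", {
  expect_equal(e2e_total(0, 0), 0)
  expect_equal(e2e_total(1, 1), 2.1)
  expect_equal(e2e_total(2, 5), 6.0)
})
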