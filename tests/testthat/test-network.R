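# Embedding, transformer block, structure module, recycling, training.

toy_inputs <- function(L = 6) {
  seqc <- rep(c("A", "U", "G"), length.out = L)
  ss <- secondary_structure(if (L >= 2) list(c(1, L)) else list(), L)
  list(seqc = seqc, ss = ss,
       sf = build_seq_features(seqc),
       pf = build_pair_features(ss, NULL, L))
}

test_that("embedding shapes and locality", {
  m <- rna_model(network_config_toy(), "e2e", seed = 1)
  ti <- toy_inputs(1)
  emb <- network_embed(m, matrix(c(1, 0, 0, 0, 0), 1),
                       array(0, c(1, 1, 4)))
  expect_equal(dim(emb$s), c(1, 16))
  expect_equal(dim(emb$z), c(1, 16))
  # zero inputs: only the positional contributions remain
  L <- 4
  z0 <- network_embed(m, matrix(0, L, 5), array(0, c(L, L, 4)))
  pos <- m$store[["embed.pos"]][1:L, ] +
    matrix(m$store[["embed.seq.b"]], L, 16, byrow = TRUE)
  expect_equal(z0$s, unname(pos + 0), tolerance = 1e-12)
  # inputs differing at one position differ only there (before attention)
  sf1 <- build_seq_features(c("A", "U", "G", "C"))
  sf2 <- build_seq_features(c("A", "U", "A", "C"))
  pf <- array(0, c(4, 4, 4))
  s1 <- network_embed(m, sf1, pf)$s
  s2 <- network_embed(m, sf2, pf)$s
  expect_equal(s1[-3, ], s2[-3, ], tolerance = 1e-12)
  expect_gt(max(abs(s1[3, ] - s2[3, ])), 0)
})

test_that("freshly initialized blocks act as the identity (zero output projections)", {
  m <- rna_model(network_config_toy(), "e2e", seed = 2)
  ti <- toy_inputs(5)
  emb <- network_embed(m, ti$sf, ti$pf)
  blk <- network_transformer_block(m, emb$s, emb$z)
  expect_equal(blk$s, emb$s, tolerance = 1e-12)
  expect_equal(blk$z, emb$z, tolerance = 1e-12)
})

test_that("transformer blocks preserve shapes and stay finite", {
  m <- rna_model(network_config_toy(), "e2e", seed = 3)
  # push the parameters away from the identity initialization
  ti <- toy_inputs(5)
  emb <- network_embed(m, ti$sf, ti$pf)
  invisible(network_transformer_block(m, emb$s, emb$z))
  for (nm in ls(m$store)) {
    if (startsWith(nm, ".")) next
    if (grepl("\\.out\\.w$", nm))
      m$store[[nm]] <- matrix(stats::rnorm(length(m$store[[nm]]), 0, 0.3),
                              nrow(m$store[[nm]]))
  }
  set.seed(7)
  for (draw in 1:100) {
    s <- matrix(rnorm(5 * 16), 5)
    z <- matrix(rnorm(25 * 16), 25)
    out <- network_transformer_block(m, s, z)
    expect_equal(dim(out$s), dim(s))
    expect_equal(dim(out$z), dim(z))
    expect_true(all(is.finite(out$s)) && all(is.finite(out$z)))
  }
})

test_that("structure module outputs valid frames, identity at init", {
  m <- rna_model(network_config_toy(), "e2e", seed = 4)
  ti <- toy_inputs(3)
  emb <- network_embed(m, ti$sf, ti$pf)
  fs <- network_structure_module(m, emb$s, emb$z)
  expect_equal(fs$L, 3)
  for (i in 1:3) {
    Ri <- matrix(fs$R[i, , ], 3, 3)
    expect_equal(det(Ri), 1, tolerance = 1e-6)
    # zero-initialized update head: identity frames out
    expect_equal(Ri, diag(3), tolerance = 1e-9)
    expect_equal(fs$t[i, ], c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("structure module is equivariant to global rigid motions", {
  ti <- toy_inputs(8)
  m <- rna_model(network_config_toy(), "e2e", seed = 5)
  # train briefly so the module performs non-trivial updates
  ref <- build_ideal_helix(ti$seqc, ti$ss$pair_table)
  invisible(train_toy(m, ti$seqc, ti$ss, ref$beads, steps = 10))
  emb <- network_embed(m, ti$sf, ti$pf)
  base <- network_structure_module(m, emb$s, emb$z)
  expect_gt(max(abs(base$t)), 1e-4)     # updates actually moved frames
  g <- random_rigid(6)
  idf <- frame_set(array(rep(diag(3), each = 8), c(8, 3, 3)),
                   matrix(0, 8, 3))
  moved <- network_structure_module(m, emb$s, emb$z,
                                    init_frames = frame_set_transform(g, idf))
  comp <- frame_set_transform(g, base)
  expect_equal(moved$R, comp$R, tolerance = 1e-5)
  expect_equal(moved$t, comp$t, tolerance = 1e-5)
})

test_that("forward with recycling is deterministic and normalized", {
  ti <- toy_inputs(6)
  m1 <- rna_model(network_config_toy(), "e2e", seed = 7)
  m2 <- rna_model(network_config_toy(), "e2e", seed = 7)
  f1 <- model_forward(m1, ti$seqc, ti$ss, n_recycles = 1)
  f2 <- model_forward(m2, ti$seqc, ti$ss, n_recycles = 1)
  expect_identical(f1$frames$t, f2$frames$t)
  expect_identical(f1$dist_probs, f2$dist_probs)
  sums <- apply(f1$dist_probs, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  mg <- rna_model(network_config_toy(), "geometry", seed = 8)
  fg <- model_forward(mg, ti$seqc, ti$ss, n_recycles = 0)
  for (term in GEOMETRY_TERMS) {
    sums <- apply(fg$geo_probs[[term]], c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
  }
  restr <- geometry_probs_to_restraints(fg$geo_probs)
  expect_s3_class(restr, "geometry_restraints")
})

test_that("toy training is deterministic, 0 steps yields one loss", {
  ti <- toy_inputs(6)
  ref <- build_ideal_helix(ti$seqc, ti$ss$pair_table)
  r0 <- train_toy(rna_model(network_config_toy(), "e2e", seed = 9),
                  ti$seqc, ti$ss, ref$beads, steps = 0)
  expect_length(r0$trace, 1)
  ra <- train_toy(rna_model(network_config_toy(), "e2e", seed = 9),
                  ti$seqc, ti$ss, ref$beads, steps = 5)
  rb <- train_toy(rna_model(network_config_toy(), "e2e", seed = 9),
                  ti$seqc, ti$ss, ref$beads, steps = 5)
  expect_identical(ra$trace, rb$trace)
  expect_lt(ra$final_loss, ra$trace[1])
})

test_that("geometry-mode training reduces the geometry cross-entropy", {
  ti <- toy_inputs(6)
  ref <- build_ideal_helix(ti$seqc, ti$ss$pair_table)
  m <- rna_model(network_config_toy(), "geometry", seed = 10)
  res <- train_toy(m, ti$seqc, ti$ss, ref$beads, steps = 150)
  expect_lt(res$final_loss, 0.5 * res$trace[1])
})

test_that("model checkpoints round-trip through the archive", {
  ti <- toy_inputs(4)
  m <- rna_model(network_config_toy(), "e2e", seed = 11)
  f1 <- model_forward(m, ti$seqc, ti$ss, n_recycles = 0)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  f2 <- model_forward(m2, ti$seqc, ti$ss, n_recycles = 0)
  expect_equal(f1$frames$t, f2$frames$t, tolerance = 1e-12)
  expect_equal(f1$s, f2$s, tolerance = 1e-12)
})
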