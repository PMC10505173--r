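# Configurable-scale RNA transformer and IPA structure module.  The
# architecture follows the two-track (sequence + pair) transformer with
# triangle updates, an invariant-point-attention structure module
# operating on per-residue rigid frames, recycling, and either an
# end-to-end head (frames + inter-N distance map) or a geometry head
# (six binned probability tensors).  Differentiation runs on the tape
# engine in autodiff.R; full-scale training is out of scope, but the toy
# preset trains in seconds per step on one CPU.

#' Network configuration
#'
#' Defaults are the full-scale hyperparameters; use
#' [network_config_toy()] for a configuration that trains on one CPU in
#' seconds for L <= 40.
#'
#' @param n_blocks transformer blocks.
#' @param d_s,d_z sequence / pair channel sizes.
#' @param seq_heads,seq_head_dim sequence-attention heads and head size.
#' @param transition_mult expansion factor of the transition layers.
#' @param opm_dim outer-product-mean projection size.
#' @param tri_mult_dim triangle-multiplicative hidden channels.
#' @param tri_att_heads,tri_att_dim triangle-attention heads and size.
#' @param sm_d_s,sm_d_z structure-module sequence / pair channels.
#' @param ipa_heads,ipa_dim,ipa_qpoints,ipa_vpoints IPA hyperparameters.
#' @param sm_iters structure-module iterations.
#' @param recycles recycling passes beyond the first.
#' @param max_len largest supported length (positional embedding rows).
#' @param relpos_clip relative-position clipping for the 2-D encoding.
#' @param double_starting_node if TRUE both triangle-attention blocks
#'   use the starting-node orientation (as printed in the architecture
#'   listing); FALSE uses starting + ending node.
#' @return Named list of settings.
#' @export
network_config <- function(n_blocks = 48L, d_s = 64L, d_z = 64L,
                           seq_heads = 8L, seq_head_dim = 8L,
                           transition_mult = 2L, opm_dim = 12L,
                           tri_mult_dim = 32L, tri_att_heads = 4L,
                           tri_att_dim = 8L, sm_d_s = 128L, sm_d_z = 64L,
                           ipa_heads = 8L, ipa_dim = 16L,
                           ipa_qpoints = 4L, ipa_vpoints = 6L,
                           sm_iters = 5L, recycles = 3L, max_len = 256L,
                           relpos_clip = 32L,
                           double_starting_node = TRUE) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[!(names(cfg) %in% "double_starting_node")],
                       function(x) x > 0, logical(1))))
  cfg
}

#' Toy network preset (CPU-scale tests)
#' @param ... overrides passed to [network_config()].
#' @return A [network_config()] list.
#' @export
network_config_toy <- function(...) {
  args <- list(n_blocks = 2L, d_s = 16L, d_z = 16L, seq_heads = 4L,
               seq_head_dim = 4L, opm_dim = 4L, tri_mult_dim = 8L,
               tri_att_heads = 2L, tri_att_dim = 4L, sm_d_s = 16L,
               sm_d_z = 16L, ipa_heads = 4L, ipa_dim = 8L,
               ipa_qpoints = 2L, ipa_vpoints = 3L, recycles = 1L,
               max_len = 64L)
  do.call(network_config, utils::modifyList(args, list(...)))
}

#' Create a network model
#'
#' Parameters are initialized lazily, deterministically from the seed,
#' on the first forward pass: weights N(0, 1/sqrt(fan_in)), gating
#' biases +1, and every residual-output projection zero so each block
#' starts as the identity.
#'
#' @param cfg a [network_config()].
#' @param mode "e2e" (frames + inter-N distance head) or "geometry"
#'   (six binned probability heads).
#' @param seed integer seed for parameter initialization.
#' @return Object of class `rna_model`.
#' @export
rna_model <- function(cfg = network_config_toy(), mode = c("e2e", "geometry"),
                      seed = 1L) {
  mode <- match.arg(mode)
  store <- new.env(parent = emptyenv())
  store$.rng <- as.integer(seed)
  structure(list(cfg = cfg, mode = mode, seed = as.integer(seed),
                 store = store),
            class = "rna_model")
}

#' @export
print.rna_model <- function(x, ...) {
  np <- sum(vapply(ls(x$store), function(nm)
    if (startsWith(nm, ".")) 0L else length(x$store[[nm]]), integer(1)))
  cat("<rna_model>", x$mode, "mode,", x$cfg$n_blocks, "blocks,",
      np, "parameters\n")
  invisible(x)
}

# deterministic lazy parameter access
.get_par <- function(store, name, nr, nc, init = c("fan", "zero", "one")) {
  init <- match.arg(init)
  if (is.null(store[[name]])) {
    store[[name]] <- switch(init,
      zero = matrix(0, nr, nc),
      one = matrix(1, nr, nc),
      fan = with_seed(store$.rng, matrix(stats::rnorm(nr * nc, 0,
                                                      1 / sqrt(nr)), nr, nc)))
    store$.rng <- store$.rng + 1L
  }
  store[[name]]
}

# linear layer node: x %*% W + b
.lin <- function(tp, store, x, name, nin, nout, init = "fan",
                 bias_init = "zero") {
  W <- ad_param(tp, store, {.get_par(store, paste0(name, ".w"), nin, nout,
                                     init); paste0(name, ".w")})
  b <- ad_param(tp, store, {.get_par(store, paste0(name, ".b"), 1, nout,
                                     bias_init); paste0(name, ".b")})
  ad_addbias(tp, ad_matmul(tp, x, W), b)
}

.ln <- function(tp, store, x, name, d) {
  g <- ad_param(tp, store, {.get_par(store, paste0(name, ".g"), 1, d, "one")
                            paste0(name, ".g")})
  b <- ad_param(tp, store, {.get_par(store, paste0(name, ".b"), 1, d, "zero")
                            paste0(name, ".b")})
  ad_layernorm(tp, x, g, b)
}

# ---- embedding ------------------------------------------------------------

.relpos_onehot <- function(L, clip) {
  ii <- rep(seq_len(L), each = L); jj <- rep(seq_len(L), times = L)
  d <- pmin(pmax(jj - ii, -clip), clip) + clip + 1L
  m <- matrix(0, L * L, 2L * clip + 1L)
  m[cbind(seq_len(L * L), d)] <- 1
  m
}

.embed_forward <- function(tp, store, cfg, seq_feat, pair_feat, L,
                           prev = NULL) {
  sf <- ad_const(tp, seq_feat)
  pf <- ad_const(tp, pair_feat)
  s <- .lin(tp, store, sf, "embed.seq", 5L, cfg$d_s)
  pos <- ad_param(tp, store, {.get_par(store, "embed.pos", cfg$max_len,
                                       cfg$d_s); "embed.pos"})
  s <- ad_add(tp, s, ad_rows(tp, pos, seq_len(L)))
  ii <- rep(seq_len(L), each = L); jj <- rep(seq_len(L), times = L)
  zl <- .lin(tp, store, sf, "embed.left", 5L, cfg$d_z)
  zr <- .lin(tp, store, sf, "embed.right", 5L, cfg$d_z)
  z <- ad_add(tp, ad_rows(tp, zl, ii), ad_rows(tp, zr, jj))
  z <- ad_add(tp, z, .lin(tp, store, pf, "embed.pair", 4L, cfg$d_z))
  rp <- ad_const(tp, .relpos_onehot(L, cfg$relpos_clip))
  z <- ad_add(tp, z, .lin(tp, store, rp, "embed.relpos",
                          2L * cfg$relpos_clip + 1L, cfg$d_z))
  if (!is.null(prev)) {
    ps <- .ln(tp, store, ad_const(tp, prev$s), "recycle.s_ln", cfg$d_s)
    pz <- .ln(tp, store, ad_const(tp, prev$z), "recycle.z_ln", cfg$d_z)
    s <- ad_add(tp, s, ps)
    z <- ad_add(tp, z, pz)
    if (!is.null(prev$dist_onehot))
      z <- ad_add(tp, z, .lin(tp, store, ad_const(tp, prev$dist_onehot),
                              "recycle.dist", 38L, cfg$d_z, init = "zero"))
  }
  list(s = s, z = z)
}

# ---- transformer block ----------------------------------------------------

.seq_attention <- function(tp, store, cfg, s, z, L, pre) {
  h <- cfg$seq_heads; c <- cfg$seq_head_dim; d <- cfg$d_s
  sln <- .ln(tp, store, s, paste0(pre, ".ln_s"), d)
  zln <- .ln(tp, store, z, paste0(pre, ".ln_z"), cfg$d_z)
  Q <- ad_split_heads(tp, .lin(tp, store, sln, paste0(pre, ".q"), d, h * c), h)
  K <- ad_split_heads(tp, .lin(tp, store, sln, paste0(pre, ".k"), d, h * c), h)
  V <- ad_split_heads(tp, .lin(tp, store, sln, paste0(pre, ".v"), d, h * c), h)
  bias_cols <- .lin(tp, store, zln, paste0(pre, ".bias"), cfg$d_z, h)
  bias <- ad_rbind(tp, lapply(seq_len(h), function(k)
    ad_vec2mat(tp, ad_cols(tp, bias_cols, k), L)))
  att <- ad_batched_attention(tp, Q, K, V, bias, nb = h,
                              scale = 1 / sqrt(c))
  gate <- ad_split_heads(tp, ad_sigmoid(tp,
    .lin(tp, store, sln, paste0(pre, ".gate"), d, h * c,
         bias_init = "one")), h)
  out <- ad_merge_heads(tp, ad_mul(tp, att, gate), h)
  .lin(tp, store, out, paste0(pre, ".out"), h * c, d, init = "zero")
}

.transition <- function(tp, store, x, d, mult, pre) {
  xln <- .ln(tp, store, x, paste0(pre, ".ln"), d)
  hdim <- d * mult
  .lin(tp, store, ad_relu(tp, .lin(tp, store, xln, paste0(pre, ".1"),
                                   d, hdim)),
       paste0(pre, ".2"), hdim, d, init = "zero")
}

.opm <- function(tp, store, cfg, s, pre) {
  sln <- .ln(tp, store, s, paste0(pre, ".ln"), cfg$d_s)
  a <- .lin(tp, store, sln, paste0(pre, ".a"), cfg$d_s, cfg$opm_dim)
  b <- .lin(tp, store, sln, paste0(pre, ".b"), cfg$d_s, cfg$opm_dim)
  o <- ad_pairouter(tp, a, b)
  .lin(tp, store, o, paste0(pre, ".out"), cfg$opm_dim^2, cfg$d_z,
       init = "zero")
}

.tri_mult <- function(tp, store, cfg, z, L, pre, direction) {
  dz <- cfg$d_z; C <- cfg$tri_mult_dim
  zln <- .ln(tp, store, z, paste0(pre, ".ln"), dz)
  a <- ad_mul(tp,
              ad_sigmoid(tp, .lin(tp, store, zln, paste0(pre, ".ag"), dz, C,
                                  bias_init = "one")),
              .lin(tp, store, zln, paste0(pre, ".a"), dz, C))
  b <- ad_mul(tp,
              ad_sigmoid(tp, .lin(tp, store, zln, paste0(pre, ".bg"), dz, C,
                                  bias_init = "one")),
              .lin(tp, store, zln, paste0(pre, ".b"), dz, C))
  x <- ad_trimul(tp, a, b, L, direction)
  xln <- .ln(tp, store, x, paste0(pre, ".ln_out"), C)
  g <- ad_sigmoid(tp, .lin(tp, store, zln, paste0(pre, ".g"), dz, dz,
                           bias_init = "one"))
  ad_mul(tp, g, .lin(tp, store, xln, paste0(pre, ".out"), C, dz,
                     init = "zero"))
}

.tri_attention <- function(tp, store, cfg, z, L, pre, node = "starting") {
  dz <- cfg$d_z; h <- cfg$tri_att_heads; c <- cfg$tri_att_dim
  zin <- if (node == "ending") ad_transpose_pair(tp, z, L) else z
  zln <- .ln(tp, store, zin, paste0(pre, ".ln"), dz)
  Q <- ad_split_heads(tp, .lin(tp, store, zln, paste0(pre, ".q"),
                               dz, h * c), h)
  K <- ad_split_heads(tp, .lin(tp, store, zln, paste0(pre, ".k"),
                               dz, h * c), h)
  V <- ad_split_heads(tp, .lin(tp, store, zln, paste0(pre, ".v"),
                               dz, h * c), h)
  bias_cols <- .lin(tp, store, zln, paste0(pre, ".bias"), dz, h)
  bias <- ad_rbind(tp, lapply(seq_len(h), function(k)
    ad_tile_rows(tp, ad_vec2mat(tp, ad_cols(tp, bias_cols, k), L), L)))
  att <- ad_batched_attention(tp, Q, K, V, bias, nb = h * L,
                              scale = 1 / sqrt(c))
  gate <- ad_split_heads(tp, ad_sigmoid(tp,
    .lin(tp, store, zln, paste0(pre, ".gate"), dz, h * c,
         bias_init = "one")), h)
  out <- ad_merge_heads(tp, ad_mul(tp, att, gate), h)
  out <- .lin(tp, store, out, paste0(pre, ".out"), h * c, dz,
              init = "zero")
  if (node == "ending") ad_transpose_pair(tp, out, L) else out
}

.transformer_block <- function(tp, store, cfg, s, z, L, pre) {
  s <- ad_add(tp, s, .seq_attention(tp, store, cfg, s, z, L,
                                    paste0(pre, ".att")))
  s <- ad_add(tp, s, .transition(tp, store, s, cfg$d_s,
                                 cfg$transition_mult, paste0(pre, ".st")))
  z <- ad_add(tp, z, .opm(tp, store, cfg, s, paste0(pre, ".opm")))
  z <- ad_add(tp, z, .tri_mult(tp, store, cfg, z, L, paste0(pre, ".tmo"),
                               "outgoing"))
  z <- ad_add(tp, z, .tri_mult(tp, store, cfg, z, L, paste0(pre, ".tmi"),
                               "incoming"))
  z <- ad_add(tp, z, .tri_attention(tp, store, cfg, z, L,
                                    paste0(pre, ".tas"), "starting"))
  second <- if (cfg$double_starting_node) "starting" else "ending"
  z <- ad_add(tp, z, .tri_attention(tp, store, cfg, z, L,
                                    paste0(pre, ".tas2"), second))
  z <- ad_add(tp, z, .transition(tp, store, z, cfg$d_z,
                                 cfg$transition_mult, paste0(pre, ".pt")))
  list(s = s, z = z)
}

# ---- invariant point attention + structure module ------------------------

.ipa <- function(tp, store, cfg, s, zs, Rn, tn, L, pre) {
  h <- cfg$ipa_heads; c <- cfg$ipa_dim
  nqp <- cfg$ipa_qpoints; npv <- cfg$ipa_vpoints
  ds <- cfg$sm_d_s; dz <- cfg$sm_d_z
  wC <- sqrt(2 / (9 * nqp)); wL <- sqrt(1 / 3)
  outs <- list()
  for (k in seq_len(h)) {
    hp <- paste0(pre, ".h", k)
    q <- .lin(tp, store, s, paste0(hp, ".q"), ds, c)
    kk <- .lin(tp, store, s, paste0(hp, ".k"), ds, c)
    v <- .lin(tp, store, s, paste0(hp, ".v"), ds, c)
    qp <- .lin(tp, store, s, paste0(hp, ".qp"), ds, 3L * nqp)
    kp <- .lin(tp, store, s, paste0(hp, ".kp"), ds, 3L * nqp)
    qpg <- ad_add_trans(tp, ad_rotate_points(tp, Rn, qp), tn, nqp)
    kpg <- ad_add_trans(tp, ad_rotate_points(tp, Rn, kp), tn, nqp)
    sqd <- ad_pair_sqdist(tp, qpg, kpg, nqp)
    bias <- ad_vec2mat(tp, .lin(tp, store, zs, paste0(hp, ".bias"),
                                dz, 1L), L)
    gamma <- ad_softplus(tp, ad_param(tp, store,
      {.get_par(store, paste0(hp, ".gamma"), 1, 1, "one")
       paste0(hp, ".gamma")}))
    logits <- ad_scale(tp, ad_matmul(tp, q, ad_node(tp, t(kk$val), list(kk),
      function(g) list(t(g)))), 1 / sqrt(c))
    logits <- ad_add(tp, logits, bias)
    logits <- ad_sub(tp, logits,
                     ad_scale_by(tp, ad_scale(tp, sqd, wC / 2), gamma))
    P <- ad_softmax_rows(tp, ad_scale(tp, logits, wL))
    o1 <- ad_matmul(tp, P, v)
    vp <- .lin(tp, store, s, paste0(hp, ".vp"), ds, 3L * npv)
    vpg <- ad_add_trans(tp, ad_rotate_points(tp, Rn, vp), tn, npv)
    og <- ad_matmul(tp, P, vpg)
    ol <- ad_rotate_points(tp, Rn,
                           ad_add_trans(tp, og, tn, npv, subtract = TRUE),
                           inverse = TRUE)
    onorm <- ad_point_norms(tp, ol, npv)
    opair <- ad_pair_readout(tp, P, zs, L)
    outs[[k]] <- ad_cbind(tp, list(o1, ol, onorm, opair))
  }
  width <- h * (c + 3L * npv + npv + cfg$sm_d_z)
  .lin(tp, store, ad_cbind(tp, outs), paste0(pre, ".out"), width, ds,
       init = "zero")
}

.structure_module <- function(tp, store, cfg, s_trunk, z_trunk, L,
                              init_frames = NULL) {
  s <- .lin(tp, store, .ln(tp, store, s_trunk, "sm.ln_s", cfg$d_s),
            "sm.proj_s", cfg$d_s, cfg$sm_d_s)
  zs <- .lin(tp, store, .ln(tp, store, z_trunk, "sm.ln_z", cfg$d_z),
             "sm.proj_z", cfg$d_z, cfg$sm_d_z)
  if (is.null(init_frames)) {
    R0 <- matrix(rep(as.numeric(diag(3)), each = L), L, 9)
    t0 <- matrix(0, L, 3)
  } else {
    R0 <- t(vapply(seq_len(L), function(i)
      as.numeric(init_frames$R[i, , ]), numeric(9)))
    t0 <- init_frames$t
  }
  Rn <- ad_const(tp, R0); tn <- ad_const(tp, t0)
  for (it in seq_len(cfg$sm_iters)) {
    s <- ad_add(tp, s, .ipa(tp, store, cfg, s, zs, Rn, tn, L, "sm.ipa"))
    s <- .ln(tp, store, s, "sm.ln_ipa", cfg$sm_d_s)
    s <- ad_add(tp, s, .transition(tp, store, s, cfg$sm_d_s, 2L, "sm.tr"))
    s <- .ln(tp, store, s, "sm.ln_tr", cfg$sm_d_s)
    upd <- .lin(tp, store, s, "sm.update", cfg$sm_d_s, 6L, init = "zero")
    dR <- ad_quat_to_rot(tp, ad_cols(tp, upd, 1:3))
    dt <- ad_cols(tp, upd, 4:6)
    tn <- ad_add(tp, tn, ad_rotate_points(tp, Rn, dt))
    Rn <- ad_rot_compose(tp, Rn, dR)
  }
  list(Rn = Rn, tn = tn, s = s, zs = zs)
}

# frame_set from (L x 9, L x 3) values, with orthogonality re-projection
# (quaternion composition keeps rotations exact up to roundoff)
.frames_from_nodes <- function(Rv, tv) {
  L <- nrow(Rv)
  R <- array(0, c(L, 3, 3))
  for (i in seq_len(L)) {
    M <- matrix(Rv[i, ], 3, 3)
    sv <- svd(M)
    R[i, , ] <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*%
      t(sv$v)
  }
  frame_set(R, tv)
}

# ---- losses as tape nodes -------------------------------------------------

# FAPE between tape frames and a fixed true frame set
ad_fape <- function(tape, Rn, tn, true_fs, tmpl_atoms, d_cut, eps,
                    reduce = "mean") {
  L <- nrow(Rn$val)
  conf <- .frames_from_nodes_raw(Rn$val, tn$val)
  res <- fape_core(conf, true_fs, tmpl_atoms, d_cut, eps, reduce,
                   grad = TRUE)
  gRm <- matrix(0, L, 9)
  for (r in 1:3) for (c in 1:3) gRm[, .rc(r, c)] <- res$gR[, r, c]
  ad_node(tape, matrix(res$value, 1, 1), list(Rn, tn), function(g) {
    gg <- as.numeric(g)
    list(gRm * gg, res$gt * gg)
  })
}

# frame_set without re-orthogonalization (tape rotations are exact
# quaternion products; validation tolerance suffices)
.frames_from_nodes_raw <- function(Rv, tv) {
  L <- nrow(Rv)
  R <- array(0, c(L, 3, 3))
  for (i in seq_len(L)) R[i, , ] <- matrix(Rv[i, ], 3, 3)
  frame_set(R, tv)
}

# softmax cross-entropy over rows with integer labels (NA rows skipped)
ad_softmax_ce <- function(tape, logits, labels) {
  x <- logits$val
  ok <- which(!is.na(labels))
  m <- apply(x, 1, max)
  e <- exp(x - m)
  p <- e / rowSums(e)
  ll <- log(pmax(p[cbind(ok, labels[ok])], 1e-12))
  val <- -sum(ll)
  ad_node(tape, matrix(val, 1, 1), list(logits), function(g) {
    gg <- as.numeric(g)
    dx <- matrix(0, nrow(x), ncol(x))
    dx[ok, ] <- p[ok, , drop = FALSE]
    dx[cbind(ok, labels[ok])] <- dx[cbind(ok, labels[ok])] - 1
    list(dx * gg)
  })
}

# ---- full forward pass ----------------------------------------------------

# pair-feature tensor (L x L x 4) -> L^2 x 4 matrix, rows i-major
.pair_feat_matrix <- function(arr) {
  L <- dim(arr)[1]
  out <- matrix(0, L * L, dim(arr)[3])
  for (c in seq_len(dim(arr)[3])) out[, c] <- as.numeric(t(arr[, , c]))
  out
}

.forward_cycle <- function(tp, store, cfg, mode, seq_feat, pair_feat, L,
                           prev = NULL, init_frames = NULL) {
  emb <- .embed_forward(tp, store, cfg, seq_feat, pair_feat, L, prev)
  s <- emb$s; z <- emb$z
  for (b in seq_len(cfg$n_blocks)) {
    r <- .transformer_block(tp, store, cfg, s, z, L, paste0("tb", b))
    s <- r$s; z <- r$z
  }
  out <- list(s = s, z = z)
  if (mode == "e2e") {
    sm <- .structure_module(tp, store, cfg, s, z, L, init_frames)
    out$Rn <- sm$Rn; out$tn <- sm$tn
    out$dist_logits <- .lin(tp, store,
                            .ln(tp, store, z, "head.dist_ln", cfg$d_z),
                            "head.dist", cfg$d_z, 38L, init = "zero")
  } else {
    zln <- .ln(tp, store, z, "head.geo_ln", cfg$d_z)
    spec <- geometry_bin_spec()
    out$geo_logits <- list()
    for (term in GEOMETRY_TERMS)
      out$geo_logits[[term]] <- .lin(tp, store, zln,
                                     paste0("head.", term), cfg$d_z,
                                     spec[[term]]$n_total, init = "zero")
  }
  out
}

# binned one-hot N-N distance map of the previous cycle's structure
.prev_dist_onehot <- function(Rv, tv, sequence, templates) {
  L <- nrow(Rv)
  rN <- t(vapply(sequence, function(b)
    templates[[b]]$local_coords[3, ], numeric(3)))
  Npos <- matrix(0, L, 3)
  for (i in seq_len(L))
    Npos[i, ] <- as.numeric(matrix(Rv[i, ], 3, 3) %*% rN[i, ]) + tv[i, ]
  q <- rowSums(Npos^2)
  d <- sqrt(pmax(outer(q, q, "+") - 2 * Npos %*% t(Npos), 0))
  lab <- discretize(d, ndist_bin_spec(), "dist_N38")
  oh <- matrix(0, L * L, 38L)
  oh[cbind(seq_len(L * L), as.numeric(t(lab)))] <- 1
  oh
}

#' Run the network forward with recycling
#'
#' Executes `n_recycles + 1` passes; all but the last run without
#' gradient bookkeeping and feed their sequence/pair representations
#' (and, in e2e mode, the binned inter-N distance map of the predicted
#' structure) into the next pass.
#'
#' @param model An `rna_model`.
#' @param sequence `nt_sequence` or character vector.
#' @param ss_a,ss_b secondary-structure sources (`secondary_structure`);
#'   `ss_b` defaults to duplicating `ss_a`.
#' @param n_recycles recycling passes beyond the first (default from the
#'   model config).
#' @param init_frames optional `frame_set` initializing the structure
#'   module (defaults to identity frames).
#' @return In e2e mode: list with `frames` (`frame_set`), `beads`
#'   (`bead_structure`), `dist_probs` (L x L x 38) and representation
#'   values.  In geometry mode: list with `geo_probs` (named list of
#'   L x L x bins probability arrays) and representations.
#' @export
model_forward <- function(model, sequence, ss_a, ss_b = NULL,
                          n_recycles = NULL, init_frames = NULL) {
  cfg <- model$cfg
  sequence <- as.character(nt_sequence(sequence))
  L <- length(sequence)
  if (L > cfg$max_len) stop("model_forward: L exceeds config max_len")
  if (is.null(n_recycles)) n_recycles <- cfg$recycles
  seq_feat <- build_seq_features(sequence)
  pair_feat <- .pair_feat_matrix(build_pair_features(ss_a, ss_b, L))
  templates <- derive_templates()
  prev <- NULL
  for (cyc in seq_len(n_recycles + 1L)) {
    tp <- ad_tape()
    out <- .forward_cycle(tp, model$store, cfg, model$mode, seq_feat,
                          pair_feat, L, prev, init_frames)
    if (cyc <= n_recycles) {
      prev <- list(s = out$s$val, z = out$z$val)
      if (model$mode == "e2e")
        prev$dist_onehot <- .prev_dist_onehot(out$Rn$val, out$tn$val,
                                              sequence, templates)
    }
  }
  res <- list(s = out$s$val, z = out$z$val, tape = tp, out = out,
              sequence = sequence)
  if (model$mode == "e2e") {
    res$frames <- .frames_from_nodes(out$Rn$val, out$tn$val)
    res$beads <- beads_from_frames(res$frames, sequence, templates)
    res$dist_probs <- .softmax_to_array(out$dist_logits$val, L, 38L)
  } else {
    spec <- geometry_bin_spec()
    res$geo_probs <- lapply(GEOMETRY_TERMS, function(term)
      .softmax_to_array(out$geo_logits[[term]]$val, L,
                        spec[[term]]$n_total))
    names(res$geo_probs) <- GEOMETRY_TERMS
  }
  res
}

.softmax_to_array <- function(logits, L, B) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  arr <- array(0, c(L, L, B))
  for (b in seq_len(B)) arr[, , b] <- matrix(p[, b], L, L, byrow = TRUE)
  arr
}

#' Convert geometry-mode probabilities into restraints
#'
#' Symmetrizes each term over (i, j) (the mean of the two ordered
#' slices, itself a probability vector).
#'
#' @param geo_probs named list of L x L x bins arrays, as returned by
#'   [model_forward()] in geometry mode.
#' @return A `geometry_restraints`.
#' @export
geometry_probs_to_restraints <- function(geo_probs) {
  sym <- lapply(geo_probs, function(a) (a + aperm(a, c(2, 1, 3))) / 2)
  geometry_restraints(sym)
}

# ---- public single-piece wrappers (tests, inspection) --------------------

#' Embed input features (value-level)
#' @param model An `rna_model`.
#' @param seq_feature L x 5 one-hot matrix.
#' @param pair_feature L x L x 4 array (or L^2 x 4 matrix).
#' @return List with `s` (L x d_s) and `z` (L^2 x d_z, rows i-major).
#' @export
network_embed <- function(model, seq_feature, pair_feature) {
  if (length(dim(pair_feature)) == 3L)
    pair_feature <- .pair_feat_matrix(pair_feature)
  L <- nrow(seq_feature)
  tp <- ad_tape()
  emb <- .embed_forward(tp, model$store, model$cfg, seq_feature,
                        pair_feature, L)
  list(s = emb$s$val, z = emb$z$val)
}

#' Apply one transformer block (value-level)
#' @param model An `rna_model`.
#' @param s L x d_s matrix.
#' @param z L^2 x d_z matrix (rows i-major).
#' @param block block index (selects that block's parameters).
#' @return List with updated `s` and `z`.
#' @export
network_transformer_block <- function(model, s, z, block = 1L) {
  L <- nrow(s)
  tp <- ad_tape()
  r <- .transformer_block(tp, model$store, model$cfg, ad_const(tp, s),
                          ad_const(tp, z), L, paste0("tb", block))
  list(s = r$s$val, z = r$z$val)
}

#' Run the structure module (value-level)
#' @param model An `rna_model`.
#' @param s L x d_s matrix.
#' @param z L^2 x d_z matrix.
#' @param init_frames optional starting `frame_set`.
#' @return A `frame_set`.
#' @export
network_structure_module <- function(model, s, z, init_frames = NULL) {
  L <- nrow(s)
  tp <- ad_tape()
  sm <- .structure_module(tp, model$store, model$cfg, ad_const(tp, s),
                          ad_const(tp, z), L, init_frames)
  .frames_from_nodes(sm$Rn$val, sm$tn$val)
}

# ---- toy training ---------------------------------------------------------

.adam_state <- function() new.env(parent = emptyenv())

.adam_step <- function(store, grads, state, lr, step, b1 = 0.9,
                       b2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state[[nm]])) state[[nm]] <- list(m = g * 0, v = g * 0)
    st <- state[[nm]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    state[[nm]] <- st
    mhat <- st$m / (1 - b1^step)
    vhat <- st$v / (1 - b2^step)
    store[[nm]] <- store[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
}

#' Overfit the toy network on one structure
#'
#' Optimizes the end-to-end loss (1.5 FAPE + 0.6 inter-N distance
#' cross-entropy) or the geometry cross-entropy with Adam at the stated
#' initial learning rate (1e-3), full batch on a single RNA.
#' Deterministic given the model seed (parameter init) and inputs.
#'
#' @param model An `rna_model` (toy config recommended; L <= 40).
#' @param sequence character base types.
#' @param ss reference `secondary_structure` (network input features).
#' @param target a `bead_structure` reference (supervision).
#' @param steps optimizer steps (0 returns the initial loss only).
#' @param lr Adam learning rate.
#' @param n_recycles recycling passes during training (gradients flow
#'   through the final pass only).
#' @return List with `model`, `trace` (loss per step, length steps + 1,
#'   the first entry being the initial loss) and `final_loss`.
#' @export
train_toy <- function(model, sequence, ss, target, steps = 500L,
                      lr = 1e-3, n_recycles = 0L) {
  cfg <- model$cfg
  sequence <- as.character(nt_sequence(sequence))
  L <- length(sequence)
  stopifnot(L <= 40L)
  seq_feat <- build_seq_features(sequence)
  pair_feat <- .pair_feat_matrix(build_pair_features(ss, NULL, L))
  templates <- derive_templates()
  lcfg <- loss_config()
  if (model$mode == "e2e") {
    true_fs <- frames_from_structure(target, templates, sequence)
    ta <- .template_atoms(sequence, templates)
    dN <- pairwise_distances(target, "N")
    dlab <- discretize(dN, ndist_bin_spec(), "dist_N38")
    diag(dlab) <- NA_integer_
    dlab_vec <- as.integer(t(dlab))            # i-major rows
  } else {
    glab <- geometry_labels(target)
    glab_vec <- lapply(glab, function(m) as.integer(t(m)))
  }
  state <- .adam_state()
  trace <- numeric(0)
  for (step in 0:steps) {
    prev <- NULL
    for (cyc in seq_len(n_recycles)) {
      tp0 <- ad_tape()
      o0 <- .forward_cycle(tp0, model$store, cfg, model$mode, seq_feat,
                           pair_feat, L, prev)
      prev <- list(s = o0$s$val, z = o0$z$val)
      if (model$mode == "e2e")
        prev$dist_onehot <- .prev_dist_onehot(o0$Rn$val, o0$tn$val,
                                              sequence, templates)
    }
    tp <- ad_tape()
    out <- .forward_cycle(tp, model$store, cfg, model$mode, seq_feat,
                          pair_feat, L, prev)
    if (model$mode == "e2e") {
      fape_nd <- ad_fape(tp, out$Rn, out$tn, true_fs, ta, lcfg$d_cut,
                         lcfg$epsilon)
      ce_nd <- ad_softmax_ce(tp, out$dist_logits, dlab_vec)
      loss <- ad_add(tp, ad_scale(tp, fape_nd, lcfg$fape_weight),
                     ad_scale(tp, ce_nd, lcfg$dist_weight))
    } else {
      loss <- NULL
      for (term in GEOMETRY_TERMS) {
        w <- if (startsWith(term, "dist")) lcfg$w_distance
             else lcfg$w_dihedral
        nd <- ad_scale(tp, ad_softmax_ce(tp, out$geo_logits[[term]],
                                         glab_vec[[term]]), w)
        loss <- if (is.null(loss)) nd else ad_add(tp, loss, nd)
      }
    }
    lv <- as.numeric(loss$val)
    if (!is.finite(lv))
      stop("train_toy: non-finite loss at step ", step)
    trace <- c(trace, lv)
    if (step == steps) break
    ad_backward(tp, loss)
    .adam_step(model$store, ad_param_grads(tp, model$store), state, lr,
               step + 1)
  }
  list(model = model, trace = trace, final_loss = trace[length(trace)])
}
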