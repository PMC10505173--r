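# Minimal reverse-mode automatic differentiation on a tape of matrix
# operations.  Every value is a base-R numeric matrix; nodes are
# environments carrying the value, parent links and a backward closure.
# This is deliberately small: just the operations the RNA transformer /
# IPA network needs, each with an analytic backward rule exercised by
# finite-difference tests.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$params <- list()          # name -> list of leaf nodes
  tp
}

ad_node <- function(tape, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_const <- function(tape, x) ad_node(tape, as.matrix(x))

# tracked parameter leaf; the same name may be fetched repeatedly
ad_param <- function(tape, store, name) {
  nd <- ad_node(tape, store[[name]])
  tape$params[[name]] <- c(tape$params[[name]], list(nd))
  nd
}

ad_backward <- function(tape, loss) {
  stopifnot(length(loss$val) == 1L)
  loss$grad <- matrix(1, 1, 1)
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    pg <- nd$backfn(nd$grad)
    for (m in seq_along(nd$parents)) {
      p <- nd$parents[[m]]
      if (is.null(pg[[m]])) next
      p$grad <- if (is.null(p$grad)) pg[[m]] else p$grad + pg[[m]]
    }
  }
  invisible(NULL)
}

# gradient per parameter name (summed over every fetch of that name)
ad_param_grads <- function(tape, store) {
  out <- list()
  for (name in names(tape$params)) {
    g <- NULL
    for (nd in tape$params[[name]])
      if (!is.null(nd$grad)) g <- if (is.null(g)) nd$grad else g + nd$grad
    if (is.null(g)) g <- array(0, dim(store[[name]]))
    out[[name]] <- g
  }
  out
}

# ---- elementwise and linear ops ------------------------------------------

ad_add <- function(tape, a, b)
  ad_node(tape, a$val + b$val, list(a, b), function(g) list(g, g))

ad_sub <- function(tape, a, b)
  ad_node(tape, a$val - b$val, list(a, b), function(g) list(g, -g))

ad_mul <- function(tape, a, b)
  ad_node(tape, a$val * b$val, list(a, b),
          local({ av <- a$val; bv <- b$val
                  function(g) list(g * bv, g * av) }))

ad_scale <- function(tape, a, k)
  ad_node(tape, a$val * k, list(a), function(g) list(g * k))

ad_shift <- function(tape, a, k)
  ad_node(tape, a$val + k, list(a), function(g) list(g))

# add a 1 x n row bias to every row
ad_addbias <- function(tape, a, b)
  ad_node(tape, sweep(a$val, 2, as.numeric(b$val), "+"), list(a, b),
          function(g) list(g, matrix(colSums(g), 1)))

ad_matmul <- function(tape, a, b)
  ad_node(tape, a$val %*% b$val, list(a, b),
          local({ av <- a$val; bv <- b$val
                  function(g) list(g %*% t(bv), crossprod(av, g)) }))

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(tape, s, list(a), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(tape, a) {
  s <- tanh(a$val)
  ad_node(tape, s, list(a), function(g) list(g * (1 - s^2)))
}

ad_relu <- function(tape, a) {
  m <- a$val > 0
  ad_node(tape, a$val * m, list(a), function(g) list(g * m))
}

ad_softplus <- function(tape, a) {
  v <- log1p(exp(-abs(a$val))) + pmax(a$val, 0)
  s <- 1 / (1 + exp(-a$val))
  ad_node(tape, v, list(a), function(g) list(g * s))
}

ad_sum <- function(tape, a)
  ad_node(tape, matrix(sum(a$val), 1, 1), list(a),
          local({ d <- dim(a$val); function(g)
            list(matrix(as.numeric(g), d[1], d[2])) }))

# ---- shape ops ------------------------------------------------------------

ad_rows <- function(tape, a, idx)
  ad_node(tape, a$val[idx, , drop = FALSE], list(a),
          local({ d <- dim(a$val); function(g) {
            out <- matrix(0, d[1], d[2])
            gs <- rowsum(g, idx)
            out[as.integer(rownames(gs)), ] <- gs
            list(out) } }))

ad_cols <- function(tape, a, idx)
  ad_node(tape, a$val[, idx, drop = FALSE], list(a),
          local({ d <- dim(a$val); function(g) {
            out <- matrix(0, d[1], d[2])
            for (m in seq_along(idx)) out[, idx[m]] <- out[, idx[m]] + g[, m]
            list(out) } }))

ad_rbind <- function(tape, nodes) {
  vals <- lapply(nodes, `[[`, "val")
  hts <- vapply(vals, nrow, integer(1))
  ends <- cumsum(hts); starts <- ends - hts + 1L
  ad_node(tape, do.call(rbind, vals), nodes, function(g)
    lapply(seq_along(hts), function(m)
      g[starts[m]:ends[m], , drop = FALSE]))
}

# multiply a matrix node by a 1x1 scalar node
ad_scale_by <- function(tape, a, s) {
  av <- a$val; sv <- as.numeric(s$val)
  ad_node(tape, av * sv, list(a, s), function(g)
    list(g * sv, matrix(sum(g * av), 1, 1)))
}

ad_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, `[[`, "val")
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, vals), nodes, function(g)
    lapply(seq_along(widths), function(m)
      g[, starts[m]:ends[m], drop = FALSE]))
}

# (L x h*c) -> (h*L x c), head-major blocks
ad_split_heads <- function(tape, a, h) {
  L <- nrow(a$val); c <- ncol(a$val) / h
  fwd <- function(x) {
    out <- matrix(0, h * L, c)
    for (k in seq_len(h))
      out[((k - 1) * L + 1):(k * L), ] <- x[, ((k - 1) * c + 1):(k * c)]
    out
  }
  bwd <- function(g) {
    out <- matrix(0, L, h * c)
    for (k in seq_len(h))
      out[, ((k - 1) * c + 1):(k * c)] <- g[((k - 1) * L + 1):(k * L), ]
    list(out)
  }
  ad_node(tape, fwd(a$val), list(a), bwd)
}

ad_merge_heads <- function(tape, a, h) {
  n <- nrow(a$val); L <- n / h; c <- ncol(a$val)
  fwd <- function(x) {
    out <- matrix(0, L, h * c)
    for (k in seq_len(h))
      out[, ((k - 1) * c + 1):(k * c)] <- x[((k - 1) * L + 1):(k * L), ]
    out
  }
  bwd <- function(g) {
    out <- matrix(0, n, c)
    for (k in seq_len(h))
      out[((k - 1) * L + 1):(k * L), ] <- g[, ((k - 1) * c + 1):(k * c)]
    list(out)
  }
  ad_node(tape, fwd(a$val), list(a), bwd)
}

# L^2 x 1 column (row index (i-1)L+j) <-> L x L matrix [i, j]
ad_vec2mat <- function(tape, a, L)
  ad_node(tape, matrix(a$val, L, L, byrow = TRUE), list(a),
          function(g) list(matrix(as.numeric(t(g)), ncol = 1)))

# permute pair rows from (i-major) to (j-major) indexing
ad_transpose_pair <- function(tape, a, L) {
  ii <- rep(seq_len(L), each = L); jj <- rep(seq_len(L), times = L)
  perm <- (jj - 1L) * L + ii            # new row r holds old row perm[r]
  ad_rows(tape, a, order(perm))
}

ad_tile_rows <- function(tape, a, times) {
  n <- nrow(a$val)
  ad_node(tape, a$val[rep(seq_len(n), times = times), , drop = FALSE],
          list(a), function(g) {
            out <- g[seq_len(n), , drop = FALSE]
            for (k in seq_len(times - 1))
              out <- out + g[k * n + seq_len(n), , drop = FALSE]
            list(out)
          })
}

# ---- normalization and attention -----------------------------------------

ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$val
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$val); bv <- as.numeric(beta$val)
  y <- sweep(xhat * rep(gv, each = nrow(x)), 2, bv, "+")
  n <- ncol(x)
  ad_node(tape, y, list(a, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1)
    dbeta <- matrix(colSums(g), 1)
    gx <- sweep(g, 2, gv, "*")
    dx <- inv * (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat))
    list(dx, dgamma, dbeta)
  })
}

ad_softmax_rows <- function(tape, a) {
  x <- a$val
  m <- apply(x, 1, max)
  e <- exp(x - m)
  p <- e / rowSums(e)
  ad_node(tape, p, list(a), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# batched row attention: Q (nb*n x c), K (nb*m x c), V (nb*m x cv),
# bias (nb*n x m or NULL); softmax over keys within each batch
ad_batched_attention <- function(tape, Q, K, V, bias = NULL, nb, scale) {
  n <- nrow(Q$val) / nb; m <- nrow(K$val) / nb
  Ps <- vector("list", nb)
  out <- matrix(0, nb * n, ncol(V$val))
  for (b in seq_len(nb)) {
    qi <- ((b - 1) * n + 1):(b * n); ki <- ((b - 1) * m + 1):(b * m)
    logits <- (Q$val[qi, , drop = FALSE] %*%
                 t(K$val[ki, , drop = FALSE])) * scale
    if (!is.null(bias)) logits <- logits + bias$val[qi, , drop = FALSE]
    logits <- logits - apply(logits, 1, max)
    e <- exp(logits)
    P <- e / rowSums(e)
    Ps[[b]] <- P
    out[qi, ] <- P %*% V$val[ki, , drop = FALSE]
  }
  parents <- if (is.null(bias)) list(Q, K, V) else list(Q, K, V, bias)
  ad_node(tape, out, parents, function(g) {
    dQ <- matrix(0, nrow(Q$val), ncol(Q$val))
    dK <- matrix(0, nrow(K$val), ncol(K$val))
    dV <- matrix(0, nrow(V$val), ncol(V$val))
    dB <- if (!is.null(bias)) matrix(0, nrow(bias$val), ncol(bias$val))
    for (b in seq_len(nb)) {
      qi <- ((b - 1) * n + 1):(b * n); ki <- ((b - 1) * m + 1):(b * m)
      P <- Ps[[b]]
      gb <- g[qi, , drop = FALSE]
      dV[ki, ] <- dV[ki, ] + crossprod(P, gb)
      dP <- gb %*% t(V$val[ki, , drop = FALSE])
      dlog <- P * (dP - rowSums(dP * P))
      dQ[qi, ] <- dQ[qi, ] + (dlog %*% K$val[ki, , drop = FALSE]) * scale
      dK[ki, ] <- dK[ki, ] + crossprod(dlog, Q$val[qi, , drop = FALSE]) * scale
      if (!is.null(bias)) dB[qi, ] <- dB[qi, ] + dlog
    }
    if (is.null(bias)) list(dQ, dK, dV) else list(dQ, dK, dV, dB)
  })
}

# ---- pair-tensor ops ------------------------------------------------------

# outer product of per-residue projections: (L x p), (L x q) -> L^2 x p*q
ad_pairouter <- function(tape, a, b) {
  L <- nrow(a$val); p <- ncol(a$val); q <- ncol(b$val)
  ii <- rep(seq_len(L), each = L); jj <- rep(seq_len(L), times = L)
  av <- a$val; bv <- b$val
  out <- av[ii, rep(seq_len(p), each = q), drop = FALSE] *
    bv[jj, rep(seq_len(q), times = p), drop = FALSE]
  ad_node(tape, out, list(a, b), function(g) {
    da <- matrix(0, L, p); db <- matrix(0, L, q)
    for (s in seq_len(p)) {
      Gs <- g[, ((s - 1) * q + 1):(s * q), drop = FALSE]
      da[, s] <- rowsum(rowSums(Gs * bv[jj, , drop = FALSE]), ii)
    }
    for (t in seq_len(q)) {
      Gt <- g[, seq(t, p * q, by = q), drop = FALSE]
      db[, t] <- rowsum(rowSums(Gt * av[ii, , drop = FALSE]), jj)
    }
    list(da, db)
  })
}

# triangle multiplicative update: a, b are L^2 x C (row (i-1)L+j);
# outgoing: out_ij,c = sum_k a_ik,c b_jk,c ; incoming: sum_k a_ki,c b_kj,c
ad_trimul <- function(tape, a, b, L, direction = c("outgoing", "incoming")) {
  direction <- match.arg(direction)
  C <- ncol(a$val)
  tomat <- function(x, c) matrix(x[, c], L, L, byrow = TRUE)   # [i, j]
  av <- a$val; bv <- b$val
  out <- matrix(0, L * L, C)
  for (c in seq_len(C)) {
    A <- tomat(av, c); B <- tomat(bv, c)
    O <- if (direction == "outgoing") A %*% t(B) else crossprod(A, B)
    out[, c] <- as.numeric(t(O))
  }
  ad_node(tape, out, list(a, b), function(g) {
    da <- matrix(0, L * L, C); db <- matrix(0, L * L, C)
    for (c in seq_len(C)) {
      A <- tomat(av, c); B <- tomat(bv, c); G <- tomat(g, c)
      if (direction == "outgoing") {
        dA <- G %*% B; dB <- crossprod(G, A)
      } else {
        dA <- B %*% t(G); dB <- A %*% G
      }
      da[, c] <- as.numeric(t(dA)); db[, c] <- as.numeric(t(dB))
    }
    list(da, db)
  })
}

# attention-weighted pair readout: P (L x L), Z (L^2 x c) ->
# out[i, ] = sum_j P[i, j] Z[(i-1)L+j, ]
ad_pair_readout <- function(tape, P, Z, L) {
  ii <- rep(seq_len(L), each = L)
  w <- as.numeric(t(P$val))           # row (i-1)L+j -> P[i, j]
  Zv <- Z$val
  out <- rowsum(Zv * w, ii)
  ad_node(tape, out, list(P, Z), function(g) {
    gz <- g[ii, , drop = FALSE]
    dZ <- gz * w
    dP <- matrix(rowSums(gz * Zv), L, L, byrow = TRUE)
    list(dP, dZ)
  })
}

# summed squared point distances: A, B are L x 3*np ->
# D[i, j] = sum_p || a_ip - b_jp ||^2
ad_pair_sqdist <- function(tape, A, B, np) {
  av <- A$val; bv <- B$val
  L <- nrow(av)
  D <- outer(rowSums(av^2), rowSums(bv^2), "+")
  for (p in seq_len(np)) {
    cols <- (3 * (p - 1) + 1):(3 * p)
    D <- D - 2 * av[, cols, drop = FALSE] %*% t(bv[, cols, drop = FALSE])
  }
  ad_node(tape, D, list(A, B), function(g) {
    dA <- matrix(0, L, 3 * np); dB <- matrix(0, L, 3 * np)
    rs <- rowSums(g); cs <- colSums(g)
    for (p in seq_len(np)) {
      cols <- (3 * (p - 1) + 1):(3 * p)
      dA[, cols] <- 2 * (rs * av[, cols, drop = FALSE] -
                           g %*% bv[, cols, drop = FALSE])
      dB[, cols] <- 2 * (cs * bv[, cols, drop = FALSE] -
                           crossprod(g, av[, cols, drop = FALSE]))
    }
    list(dA, dB)
  })
}

# per-point norms: P (L x 3*np) -> (L x np), sqrt(|p|^2 + eps)
ad_point_norms <- function(tape, P, np, eps = 1e-8) {
  pv <- P$val; L <- nrow(pv)
  out <- matrix(0, L, np)
  for (p in seq_len(np)) {
    cols <- (3 * (p - 1) + 1):(3 * p)
    out[, p] <- sqrt(rowSums(pv[, cols, drop = FALSE]^2) + eps)
  }
  ad_node(tape, out, list(P), function(g) {
    dP <- matrix(0, L, 3 * np)
    for (p in seq_len(np)) {
      cols <- (3 * (p - 1) + 1):(3 * p)
      dP[, cols] <- pv[, cols, drop = FALSE] * (g[, p] / out[, p])
    }
    list(dP)
  })
}

# ---- batched rotation ops (rotations as L x 9, column-major 3x3) ---------

.rc <- function(r, c) 3L * (c - 1L) + r

# compose: C_i = A_i %*% B_i
ad_rot_compose <- function(tape, A, B) {
  av <- A$val; bv <- B$val
  L <- nrow(av)
  out <- matrix(0, L, 9)
  for (r in 1:3) for (s in 1:3) {
    acc <- 0
    for (k in 1:3) acc <- acc + av[, .rc(r, k)] * bv[, .rc(k, s)]
    out[, .rc(r, s)] <- acc
  }
  ad_node(tape, out, list(A, B), function(g) {
    dA <- matrix(0, L, 9); dB <- matrix(0, L, 9)
    for (r in 1:3) for (k in 1:3) {
      acc <- 0
      for (s in 1:3) acc <- acc + g[, .rc(r, s)] * bv[, .rc(k, s)]
      dA[, .rc(r, k)] <- acc
    }
    for (k in 1:3) for (s in 1:3) {
      acc <- 0
      for (r in 1:3) acc <- acc + av[, .rc(r, k)] * g[, .rc(r, s)]
      dB[, .rc(k, s)] <- acc
    }
    list(dA, dB)
  })
}

# rotate m stacked points per residue: y_p = R x_p (inverse = R^T x_p)
ad_rotate_points <- function(tape, R, P, inverse = FALSE) {
  rv <- R$val; pv <- P$val
  L <- nrow(rv); m <- ncol(pv) / 3
  idx <- function(r, k) if (inverse) .rc(k, r) else .rc(r, k)
  out <- matrix(0, L, ncol(pv))
  for (p in seq_len(m)) for (r in 1:3) {
    acc <- 0
    for (k in 1:3) acc <- acc + rv[, idx(r, k)] * pv[, 3 * (p - 1) + k]
    out[, 3 * (p - 1) + r] <- acc
  }
  ad_node(tape, out, list(R, P), function(g) {
    dR <- matrix(0, L, 9); dP <- matrix(0, L, ncol(pv))
    for (p in seq_len(m)) {
      for (r in 1:3) for (k in 1:3)
        dR[, idx(r, k)] <- dR[, idx(r, k)] +
          g[, 3 * (p - 1) + r] * pv[, 3 * (p - 1) + k]
      for (k in 1:3) {
        acc <- 0
        for (r in 1:3) acc <- acc + rv[, idx(r, k)] * g[, 3 * (p - 1) + r]
        dP[, 3 * (p - 1) + k] <- acc
      }
    }
    list(dR, dP)
  })
}

# add per-residue translation t (L x 3) to m stacked points (L x 3m)
ad_add_trans <- function(tape, P, t, m, subtract = FALSE) {
  sgn <- if (subtract) -1 else 1
  tv <- t$val
  out <- P$val + sgn * tv[, rep(1:3, times = m), drop = FALSE]
  ad_node(tape, out, list(P, t), function(g) {
    dt <- matrix(0, nrow(tv), 3)
    for (p in seq_len(m))
      dt <- dt + g[, (3 * (p - 1) + 1):(3 * p), drop = FALSE]
    list(g, sgn * dt)
  })
}

# normalized quaternion (1, b, c, d) update -> rotation matrix (L x 9)
ad_quat_to_rot <- function(tape, q) {
  qv <- q$val
  L <- nrow(qv)
  b <- qv[, 1]; c <- qv[, 2]; d <- qv[, 3]
  n2 <- 1 + b^2 + c^2 + d^2
  a <- 1
  R <- cbind(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
             2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
             2 * (b * d + a * c), 2 * (c * d - a * b),
             a^2 - b^2 - c^2 + d^2) / n2
  # columns above are R[r, c] in column-major order rc(1,1), rc(2,1), ...
  ad_node(tape, R, list(q), function(g) {
    dq <- matrix(0, L, 3)
    # exact derivative of the closed form, per quaternion component
    for (comp in 1:3) {
      bb <- b; cc <- c; dd <- d
      eb <- as.numeric(comp == 1); ec <- as.numeric(comp == 2)
      ed <- as.numeric(comp == 3)
      # dR/dcomp by symbolic differentiation of the entries
      num <- cbind(2 * bb * eb - 2 * cc * ec - 2 * dd * ed,
                   2 * (eb * cc + bb * ec + ed),
                   2 * (eb * dd + bb * ed - ec),
                   2 * (eb * cc + bb * ec - ed),
                   -2 * bb * eb + 2 * cc * ec - 2 * dd * ed,
                   2 * (ec * dd + cc * ed + eb),
                   2 * (eb * dd + bb * ed + ec),
                   2 * (ec * dd + cc * ed - eb),
                   -2 * bb * eb - 2 * cc * ec + 2 * dd * ed)
      dn2 <- 2 * (bb * eb + cc * ec + dd * ed)
      dR <- num / n2 - R * (dn2 / n2)
      dq[, comp] <- rowSums(g * dR)
    }
    list(dq)
  })
}
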