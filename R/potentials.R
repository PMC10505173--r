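# Hybrid deep potentials: per-pair cubic-spline curves over the binned
# geometry terms (E_geo) and the clamped frame-space discrepancy to the
# end-to-end predictions (E_e2e).  All energies are differentiable with
# analytic gradients for the L-BFGS folding stage.

#' Geometry restraints container
#'
#' Per-pair probability tensors over the term bin layouts of
#' [geometry_bin_spec()].
#'
#' @param tensors named list over `GEOMETRY_TERMS` of L x L x n_total
#'   arrays; each off-diagonal (i, j) slice must sum to 1 (1e-5) and each
#'   tensor must be symmetric in (i, j).
#' @return Object of class `geometry_restraints`.
#' @export
geometry_restraints <- function(tensors) {
  spec <- geometry_bin_spec()
  missing <- setdiff(GEOMETRY_TERMS, names(tensors))
  if (length(missing))
    stop("geometry_restraints: missing term(s): ",
         paste(missing, collapse = ", "))
  L <- dim(tensors[[1]])[1]
  for (term in GEOMETRY_TERMS) {
    x <- tensors[[term]]
    if (!all(dim(x) == c(L, L, spec[[term]]$n_total)))
      stop("geometry_restraints: bad shape for ", term)
    sums <- apply(x, c(1, 2), sum)
    diag(sums) <- 1
    if (max(abs(sums - 1)) > 1e-5)
      stop("geometry_restraints: ", term, " slices do not sum to 1")
    sym_err <- max(abs(x - aperm(x, c(2, 1, 3))))
    if (sym_err > 1e-5)
      stop("geometry_restraints: ", term, " not symmetric in (i, j)")
  }
  structure(list(tensors = tensors[GEOMETRY_TERMS], L = L),
            class = "geometry_restraints")
}

#' @export
print.geometry_restraints <- function(x, ...) {
  cat("<geometry_restraints> L =", x$L, "\n"); invisible(x)
}

#' End-to-end prediction ensemble
#'
#' @param frame_sets list of K `frame_set` objects of equal length (the
#'   fixed predicted frames that anchor the end-to-end potential).
#' @return Object of class `e2e_prediction`.
#' @export
e2e_prediction <- function(frame_sets) {
  if (!length(frame_sets)) stop("e2e_prediction: need at least one frame set")
  L <- frame_sets[[1]]$L
  ok <- vapply(frame_sets, function(f) inherits(f, "frame_set") && f$L == L,
               logical(1))
  if (!all(ok)) stop("e2e_prediction: frame sets invalid or unequal lengths")
  structure(list(frame_sets = frame_sets, K = length(frame_sets), L = L),
            class = "e2e_prediction")
}

#' @export
print.e2e_prediction <- function(x, ...) {
  cat("<e2e_prediction> K =", x$K, ", L =", x$L, "\n"); invisible(x)
}

# ---- cubic-spline machinery ----------------------------------------------
# Uniform knots.  Clamped splines (f' = 0 at both ends) give constant,
# C1 extrapolation for the distance terms; cyclic splines give exact
# periodicity for the dihedral terms.  The knot grid is shared by every
# pair of a term, so second derivatives for all pairs come from one
# precomputed linear operator: M = Y %*% t(OP).

.spline_op_clamped <- function(n, h) {
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  A[1, 1] <- h / 3; A[1, 2] <- h / 6
  B[1, 1] <- -1 / h; B[1, 2] <- 1 / h
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h / 6; A[i, i] <- 2 * h / 3; A[i, i + 1] <- h / 6
    B[i, i - 1] <- 1 / h; B[i, i] <- -2 / h; B[i, i + 1] <- 1 / h
  }
  A[n, n - 1] <- h / 6; A[n, n] <- h / 3
  B[n, n - 1] <- 1 / h; B[n, n] <- -1 / h
  solve(A, B)
}

.spline_op_periodic <- function(n, h) {
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    A[i, im] <- A[i, im] + h / 6
    A[i, i] <- A[i, i] + 2 * h / 3
    A[i, ip] <- A[i, ip] + h / 6
    B[i, im] <- B[i, im] + 1 / h
    B[i, i] <- B[i, i] - 2 / h
    B[i, ip] <- B[i, ip] + 1 / h
  }
  solve(A, B)
}

.spline_ops <- function(kind, n, h) {
  key <- paste0("spl_", kind, "_", n)
  if (is.null(.rnaforge_cache[[key]]))
    .rnaforge_cache[[key]] <- if (kind == "clamped")
      .spline_op_clamped(n, h) else .spline_op_periodic(n, h)
  .rnaforge_cache[[key]]
}

# vectorized evaluation: Y, M are npair x n (values / 2nd derivatives),
# x a vector of npair query points.  Returns value and derivative.
.spline_eval <- function(x, Y, M, x1, h, n, periodic = FALSE) {
  if (periodic) {
    period <- n * h
    x <- ((x - x1) %% period) + x1
    k <- pmin(1L + as.integer(floor((x - x1) / h)), n)
    kp <- ifelse(k == n, 1L, k + 1L)
    xk <- x1 + (k - 1) * h
  } else {
    xn <- x1 + (n - 1) * h
    x <- pmin(pmax(x, x1), xn)           # clamped-flat continuation
    k <- pmin(1L + as.integer(floor((x - x1) / h)), n - 1L)
    kp <- k + 1L
    xk <- x1 + (k - 1) * h
  }
  idx <- seq_along(x)
  yk <- Y[cbind(idx, k)]; ykp <- Y[cbind(idx, kp)]
  mk <- M[cbind(idx, k)]; mkp <- M[cbind(idx, kp)]
  s <- x - xk; sb <- h - s
  val <- mk * sb^3 / (6 * h) + mkp * s^3 / (6 * h) +
    (yk / h - mk * h / 6) * sb + (ykp / h - mkp * h / 6) * s
  der <- -mk * sb^2 / (2 * h) + mkp * s^2 / (2 * h) -
    (yk / h - mk * h / 6) + (ykp / h - mkp * h / 6)
  list(value = val, deriv = der)
}

#' Build per-pair spline potentials from geometry restraints
#'
#' Distance terms: the curve for pair (i, j) is
#' `-log((P_b + eps) / (P_ref + eps))` over the content-bin centers,
#' where `P_ref` is the probability of the last content bin below the
#' range maximum (the reference state); splined with clamped ends so the
#' potential continues flat (zero force) beyond the binned range.
#' Dihedral terms: `-0.5 * (log(P_b + eps) - log(1/36 + eps))` splined
#' periodically over the 36 angle-bin centers; the uniform-reference
#' offset makes uninformative restraints exert no force.
#'
#' @param restraints A `geometry_restraints`.
#' @param eps probability regularizer of the potential (default 1e-4).
#' @return Object of class `geometry_potential`.
#' @export
build_geometry_potential <- function(restraints, eps = 1e-4) {
  stopifnot(inherits(restraints, "geometry_restraints"))
  spec <- geometry_bin_spec()
  L <- restraints$L
  out <- list()
  for (term in GEOMETRY_TERMS) {
    sp <- spec[[term]]
    n <- sp$n_content
    x <- restraints$tensors[[term]]
    P <- matrix(0, L * L, n)           # pair index p = i + (j-1) L
    if (sp$kind == "distance") {
      for (b in seq_len(n)) P[, b] <- as.vector(x[, , b + 1L])
      ref <- P[, n]
      Y <- -log((P + eps) / (ref + eps))
      h <- (sp$hi - sp$lo) / n
      x1 <- sp$lo + h / 2
      M <- Y %*% t(.spline_ops("clamped", n, h))
      out[[term]] <- list(kind = "distance", Y = Y, M = M, x1 = x1, h = h,
                          n = n, atoms = sp$atoms)
    } else {
      for (b in seq_len(n)) P[, b] <- as.vector(x[, , b])
      Y <- -0.5 * (log(P + eps) - log(1 / n + eps))
      h <- 2 * pi / n
      x1 <- -pi + h / 2
      M <- Y %*% t(.spline_ops("periodic", n, h))
      out[[term]] <- list(kind = "dihedral", Y = Y, M = M, x1 = x1, h = h,
                          n = n, atoms = sp$atoms,
                          gate_atom = sp$gate_atom, gate_max = sp$gate_max)
    }
  }
  structure(list(terms = out, L = L, eps = eps),
            class = "geometry_potential")
}

#' @export
print.geometry_potential <- function(x, ...) {
  cat("<geometry_potential> L =", x$L, ", eps =", x$eps, "\n")
  invisible(x)
}

#' Evaluate one pair's potential curve on a grid (diagnostics/tests)
#' @param pot A `geometry_potential`.
#' @param term term name.
#' @param i,j residue pair.
#' @param x numeric vector of distances (Angstrom) or angles (radians).
#' @return Numeric vector of curve values.
#' @export
spline_curve <- function(pot, term, i, j, x) {
  tm <- pot$terms[[term]]
  p <- i + (j - 1) * pot$L
  Y <- tm$Y[rep(p, length(x)), , drop = FALSE]
  M <- tm$M[rep(p, length(x)), , drop = FALSE]
  .spline_eval(x, Y, M, tm$x1, tm$h, tm$n,
               periodic = tm$kind == "dihedral")$value
}

# ---- geometry energy ------------------------------------------------------

# dihedral gradient wrt the four defining points (rows paired with the
# angle vector); standard rigid-body formulas
.dihedral_point_grads <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
  nb2 <- sqrt(rowSums(b2^2))
  g1 <- -n1 * (nb2 / n1sq)
  g4 <- n2 * (nb2 / n2sq)
  c1 <- rowSums(b1 * b2) / nb2^2
  c2 <- rowSums(b3 * b2) / nb2^2
  g2 <- -(1 + c1) * g1 + c2 * g4
  g3 <- c1 * g1 - (1 + c2) * g4
  list(g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

#' Geometry potential energy of a conformation
#'
#' Sums, over ordered residue pairs, the distance-term spline values at
#' the current bead distances and the dihedral-term spline values at the
#' current pair dihedrals; a dihedral contributes only while its gating
#' virtual bond is shorter than the term's maximum distance M.
#'
#' @param conf A `bead_structure` (current conformation).
#' @param potentials A `geometry_potential` on the same length.
#' @param grad if TRUE also return the gradient with respect to the bead
#'   coordinates (L x 3 x 3 array).
#' @return List with `value` and, when requested, `g_beads`.
#' @export
energy_geo <- function(conf, potentials, grad = FALSE) {
  L <- conf$L
  stopifnot(potentials$L == L)
  if (L < 2) return(list(value = 0))
  off <- which(matrix(TRUE, L, L) & !diag(TRUE, L))   # ordered pairs i != j
  ii <- ((off - 1) %% L) + 1L
  jj <- ((off - 1) %/% L) + 1L
  atom_xyz <- list("P" = bead_atom(conf, "P"),
                   "C4'" = bead_atom(conf, "C4'"),
                   "N" = bead_atom(conf, "N"))
  total <- 0
  if (grad) gb <- array(0, c(L, 3, 3))
  acc <- function(atom, res_idx, g) {
    a <- match(atom, BEAD_ATOMS)
    gm <- rowsum(g, res_idx)
    rows <- as.integer(rownames(gm))
    gb[rows, a, ] <<- gb[rows, a, ] + gm
  }
  dist_cache <- list()
  for (term in GEOMETRY_TERMS) {
    tm <- potentials$terms[[term]]
    if (tm$kind == "distance") {
      X <- atom_xyz[[tm$atoms]]
      diff <- X[ii, , drop = FALSE] - X[jj, , drop = FALSE]
      d <- sqrt(rowSums(diff^2))
      dist_cache[[tm$atoms]] <- d
      ev <- .spline_eval(d, tm$Y[off, , drop = FALSE],
                         tm$M[off, , drop = FALSE], tm$x1, tm$h, tm$n)
      total <- total + sum(ev$value)
      if (grad) {
        u <- diff / pmax(d, 1e-9)
        g <- ev$deriv * u
        acc(tm$atoms, ii, g)
        acc(tm$atoms, jj, -g)
      }
    } else {
      at <- tm$atoms
      p1 <- atom_xyz[[at[1]]][ii, , drop = FALSE]
      p2 <- atom_xyz[[at[2]]][ii, , drop = FALSE]
      p3 <- atom_xyz[[at[3]]][jj, , drop = FALSE]
      p4 <- atom_xyz[[at[4]]][jj, , drop = FALSE]
      th <- dihedral_points(p1, p2, p3, p4)
      gate_d <- dist_cache[[tm$gate_atom]]
      open <- is.finite(th) & gate_d < tm$gate_max
      if (!any(open)) next
      sel <- which(open)
      ev <- .spline_eval(th[sel], tm$Y[off[sel], , drop = FALSE],
                         tm$M[off[sel], , drop = FALSE], tm$x1, tm$h,
                         tm$n, periodic = TRUE)
      total <- total + sum(ev$value)
      if (grad) {
        dg <- .dihedral_point_grads(p1[sel, , drop = FALSE],
                                    p2[sel, , drop = FALSE],
                                    p3[sel, , drop = FALSE],
                                    p4[sel, , drop = FALSE])
        acc(at[1], ii[sel], ev$deriv * dg$g1)
        acc(at[2], ii[sel], ev$deriv * dg$g2)
        acc(at[3], jj[sel], ev$deriv * dg$g3)
        acc(at[4], jj[sel], ev$deriv * dg$g4)
      }
    }
  }
  out <- list(value = total)
  if (grad) out$g_beads <- gb
  out
}

# ---- end-to-end energy ----------------------------------------------------

#' End-to-end (FAPE-form) potential energy of a conformation
#'
#' Sum over the K predictions of the clamped frame-aligned discrepancy
#' between the fixed predicted frames and the current conformation
#' frames, over the three bead atoms of every residue.
#'
#' @param conf_frames `frame_set` of the current conformation.
#' @param preds An `e2e_prediction`.
#' @param sequence character base types (selects templates).
#' @param cfg a [loss_config()] (supplies d_cut and epsilon).
#' @param grad if TRUE also return gradients with respect to the
#'   conformation frames (`gR`: L x 3 x 3, `gt`: L x 3).
#' @param templates template map.
#' @return List with `value` and optionally `gR`, `gt`.
#' @export
energy_e2e <- function(conf_frames, preds, sequence, cfg = loss_config(),
                       grad = FALSE, templates = derive_templates()) {
  stopifnot(inherits(preds, "e2e_prediction"),
            conf_frames$L == preds$L)
  ta <- .template_atoms(sequence, templates)
  total <- 0
  if (grad) { gR <- array(0, c(conf_frames$L, 3, 3))
              gt <- matrix(0, conf_frames$L, 3) }
  for (k in seq_len(preds$K)) {
    res <- fape_core(conf_frames, preds$frame_sets[[k]], ta,
                     cfg$d_cut, cfg$epsilon, reduce = "sum", grad = grad)
    total <- total + res$value
    if (grad) { gR <- gR + res$gR; gt <- gt + res$gt }
  }
  out <- list(value = total)
  if (grad) { out$gR <- gR; out$gt <- gt }
  out
}

#' Hybrid deep-potential energy
#'
#' Unweighted sum of the available components (end-to-end and geometry),
#' matching the ablation modes of the folding stage.
#'
#' @param conf_frames `frame_set` of the current conformation.
#' @param sequence character base types.
#' @param preds An `e2e_prediction` or NULL.
#' @param potentials A `geometry_potential` or NULL.
#' @param cfg a [loss_config()].
#' @param templates template map.
#' @return Scalar energy.
#' @export
energy_hybrid <- function(conf_frames, sequence, preds = NULL,
                          potentials = NULL, cfg = loss_config(),
                          templates = derive_templates()) {
  if (is.null(preds) && is.null(potentials))
    stop("energy_hybrid: both potential components absent")
  total <- 0
  if (!is.null(preds))
    total <- total + energy_e2e(conf_frames, preds, sequence, cfg,
                                templates = templates)$value
  if (!is.null(potentials)) {
    beads <- beads_from_frames(conf_frames, sequence, templates)
    total <- total + energy_geo(beads, potentials)$value
  }
  total
}
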