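# Rigid frames: per-residue rotation + translation mapping a local 3-atom
# template into global space.  Rotations are proper (det = +1) throughout.

#' Construct a rigid frame
#'
#' A rigid frame is a proper rotation `R` (3x3, det = +1) plus a translation
#' `t` (length-3, Angstrom).  Applying the frame maps local coordinates `x`
#' to global coordinates `R x + t`.
#'
#' @param rotation 3x3 rotation matrix with determinant +1.
#' @param translation numeric length-3 translation vector.
#' @return An object of class `rigid_frame` (list with `R`, `t`).
#' @export
rigid_frame <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_frame: non-finite entries")
  err_orth <- max(abs(crossprod(rotation) - diag(3)))
  if (err_orth > 1e-6)
    stop("rigid_frame: rotation not orthogonal (max deviation ",
         format(err_orth), ")")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rigid_frame: rotation must be proper (det = +1), got det = ",
         format(det(rotation)))
  structure(list(R = rotation, t = translation), class = "rigid_frame")
}

#' @export
print.rigid_frame <- function(x, ...) {
  cat("<rigid_frame>\n")
  cat("rotation:\n"); print(round(x$R, 4))
  cat("translation:", paste(round(x$t, 4), collapse = " "), "\n")
  invisible(x)
}

#' Identity frame
#' @return The identity `rigid_frame`.
#' @export
frame_identity <- function() rigid_frame()

#' Apply a rigid frame to points
#'
#' @param frame A `rigid_frame`.
#' @param points n x 3 numeric matrix (or length-3 vector) of local
#'   coordinates.
#' @return n x 3 matrix of global coordinates `R x + t`.
#' @export
frame_apply <- function(frame, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(points %*% t(frame$R), 2, frame$t, "+")
}

#' Compose two rigid frames
#'
#' `frame_compose(a, b)` is the frame performing `b` first then `a`:
#' `(a o b)(x) = a(b(x))`.
#'
#' @param a,b `rigid_frame` objects.
#' @return The composed `rigid_frame`.
#' @export
frame_compose <- function(a, b) {
  rigid_frame(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid frame
#' @param a A `rigid_frame`.
#' @return The inverse frame, mapping global back to local coordinates.
#' @export
frame_invert <- function(a) {
  rigid_frame(t(a$R), as.numeric(-t(a$R) %*% a$t))
}

# ---- Kabsch superposition -------------------------------------------------

#' Optimal rigid superposition (Kabsch / SVD orthogonalization)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum || R x_i + t - y_i ||^2` for paired point sets, by SVD of the
#' cross-covariance with determinant sign correction.  This realizes
#' SVD orthogonalization: the least-squares projection onto SO(3).
#'
#' @param x n x 3 matrix of source points (e.g. a local template).
#' @param y n x 3 matrix of target points.
#' @param allow_reflection if TRUE the unconstrained orthogonal optimum is
#'   returned even when improper (used only by test comparators).
#' @return A `rigid_frame` with attribute `rmsd` (residual RMSD after
#'   superposition).
#' @export
kabsch_frame <- function(x, y, allow_reflection = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3L, ncol(y) == 3L)
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  H <- crossprod(x0, y0)                 # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (allow_reflection) d <- 1
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  t <- cy - as.numeric(R %*% cx)
  fitted <- sweep(x %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  out <- rigid_frame(R, t)
  attr(out, "rmsd") <- rmsd
  out
}

#' Build a residue frame from observed bead coordinates
#'
#' Given the observed (P, C4', N) bead triad of a residue and the
#' predefined local template of its base type, returns the rigid frame
#' `T` such that `T(template)` best superposes onto the observation
#' (Kabsch/SVD with determinant correction).
#'
#' @param observed 3 x 3 matrix of observed bead coordinates, rows in the
#'   fixed atom order (P, C4', N).
#' @param template A `nt_template` (see [derive_templates()]) or a plain
#'   3 x 3 local-coordinate matrix.
#' @return A `rigid_frame`; attribute `rmsd` reports the residual.
#' @export
frame_from_beads <- function(observed, template) {
  obs <- as.matrix(observed)
  loc <- if (inherits(template, "nt_template")) template$local_coords
         else as.matrix(template)
  stopifnot(all(dim(obs) == c(3L, 3L)), all(dim(loc) == c(3L, 3L)))
  if (!all(is.finite(obs))) stop("frame_from_beads: non-finite coordinates")
  # degenerate geometry: collinear or coincident bead triad
  v1 <- obs[2, ] - obs[1, ]; v2 <- obs[3, ] - obs[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  scale <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
  if (scale < 1e-8 || sqrt(sum(cr^2)) < 1e-8 * scale^2)
    stop("frame_from_beads: degenerate (collinear or coincident) bead triad")
  kabsch_frame(loc, obs)
}

# ---- rotation parameterizations ------------------------------------------

#' Exponential map: rotation vector to rotation matrix (Rodrigues)
#' @param w numeric length-3 rotation vector (axis * angle, radians).
#' @return 3x3 rotation matrix.
#' @export
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  if (th < 1e-12) return(diag(3) + K)
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * (K %*% K)
}

#' Logarithm map: rotation matrix to rotation vector
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 rotation vector.
#' @export
matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  th <- acos(ct)
  if (th < 1e-8) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (th > pi - 1e-6) {
    # near-pi: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonals
    i <- which.max(axis)
    if (i == 1) { axis[2] <- B[1, 2] / axis[1]; axis[3] <- B[1, 3] / axis[1] }
    if (i == 2) { axis[1] <- B[1, 2] / axis[2]; axis[3] <- B[2, 3] / axis[2] }
    if (i == 3) { axis[1] <- B[1, 3] / axis[3]; axis[2] <- B[2, 3] / axis[3] }
    return(axis / sqrt(sum(axis^2)) * th)
  }
  c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th)) * th
}

# contraction of a gradient wrt R (3x3) down to the rotation vector:
# returns g_w[k] = sum(G * dR/dw_k).  Exact derivative of the exponential
# map (Gallego & Yezzi 2015); small-angle branch uses dR/dw_k = [e_k]x.
rotvec_grad <- function(w, G) {
  th2 <- sum(w^2)
  R <- rotvec_to_matrix(w)
  g <- numeric(3)
  if (th2 < 1e-16) {
    for (k in 1:3) {
      e <- c(0, 0, 0); e[k] <- 1
      Ek <- matrix(c(0, e[3], -e[2], -e[3], 0, e[1], e[2], -e[1], 0), 3, 3)
      g[k] <- sum(G * (Ek %*% R))
    }
    return(g)
  }
  W <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  ImR <- diag(3) - R
  for (k in 1:3) {
    e <- c(0, 0, 0); e[k] <- 1
    v <- w[k] * w + c(
      w[2] * ImR[3, k] - w[3] * ImR[2, k],
      w[3] * ImR[1, k] - w[1] * ImR[3, k],
      w[1] * ImR[2, k] - w[2] * ImR[1, k])
    Vk <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    g[k] <- sum(G * ((Vk %*% R) / th2))
  }
  g
}

# ---- frame sets -----------------------------------------------------------

#' A set of per-residue rigid frames
#'
#' Stored densely: `R` is an L x 3 x 3 array, `t` an L x 3 matrix.
#'
#' @param R L x 3 x 3 array of rotations (or list of 3x3 matrices).
#' @param t L x 3 matrix of translations.
#' @return Object of class `frame_set`.
#' @export
frame_set <- function(R, t) {
  if (is.list(R)) {
    L <- length(R)
    Ra <- array(0, c(L, 3, 3))
    for (i in seq_len(L)) Ra[i, , ] <- R[[i]]
    R <- Ra
  }
  t <- as.matrix(t)
  L <- dim(R)[1]
  stopifnot(length(dim(R)) == 3L, dim(R)[2] == 3L, dim(R)[3] == 3L,
            nrow(t) == L, ncol(t) == 3L)
  for (i in seq_len(L)) {
    Ri <- matrix(R[i, , ], 3, 3)
    if (max(abs(crossprod(Ri) - diag(3))) > 1e-6 || abs(det(Ri) - 1) > 1e-6)
      stop("frame_set: frame ", i, " is not a proper rotation")
  }
  structure(list(R = R, t = t, L = L), class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat("<frame_set> L =", x$L, "\n"); invisible(x)
}

#' Number of frames
#' @param x A `frame_set`.
#' @export
frame_set_length <- function(x) x$L

#' Extract one frame from a frame set
#' @param fs A `frame_set`.
#' @param i residue index (1-based).
#' @return A `rigid_frame`.
#' @export
frame_set_get <- function(fs, i) rigid_frame(matrix(fs$R[i, , ], 3, 3), fs$t[i, ])

#' Build a frame set from per-residue bead triads
#'
#' @param beads A `bead_structure`.
#' @param templates Template map from [derive_templates()].
#' @param sequence Character vector of base types (length L); defaults to
#'   the sequence attached to `beads`.
#' @return A `frame_set`.
#' @export
frames_from_structure <- function(beads, templates = derive_templates(),
                                  sequence = attr(beads, "sequence")) {
  L <- dim(beads$coords)[1]
  if (is.null(sequence)) sequence <- rep("U", L)
  R <- array(0, c(L, 3, 3)); t <- matrix(0, L, 3)
  for (i in seq_len(L)) {
    f <- frame_from_beads(matrix(beads$coords[i, , ], 3, 3),
                          templates[[sequence[i]]])
    R[i, , ] <- f$R; t[i, ] <- f$t
  }
  frame_set(R, t)
}

#' Apply one global rigid motion to every frame of a set (left composition)
#' @param g A `rigid_frame` global motion.
#' @param fs A `frame_set`.
#' @return The transformed `frame_set`.
#' @export
frame_set_transform <- function(g, fs) {
  L <- fs$L
  R <- array(0, c(L, 3, 3)); t <- matrix(0, L, 3)
  for (i in seq_len(L)) {
    R[i, , ] <- g$R %*% matrix(fs$R[i, , ], 3, 3)
    t[i, ] <- as.numeric(g$R %*% fs$t[i, ]) + g$t
  }
  frame_set(R, t)
}

#' Bead coordinates realized by a frame set
#'
#' Places each residue's 3-atom template with its frame, giving the
#' L x 3 x 3 bead tensor in the fixed (P, C4', N) atom order.
#'
#' @inheritParams frames_from_structure
#' @param frames A `frame_set`.
#' @return A `bead_structure`.
#' @export
beads_from_frames <- function(frames, sequence, templates = derive_templates()) {
  L <- frames$L
  stopifnot(length(sequence) == L)
  coords <- array(0, c(L, 3, 3))
  for (i in seq_len(L)) {
    loc <- templates[[sequence[i]]]$local_coords
    coords[i, , ] <- sweep(loc %*% t(matrix(frames$R[i, , ], 3, 3)),
                           2, frames$t[i, ], "+")
  }
  bead_structure(coords, sequence = sequence)
}
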