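# Training objectives: FAPE, inter-N distance cross-entropy, geometry
# cross-entropy, and their weighted sum.

#' Loss configuration
#'
#' @param fape_weight weight of the FAPE term in the end-to-end loss.
#' @param dist_weight weight of the inter-N distance cross-entropy.
#' @param d_cut FAPE clamp distance (Angstrom).
#' @param epsilon FAPE epsilon inside the square root (Angstrom^2 scale).
#' @param w_distance,w_dihedral geometry cross-entropy term weights.
#' @param fape_reduce "mean" (default; scale-stable across lengths) or
#'   "sum" over the i x j FAPE terms.
#' @return Named list of loss settings.
#' @export
loss_config <- function(fape_weight = 1.5, dist_weight = 0.6,
                        d_cut = 30, epsilon = 1e-3,
                        w_distance = 1.0, w_dihedral = 0.5,
                        fape_reduce = c("mean", "sum")) {
  fape_reduce <- match.arg(fape_reduce)
  stopifnot(fape_weight > 0, dist_weight > 0, d_cut > 0, epsilon > 0,
            w_distance > 0, w_dihedral > 0)
  list(fape_weight = fape_weight, dist_weight = dist_weight,
       d_cut = d_cut, epsilon = epsilon, w_distance = w_distance,
       w_dihedral = w_dihedral, fape_reduce = fape_reduce)
}

# per-residue local template atoms as a (3L) x 3 matrix + residue index
.template_atoms <- function(sequence, templates = derive_templates()) {
  L <- length(sequence)
  r <- matrix(0, 3 * L, 3)
  for (j in seq_len(L))
    r[(3 * j - 2):(3 * j), ] <- templates[[sequence[j]]]$local_coords
  list(r = r, res = rep(seq_len(L), each = 3))
}

# global atom positions realized by a frame set (row t convention)
.frames_atoms <- function(fs, tmpl_atoms) {
  n <- nrow(tmpl_atoms$r)
  out <- matrix(0, n, 3)
  for (j in seq_len(fs$L)) {
    sel <- tmpl_atoms$res == j
    out[sel, ] <- sweep(tmpl_atoms$r[sel, , drop = FALSE] %*%
                          t(matrix(fs$R[j, , ], 3, 3)), 2, fs$t[j, ], "+")
  }
  out
}

# Core clamped frame-aligned point error between a "conf" frame set and a
# "fixed" frame set, with optional analytic gradient with respect to the
# conf frames.  Each term is min(d_cut, sqrt(||T_i^-1(x_j) -
# T_i'^-1(x_j')||^2 + eps)) over frames i and all template atoms j.
fape_core <- function(conf, fixed, tmpl_atoms, d_cut, eps,
                      reduce = "mean", grad = FALSE) {
  L <- conf$L
  stopifnot(fixed$L == L)
  Xc <- .frames_atoms(conf, tmpl_atoms)
  Xf <- .frames_atoms(fixed, tmpl_atoms)
  n_at <- nrow(Xc)
  scale <- if (reduce == "mean") 1 / (L * n_at) else 1
  total <- 0
  if (grad) {
    gR <- array(0, c(L, 3, 3)); gt <- matrix(0, L, 3)
    gu <- matrix(0, n_at, 3)
  }
  for (i in seq_len(L)) {
    Ri <- matrix(conf$R[i, , ], 3, 3); ti <- conf$t[i, ]
    Rf <- matrix(fixed$R[i, , ], 3, 3); tf <- fixed$t[i, ]
    b <- sweep(Xc, 2, ti) %*% Ri
    a <- sweep(Xf, 2, tf) %*% Rf
    e <- b - a
    c2 <- rowSums(e^2) + eps
    cc <- sqrt(c2)
    total <- total + sum(pmin(cc, d_cut))
    if (grad) {
      w <- scale * as.numeric(cc < d_cut) / cc
      de <- e * w                       # dL/de rows
      gu_i <- de %*% t(Ri)              # back through b = (u - t) R
      gu <- gu + gu_i
      gt[i, ] <- gt[i, ] - colSums(gu_i)
      gR[i, , ] <- gR[i, , ] + crossprod(sweep(Xc, 2, ti), de)
    }
  }
  value <- total * scale
  if (!grad) return(list(value = value))
  # atoms u_j = R_j r + t_j
  for (j in seq_len(L)) {
    sel <- tmpl_atoms$res == j
    gsel <- gu[sel, , drop = FALSE]
    gt[j, ] <- gt[j, ] + colSums(gsel)
    gR[j, , ] <- gR[j, , ] + crossprod(gsel, tmpl_atoms$r[sel, , drop = FALSE])
  }
  list(value = value, gR = gR, gt = gt)
}

#' Frame aligned point error (FAPE)
#'
#' Clamped, epsilon-regularized deviation between two frame sets,
#' measured in every residue's local frame over all template atoms:
#' `mean_ij min(d_cut, sqrt(||T_i^-1(T_j(r)) - T_i'^-1(T_j'(r))||^2 +
#' eps))`.  Invariant to any global rigid motion applied to either frame
#' set, but sensitive to reflection, which is what lets it discriminate
#' a structure from its mirror image.
#'
#' @param pred_frames,true_frames `frame_set` objects of equal length.
#' @param sequence character vector of base types (selects templates).
#' @param cfg a [loss_config()].
#' @param templates template map from [derive_templates()].
#' @return Scalar loss value.
#' @export
fape_loss <- function(pred_frames, true_frames, sequence,
                      cfg = loss_config(), templates = derive_templates()) {
  if (pred_frames$L != true_frames$L)
    stop("fape_loss: frame sets differ in length")
  ta <- .template_atoms(sequence, templates)
  fape_core(pred_frames, true_frames, ta, cfg$d_cut, cfg$epsilon,
            cfg$fape_reduce)$value
}

# ---- inter-N distance cross-entropy (38 bins over 2-40 Angstrom) ---------

#' Bin layout of the inter-N distance loss
#' @return Spec list with one term `dist_N38` usable with [discretize()].
#' @export
ndist_bin_spec <- function() {
  list(dist_N38 = list(kind = "distance", atoms = "N", n_content = 36L,
                       lo = 2, hi = 40, n_total = 38L))
}

.check_prob_slices <- function(p, tol = 1e-5, what = "probability") {
  sums <- apply(p, c(1, 2), sum)
  if (max(abs(sums - 1)) > tol)
    stop(what, " slices do not sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  invisible(TRUE)
}

#' Inter-N distance cross-entropy loss
#'
#' `-sum_ij sum_b y log p` over the 38 N-N distance bins (36 content
#' bins over 2-40 Angstrom plus < 2 and > 40), diagonal masked.
#'
#' @param pred_probs L x L x 38 array of predicted bin probabilities
#'   (each (i, j) slice summing to 1).
#' @param true_N_distances L x L matrix of target N-N distances
#'   (Angstrom), e.g. from [pairwise_distances()].
#' @return Scalar loss (summed over ordered pairs, as in the training
#'   objective).
#' @export
distance_ce <- function(pred_probs, true_N_distances) {
  L <- dim(pred_probs)[1]
  stopifnot(dim(pred_probs)[2] == L, dim(pred_probs)[3] == 38L,
            all(dim(true_N_distances) == c(L, L)))
  .check_prob_slices(pred_probs, what = "distance_ce: probability")
  labels <- discretize(true_N_distances, ndist_bin_spec(), "dist_N38")
  total <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    p <- max(pred_probs[i, j, labels[i, j]], 1e-12)
    total <- total - log(p)
  }
  total
}

#' Geometry cross-entropy loss
#'
#' Weighted sum over the six geometry terms of the label cross-entropy,
#' with weight 1.0 for distance terms and 0.5 for dihedral terms.
#'
#' @param pred named list over `GEOMETRY_TERMS` of L x L x bins arrays.
#' @param labels named list of L x L integer label matrices, as from
#'   [geometry_labels()].
#' @param cfg a [loss_config()].
#' @return Scalar loss.
#' @export
geometry_ce <- function(pred, labels, cfg = loss_config()) {
  missing <- setdiff(GEOMETRY_TERMS, names(pred))
  if (length(missing))
    stop("geometry_ce: missing term(s): ", paste(missing, collapse = ", "))
  total <- 0
  for (term in GEOMETRY_TERMS) {
    w <- if (startsWith(term, "dist")) cfg$w_distance else cfg$w_dihedral
    p <- pred[[term]]
    .check_prob_slices(p, what = paste0("geometry_ce: ", term))
    lab <- labels[[term]]
    L <- dim(p)[1]
    for (i in seq_len(L)) for (j in seq_len(L)) {
      if (i == j || is.na(lab[i, j])) next
      total <- total - w * log(max(p[i, j, lab[i, j]], 1e-12))
    }
  }
  total
}

#' Combined end-to-end training loss
#'
#' @param fape FAPE loss value.
#' @param dist_ce inter-N distance cross-entropy value.
#' @param cfg a [loss_config()] (weights 1.5 and 0.6 by default).
#' @return `fape_weight * fape + dist_weight * dist_ce`.
#' @export
e2e_total <- function(fape, dist_ce, cfg = loss_config()) {
  cfg$fape_weight * fape + cfg$dist_weight * dist_ce
}
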