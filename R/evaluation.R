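# Model-quality metrics: P-atom RMSD, TM-score, interaction network
# fidelity (INF), deformation index (DI), handedness, and a simplified
# heavy-atom clash estimate.

#' Interaction set
#'
#' Base interactions of a structure, split by category: Watson-Crick
#' (wc), non-Watson-Crick (nwc) and stacking.
#'
#' @param wc,nwc,stack each a list of length-2 index vectors or a 2-column
#'   matrix of unordered residue pairs (1-based).
#' @param L sequence length (for index validation).
#' @return Object of class `interaction_set`.
#' @export
interaction_set <- function(wc = list(), nwc = list(), stack = list(),
                            L = NULL) {
  norm <- function(x) {
    if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(r) x[r, ])
    x <- lapply(x, function(p) sort(as.integer(p)))
    if (length(x)) {
      key <- vapply(x, paste, character(1), collapse = "-")
      if (anyDuplicated(key)) stop("interaction_set: duplicate pairs")
      if (!is.null(L) && any(unlist(x) < 1 | unlist(x) > L))
        stop("interaction_set: index out of range")
    }
    x
  }
  structure(list(wc = norm(wc), nwc = norm(nwc), stack = norm(stack),
                 L = L),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("<interaction_set>", length(x$wc), "WC,", length(x$nwc), "nWC,",
      length(x$stack), "stacking\n")
  invisible(x)
}

.as_coords <- function(x, atom = "P") {
  if (inherits(x, "bead_structure")) bead_atom(x, atom)
  else if (inherits(x, "full_atom_structure")) fa_atom_coords(x, atom)
  else as.matrix(x)
}

#' Optimal superposition RMSD
#'
#' Kabsch-optimal rigid superposition of one bead atom type (default P,
#' the usual choice for RNA topology evaluation).
#'
#' @param a,b `bead_structure`s (or n x 3 coordinate matrices) with 1:1
#'   residue correspondence.
#' @param atom bead atom used ("P", "C4'", "N").
#' @return RMSD in Angstrom, with the aligning `rigid_frame` (mapping
#'   `a` onto `b`) as attribute `frame`.
#' @export
superpose_rmsd <- function(a, b, atom = "P") {
  xa <- .as_coords(a, atom); xb <- .as_coords(b, atom)
  if (nrow(xa) != nrow(xb)) stop("superpose_rmsd: length mismatch")
  f <- kabsch_frame(xa, xb)
  out <- attr(f, "rmsd")
  attr(out, "frame") <- f
  out
}

# RNA-specific TM-score normalization length scale (piecewise table for
# short chains, square-root law from L = 30)
tm_d0 <- function(L) {
  if (L <= 11) 0.3
  else if (L <= 15) 0.4
  else if (L <= 19) 0.5
  else if (L <= 23) 0.6
  else if (L < 30) 0.7
  else 0.6 * sqrt(L - 0.5) - 2.5
}

.tm_under <- function(xa_fit, xb, d0) {
  d2 <- rowSums((xa_fit - xb)^2)
  sum(1 / (1 + d2 / d0^2)) / nrow(xb)
}

#' Template-modeling score (TM-score) for equal-length structures
#'
#' `max over superpositions of (1/L) sum_i 1 / (1 + (d_i/d0)^2)` with
#' the RNA d0, maximized by a fragment-seeded iterative search: initial
#' superpositions from sliding fragments (full length, halves and
#' 4-residue windows), each refined by alternating subset selection
#' (d_i < cutoff) and re-superposition.
#'
#' @param model,target `bead_structure`s or n x 3 matrices (P atoms
#'   used), equal length, 1:1 correspondence.
#' @param atom bead atom for scoring.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, target, atom = "P") {
  xa <- .as_coords(model, atom); xb <- .as_coords(target, atom)
  if (nrow(xa) != nrow(xb)) stop("tm_score: length mismatch")
  L <- nrow(xa)
  if (L < 3) stop("tm_score: need at least 3 residues")
  d0 <- tm_d0(L)
  frag_lens <- unique(pmax(3L, c(L, L %/% 2L, 4L)))
  best <- 0; best_f <- NULL
  for (fl in frag_lens) {
    starts <- unique(c(seq(1L, L - fl + 1L, by = max(1L, fl %/% 2L)),
                       L - fl + 1L))
    for (st in starts) {
      idx <- st:(st + fl - 1L)
      for (cut in c(8, 6, 4.5, 3.5, max(1.5, d0 + 0.5))) {
        sel <- idx
        for (iter in 1:20) {
          f <- kabsch_frame(xa[sel, , drop = FALSE],
                            xb[sel, , drop = FALSE])
          fit <- frame_apply(f, xa)
          tm <- .tm_under(fit, xb, d0)
          if (tm > best) { best <- tm; best_f <- f }
          d <- sqrt(rowSums((fit - xb)^2))
          new_sel <- which(d < cut)
          if (length(new_sel) < 3) new_sel <- order(d)[1:3]
          if (length(new_sel) == length(sel) && all(new_sel == sel)) break
          sel <- new_sel
        }
      }
    }
  }
  # local polish of the best superposition (TM is a max over rigid
  # motions; the fragment search only locates the basin)
  if (!is.null(best_f)) {
    par0 <- c(matrix_to_rotvec(best_f$R), best_f$t)
    negtm <- function(p) {
      fit <- sweep(xa %*% t(rotvec_to_matrix(p[1:3])), 2, p[4:6], "+")
      -.tm_under(fit, xb, d0)
    }
    pol <- stats::optim(par0, negtm,
                        control = list(maxit = 800, reltol = 1e-12))
    best <- max(best, -pol$value)
  }
  best
}

# confusion counts of pair sets over the C(L, 2) universe
.pair_confusion <- function(ref, pred, L) {
  key <- function(ps) vapply(ps, paste, character(1), collapse = "-")
  kr <- key(ref); kp <- key(pred)
  tp <- length(intersect(kr, kp))
  fp <- length(setdiff(kp, kr))
  fn <- length(setdiff(kr, kp))
  tn <- choose(L, 2) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

.mcc <- function(cc) {
  denom <- sqrt((cc["tp"] + cc["fp"]) * (cc["tp"] + cc["fn"]) *
                  (cc["tn"] + cc["fp"]) * (cc["tn"] + cc["fn"]))
  if (denom == 0) return(NA_real_)
  unname((cc["tp"] * cc["tn"] - cc["fp"] * cc["fn"]) / denom)
}

.ppv_tpr <- function(cc) {
  if (cc["tp"] + cc["fp"] == 0 || cc["tp"] + cc["fn"] == 0)
    return(NA_real_)
  unname(sqrt((cc["tp"] / (cc["tp"] + cc["fp"])) *
                (cc["tp"] / (cc["tp"] + cc["fn"]))))
}

#' Interaction network fidelity (INF)
#'
#' Matthews correlation coefficient between the reference and predicted
#' interactions over the residue-pair universe, per category (wc, nwc,
#' stack) and pooled over all interactions (INF_all).  The
#' `sqrt(PPV * TPR)` variant is also reported.
#'
#' @param ref,pred `interaction_set`s on the same length.
#' @param L sequence length (defaults from `ref`).
#' @return Data frame with columns `category`, `inf` (MCC),
#'   `inf_ppv_tpr`, and the confusion counts; categories with an empty
#'   reference are NA.
#' @export
inf_score <- function(ref, pred, L = ref$L) {
  if (is.null(L)) stop("inf_score: sequence length required")
  cats <- c("wc", "nwc", "stack")
  rows <- list()
  for (cat in cats) {
    cc <- .pair_confusion(ref[[cat]], pred[[cat]], L)
    rows[[cat]] <- data.frame(category = cat,
      inf = if (length(ref[[cat]])) .mcc(cc) else NA_real_,
      inf_ppv_tpr = if (length(ref[[cat]])) .ppv_tpr(cc) else NA_real_,
      tp = cc["tp"], fp = cc["fp"], fn = cc["fn"], tn = cc["tn"])
  }
  allr <- unique(c(ref$wc, ref$nwc, ref$stack))
  allp <- unique(c(pred$wc, pred$nwc, pred$stack))
  cc <- .pair_confusion(allr, allp, L)
  rows$all <- data.frame(category = "all",
    inf = if (length(allr)) .mcc(cc) else NA_real_,
    inf_ppv_tpr = if (length(allr)) .ppv_tpr(cc) else NA_real_,
    tp = cc["tp"], fp = cc["fp"], fn = cc["fn"], tn = cc["tn"])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Deformation index
#'
#' RMSD between the optimally aligned structures divided by the overall
#' interaction network fidelity (negative INF values are floored at 0
#' first, making the index undefined).
#'
#' @param rmsd superposition RMSD (Angstrom).
#' @param inf_all pooled INF value.
#' @return `rmsd / inf_all`; NA with a warning when `inf_all <= 0`.
#' @export
di_score <- function(rmsd, inf_all) {
  inf_all <- max(0, inf_all)
  if (!is.finite(inf_all) || inf_all == 0) {
    warning("di_score: INF_all is zero; deformation index undefined")
    return(NA_real_)
  }
  rmsd / inf_all
}

# C4' pseudotorsion tau(i) over the window (i-1, i, i+1, i+2)
.pseudotorsions <- function(s) {
  C4 <- .as_coords(s, "C4'")
  L <- nrow(C4)
  tau <- rep(NA_real_, L)
  if (L >= 4)
    tau[2:(L - 2)] <- dihedral_points(C4[1:(L - 3), , drop = FALSE],
                                      C4[2:(L - 2), , drop = FALSE],
                                      C4[3:(L - 1), , drop = FALSE],
                                      C4[4:L, , drop = FALSE])
  tau
}

.circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Handedness score
#'
#' Fraction of non-loop (base-paired) residues whose C4' pseudotorsion
#' in the model is closer (circular distance) to the target's than to
#' the mirror image's (the negated torsion).  Ties count as "not
#' closer": they stay in the denominator but not the numerator.
#'
#' @param model,target `bead_structure`s of equal length.
#' @param ss reference `secondary_structure` defining non-loop residues.
#' @return Fraction in [0, 1]; NA if no residue is eligible.
#' @export
handedness <- function(model, target, ss) {
  tm <- .pseudotorsions(model)
  tt <- .pseudotorsions(target)
  nonloop <- classify_loops(ss)
  elig <- which(nonloop & is.finite(tm) & is.finite(tt))
  if (!length(elig)) return(NA_real_)
  closer <- .circ_dist(tm[elig], tt[elig]) < .circ_dist(tm[elig], -tt[elig])
  sum(closer) / length(elig)
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80)

#' Simplified clash estimate
#'
#' Counts non-bonded heavy-atom pairs whose van der Waals overlap
#' (sum of radii minus distance) is at least 0.4 Angstrom, excluding
#' same-residue pairs and the backbone-linkage neighborhood, normalized
#' per 1000 atoms.  A documented approximation, not MolProbity.
#'
#' @param s A `full_atom_structure`.
#' @param overlap_cut overlap threshold (Angstrom).
#' @return List with `n_clashes`, `per_1000` and `n_atoms`.
#' @export
clash_estimate <- function(s, overlap_cut = 0.4) {
  n <- nrow(s$xyz)
  el <- atom_element(s$atom)
  r <- VDW_RADII[el]
  r[is.na(r)] <- 1.7
  dm <- as.matrix(stats::dist(s$xyz))
  rsum <- outer(r, r, "+")
  same <- outer(s$resno, s$resno, "==")
  fwd <- outer(s$resno, s$resno, function(a, b) b - a == 1)
  linkset_a <- s$atom %in% c("C3'", "O3'", "C2'")
  linkset_b <- s$atom %in% c("P", "OP1", "OP2", "O5'")
  lm <- outer(linkset_a, linkset_b, "&") & fwd
  excl <- same | lm | t(lm)
  overlap <- rsum - dm
  overlap[excl] <- -Inf
  overlap[upper.tri(overlap, diag = TRUE)] <- -Inf
  ncl <- sum(overlap >= overlap_cut)
  list(n_clashes = ncl, per_1000 = ncl / n * 1000, n_atoms = n)
}

#' Detect Watson-Crick pairs from a full-atom structure
#'
#' Geometric criterion: complementary bases (A-U, G-C) whose purine N1
#' to pyrimidine N3 distance is below `hbond_cut` and whose C1'-C1'
#' distance lies in the canonical pairing window.
#'
#' @param s A `full_atom_structure`.
#' @param hbond_cut N1-N3 distance cutoff (Angstrom).
#' @param c1_range allowed C1'-C1' distance window (Angstrom).
#' @return An `interaction_set` with the detected `wc` pairs.
#' @export
detect_wc_pairs <- function(s, hbond_cut = 3.4, c1_range = c(8.5, 11.5)) {
  seqc <- fa_sequence(s)
  L <- length(seqc)
  glyco_n <- ifelse(seqc %in% c("A", "G"), "N9", "N1")
  N1 <- fa_atom_coords(s, "N1")     # purine N1 rows valid for A/G
  N3 <- fa_atom_coords(s, "N3")
  C1 <- fa_atom_coords(s, "C1'")
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  pairs <- list()
  taken <- rep(FALSE, L)
  cand <- list()
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j <= i) next
    pu <- if (seqc[i] %in% c("A", "G")) i else if (seqc[j] %in% c("A", "G")) j
          else next
    py <- if (pu == i) j else i
    if (!(seqc[py] %in% c("U", "C"))) next
    if (comp[[seqc[pu]]] != seqc[py]) next
    dnn <- sqrt(sum((N1[pu, ] - N3[py, ])^2))
    dcc <- sqrt(sum((C1[i, ] - C1[j, ])^2))
    if (is.finite(dnn) && dnn < hbond_cut &&
        is.finite(dcc) && dcc >= c1_range[1] && dcc <= c1_range[2])
      cand[[length(cand) + 1]] <- c(i, j, dnn)
  }
  if (length(cand)) {
    ord <- order(vapply(cand, `[`, numeric(1), 3))
    for (k in ord) {
      i <- cand[[k]][1]; j <- cand[[k]][2]
      if (taken[i] || taken[j]) next
      taken[i] <- taken[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  interaction_set(wc = pairs, L = L)
}

#' Score a model against a target (summary table)
#'
#' @param model,target `bead_structure`s (equal length).
#' @param ss optional reference `secondary_structure` (for handedness).
#' @param ref_interactions,pred_interactions optional `interaction_set`s
#'   for INF/DI.
#' @param model_fa optional `full_atom_structure` for the clash estimate.
#' @return One-row data frame of metric values.
#' @export
score_model <- function(model, target, ss = NULL,
                        ref_interactions = NULL,
                        pred_interactions = NULL, model_fa = NULL) {
  rmsd <- superpose_rmsd(model, target)
  tm <- tm_score(model, target)
  out <- data.frame(rmsd_p = as.numeric(rmsd), tm_score = tm)
  if (!is.null(ref_interactions) && !is.null(pred_interactions)) {
    inf <- inf_score(ref_interactions, pred_interactions)
    out$inf_wc <- inf$inf[inf$category == "wc"]
    out$inf_nwc <- inf$inf[inf$category == "nwc"]
    out$inf_stack <- inf$inf[inf$category == "stack"]
    out$inf_all <- inf$inf[inf$category == "all"]
    out$di <- if (is.na(out$inf_all)) NA_real_ else
      suppressWarnings(di_score(out$rmsd_p, out$inf_all))
  }
  if (!is.null(ss)) out$handedness <- handedness(model, target, ss)
  if (!is.null(model_fa)) out$clash_per_1000 <-
    clash_estimate(model_fa)$per_1000
  out
}
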