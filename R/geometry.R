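# Inter-nucleotide geometry terms: three bead-atom distances and three
# long-range pair dihedrals, plus their discretization onto the fixed
# bin layout used by the geometry restraints.

#' Bin specification for the six geometry terms
#'
#' Distance terms (P-P, C4'-C4', N-N) have 56 / 44 / 32 uniform content
#' bins over [2, 30], [2, 24] and [2, 18] Angstrom, plus two extra bins
#' (< 2 and >= M, the range maximum).  Dihedral terms (P-C4'-C4'-P,
#' C4'-N-N-C4', P-N-N-P) have 36 uniform bins over (-pi, pi] plus one
#' extra bin taken whenever the gating virtual bond (C4'-C4' for PCCP,
#' N-N for CNNC and PNNP) is at least its maximum distance M.
#'
#' @return Named list of term specs (`dist_PP`, `dist_CC`, `dist_NN`,
#'   `dih_PCCP`, `dih_CNNC`, `dih_PNNP`), each with fields `kind`,
#'   `atoms`, `n_content`, `lo`, `hi`, `n_total`, and for dihedrals
#'   `gate_atom`/`gate_max`.
#' @export
geometry_bin_spec <- function() {
  dist_spec <- function(atom, n, hi)
    list(kind = "distance", atoms = atom, n_content = n, lo = 2, hi = hi,
         n_total = n + 2L)
  dih_spec <- function(atoms, gate_atom, gate_max)
    list(kind = "dihedral", atoms = atoms, n_content = 36L, lo = -pi,
         hi = pi, n_total = 37L, gate_atom = gate_atom,
         gate_max = gate_max)
  list(
    dist_PP = dist_spec("P", 56L, 30),
    dist_CC = dist_spec("C4'", 44L, 24),
    dist_NN = dist_spec("N", 32L, 18),
    dih_PCCP = dih_spec(c("P", "C4'", "C4'", "P"), "C4'", 24),
    dih_CNNC = dih_spec(c("C4'", "N", "N", "C4'"), "N", 18),
    dih_PNNP = dih_spec(c("P", "N", "N", "P"), "N", 18)
  )
}

#' Names of the six geometry terms, in canonical order
#' @format Character vector of length 6.
#' @export
GEOMETRY_TERMS <- c("dist_PP", "dist_CC", "dist_NN",
                    "dih_PCCP", "dih_CNNC", "dih_PNNP")

#' Pairwise distances between one bead atom across residues
#'
#' @param s A `bead_structure`.
#' @param atom one of "P", "C4'", "N".
#' @return Symmetric L x L matrix (Angstrom), zero diagonal; rows and
#'   columns of masked residues are NA.
#' @export
pairwise_distances <- function(s, atom = c("P", "C4'", "N")) {
  atom <- match.arg(atom)
  x <- bead_atom(s, atom)
  q <- rowSums(x^2)
  d2 <- outer(q, q, "+") - 2 * (x %*% t(x))
  d <- sqrt(pmax(d2, 0))
  diag(d) <- 0
  if (any(!s$mask)) { d[!s$mask, ] <- NA_real_; d[, !s$mask] <- NA_real_ }
  d
}

# signed dihedral for matrices of quadruple points (rows) -> radians
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cr(n1, n2) * b2) / nb2
  th <- atan2(y, x)
  deg <- rowSums(n1^2) < 1e-16 | rowSums(n2^2) < 1e-16 | nb2 < 1e-12
  th[deg] <- NA_real_
  th
}

#' Long-range dihedral of one residue pair
#'
#' Schemes: "PCCP" = P(i)-C4'(i)-C4'(j)-P(j), "CNNC" =
#' C4'(i)-N(i)-N(j)-C4'(j), "PNNP" = P(i)-N(i)-N(j)-P(j).  Standard
#' signed dihedral in (-pi, pi], IUPAC convention; a degenerate
#' (collinear) quadruple yields NA, mapped downstream to the extra bin.
#'
#' @param s A `bead_structure`.
#' @param i,j residue indices, i != j.
#' @param scheme one of "PCCP", "CNNC", "PNNP".
#' @return Dihedral angle in radians.
#' @export
pair_dihedral <- function(s, i, j, scheme = c("PCCP", "CNNC", "PNNP")) {
  scheme <- match.arg(scheme)
  if (i == j) stop("pair_dihedral: i and j must differ")
  at <- switch(scheme,
               PCCP = c("P", "C4'", "C4'", "P"),
               CNNC = c("C4'", "N", "N", "C4'"),
               PNNP = c("P", "N", "N", "P"))
  idx <- match(at, BEAD_ATOMS)
  dihedral_points(matrix(s$coords[i, idx[1], ], 1),
                  matrix(s$coords[i, idx[2], ], 1),
                  matrix(s$coords[j, idx[3], ], 1),
                  matrix(s$coords[j, idx[4], ], 1))
}

#' All pairwise dihedrals of one scheme
#' @inheritParams pair_dihedral
#' @return L x L matrix of angles (radians); NA on the diagonal and for
#'   degenerate quadruples.
#' @export
pairwise_dihedrals <- function(s, scheme = c("PCCP", "CNNC", "PNNP")) {
  scheme <- match.arg(scheme)
  at <- switch(scheme,
               PCCP = c("P", "C4'", "C4'", "P"),
               CNNC = c("C4'", "N", "N", "C4'"),
               PNNP = c("P", "N", "N", "P"))
  idx <- match(at, BEAD_ATOMS)
  L <- s$L
  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  a1 <- matrix(s$coords[, idx[1], ], ncol = 3)[ii, , drop = FALSE]
  a2 <- matrix(s$coords[, idx[2], ], ncol = 3)[ii, , drop = FALSE]
  a3 <- matrix(s$coords[, idx[3], ], ncol = 3)[jj, , drop = FALSE]
  a4 <- matrix(s$coords[, idx[4], ], ncol = 3)[jj, , drop = FALSE]
  th <- dihedral_points(a1, a2, a3, a4)
  m <- matrix(th, L, L)          # column-major: [i, j] for ii fast index
  diag(m) <- NA_real_
  if (any(!s$mask)) { m[!s$mask, ] <- NA_real_; m[, !s$mask] <- NA_real_ }
  m
}

#' Discretize geometry values onto a term's bin layout
#'
#' Distance terms: bin 1 is d < 2 Angstrom, content bins are half-open
#' `[lo + (k-1) w, lo + k w)`, the last bin is d >= M.  Dihedral terms:
#' 36 half-open bins over [-pi, pi) with +pi wrapped into the last
#' content bin; whenever the gating virtual-bond length is >= M (or the
#' angle is undefined) the extra bin `n_content + 1` is taken regardless
#' of the angle.
#'
#' @param values numeric vector/matrix of distances (Angstrom) or
#'   dihedrals (radians).
#' @param spec the bin-spec list from [geometry_bin_spec()].
#' @param term term name, e.g. "dist_PP".
#' @param gate_lengths for dihedral terms, the virtual-bond lengths
#'   (same shape as `values`) used for the beyond-M gate.
#' @return Integer bin indices (1-based), same shape as `values`.
#' @export
discretize <- function(values, spec = geometry_bin_spec(), term,
                       gate_lengths = NULL) {
  sp <- spec[[term]]
  if (is.null(sp)) stop("discretize: unknown term ", term)
  v <- values
  if (sp$kind == "distance") {
    w <- (sp$hi - sp$lo) / sp$n_content
    idx <- ifelse(v < sp$lo, 1L,
           ifelse(v >= sp$hi, sp$n_total,
                  1L + 1L + as.integer(floor((v - sp$lo) / w))))
    idx <- pmin(idx, sp$n_total)
  } else {
    w <- 2 * pi / sp$n_content
    vv <- v
    vv[!is.na(vv) & vv >= pi] <- pi - 1e-12      # wrap +pi into last bin
    vv[!is.na(vv) & vv < -pi] <- -pi
    idx <- 1L + as.integer(floor((vv + pi) / w))
    idx <- pmin(pmax(idx, 1L), sp$n_content)
    gate <- is.na(v)
    if (!is.null(gate_lengths)) gate <- gate | (gate_lengths >= sp$gate_max)
    idx[gate] <- sp$n_total
  }
  if (!is.null(dim(values))) idx <- array(idx, dim(values))
  idx
}

#' Geometry labels for every term of a structure
#'
#' The supervised targets of the geometry models: per term an L x L
#' integer matrix of bin indices (diagonal NA).
#'
#' @param s A `bead_structure`.
#' @param spec bin spec from [geometry_bin_spec()].
#' @return Named list of L x L integer matrices over `GEOMETRY_TERMS`.
#' @export
geometry_labels <- function(s, spec = geometry_bin_spec()) {
  dists <- list(dist_PP = pairwise_distances(s, "P"),
                dist_CC = pairwise_distances(s, "C4'"),
                dist_NN = pairwise_distances(s, "N"))
  out <- list()
  for (term in c("dist_PP", "dist_CC", "dist_NN")) {
    lab <- discretize(dists[[term]], spec, term)
    diag(lab) <- NA_integer_
    out[[term]] <- lab
  }
  gates <- list(dih_PCCP = dists$dist_CC, dih_CNNC = dists$dist_NN,
                dih_PNNP = dists$dist_NN)
  for (term in c("dih_PCCP", "dih_CNNC", "dih_PNNP")) {
    scheme <- sub("dih_", "", term)
    th <- pairwise_dihedrals(s, scheme)
    lab <- discretize(th, spec, term, gate_lengths = gates[[term]])
    diag(lab) <- NA_integer_
    out[[term]] <- lab
  }
  out
}
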