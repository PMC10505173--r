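# Full-atom RNA structures: a flat atom table plus an n x 3 coordinate
# matrix.  Single chain, 1-based residue numbering.

#' Full-atom RNA structure
#'
#' @param atom character vector of atom names (PDB v3 nomenclature,
#'   primes as in C4').
#' @param resno integer vector of residue numbers (1-based).
#' @param resid character vector of residue types (A/U/G/C).
#' @param xyz n x 3 numeric matrix of coordinates (Angstrom).
#' @param chain single chain identifier.
#' @return Object of class `full_atom_structure`.
#' @export
full_atom_structure <- function(atom, resno, resid, xyz, chain = "A") {
  xyz <- as.matrix(xyz)
  n <- length(atom)
  stopifnot(length(resno) == n, length(resid) == n, nrow(xyz) == n,
            ncol(xyz) == 3L)
  structure(list(atom = as.character(atom), resno = as.integer(resno),
                 resid = as.character(resid), xyz = unname(xyz),
                 chain = chain),
            class = "full_atom_structure")
}

#' @export
print.full_atom_structure <- function(x, ...) {
  cat("<full_atom_structure>", length(unique(x$resno)), "residues,",
      length(x$atom), "atoms\n")
  invisible(x)
}

#' Element symbol from an RNA atom name
#' @param atom character vector of atom names.
#' @return character vector of element symbols.
#' @export
atom_element <- function(atom) {
  ifelse(atom == "P", "P", substr(gsub("[^A-Z]", "", atom), 1, 1))
}

#' Number of residues in a full-atom structure
#' @param s A `full_atom_structure`.
#' @export
fa_nres <- function(s) length(unique(s$resno))

#' Sequence of a full-atom structure
#' @param s A `full_atom_structure`.
#' @return character vector of residue types in residue order.
#' @export
fa_sequence <- function(s) {
  ord <- !duplicated(s$resno)
  s$resid[ord][order(unique(s$resno))]
}

#' Coordinates of one named atom per residue
#' @param s A `full_atom_structure`.
#' @param name atom name, e.g. "P" or "C4'".
#' @return L x 3 matrix (NA rows where the atom is absent).
#' @export
fa_atom_coords <- function(s, name) {
  resnos <- sort(unique(s$resno))
  out <- matrix(NA_real_, length(resnos), 3)
  sel <- s$atom == name
  idx <- match(s$resno[sel], resnos)
  out[idx, ] <- s$xyz[sel, , drop = FALSE]
  out
}

#' Extract the three-bead model from a full-atom structure
#'
#' Beads are P, C4', and the glycosidic nitrogen: N9 for purines (A, G),
#' N1 for pyrimidines (U, C).  Residues missing any bead atom are masked
#' with a warning.
#'
#' @param s A `full_atom_structure`.
#' @return A `bead_structure` with the structure's sequence attached.
#' @export
fa_extract_beads <- function(s) {
  seqc <- fa_sequence(s)
  L <- length(seqc)
  glyco <- ifelse(seqc %in% c("A", "G"), "N9", "N1")
  P <- fa_atom_coords(s, "P")
  C4 <- fa_atom_coords(s, "C4'")
  Nmat <- matrix(NA_real_, L, 3)
  resnos <- sort(unique(s$resno))
  for (i in seq_len(L)) {
    sel <- s$resno == resnos[i] & s$atom == glyco[i]
    if (any(sel)) Nmat[i, ] <- s$xyz[which(sel)[1], ]
  }
  coords <- array(NA_real_, c(L, 3, 3))
  coords[, 1, ] <- P; coords[, 2, ] <- C4; coords[, 3, ] <- Nmat
  mask <- apply(coords, 1, function(m) all(is.finite(m)))
  if (any(!mask))
    warning("fa_extract_beads: ", sum(!mask),
            " residue(s) missing bead atoms; masked")
  coords[!mask, , ] <- 0
  bead_structure(coords, mask = mask, sequence = seqc)
}

#' Apply a rigid frame to a full-atom structure
#' @param g A `rigid_frame`.
#' @param s A `full_atom_structure`.
#' @return The transformed structure.
#' @export
fa_transform <- function(g, s) {
  s$xyz <- frame_apply(g, s$xyz)
  s
}
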