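# Sequences and three-bead coarse-grained structures.

RNA_ALPHABET <- c("A", "U", "G", "C", "N")
BEAD_ATOMS <- c("P", "C4'", "N")   # fixed atom order everywhere

#' Validate an RNA sequence
#'
#' Residues are over the 5-letter alphabet A/U/G/C/N, where N is the
#' unknown/degenerate state.
#'
#' @param x character vector of single letters, or a single string.
#' @return character vector of residues (class `nt_sequence`).
#' @export
nt_sequence <- function(x) {
  if (length(x) == 1L && nchar(x[1]) > 1L) x <- strsplit(x, "")[[1]]
  x <- toupper(x)
  if (length(x) < 1L) stop("nt_sequence: empty sequence")
  bad <- setdiff(unique(x), RNA_ALPHABET)
  if (length(bad))
    stop("nt_sequence: invalid symbols: ", paste(bad, collapse = ", "))
  structure(x, class = "nt_sequence")
}

#' @export
print.nt_sequence <- function(x, ...) {
  cat("<nt_sequence> L =", length(x), ":", paste(unclass(x), collapse = ""),
      "\n")
  invisible(x)
}

#' Read a single-record FASTA file as an RNA sequence
#'
#' T is silently mapped to U; letters outside A/U/G/C/T are mapped to N
#' with a warning.
#'
#' @param path path to a FASTA file with exactly one record.
#' @return An `nt_sequence`.
#' @export
read_fasta <- function(path) {
  txt <- if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("read_fasta: empty file: ", path)
    if (length(set) > 1L)
      warning("read_fasta: multiple records; using the first")
    as.character(set[[1]])
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("read_fasta: empty file: ", path)
    headers <- grep("^>", lines)
    if (!length(headers)) stop("read_fasta: no FASTA header in ", path)
    if (length(headers) > 1L) {
      warning("read_fasta: multiple records; using the first")
      lines <- lines[seq(headers[1], headers[2] - 1L)]
    }
    paste(lines[-1], collapse = "")
  }
  chars <- toupper(strsplit(gsub("\\s", "", txt), "")[[1]])
  if (!length(chars)) stop("read_fasta: record has an empty sequence")
  chars[chars == "T"] <- "U"
  unknown <- !(chars %in% c("A", "U", "G", "C"))
  if (any(chars[unknown] != "N") && any(unknown)) {
    bad <- unique(chars[unknown & chars != "N"])
    if (length(bad))
      warning("read_fasta: unknown letters mapped to N: ",
              paste(bad, collapse = ", "))
  }
  chars[unknown] <- "N"
  nt_sequence(chars)
}

#' Three-bead coarse-grained structure
#'
#' Per residue the (P, C4', N) coordinates in Angstrom, in that fixed
#' atom order; `mask` marks observed residues.
#'
#' @param coords L x 3 x 3 array: residue x atom (P, C4', N) x xyz.
#' @param mask logical length-L vector of observed residues.
#' @param sequence optional character vector of base types, kept as an
#'   attribute.
#' @return Object of class `bead_structure`.
#' @export
bead_structure <- function(coords, mask = NULL, sequence = NULL) {
  coords <- unname(coords)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[3] == 3L)
  L <- dim(coords)[1]
  if (is.null(mask)) mask <- rep(TRUE, L)
  stopifnot(length(mask) == L)
  if (any(!is.finite(coords[mask, , ])))
    stop("bead_structure: non-finite coordinates at observed residues")
  out <- structure(list(coords = coords, mask = as.logical(mask), L = L),
                   class = "bead_structure")
  if (!is.null(sequence)) {
    stopifnot(length(sequence) == L)
    attr(out, "sequence") <- as.character(sequence)
  }
  out
}

#' @export
print.bead_structure <- function(x, ...) {
  cat("<bead_structure> L =", x$L, "(", sum(x$mask), "observed )\n")
  invisible(x)
}

#' Coordinates of one bead atom across residues
#' @param s A `bead_structure`.
#' @param atom one of "P", "C4'", "N".
#' @return L x 3 matrix.
#' @export
bead_atom <- function(s, atom = c("P", "C4'", "N")) {
  atom <- match.arg(atom)
  idx <- match(atom, BEAD_ATOMS)
  matrix(s$coords[, idx, ], ncol = 3)
}

#' Mirror a structure through the z = 0 plane
#'
#' Negates every z coordinate.  All pairwise distances are preserved;
#' every dihedral angle changes sign, which is what makes chirality
#' detectable downstream (FAPE, handedness).
#'
#' @param s A `bead_structure`.
#' @return The mirrored `bead_structure`.
#' @export
mirror_structure <- function(s) {
  coords <- s$coords
  coords[, , 3] <- -coords[, , 3]
  bead_structure(coords, mask = s$mask, sequence = attr(s, "sequence"))
}

#' Mirror full-atom coordinates through the z = 0 plane
#' @param s A `full_atom_structure`.
#' @return The mirrored structure.
#' @export
mirror_full_atom <- function(s) {
  s$xyz[, 3] <- -s$xyz[, 3]
  s
}

#' Apply a rigid frame to a bead structure
#' @param g A `rigid_frame`.
#' @param s A `bead_structure`.
#' @return The transformed `bead_structure`.
#' @export
bead_transform <- function(g, s) {
  coords <- s$coords
  for (a in 1:3)
    coords[, a, ] <- sweep(matrix(coords[, a, ], ncol = 3) %*% t(g$R),
                           2, g$t, "+")
  bead_structure(coords, mask = s$mask, sequence = attr(s, "sequence"))
}
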