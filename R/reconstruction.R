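# Full-atom reconstruction from the three-bead model: rigid placement of
# per-base full-atom templates on the bead triads, fast local fixes that
# keep the bead model frozen, and a hook for external minimization.

WC_CONJUGATE <- c(A = "U", U = "A", G = "C", C = "G")

# resolve 'N' residues: U when unpaired, Watson-Crick conjugate of the
# partner when paired
.resolve_bases <- function(sequence, ss = NULL) {
  out <- sequence
  partner <- integer(length(sequence))
  if (!is.null(ss))
    for (p in ss$pair_table) { partner[p[1]] <- p[2]; partner[p[2]] <- p[1] }
  for (i in which(sequence == "N")) {
    if (partner[i] == 0) { out[i] <- "U"; next }
    pb <- sequence[partner[i]]
    if (pb == "N")
      stop("reconstruct_full_atom: residue ", i, " is 'N' paired with 'N' ",
           "at ", partner[i], "; base cannot be resolved")
    out[i] <- WC_CONJUGATE[[pb]]
  }
  out
}

#' Reconstruct a full-atom structure from a bead model
#'
#' For each residue the full-atom A-form template of its base type is
#' rigidly superposed onto the observed (P, C4', N) bead triad.
#' Residues typed 'N' are mutated to 'U' when unpaired or to the
#' Watson-Crick conjugate of their secondary-structure partner.
#'
#' @param beads A `bead_structure`.
#' @param sequence character base types (defaults to the sequence
#'   attached to `beads`).
#' @param ss optional `secondary_structure` (needed to resolve paired
#'   'N' residues).
#' @return A `full_atom_structure`.
#' @export
reconstruct_full_atom <- function(beads, sequence = attr(beads, "sequence"),
                                  ss = NULL) {
  if (is.null(sequence)) stop("reconstruct_full_atom: sequence required")
  sequence <- as.character(nt_sequence(sequence))
  L <- beads$L
  stopifnot(length(sequence) == L)
  bases <- .resolve_bases(sequence, ss)
  tmpl <- derive_templates()
  fa_tmpl <- full_atom_templates()
  atom <- character(0); resno <- integer(0); resid <- character(0)
  xyz <- NULL
  for (i in seq_len(L)) {
    if (!beads$mask[i]) next
    b <- bases[i]
    f <- frame_from_beads(matrix(beads$coords[i, , ], 3, 3), tmpl[[b]])
    u <- frame_apply(f, fa_tmpl[[b]])
    atom <- c(atom, rownames(fa_tmpl[[b]]))
    resno <- c(resno, rep(i, nrow(u)))
    resid <- c(resid, rep(b, nrow(u)))
    xyz <- rbind(xyz, u)
  }
  full_atom_structure(atom, resno, resid, xyz)
}

# frozen-bead mask: P, C4' and the glycosidic N of each residue
.bead_atom_mask <- function(s) {
  glyco <- ifelse(s$resid %in% c("A", "G"), "N9", "N1")
  s$atom == "P" | s$atom == "C4'" | s$atom == glyco
}

# backbone-continuity gate: O3'(i)-P(i+1) treated as bonded only when
# the bead geometry supports chain continuity
.linked_residues <- function(s, gate = 8) {
  resnos <- sort(unique(s$resno))
  C4 <- fa_atom_coords(s, "C4'"); P <- fa_atom_coords(s, "P")
  n <- length(resnos)
  if (n < 2) return(integer(0))
  ok <- vapply(seq_len(n - 1), function(k) {
    d <- sqrt(sum((C4[k, ] - P[k + 1, ])^2))
    is.finite(d) && d < gate
  }, logical(1))
  which(ok)                       # indices k with link k -> k+1
}

# current violations: backbone links off 1.6 A by > tol, and non-bonded
# heavy-atom pairs closer than `clash_d`
.violations <- function(s, clash_d = 2.0, bond_tol = 0.25) {
  links <- .linked_residues(s)
  resnos <- sort(unique(s$resno))
  bond <- list()
  for (k in links) {
    i1 <- which(s$resno == resnos[k] & s$atom == "O3'")
    i2 <- which(s$resno == resnos[k + 1] & s$atom == "P")
    if (!length(i1) || !length(i2)) next
    d <- sqrt(sum((s$xyz[i1, ] - s$xyz[i2, ])^2))
    if (abs(d - 1.6) > bond_tol)
      bond[[length(bond) + 1]] <- c(i1, i2, d)
  }
  n <- nrow(s$xyz)
  dm <- as.matrix(stats::dist(s$xyz))
  excl <- outer(s$resno, s$resno, "==")
  adj <- outer(s$resno, s$resno, function(a, b) abs(a - b) == 1)
  linkset_a <- s$atom %in% c("C3'", "O3'", "C2'")
  linkset_b <- s$atom %in% c("P", "OP1", "OP2", "O5'")
  fwd <- outer(s$resno, s$resno, function(a, b) b - a == 1)
  lm <- (outer(linkset_a, linkset_b, "&") & fwd)
  excl <- excl | lm | t(lm)
  dm[excl] <- Inf
  dm[upper.tri(dm, diag = TRUE)] <- Inf
  cl <- which(dm < clash_d, arr.ind = TRUE)
  list(bonds = bond, clashes = cl, dist = dm)
}

#' Fast local fixes on a reconstructed structure
#'
#' Damped gradient adjustment of non-bead atoms only: backbone
#' O3'-P(i+1) links are pulled toward 1.6 Angstrom and heavy-atom pairs
#' closer than 2.0 Angstrom are pushed apart.  The (P, C4', N) bead
#' atoms are bitwise frozen.
#'
#' @param s A `full_atom_structure`.
#' @param max_iter maximum relaxation sweeps.
#' @param step damping factor of each displacement.
#' @return The adjusted structure, with attribute `report`: counts of
#'   bond and clash violations before and after.
#' @export
fast_fixes <- function(s, max_iter = 100L, step = 0.4) {
  frozen <- .bead_atom_mask(s)
  v0 <- .violations(s)
  report <- list(bonds_before = length(v0$bonds),
                 clashes_before = nrow(v0$clashes))
  for (it in seq_len(max_iter)) {
    v <- .violations(s)
    if (!length(v$bonds) && !nrow(v$clashes)) break
    disp <- matrix(0, nrow(s$xyz), 3)
    for (b in v$bonds) {
      i1 <- b[1]; i2 <- b[2]; d <- b[3]
      u <- (s$xyz[i2, ] - s$xyz[i1, ]) / d
      corr <- (d - 1.6)
      if (!frozen[i1]) disp[i1, ] <- disp[i1, ] + corr * u / 2
      if (!frozen[i2]) disp[i2, ] <- disp[i2, ] - corr * u / 2
    }
    if (nrow(v$clashes)) for (r in seq_len(nrow(v$clashes))) {
      i1 <- v$clashes[r, 1]; i2 <- v$clashes[r, 2]
      d <- v$dist[i1, i2]
      u <- (s$xyz[i2, ] - s$xyz[i1, ]) / max(d, 1e-6)
      corr <- (2.0 - d)
      if (!frozen[i1]) disp[i1, ] <- disp[i1, ] - corr * u / 2
      if (!frozen[i2]) disp[i2, ] <- disp[i2, ] + corr * u / 2
    }
    s$xyz <- s$xyz + step * disp
  }
  v1 <- .violations(s)
  report$bonds_after <- length(v1$bonds)
  report$clashes_after <- nrow(v1$clashes)
  attr(s, "report") <- report
  s
}

#' External-minimizer refinement hook
#'
#' Computes the minimization step count `k * N_atoms / 20` (k = 0.6)
#' and, when an external command is configured, shells out to it with a
#' PDB round-trip; otherwise returns the input unchanged with a
#' warning.  The command receives the input and output PDB paths.
#'
#' @param s A `full_atom_structure`.
#' @param command external minimizer command template with placeholders
#'   `{in}`, `{out}`, `{steps}`; NULL disables.
#' @param k empirical step-count coefficient.
#' @return The refined (or unchanged) structure; attribute `steps`
#'   carries the computed step count.
#' @export
refinement_hook <- function(s, command = NULL, k = 0.6) {
  steps <- round(k * nrow(s$xyz) / 20)
  if (is.null(command)) {
    warning("refinement_hook: no external minimizer configured; ",
            "returning input unchanged (", steps, " steps would be run)")
    attr(s, "steps") <- steps
    return(s)
  }
  fin <- tempfile(fileext = ".pdb"); fout <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(fin, fout)))
  write_pdb(s, fin)
  cmd <- gsub("{in}", fin, gsub("{out}", fout,
              gsub("{steps}", steps, command, fixed = TRUE),
              fixed = TRUE), fixed = TRUE)
  status <- try(system(cmd), silent = TRUE)
  if (inherits(status, "try-error") || !file.exists(fout) ||
      (is.numeric(status) && status != 0)) {
    warning("refinement_hook: external tool failed; returning input")
    attr(s, "steps") <- steps
    return(s)
  }
  out <- read_pdb(fout)
  attr(out, "steps") <- steps
  out
}
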