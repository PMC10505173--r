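# File formats: PDB (via bio3d), the keyed-array restraint archive
# (JSON), dot-bracket files, and model checkpoints.

RESTRAINT_FORMAT_VERSION <- "1.0"

# short textual fingerprint of the bin layout, stored in archives so a
# mismatched reader fails loudly
.bin_spec_hash <- function(spec = geometry_bin_spec()) {
  paste(vapply(names(spec), function(t) {
    sp <- spec[[t]]
    paste0(t, ":", sp$n_content, ":", sp$lo, ":", round(sp$hi, 6))
  }, character(1)), collapse = ";")
}

#' Write a structure as PDB
#'
#' Single model, single chain, 1-based residue numbering.  A
#' `bead_structure` is written with its three bead atoms per residue.
#'
#' @param s A `full_atom_structure` or `bead_structure`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  if (inherits(s, "bead_structure")) {
    seqc <- attr(s, "sequence")
    if (is.null(seqc)) seqc <- rep("U", s$L)
    atom <- character(0); resno <- integer(0); resid <- character(0)
    xyz <- NULL
    for (i in seq_len(s$L)) {
      if (!s$mask[i]) next
      nm <- c("P", "C4'", glyco_atom(seqc[i]))
      atom <- c(atom, nm); resno <- c(resno, rep(i, 3))
      resid <- c(resid, rep(seqc[i], 3))
      xyz <- rbind(xyz, matrix(s$coords[i, , ], 3, 3))
    }
    s <- full_atom_structure(atom, resno, resid, xyz)
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(s$xyz)),
                   type = rep("ATOM", length(s$atom)),
                   resno = s$resno,
                   resid = s$resid,
                   eleno = seq_along(s$atom),
                   elety = s$atom,
                   chain = rep(s$chain, length(s$atom)),
                   elesy = atom_element(s$atom))
  invisible(path)
}

#' Read a single-chain RNA PDB file
#'
#' Accepts residues named A/U/G/C/N (one-letter or with common
#' prefixes); rejects multi-model, multi-chain and insertion-coded
#' files.
#'
#' @param path PDB file.
#' @return A `full_atom_structure`.
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("read_pdb: no ATOM records in ", path)
  chains <- unique(at$chain[!is.na(at$chain)])
  if (length(chains) > 1)
    stop("read_pdb: multiple chains (", paste(chains, collapse = ", "),
         "); single-chain files only")
  if (any(!is.na(at$insert)))
    stop("read_pdb: insertion codes are not supported")
  resid <- toupper(at$resid)
  resid <- sub("^R", "", resid)        # RA/RU/RG/RC naming
  map <- c(A = "A", U = "U", G = "G", C = "C", N = "N",
           ADE = "A", URA = "U", URI = "U", GUA = "G", CYT = "C")
  base <- map[resid]
  if (any(is.na(base)))
    stop("read_pdb: non-RNA residue(s): ",
         paste(unique(resid[is.na(base)]), collapse = ", "))
  resno_raw <- at$resno
  resno <- match(resno_raw, sort(unique(resno_raw)))   # 1-based, ordered
  full_atom_structure(at$elety, resno, unname(base),
                      cbind(at$x, at$y, at$z),
                      chain = if (length(chains)) chains[1] else "A")
}

#' Read a dot-bracket file
#'
#' First non-header, non-sequence line containing bracket/dot characters
#' is parsed.
#'
#' @param path text file.
#' @return A `secondary_structure`.
#' @export
read_dot_bracket <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  db <- grep("^[.()\\[\\]{}<>]+$", lines, value = TRUE)
  if (!length(db)) stop("read_dot_bracket: no dot-bracket line in ", path)
  parse_dot_bracket(db[1])
}

# ---- restraint archive (keyed JSON container) ----------------------------

#' Write a restraint archive
#'
#' Keyed-array container holding the six geometry probability tensors
#' and/or the K end-to-end frame arrays, with metadata (L, bin-spec
#' fingerprint, format version).  Serialized as JSON at full double
#' precision.
#'
#' @param path output file.
#' @param geometry A `geometry_restraints`, or NULL.
#' @param e2e An `e2e_prediction`, or NULL.
#' @return Invisibly, `path`.
#' @export
write_restraints <- function(path, geometry = NULL, e2e = NULL) {
  if (is.null(geometry) && is.null(e2e))
    stop("write_restraints: nothing to write")
  L <- if (!is.null(geometry)) geometry$L else e2e$L
  obj <- list(meta = list(L = L, version = RESTRAINT_FORMAT_VERSION,
                          bin_spec = .bin_spec_hash()))
  if (!is.null(geometry)) obj$geometry <- geometry$tensors
  if (!is.null(e2e)) {
    K <- e2e$K
    rot <- array(0, c(K, L, 3, 3)); tra <- array(0, c(K, L, 3))
    for (k in seq_len(K)) {
      rot[k, , , ] <- e2e$frame_sets[[k]]$R
      tra[k, , ] <- e2e$frame_sets[[k]]$t
    }
    obj$e2e <- list(rotations = rot, translations = tra)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a restraint archive
#'
#' @param path archive written by [write_restraints()].
#' @return List with `geometry` (a `geometry_restraints` or NULL),
#'   `e2e` (an `e2e_prediction` or NULL), and `meta`.
#' @export
read_restraints <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- obj$meta
  if (is.null(meta$L)) stop("read_restraints: missing metadata in ", path)
  if (!identical(meta$bin_spec, .bin_spec_hash()))
    stop("read_restraints: bin layout of ", path,
         " does not match this build")
  L <- as.integer(meta$L)
  out <- list(meta = meta, geometry = NULL, e2e = NULL)
  if (!is.null(obj$geometry)) {
    tens <- lapply(obj$geometry, function(a) {
      arr <- array(as.numeric(a), dim(a))
      if (dim(arr)[1] != L) stop("read_restraints: tensor/metadata ",
                                 "length mismatch")
      arr
    })
    out$geometry <- geometry_restraints(tens)
  }
  if (!is.null(obj$e2e)) {
    rot <- array(as.numeric(obj$e2e$rotations), dim(obj$e2e$rotations))
    tra <- array(as.numeric(obj$e2e$translations),
                 dim(obj$e2e$translations))
    if (dim(rot)[2] != L) stop("read_restraints: e2e/metadata mismatch")
    K <- dim(rot)[1]
    out$e2e <- e2e_prediction(lapply(seq_len(K), function(k)
      frame_set(array(rot[k, , , ], c(L, 3, 3)),
                matrix(tra[k, , ], L, 3))))
  }
  out
}

# ---- model checkpoints ----------------------------------------------------

#' Save a network model checkpoint
#'
#' Keyed-array container of named parameter matrices plus the config.
#'
#' @param model An `rna_model`.
#' @param path output file (JSON).
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  nms <- setdiff(ls(model$store), character(0))
  nms <- nms[!startsWith(nms, ".")]
  params <- lapply(nms, function(nm) model$store[[nm]])
  names(params) <- nms
  jsonlite::write_json(list(config = model$cfg, mode = model$mode,
                            seed = model$seed, rng = model$store$.rng,
                            params = params),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a network model checkpoint
#' @param path file written by [save_model()].
#' @return An `rna_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  int_fields <- setdiff(names(cfg), "double_starting_node")
  cfg[int_fields] <- lapply(cfg[int_fields], as.integer)
  model <- rna_model(do.call(network_config, cfg), obj$mode,
                     as.integer(obj$seed))
  for (nm in names(obj$params))
    model$store[[nm]] <- matrix(as.numeric(obj$params[[nm]]),
                                nrow(obj$params[[nm]]),
                                ncol(obj$params[[nm]]))
  model$store$.rng <- as.integer(obj$rng)
  model
}

#' Read an interactions annotation file
#'
#' Whitespace-delimited lines `category i j` with category one of
#' wc/nwc/stack and 1-based residue indices.
#'
#' @param path text file.
#' @param L sequence length for validation.
#' @return An `interaction_set`.
#' @export
read_interactions <- function(path, L = NULL) {
  tb <- utils::read.table(path, header = FALSE,
                          col.names = c("category", "i", "j"))
  tb$category <- tolower(tb$category)
  bad <- setdiff(unique(tb$category), c("wc", "nwc", "stack"))
  if (length(bad))
    stop("read_interactions: unknown category: ", paste(bad, collapse = ", "))
  get <- function(cat) {
    sel <- tb[tb$category == cat, , drop = FALSE]
    lapply(seq_len(nrow(sel)), function(r) c(sel$i[r], sel$j[r]))
  }
  interaction_set(wc = get("wc"), nwc = get("nwc"), stack = get("stack"),
                  L = L)
}
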