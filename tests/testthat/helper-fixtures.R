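# Shared fixtures, built in code and cached for the test session.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

fix_hairpin16 <- function() fixture("hairpin16", function() {
  seqc <- strsplit("GGGGGGAAAACCCCCC", "")[[1]]
  pairs <- lapply(1:6, function(i) c(i, 17 - i))
  h <- build_ideal_helix(seqc, pairs)
  list(sequence = seqc, pairs = pairs,
       ss = secondary_structure(pairs, 16),
       beads = h$beads, full_atom = h$full_atom)
})

fix_duplex8 <- function() fixture("duplex8", function() {
  make_reference("duplex", stem = 8, seed = 1)
})

fix_hairpin20 <- function() fixture("hairpin20", function() {
  make_reference("hairpin", stem = 8, loop = 4, seed = 3)
})

fix_templates <- function() fixture("templates", derive_templates)

fix_true_frames <- function() fixture("true_frames", function() {
  hp <- fix_hairpin16()
  frames_from_structure(hp$beads, fix_templates(), hp$sequence)
})

random_rigid <- function(seed = 1, trans_sd = 5) {
  set.seed(seed)
  rigid_frame(rotvec_to_matrix(rnorm(3)), rnorm(3, 0, trans_sd))
}

# uniform geometry restraints (every content bin equally likely)
uniform_restraints <- function(L) {
  spec <- geometry_bin_spec()
  out <- list()
  for (term in names(spec)) {
    sp <- spec[[term]]
    x <- array(0, c(L, L, sp$n_total))
    first <- if (sp$kind == "distance") 2L else 1L
    for (b in first:(first + sp$n_content - 1L))
      x[, , b] <- 1 / sp$n_content
    out[[term]] <- x
  }
  geometry_restraints(out)
}

p_rmsd <- function(a, b) as.numeric(superpose_rmsd(a, b, atom = "P"))
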