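# Oracle fixtures: synthetic stand-ins for the trained networks.
# Reference structures with known secondary structure, oracle geometry
# probability tensors sharpened around the true bins, noisy oracle
# end-to-end frame predictions, and controlled perturbations.

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Oracle configuration
#'
#' @param temperature softmax width over bin indices (bins; 0 gives
#'   one-hot restraints on the true bin).
#' @param noise_rot rotation noise of the e2e replicas (degrees, sd).
#' @param noise_trans translation noise of the e2e replicas
#'   (Angstrom, sd per axis, applied in the residue's local frame).
#' @param replicas number K of end-to-end replicas.
#' @param seed integer seed for the replica noise.
#' @return Named list of oracle settings.
#' @export
oracle_config <- function(temperature = 0.5, noise_rot = 5,
                          noise_trans = 1.0, replicas = 6L, seed = 1L) {
  stopifnot(temperature >= 0, replicas >= 1)
  list(temperature = temperature, noise_rot = noise_rot,
       noise_trans = noise_trans, replicas = as.integer(replicas),
       seed = as.integer(seed))
}

#' Deterministic reference structures with known secondary structure
#'
#' Kinds: "duplex" (stem self-paired end to end, L = 2 * stem),
#' "hairpin" (stem + loop, L = 2 * stem + loop), "junction" (two stems
#' with hairpin loops joined by single-stranded linkers, branch angle
#' pinned by the layout engine).
#'
#' @param kind one of "hairpin", "duplex", "junction".
#' @param stem stem length (base pairs; per stem for the junction).
#' @param loop loop length (nucleotides).
#' @param seed seed for the (Watson-Crick consistent) random sequence.
#' @return List with `sequence` (character vector), `ss`
#'   (`secondary_structure`), `beads` (`bead_structure`), `full_atom`
#'   (`full_atom_structure`).
#' @export
make_reference <- function(kind = c("hairpin", "duplex", "junction"),
                           stem = 6L, loop = 4L, seed = 1L) {
  kind <- match.arg(kind)
  stem <- as.integer(stem); loop <- as.integer(loop)
  draw_stem <- function(n) sample(c("G", "C", "A", "U"), n, replace = TRUE,
                                  prob = c(0.35, 0.35, 0.15, 0.15))
  comp <- function(x) unname(WC_PARTNER[x])
  built <- with_seed(seed, {
    if (kind == "duplex") {
      s5 <- draw_stem(stem)
      seqc <- c(s5, rev(comp(s5)))
      pairs <- lapply(seq_len(stem), function(i) c(i, 2L * stem + 1L - i))
    } else if (kind == "hairpin") {
      s5 <- draw_stem(stem)
      seqc <- c(s5, rep("A", loop), rev(comp(s5)))
      L <- 2L * stem + loop
      pairs <- lapply(seq_len(stem), function(i) c(i, L + 1L - i))
    } else {
      s1 <- draw_stem(stem); s2 <- draw_stem(stem)
      seqc <- c(s1, rep("A", loop), rev(comp(s1)), rep("U", 2L),
                s2, rep("A", loop), rev(comp(s2)))
      off2 <- 2L * stem + loop + 2L
      L2 <- 2L * stem + loop
      pairs <- c(lapply(seq_len(stem), function(i) c(i, L2 + 1L - i)),
                 lapply(seq_len(stem),
                        function(i) c(off2 + i, off2 + L2 + 1L - i)))
    }
    list(seqc = seqc, pairs = pairs)
  })
  h <- build_ideal_helix(built$seqc, built$pairs)
  list(sequence = built$seqc,
       ss = secondary_structure(built$pairs, length(built$seqc)),
       beads = h$beads, full_atom = h$full_atom)
}

#' Oracle geometry restraints from a reference structure
#'
#' Emulates the geometry-model outputs: per pair and term, probability
#' mass centered on the true bin and spread as a Gaussian over the bin
#' index (circular for dihedral terms), renormalized over the content
#' bins.  Pairs beyond the term's maximum distance put their mass on the
#' extra bin.
#'
#' @param ref A `bead_structure` reference.
#' @param cfg An [oracle_config()].
#' @return A `geometry_restraints`.
#' @export
oracle_geometry <- function(ref, cfg = oracle_config()) {
  spec <- geometry_bin_spec()
  labels <- geometry_labels(ref)
  L <- ref$L
  floor_p <- 1e-9
  out <- list()
  for (term in GEOMETRY_TERMS) {
    sp <- spec[[term]]
    nt <- sp$n_total; nc <- sp$n_content
    tens <- array(floor_p, c(L, L, nt))
    lab <- labels[[term]]
    content_first <- if (sp$kind == "distance") 2L else 1L
    for (i in seq_len(L)) for (j in seq_len(L)) {
      if (i == j || is.na(lab[i, j])) {
        tens[i, j, ] <- 1 / nt            # uninformative diagonal slice
        next
      }
      b <- lab[i, j]
      p <- rep(floor_p, nt)
      in_content <- b >= content_first & b < content_first + nc
      if (!in_content) {
        p[b] <- 1
      } else {
        bc <- b - content_first + 1L       # 1-based content index
        ks <- seq_len(nc)
        if (cfg$temperature <= 0) {
          w <- as.numeric(ks == bc)
        } else if (sp$kind == "dihedral") {
          dd <- pmin(abs(ks - bc), nc - abs(ks - bc))
          w <- exp(-dd^2 / (2 * cfg$temperature^2))
        } else {
          w <- exp(-(ks - bc)^2 / (2 * cfg$temperature^2))
        }
        p[content_first:(content_first + nc - 1L)] <-
          p[content_first:(content_first + nc - 1L)] + w
      }
      tens[i, j, ] <- p / sum(p)
    }
    out[[term]] <- tens
  }
  geometry_restraints(out)
}

#' Oracle end-to-end frame predictions from a reference structure
#'
#' K replicas of the true per-residue frames, each composed on the right
#' with seeded small-noise transforms (rotation angle ~ N(0, noise_rot),
#' local translation ~ N(0, noise_trans) per axis).
#'
#' @param ref A `bead_structure` reference (with attached sequence).
#' @param cfg An [oracle_config()].
#' @param templates template map.
#' @return An `e2e_prediction` of K frame sets.
#' @export
oracle_e2e <- function(ref, cfg = oracle_config(),
                       templates = derive_templates()) {
  fs <- frames_from_structure(ref, templates)
  L <- fs$L
  with_seed(cfg$seed, {
    reps <- lapply(seq_len(cfg$replicas), function(k) {
      R <- array(0, c(L, 3, 3)); t <- matrix(0, L, 3)
      for (i in seq_len(L)) {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ang <- rnorm(1, 0, cfg$noise_rot * pi / 180)
        dR <- rotvec_to_matrix(ax * ang)
        dt <- rnorm(3, 0, cfg$noise_trans)
        Ri <- matrix(fs$R[i, , ], 3, 3)
        R[i, , ] <- Ri %*% dR
        t[i, ] <- fs$t[i, ] + as.numeric(Ri %*% dt)
      }
      frame_set(R, t)
    })
    e2e_prediction(reps)
  })
}

#' Perturb a structure to a target P-RMSD
#'
#' Adds seeded Gaussian coordinate noise, iteratively rescaled so the
#' realized superposed P-atom RMSD to the reference is within 10% of the
#' target.
#'
#' @param ref A `bead_structure`.
#' @param rmsd_target target P-RMSD (Angstrom; 0 returns `ref`).
#' @param seed integer seed.
#' @return A perturbed `bead_structure`.
#' @export
perturb_structure <- function(ref, rmsd_target, seed = 1L) {
  stopifnot(rmsd_target >= 0)
  if (rmsd_target == 0) return(ref)
  with_seed(seed, {
    noise <- array(rnorm(length(ref$coords)), dim(ref$coords))
    scale <- rmsd_target
    out <- ref
    for (it in 1:12) {
      out$coords <- ref$coords + scale * noise
      f <- kabsch_frame(bead_atom(out, "P"), bead_atom(ref, "P"))
      realized <- attr(f, "rmsd")
      if (abs(realized - rmsd_target) <= 0.05 * rmsd_target) break
      scale <- scale * rmsd_target / realized
    }
    bead_structure(out$coords, mask = ref$mask,
                   sequence = attr(ref, "sequence"))
  })
}
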