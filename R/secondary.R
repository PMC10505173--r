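# Secondary-structure inputs: dot-bracket parsing, pair-feature tensors,
# loop classification.

#' Secondary structure
#'
#' @param pair_table list of length-2 integer vectors (i < j, 1-based).
#' @param L sequence length.
#' @param probability_map optional L x L matrix of base-pair
#'   probabilities in [0, 1]; must be symmetric.
#' @return Object of class `secondary_structure`.
#' @export
secondary_structure <- function(pair_table = list(), L,
                                probability_map = NULL) {
  pair_table <- lapply(pair_table, function(p) sort(as.integer(p)))
  if (length(pair_table)) {
    idx <- unlist(pair_table)
    if (any(idx < 1 | idx > L))
      stop("secondary_structure: pair index out of range")
    if (anyDuplicated(idx))
      stop("secondary_structure: residue in more than one pair")
  }
  if (!is.null(probability_map)) {
    probability_map <- as.matrix(probability_map)
    stopifnot(all(dim(probability_map) == c(L, L)))
    if (any(probability_map < 0 | probability_map > 1))
      stop("secondary_structure: probabilities outside [0, 1]")
    if (max(abs(probability_map - t(probability_map))) > 1e-9)
      stop("secondary_structure: probability map not symmetric")
  }
  structure(list(pair_table = pair_table, L = as.integer(L),
                 probability_map = probability_map),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> L =", x$L, ",", length(x$pair_table),
      "pairs", if (!is.null(x$probability_map)) "+ probability map", "\n")
  invisible(x)
}

BRACKET_OPEN <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

#' Parse a dot-bracket string
#'
#' Vienna dialect with up to four bracket layers (), [], {}, <> for
#' pseudoknotted structures; each layer is matched with its own stack.
#'
#' @param text dot-bracket string.
#' @return A `secondary_structure`.
#' @export
parse_dot_bracket <- function(text) {
  chars <- strsplit(text, "")[[1]]
  L <- length(chars)
  stacks <- rep(list(integer(0)), 4)
  pairs <- list()
  for (i in seq_len(L)) {
    ch <- chars[i]
    if (ch == ".") next
    k <- match(ch, BRACKET_OPEN)
    if (!is.na(k)) { stacks[[k]] <- c(stacks[[k]], i); next }
    k <- match(ch, BRACKET_CLOSE)
    if (!is.na(k)) {
      if (!length(stacks[[k]]))
        stop("parse_dot_bracket: unbalanced '", ch, "' at position ", i)
      j <- stacks[[k]][length(stacks[[k]])]
      stacks[[k]] <- stacks[[k]][-length(stacks[[k]])]
      pairs[[length(pairs) + 1]] <- c(j, i)
      next
    }
    stop("parse_dot_bracket: unexpected character '", ch,
         "' at position ", i)
  }
  open_left <- which(lengths(stacks) > 0)
  if (length(open_left))
    stop("parse_dot_bracket: unbalanced '",
         BRACKET_OPEN[open_left[1]], "' opened at position ",
         stacks[[open_left[1]]][1])
  pairs <- pairs[order(vapply(pairs, `[`, integer(1), 1))]
  secondary_structure(pairs, L)
}

#' Render a secondary structure as dot-bracket text
#'
#' Nested structures use round brackets; pseudoknot layers are assigned
#' greedily to the first non-crossing bracket layer.
#'
#' @param ss A `secondary_structure`.
#' @return A dot-bracket string.
#' @export
render_dot_bracket <- function(ss) {
  out <- rep(".", ss$L)
  layers <- list()
  for (p in ss$pair_table) {
    placed <- FALSE
    for (k in seq_along(layers)) {
      crossing <- any(vapply(layers[[k]], function(q)
        (q[1] < p[1] & p[1] < q[2] & q[2] < p[2]) |
        (p[1] < q[1] & q[1] < p[2] & p[2] < q[2]), logical(1)))
      if (!crossing) {
        layers[[k]] <- c(layers[[k]], list(p)); placed <- TRUE
        out[p[1]] <- BRACKET_OPEN[k]; out[p[2]] <- BRACKET_CLOSE[k]
        break
      }
    }
    if (!placed) {
      k <- length(layers) + 1
      if (k > 4) stop("render_dot_bracket: more than 4 pseudoknot layers")
      layers[[k]] <- list(p)
      out[p[1]] <- BRACKET_OPEN[k]; out[p[2]] <- BRACKET_CLOSE[k]
    }
  }
  paste(out, collapse = "")
}

#' Binary base-pair map of a secondary structure
#' @param ss A `secondary_structure`.
#' @return Symmetric L x L 0/1 matrix.
#' @export
pair_map <- function(ss) {
  m <- matrix(0, ss$L, ss$L)
  for (p in ss$pair_table) { m[p[1], p[2]] <- 1; m[p[2], p[1]] <- 1 }
  m
}

#' Build the L x L x 4 pair-feature tensor from two SS sources
#'
#' Channels 1 and 2 are the binary pair maps of sources a and b;
#' channels 3 and 4 their probability maps (zeros when absent).  When a
#' single source is supplied its channels are duplicated so the feature
#' contract stays fixed at four channels.
#'
#' @param ss_a,ss_b `secondary_structure` objects on the same length;
#'   `ss_b` may be NULL to duplicate `ss_a`.
#' @param L expected length (checked against both sources).
#' @return L x L x 4 array.
#' @export
build_pair_features <- function(ss_a, ss_b = NULL, L = ss_a$L) {
  if (is.null(ss_b)) ss_b <- ss_a
  if (ss_a$L != L || ss_b$L != L)
    stop("build_pair_features: length mismatch (", ss_a$L, ", ", ss_b$L,
         " vs L = ", L, ")")
  out <- array(0, c(L, L, 4))
  out[, , 1] <- pair_map(ss_a)
  out[, , 2] <- pair_map(ss_b)
  if (!is.null(ss_a$probability_map)) out[, , 3] <- ss_a$probability_map
  if (!is.null(ss_b$probability_map)) out[, , 4] <- ss_b$probability_map
  out
}

#' One-hot sequence features (L x 5 over A, U, G, C, N)
#' @param sequence An `nt_sequence` (or coercible).
#' @return L x 5 binary matrix.
#' @export
build_seq_features <- function(sequence) {
  seqc <- as.character(nt_sequence(sequence))
  m <- matrix(0, length(seqc), 5,
              dimnames = list(NULL, RNA_ALPHABET))
  m[cbind(seq_along(seqc), match(seqc, RNA_ALPHABET))] <- 1
  m
}

#' Classify residues as non-loop (base-paired) vs loop
#'
#' A residue is flagged non-loop iff it participates in a base pair of
#' the reference secondary structure; these are the helical, handed
#' regions targeted by the handedness metric.
#'
#' @param ss A `secondary_structure`.
#' @param L expected length.
#' @return Logical length-L vector (TRUE = non-loop).
#' @export
classify_loops <- function(ss, L = ss$L) {
  if (ss$L != L) stop("classify_loops: length mismatch")
  out <- rep(FALSE, L)
  for (p in ss$pair_table) out[p] <- TRUE
  out
}

#' Read an L x L probability matrix from a whitespace-delimited text file
#' @param path file with L rows of L numeric entries.
#' @return Numeric L x L matrix.
#' @export
read_prob_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("read_prob_matrix: matrix not square")
  m
}
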