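# Deterministic bit-fingerprint featurization of molecule and template
# identifiers. Synthetic universes use opaque tokens, so features are hash
# fingerprints: a fixed number of bit positions derived from the identifier
# by a seeded linear-congruential stream. Real-chemistry adapters would
# substitute a circular (Morgan, radius 2) fingerprint for molecules and a
# structural reaction fingerprint for templates, both folded to the same
# 2048 bits; the pair encoding and everything downstream are unchanged.

.FP_BITS <- 2048L
.FP_SET <- 32L
.LCG_M <- 2^31

# polynomial rolling hash of a string, modulo 2^31 (exact in doubles)
.str_hash <- function(x) {
  h <- 2166136261 %% .LCG_M
  for (b in utf8ToInt(x)) {
    h <- (h * 131 + b) %% .LCG_M
  }
  h
}

# cache of id -> sorted bit positions; values are pure functions of the id,
# so memoization is observationally transparent
.fp_cache <- new.env(parent = emptyenv())

#' Hash fingerprint bit positions for an identifier
#'
#' Maps an identifier string to a fixed set of bit positions in a
#' `nbits`-wide fingerprint. Deterministic: the same id always yields the
#' same positions. Distinct ids may collide on some or all positions; bit
#' collisions are an accepted property of folded fingerprints, never an
#' error.
#'
#' @param id Non-empty identifier string.
#' @param nbits Fingerprint width in bits.
#' @param nset Number of pseudo-random draws used to set bits (the number of
#'   distinct positions may be smaller when draws collide).
#' @return Sorted integer vector of 0-based bit positions.
#' @export
fingerprint_bits <- function(id, nbits = .FP_BITS, nset = .FP_SET) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  key <- paste0(nbits, "#", nset, "#", id)
  hit <- .fp_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- .str_hash(id)
  pos <- integer(nset)
  for (i in seq_len(nset)) {
    h <- (h * 69069 + 12345) %% .LCG_M
    pos[i] <- (h %/% 64) %% nbits
  }
  pos <- sort(unique(as.integer(pos)))
  assign(key, pos, envir = .fp_cache)
  pos
}

#' Featurize a (molecule, template) pair
#'
#' Concatenates the molecule fingerprint and the template fingerprint into
#' one vector of length `2 * nbits` (default 4096): positions
#' `[0, nbits)` hold the molecule half, `[nbits, 2*nbits)` the template
#' half. This is the input encoding of the experience guidance network.
#'
#' @param molecule_id,template_id Identifier strings.
#' @param nbits Width of each half.
#' @param sparse If `TRUE` (default) return the 0-based indices of set bits;
#'   if `FALSE` return the dense 0/1 numeric vector.
#' @return Integer index vector or numeric vector of length `2 * nbits`.
#' @export
featurize_pair <- function(molecule_id, template_id, nbits = .FP_BITS,
                           sparse = TRUE) {
  mb <- fingerprint_bits(molecule_id, nbits)
  tb <- fingerprint_bits(template_id, nbits)
  idx <- c(mb, tb + nbits)
  if (sparse) return(idx)
  v <- numeric(2L * nbits)
  v[idx + 1L] <- 1
  v
}

# sparse design matrix for a list of (molecule, template) id pairs
.pair_matrix <- function(molecule_ids, template_ids, nbits = .FP_BITS) {
  stopifnot(length(molecule_ids) == length(template_ids))
  n <- length(molecule_ids)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- featurize_pair(molecule_ids[i], template_ids[i], nbits)
  }
  nz <- lengths(rows)
  Matrix::sparseMatrix(
    i = rep.int(seq_len(n), nz),
    j = unlist(rows) + 1L,
    x = 1,
    dims = c(n, 2L * nbits)
  )
}

#' Tanimoto similarity between two fingerprints
#'
#' Intersection over union of set bits, the standard similarity for binary
#' molecular fingerprints. Two empty fingerprints have similarity 0.
#'
#' @param bits_a,bits_b Integer vectors of set-bit positions.
#' @return Similarity in \eqn{[0, 1]}.
#' @export
tanimoto <- function(bits_a, bits_b) {
  u <- length(union(bits_a, bits_b))
  if (u == 0L) return(0)
  length(intersect(bits_a, bits_b)) / u
}
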