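## Molecular operations backed by the RDKit bridge: canonicalization,
## SMILES randomization, descriptors, scaffolds and fingerprints.

#' Canonicalize SMILES strings
#'
#' Maps every SMILES of a molecule to the toolkit-canonical form; the
#' operation is idempotent and two SMILES of the same molecule map to the
#' same output.  All cross-set identity checks in the package (uniqueness,
#' novelty, duplicate removal) compare canonical SMILES text.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict Error on unparsable input (default).  With
#'   `strict = FALSE`, unparsable entries yield `NA` instead.
#' @return Character vector of canonical SMILES.
#' @examples \dontrun{
#' canonicalizeSmiles(c("OCC", "CCO"))
#' }
#' @export
canonicalizeSmiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  res <- rdkitBridge("canonicalize", list(smiles = I(smiles)))
  valid <- unlist(res$valid)
  if (strict && !all(valid)) {
    stop("invalid SMILES: ",
         paste(utils::head(smiles[!valid], 5), collapse = ", "),
         call. = FALSE)
  }
  out <- rep(NA_character_, length(smiles))
  out[valid] <- unlist(res$canonical[valid])
  out
}

#' Test SMILES validity
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector: does each string sanitize to a valid molecule?
#' @export
isValidSmiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(logical(0))
  res <- rdkitBridge("canonicalize", list(smiles = I(smiles)))
  unlist(res$valid)
}

#' Randomized SMILES (enumeration primitive)
#'
#' Produces syntactically valid SMILES of the same molecule with a
#' randomized atom ordering, i.e. a graph traversal started from a random
#' non-hydrogen atom and proceeding in a random direction.  Every output
#' canonicalizes back to the canonical form of its input.
#'
#' @param smiles Character vector of valid SMILES.
#' @param n_variants Randomized strings to draw per molecule (with
#'   replacement; duplicates possible).
#' @param seed Optional integer seed; when `NULL`, per-molecule seeds are
#'   drawn from the current R RNG stream.
#' @return A list of character vectors (`n_variants` strings per molecule).
#' @export
randomizeSmiles <- function(smiles, n_variants = 1L, seed = NULL) {
  stopifnot(is.character(smiles), n_variants >= 1L)
  drawSeeds <- function() sample.int(.Machine$integer.max, length(smiles),
                                     replace = TRUE)
  seeds <- if (is.null(seed)) drawSeeds() else
    withr::with_seed(seed, drawSeeds())
  res <- rdkitBridge("randomize", list(smiles = I(smiles), seeds = I(seeds),
                                       n_variants = n_variants))
  valid <- unlist(res$valid)
  if (!all(valid)) {
    stop("invalid SMILES: ",
         paste(utils::head(smiles[!valid], 5), collapse = ", "),
         call. = FALSE)
  }
  lapply(res$variants, unlist)
}

#' Molecular descriptors
#'
#' Computes the eight physico-chemical descriptors used for distribution
#' learning: number of aliphatic and aromatic rings, molecular weight
#' (g/mol), log P, hydrogen-bond donor and acceptor counts, topological
#' polar surface area (A^2), and number of rotatable bonds.
#'
#' @param smiles Character vector of valid SMILES.
#' @return A `data.frame` with one row per molecule and the eight
#'   descriptor columns.
#' @export
computeDescriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- rdkitBridge("descriptors", list(smiles = I(smiles)))
  valid <- unlist(res$valid)
  if (!all(valid)) {
    stop("invalid SMILES: ",
         paste(utils::head(smiles[!valid], 5), collapse = ", "),
         call. = FALSE)
  }
  cols <- c("n_aliphatic_rings", "n_aromatic_rings", "mw", "logp", "hbd",
            "hba", "tpsa", "n_rotatable_bonds")
  ## rounded to 8 decimals: the additive descriptors (MW, logP, TPSA) carry
  ## atom-ordering float jitter ~1e-13 that would break invariance to the
  ## SMILES form of the same molecule
  out <- as.data.frame(lapply(setNames(cols, cols),
                              function(cl) round(unlist(res[[cl]]), 8)))
  rownames(out) <- NULL
  out
}

#' Bemis-Murcko scaffolds
#'
#' Extracts the ring systems plus connecting linkers of each molecule, with
#' side chains removed.  With `generic = TRUE`, atom and bond types are
#' abstracted (all atoms carbon, all bonds single), the form used for
#' scaffold-based clustering.  Acyclic molecules yield the empty scaffold
#' `""`.
#'
#' @param smiles Character vector of valid SMILES.
#' @param generic Abstract atom and bond types.
#' @return Character vector of scaffold SMILES (`""` for acyclic input).
#' @export
bemisMurckoScaffold <- function(smiles, generic = FALSE) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- rdkitBridge("scaffold", list(smiles = I(smiles), generic = generic))
  valid <- unlist(res$valid)
  if (!all(valid)) {
    stop("invalid SMILES: ",
         paste(utils::head(smiles[!valid], 5), collapse = ", "),
         call. = FALSE)
  }
  unname(vapply(res$scaffold, function(x) if (is.null(x)) "" else x,
                character(1)))
}

#' Tanimoto similarity on extended-connectivity fingerprints
#'
#' Morgan/ECFP bit-vector fingerprints with the defaults used throughout
#' the package (radius 2 bonds, 1024 bits), compared by Tanimoto
#' similarity.
#'
#' @param a,b Character vectors of valid SMILES, recycled to a common
#'   length; similarity is computed element-wise.
#' @param radius Fingerprint radius in bonds.
#' @param n_bits Fingerprint length in bits.
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
tanimotoSimilarity <- function(a, b, radius = 2L, n_bits = 1024L) {
  stopifnot(is.character(a), is.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  bits <- .morganBits(c(a, b), radius, n_bits)
  vapply(seq_len(n), function(i) {
    x <- bits[[i]]
    y <- bits[[n + i]]
    if (length(x) == 0L && length(y) == 0L) return(1)
    length(intersect(x, y)) / length(union(x, y))
  }, numeric(1))
}

## On-bit index sets of Morgan fingerprints; errors on invalid SMILES.
.morganBits <- function(smiles, radius = 2L, n_bits = 1024L) {
  res <- rdkitBridge("fingerprint_bits",
                     list(smiles = I(smiles), radius = radius,
                          n_bits = n_bits))
  valid <- unlist(res$valid)
  if (!all(valid)) {
    stop("invalid SMILES: ",
         paste(utils::head(smiles[!valid], 5), collapse = ", "),
         call. = FALSE)
  }
  lapply(res$bits, function(b) as.integer(unlist(b)))
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param smiles Character vector of valid SMILES.
#' @inheritParams tanimotoSimilarity
#' @return A symmetric `length(smiles)` square matrix of similarities.
#' @export
tanimotoMatrix <- function(smiles, radius = 2L, n_bits = 1024L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- rdkitBridge("tanimoto_matrix",
                     list(smiles = I(smiles), radius = radius,
                          n_bits = n_bits))
  valid <- unlist(res$valid)
  if (!all(valid)) {
    stop("invalid SMILES: ",
         paste(utils::head(smiles[!valid], 5), collapse = ", "),
         call. = FALSE)
  }
  mat <- do.call(rbind, lapply(res$matrix, function(r)
    vapply(r, function(x) if (is.null(x)) NA_real_ else x, numeric(1))))
  dimnames(mat) <- NULL
  mat
}
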