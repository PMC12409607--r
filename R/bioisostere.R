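## BRICS-based bioisosteric substitution: fragment the molecule at
## retrosynthetically interesting bonds, look fragments up in a replacement
## table keyed by canonical fragment SMILES, swap matches with probability
## p, and re-assemble over the recorded attachment points.

#' Read a bioisosteric replacement table
#'
#' The table file is tab-separated with header columns `fragment`,
#' `replacement`, `frequency`; fragments and replacements are SMILES with
#' `[n*]` attachment-point labels.  Keys are canonicalized (attachment
#' labels stripped to bare `*`), and per key only the `top_k` most frequent
#' replacements are retained (ties broken by canonical replacement SMILES).
#' Rows whose replacement arity differs from the fragment arity are skipped
#' with a warning.  The bundled default is a small curated demo table of
#' classic medicinal-chemistry pairs; full exports of the same schema load
#' the same way.
#'
#' @param path Path to the table; `NULL` loads the bundled demo table.
#' @param top_k Candidates kept per fragment key.
#' @return A [BioisostereTable-class].
#' @export
readBioisostereTable <- function(path = NULL, top_k = 5L) {
  stopifnot(top_k >= 1L)
  if (is.null(path)) {
    path <- system.file("extdata", "bioisosteres_demo.tsv",
                        package = "smilesaugment")
  }
  ## '#' is a bond symbol in SMILES, so only whole comment lines are
  ## stripped, never trailing text
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE)
  if (!nrow(tab)) {
    return(new("BioisostereTable", entries = list(),
               top_k = as.integer(top_k)))
  }
  if (!all(c("fragment", "replacement", "frequency") %in% names(tab))) {
    stop("bioisostere table must have columns fragment/replacement/frequency",
         call. = FALSE)
  }
  fk <- rdkitBridge("fragment_key", list(smiles = I(tab$fragment)))
  rk <- rdkitBridge("fragment_key", list(smiles = I(tab$replacement)))
  parse_ok <- unlist(fk$valid) & unlist(rk$valid)
  if (any(!parse_ok)) {
    stop("unparsable fragment/replacement SMILES in rows: ",
         paste(which(!parse_ok), collapse = ", "), call. = FALSE)
  }
  key <- unlist(fk$key)
  f_ar <- unlist(fk$arity)
  r_ar <- unlist(rk$arity)
  r_key <- unlist(rk$key)
  bad <- f_ar != r_ar | f_ar < 1L
  if (any(bad)) {
    warning("skipping ", sum(bad),
            " row(s) with attachment-arity mismatch or no attachment point")
  }
  tab <- tab[!bad, , drop = FALSE]
  key <- key[!bad]
  f_ar <- f_ar[!bad]
  r_key <- r_key[!bad]
  entries <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    e <- data.frame(replacement = tab$replacement[rows],
                    frequency = as.numeric(tab$frequency[rows]),
                    arity = f_ar[rows],
                    canon = r_key[rows],
                    stringsAsFactors = FALSE)
    e <- e[order(-e$frequency, e$canon), , drop = FALSE]
    e <- e[!duplicated(e$canon), , drop = FALSE]
    e <- utils::head(e, top_k)
    e$canon <- NULL
    rownames(e) <- NULL
    entries[[k]] <- e
  }
  new("BioisostereTable", entries = entries, top_k = as.integer(top_k))
}

#' @describeIn readBioisostereTable Number of fragment keys in a table.
#' @param x A [BioisostereTable-class].
#' @export
bioisostereKeys <- function(x) {
  stopifnot(is(x, "BioisostereTable"))
  names(x@entries)
}

#' BRICS fragment decomposition
#'
#' Cuts every BRICS bond of each molecule; fragments carry isotope-labelled
#' attachment points (`[k*]` for cut bond `k`) recording how to
#' re-assemble, and each fragment additionally gets a canonical lookup key
#' with labels stripped to bare `*`.  A molecule with no BRICS bonds yields
#' a single-fragment decomposition.
#'
#' @param smiles Character vector of valid SMILES.
#' @return A list with one element per molecule, each a `data.frame` with
#'   columns `frag` (labelled fragment SMILES), `key` (canonical lookup
#'   key) and `arity` (number of attachment points).
#' @export
bricsDecompose <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- rdkitBridge("brics_decompose", list(smiles = I(smiles)))
  valid <- unlist(res$valid)
  if (!all(valid)) {
    stop("invalid SMILES: ",
         paste(utils::head(smiles[!valid], 5), collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_along(smiles), function(i) {
    data.frame(frag = unlist(res$frags[[i]]),
               key = unlist(res$keys[[i]]),
               arity = as.integer(unlist(res$arity[[i]])),
               stringsAsFactors = FALSE)
  })
}

#' Re-assemble a BRICS decomposition
#'
#' Round-trip check primitive: cuts all BRICS bonds and re-assembles the
#' fragments over their attachment points; the result is the same molecule.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Canonical SMILES of the re-assembled molecules.
#' @export
bricsReassemble <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- rdkitBridge("brics_reassemble", list(smiles = I(smiles)))
  ok <- unlist(res$ok)
  if (!all(ok)) {
    stop("reassembly failed for: ",
         paste(utils::head(smiles[!ok], 5), collapse = ", "), call. = FALSE)
  }
  unlist(res$smiles)
}

## Choose the fragments to replace for one decomposition: each fragment
## whose key is in the table (and whose arity matches) fires independently
## with probability p; the candidate is uniform over the key's top-k list.
## Returns a list of list(idx = 0-based fragment index, rep = SMILES).
.substitutionPlan <- function(dec, table, p) {
  plan <- list()
  for (j in seq_len(nrow(dec))) {
    e <- table@entries[[dec$key[j]]]
    if (is.null(e) || e$arity[1] != dec$arity[j]) next
    if (stats::runif(1) >= p) next
    cand <- e$replacement[sample.int(nrow(e), 1L)]
    plan[[length(plan) + 1L]] <- list(idx = j - 1L, rep = cand)
  }
  plan
}

#' Bioisosteric substitution
#'
#' Each BRICS fragment of the molecule found in the replacement table is,
#' with probability `p`, replaced by a uniformly chosen candidate from its
#' top-k list; the molecule is re-assembled over the recorded attachment
#' points, sanitized and canonicalized.  When no fragment matches the
#' table, no replacement fires, or re-assembly fails sanitization, the draw
#' is a rejection (`NA`), which the fold controller treats as a retry /
#' saturation signal.
#'
#' @param smiles Character vector of valid SMILES.
#' @param table A [BioisostereTable-class].
#' @param p Per-fragment replacement probability in `[0, 1]`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Character vector: canonical SMILES of the substituted molecule,
#'   or `NA` for rejected draws.
#' @export
bioisostericSubstitute <- function(smiles, table, p, seed = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L,
            is(table, "BioisostereTable"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  }
  run <- function() {
    dec <- bricsDecompose(smiles)
    plan <- lapply(dec, .substitutionPlan, table = table, p = p)
    out <- rep(NA_character_, length(smiles))
    fired <- lengths(plan) > 0L
    if (any(fired)) {
      sub <- rdkitBridge("brics_substitute",
                         list(smiles = I(smiles[fired]),
                              repl = lapply(plan[fired], identity)))
      out[fired] <- vapply(seq_len(sum(fired)), function(j) {
        if (isTRUE(sub$ok[[j]])) sub$smiles[[j]] else NA_character_
      }, character(1))
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
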