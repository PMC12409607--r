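## The augmentation strategies: SMILES enumeration (baseline), token
## deletion (random / validity-enforced / protected), atom masking (random /
## functional-group), plus the fold controller and training-pair
## constructor.  Bioisosteric substitution lives in bioisostere.R and
## self-training in clm.R; the fold controller dispatches to all of them.

.RING_BRANCH_TOKENS <- c(as.character(1:9), "(", ")")

.isProtectedToken <- function(tokens) {
  tokens %in% .RING_BRANCH_TOKENS | startsWith(tokens, "%")
}

#' Create an augmentation configuration
#'
#' The perturbation probability `p` defaults to the value found optimal for
#' each strategy: 0.05 for token deletion and random atom masking, 0.15 for
#' bioisosteric substitution, and 0.30 for functional-group masking.
#'
#' @param strategy One of `"enumeration"`, `"deletion"`, `"masking"`,
#'   `"bioisostere"`, `"self_training"`.
#' @param variant Strategy variant; defaults to the first legal variant
#'   (`"random"` for deletion and masking, `"none"` otherwise).
#' @param p Perturbation probability in `[0, 1]`.
#' @param fold Augmentation fold `n`: the original string is kept and up to
#'   `n - 1` augmented strings are added per molecule.
#' @param seed Integer RNG seed making augmentation fully deterministic.
#' @param max_attempts Retry budget per requested augmented string.
#' @return An [AugmentationConfig-class] object.
#' @examples
#' augmentationConfig("deletion", "protected", fold = 3)
#' @export
augmentationConfig <- function(strategy, variant = NULL, p = NULL,
                               fold = 1L, seed = 1L, max_attempts = 20L) {
  strategy <- match.arg(strategy, .STRATEGIES)
  if (is.null(variant)) variant <- .VARIANTS[[strategy]][1]
  if (is.null(p)) {
    p <- switch(strategy,
                deletion = 0.05,
                masking = if (identical(variant, "functional_group")) 0.30
                          else 0.05,
                bioisostere = 0.15,
                0)
  }
  new("AugmentationConfig", strategy = strategy, variant = variant,
      p = as.numeric(p), fold = as.integer(fold), seed = as.integer(seed),
      max_attempts = as.integer(max_attempts))
}

#' Token deletion
#'
#' Deletes each token of a SMILES token sequence independently with
#' probability `p`.  Variants: `"random"` deletes any token; `"protected"`
#' never deletes ring tokens (digits `1`-`9` and `%NN` closures) or branch
#' tokens (`(`, `)`); `"validity"` repeats random deletion until the
#' surviving string sanitizes to a valid molecule, up to `max_attempts`
#' tries, after which the draw is rejected (a signaled outcome, not an
#' error).
#'
#' @param tokens Character token vector without `G`/`E` markers.
#' @param p Deletion probability in `[0, 1]`.
#' @param variant `"random"`, `"validity"`, or `"protected"`.
#' @param max_attempts Retry budget for the validity variant.
#' @return A list with elements `tokens` (surviving tokens, in order; `NULL`
#'   when rejected), `smiles` (their concatenation), and `rejected`.
#' @examples
#' deleteTokens(tokenizeSmiles("C1CC1")[[1]], p = 1, variant = "protected")
#' @export
deleteTokens <- function(tokens, p, variant = c("random", "validity",
                                                "protected"),
                         max_attempts = 20L) {
  variant <- match.arg(variant)
  stopifnot(is.character(tokens), length(tokens) >= 1L)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  }
  if (any(tokens %in% c("G", "E"))) {
    stop("deleteTokens operates on marker-free sequences", call. = FALSE)
  }
  if (variant != "validity") {
    kept <- .deleteDraw(tokens, p, variant)
    return(list(tokens = kept, smiles = paste(kept, collapse = ""),
                rejected = FALSE))
  }
  for (i in seq_len(max_attempts)) {
    kept <- .deleteDraw(tokens, p, "random")
    s <- paste(kept, collapse = "")
    if (nzchar(s) && isValidSmiles(s)) {
      return(list(tokens = kept, smiles = s, rejected = FALSE))
    }
  }
  list(tokens = NULL, smiles = NA_character_, rejected = TRUE)
}

## One deletion draw (no validity check).
.deleteDraw <- function(tokens, p, variant) {
  drop <- stats::runif(length(tokens)) < p
  if (variant == "protected") drop <- drop & !.isProtectedToken(tokens)
  tokens[!drop]
}

#' Read a functional-group SMARTS library
#'
#' The library file is tab-separated with one `SMARTS<TAB>name` pair per
#' line (`#` comments allowed).  The bundled default covers common
#' medicinal-chemistry groups (carboxylic acid, ester, amide, amine,
#' hydroxyl, ether, ketone, aldehyde, nitrile, nitro, halogen, sulfonamide,
#' thioether) and is intended to be replaced by users with their own
#' curated list.
#'
#' @param path Path to the library file; `NULL` loads the bundled default.
#' @return A `data.frame` with columns `smarts` and `name`.
#' @export
readFunctionalGroups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_groups.tsv",
                        package = "smilesaugment")
  }
  ## '#' is a bond symbol in SMARTS, so only whole comment lines are
  ## stripped, never trailing text
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fg <- utils::read.delim(text = lines, header = FALSE,
                          col.names = c("smarts", "name"),
                          stringsAsFactors = FALSE)
  if (!nrow(fg)) stop("empty functional-group library: ", path,
                      call. = FALSE)
  fg
}

#' Atom masking
#'
#' Replaces atoms of the molecular graph by the dummy atom `*` and
#' re-emits the SMILES in the input atom order, so the masked string and
#' the unmasked rendering of the source differ only in `*` tokens (this is
#' verified, and the draw retried on failure).  Mode `"random"` masks each
#' atom independently with probability `p`; `"functional_group"` masks, for
#' each SMARTS-library match in the molecule, all matched atoms with
#' probability `p` per match (overlaps are unioned).
#'
#' @param smiles Character vector of valid SMILES.
#' @param p Masking probability in `[0, 1]`.
#' @param mode `"random"` or `"functional_group"`.
#' @param fg_library Functional-group library as returned by
#'   [readFunctionalGroups()]; required for `"functional_group"` mode.
#' @param max_attempts Retries per molecule when verification fails.
#' @return Character vector of masked SMILES; the attribute `"unmasked"`
#'   holds the aligned unmasked rendering of each source molecule.
#' @export
maskAtoms <- function(smiles, p, mode = c("random", "functional_group"),
                      fg_library = NULL, max_attempts = 20L) {
  mode <- match.arg(mode)
  res <- .maskBatch(smiles, p, mode, fg_library, max_attempts)
  if (any(!res$ok)) {
    stop("masking verification failed after ", max_attempts,
         " attempts for: ",
         paste(utils::head(smiles[!res$ok], 5), collapse = ", "),
         call. = FALSE)
  }
  structure(res$masked, unmasked = res$unmasked)
}

## Precompute the per-molecule facts masking needs (atom counts and, for
## functional-group mode, the matched atom-index sets) so repeated draws
## over the same molecules reuse them.
.maskPrep <- function(smiles, mode, fg_library = NULL) {
  info <- rdkitBridge("atom_info", list(smiles = I(smiles)))
  if (!all(unlist(info$valid))) {
    stop("invalid SMILES: ",
         paste(utils::head(smiles[!unlist(info$valid)], 5), collapse = ", "),
         call. = FALSE)
  }
  matches <- NULL
  if (mode == "functional_group") {
    if (is.null(fg_library)) {
      stop("functional_group masking requires a SMARTS library",
           call. = FALSE)
    }
    sm <- rdkitBridge("smarts_matches",
                      list(smiles = I(smiles),
                           smarts = I(fg_library$smarts)))
    if (!all(unlist(sm$pattern_ok))) {
      stop("unparsable SMARTS pattern(s): ",
           paste(fg_library$smarts[!unlist(sm$pattern_ok)], collapse = ", "),
           call. = FALSE)
    }
    ## flatten to one list of 0-based atom-index vectors per molecule
    matches <- lapply(sm$matches, function(perpat) {
      out <- list()
      for (pp in perpat) for (m in pp) out <- c(out, list(unlist(m)))
      out
    })
  }
  list(n_atoms = unlist(info$n_atoms), matches = matches)
}

## One masking draw per molecule in `rows` (indices into prep).  Returns
## data.frame(masked, unmasked, ok) of length(rows).
.maskDrawOnce <- function(smiles, prep, rows, p, mode) {
  idx_sets <- lapply(rows, function(i) {
    if (mode == "random") {
      sel <- which(stats::runif(prep$n_atoms[i]) < p) - 1L
    } else {
      fire <- stats::runif(length(prep$matches[[i]])) < p
      sel <- sort(unique(unlist(prep$matches[[i]][fire])))
      if (is.null(sel)) sel <- integer(0)
    }
    as.integer(sel)
  })
  res <- rdkitBridge("mask", list(smiles = I(smiles[rows]),
                                  masked = .asJsonArrays(idx_sets)))
  masked <- unmasked <- rep(NA_character_, length(rows))
  ok <- rep(FALSE, length(rows))
  for (k in seq_along(rows)) {
    if (!isTRUE(res$ok[[k]])) next
    mk <- res$masked[[k]]
    um <- res$orig_in_order[[k]]
    if (.maskedDiffersOnlyInMask(mk, um)) {
      masked[k] <- mk
      unmasked[k] <- um
      ok[k] <- TRUE
    }
  }
  data.frame(masked = masked, unmasked = unmasked, ok = ok,
             stringsAsFactors = FALSE)
}

## Batched masking.  Returns data.frame(masked, unmasked, ok); draws are
## taken from the current R RNG stream.
.maskBatch <- function(smiles, p, mode, fg_library = NULL,
                       max_attempts = 20L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  }
  prep <- .maskPrep(smiles, mode, fg_library)
  n <- length(smiles)
  out <- data.frame(masked = rep(NA_character_, n),
                    unmasked = rep(NA_character_, n),
                    ok = rep(FALSE, n), stringsAsFactors = FALSE)
  pending <- seq_len(n)
  for (attempt in seq_len(max_attempts)) {
    if (!length(pending)) break
    res <- .maskDrawOnce(smiles, prep, pending, p, mode)
    out[pending[res$ok], ] <- res[res$ok, ]
    out$ok[pending[res$ok]] <- TRUE
    pending <- pending[!res$ok]
  }
  out
}

## Token-level verification that a masked string differs from the aligned
## unmasked rendering only at '*' positions.
.maskedDiffersOnlyInMask <- function(masked, unmasked) {
  tk_m <- tryCatch(.tokenizeOne(masked), error = function(e) NULL)
  tk_u <- tryCatch(.tokenizeOne(unmasked), error = function(e) NULL)
  if (is.null(tk_m) || is.null(tk_u) || length(tk_m) != length(tk_u)) {
    return(FALSE)
  }
  diff <- tk_m != tk_u
  all(tk_m[diff] == "*")
}

#' SMILES enumeration
#'
#' Draws up to `n_variants` distinct randomized SMILES of a molecule, none
#' textually equal to the input or its canonical form.  Fewer strings are
#' returned when the retry budget is exhausted (saturation), e.g. for small
#' or highly symmetric molecules with few distinct representations.
#'
#' @param smiles A single valid SMILES string.
#' @param n_variants Number of distinct variants requested.
#' @param max_attempts Draw budget per requested variant.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Character vector of at most `n_variants` distinct SMILES.
#' @export
enumerateSmiles <- function(smiles, n_variants, max_attempts = 20L,
                            seed = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L, n_variants >= 1L)
  run <- function() {
    canon <- canonicalizeSmiles(smiles)
    .enumerateBatch(smiles, rep(n_variants, 1L),
                    exclude = list(c(smiles, canon)),
                    max_attempts = max_attempts)[[1]]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## Batched enumeration: for each molecule draw until `need[i]` distinct
## variants outside `exclude[[i]]` are found or the budget runs out.
.enumerateBatch <- function(smiles, need, exclude, max_attempts = 20L) {
  n <- length(smiles)
  acc <- replicate(n, character(0), simplify = FALSE)
  budget <- max_attempts * need
  used <- rep(0L, n)
  repeat {
    pending <- which(lengths(acc) < need & used < budget)
    if (!length(pending)) break
    k <- max(need[pending] - lengths(acc)[pending])
    seeds <- sample.int(.Machine$integer.max, length(pending),
                        replace = TRUE)
    res <- rdkitBridge("randomize", list(smiles = I(smiles[pending]),
                                         seeds = I(seeds), n_variants = k))
    for (j in seq_along(pending)) {
      i <- pending[j]
      used[i] <- used[i] + k
      vars <- unlist(res$variants[[j]])
      vars <- setdiff(vars, c(exclude[[i]], acc[[i]]))
      if (length(vars)) {
        take <- min(length(vars), need[i] - length(acc[[i]]))
        acc[[i]] <- c(acc[[i]], vars[seq_len(take)])
      }
    }
  }
  acc
}

#' Augment a dataset to a target fold
#'
#' The fold controller: per source molecule, attempts to produce `fold - 1`
#' augmented strings with the configured strategy, enforcing per-molecule
#' textual uniqueness and excluding strings already present in the original
#' training set.  Molecules that cannot reach `fold - 1` distinct strings
#' within the attempt budget are flagged as saturated ("augmented until
#' their possible maximum").  Fully deterministic given `config@seed`.
#'
#' @param smiles Character vector of training SMILES (one per molecule, in
#'   the representation used for training, e.g. randomized strings).
#' @param config An [AugmentationConfig-class].
#' @param fg_library SMARTS library for functional-group masking.
#' @param bio_table [BioisostereTable-class] for bioisosteric substitution.
#' @param clm_config [clmConfig()] list for self-training.
#' @param val_fraction Fraction of molecules used as the validation split
#'   when self-training trains its internal model.
#' @return An [AugmentedSmiles-class] object.
#' @export
augmentToFold <- function(smiles, config, fg_library = NULL,
                          bio_table = NULL, clm_config = NULL,
                          val_fraction = 0.1) {
  stopifnot(is.character(smiles), length(smiles) >= 1L,
            is(config, "AugmentationConfig"))
  validObject(config)
  if (config@strategy == "masking" &&
      config@variant == "functional_group" && is.null(fg_library)) {
    stop("functional_group masking requires fg_library", call. = FALSE)
  }
  if (config@strategy == "bioisostere" && is.null(bio_table)) {
    stop("bioisosteric substitution requires bio_table", call. = FALSE)
  }
  if (config@strategy == "self_training" && config@fold > 1L &&
      is.null(clm_config)) {
    stop("self-training requires clm_config", call. = FALSE)
  }
  withr::with_seed(config@seed, {
    if (config@strategy == "self_training") {
      .selfTrainFold(smiles, config, clm_config, val_fraction)
    } else {
      .augmentFoldLocal(smiles, config, fg_library, bio_table)
    }
  })
}

## Fold controller for the per-molecule strategies (enumeration, deletion,
## masking, bioisostere).  Runs under an established RNG state.
.augmentFoldLocal <- function(smiles, config, fg_library, bio_table) {
  n <- length(smiles)
  need <- config@fold - 1L
  training_set <- unique(smiles)
  acc <- replicate(n, character(0), simplify = FALSE)
  tgt <- replicate(n, character(0), simplify = FALSE)

  if (need > 0L && config@strategy == "enumeration") {
    canon <- canonicalizeSmiles(smiles)
    excl <- lapply(seq_len(n), function(i)
      unique(c(training_set, canon[i])))
    acc <- .enumerateBatch(smiles, rep(need, n), excl,
                           config@max_attempts)
    tgt <- acc
  } else if (need > 0L && config@strategy == "deletion") {
    toks <- tokenizeSmiles(smiles)
    budget <- config@max_attempts * need
    used <- rep(0L, n)
    repeat {
      pending <- which(lengths(acc) < need & used < budget)
      if (!length(pending)) break
      cand <- lapply(pending, function(i) {
        k <- need - length(acc[[i]])
        vapply(seq_len(k), function(j)
          paste(.deleteDraw(toks[[i]], config@p,
                            if (config@variant == "protected") "protected"
                            else "random"),
                collapse = ""), character(1))
      })
      flat <- unlist(cand)
      keep_valid <- rep(TRUE, length(flat))
      if (config@variant == "validity" && length(flat)) {
        nonempty <- nzchar(flat)
        keep_valid <- nonempty
        if (any(nonempty)) {
          keep_valid[nonempty] <- isValidSmiles(flat[nonempty])
        }
      }
      off <- 0L
      for (j in seq_along(pending)) {
        i <- pending[j]
        k <- length(cand[[j]])
        used[i] <- used[i] + k
        cs <- cand[[j]][keep_valid[off + seq_len(k)]]
        off <- off + k
        cs <- setdiff(cs, c(training_set, acc[[i]], ""))
        if (length(cs)) {
          take <- min(length(cs), need - length(acc[[i]]))
          acc[[i]] <- c(acc[[i]], cs[seq_len(take)])
        }
      }
    }
    tgt <- acc
  } else if (need > 0L && config@strategy == "masking") {
    mode <- if (config@variant == "functional_group") "functional_group"
            else "random"
    prep <- .maskPrep(smiles, mode, fg_library)
    budget <- config@max_attempts * need
    used <- rep(0L, n)
    unmask <- replicate(n, character(0), simplify = FALSE)
    repeat {
      pending <- which(lengths(acc) < need & used < budget)
      if (!length(pending)) break
      res <- .maskDrawOnce(smiles, prep, pending, config@p, mode)
      for (j in seq_along(pending)) {
        i <- pending[j]
        used[i] <- used[i] + 1L
        if (!res$ok[j]) next
        cand <- res$masked[j]
        if (cand %in% c(training_set, acc[[i]], res$unmasked[j],
                        smiles[i])) next
        acc[[i]] <- c(acc[[i]], cand)
        unmask[[i]] <- c(unmask[[i]], res$unmasked[j])
      }
    }
    tgt <- unmask
  } else if (need > 0L && config@strategy == "bioisostere") {
    dec <- bricsDecompose(smiles)
    budget <- config@max_attempts * need
    used <- rep(0L, n)
    matchable <- vapply(dec, function(d)
      any(d$key %in% names(bio_table@entries) &
            d$arity == vapply(d$key, function(k) {
              e <- bio_table@entries[[k]]
              if (is.null(e)) -1L else e$arity[1]
            }, integer(1))), logical(1))
    used[!matchable] <- budget[1]  # nothing to replace: saturate at once
    repeat {
      pending <- which(lengths(acc) < need & used < budget & matchable)
      if (!length(pending)) break
      plan <- lapply(pending, function(i) {
        .substitutionPlan(dec[[i]], bio_table, config@p)
      })
      fired <- lengths(plan) > 0L
      used[pending] <- used[pending] + 1L
      if (any(fired)) {
        sub <- rdkitBridge("brics_substitute",
                           list(smiles = I(smiles[pending[fired]]),
                                repl = lapply(plan[fired], function(pl)
                                  lapply(pl, identity))))
        which_f <- which(fired)
        for (j in seq_along(which_f)) {
          i <- pending[which_f[j]]
          if (!isTRUE(sub$ok[[j]])) next
          cand <- sub$smiles[[j]]
          if (cand %in% c(training_set, acc[[i]], smiles[i])) next
          acc[[i]] <- c(acc[[i]], cand)
        }
      }
    }
    tgt <- acc
  }

  .buildAugmentedSmiles(smiles, acc, tgt, config)
}

## Assemble the AugmentedSmiles container from per-molecule accumulators.
.buildAugmentedSmiles <- function(smiles, acc, tgt, config) {
  n <- length(smiles)
  need <- config@fold - 1L
  ids <- if (!is.null(names(smiles)) && all(nzchar(names(smiles))))
    names(smiles) else as.character(seq_len(n))
  smiles <- unname(smiles)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    aug <- unname(acc[[i]])
    rows[[i]] <- data.frame(
      source_id = ids[i],
      original = smiles[i],
      augmented = c(smiles[i], aug),
      target = c(smiles[i], unname(tgt[[i]])),
      strategy = config@strategy,
      variant = config@variant,
      is_original = c(TRUE, rep(FALSE, length(aug))),
      stringsAsFactors = FALSE)
  }
  strings <- do.call(rbind, rows)
  rownames(strings) <- NULL
  strings$is_valid <- isValidSmiles(strings$augmented)
  collisions <- strings$augmented[!strings$is_original]
  if (anyDuplicated(collisions)) {
    message("note: ", sum(duplicated(collisions)),
            " augmented string(s) collide across molecules (kept)")
  }
  molecules <- data.frame(source_id = ids, original = smiles,
                          n_augmented = lengths(acc),
                          saturated = lengths(acc) < need,
                          stringsAsFactors = FALSE)
  rownames(molecules) <- NULL
  new("AugmentedSmiles", strings = strings, molecules = molecules)
}

#' @describeIn augmentToFold The per-string table of an augmented dataset.
#' @param x An [AugmentedSmiles-class].
#' @export
augmentedStrings <- function(x) {
  stopifnot(is(x, "AugmentedSmiles"))
  x@strings
}

#' @describeIn augmentToFold The per-molecule summary (augmented counts and
#'   saturation flags).
#' @export
sourceMolecules <- function(x) {
  stopifnot(is(x, "AugmentedSmiles"))
  x@molecules
}

#' Write an augmented dataset as tab-separated text
#'
#' @param x An [AugmentedSmiles-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAugmentedSmiles <- function(x, path) {
  stopifnot(is(x, "AugmentedSmiles"))
  out <- x@strings[, c("source_id", "original", "augmented", "strategy",
                       "variant", "is_valid")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build training pairs from an augmented dataset
#'
#' Adds the `G`/`E` markers and pairs each training string with its target:
#' for masking rows the input is the masked sequence and the target the
#' original unmasked sequence of the same molecule; for every other row
#' input and target are identical (including syntactically invalid deletion
#' outputs, which enter training as-is).  Strings longer than `max_len`
#' after markers are dropped and counted.
#'
#' @param aug An [AugmentedSmiles-class].
#' @param vocab A [SmilesVocabulary-class]; `NULL` builds one from the
#'   dataset.
#' @param max_len Maximum sequence length including markers.
#' @return A [TrainingPairSet-class].
#' @export
makeTrainingPairs <- function(aug, vocab = NULL, max_len = 150L) {
  stopifnot(is(aug, "AugmentedSmiles"))
  st <- aug@strings
  input <- tokenizeSmiles(st$augmented, with_markers = TRUE)
  target <- tokenizeSmiles(st$target, with_markers = TRUE)
  keep <- lengths(input) <= max_len & lengths(target) <= max_len
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("dropped ", n_dropped, " over-length string(s) (> ", max_len,
            " tokens)")
  }
  input <- input[keep]
  target <- target[keep]
  if (is.null(vocab)) vocab <- smilesVocabulary(c(input, target))
  new("TrainingPairSet", input = input, target = target, vocab = vocab,
      n_dropped = as.integer(n_dropped))
}
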