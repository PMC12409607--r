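## S4 class definitions for the package.  Accessors live next to the module
## code that produces each class; show methods are in show-methods.R.

#' SMILES token vocabulary
#'
#' A bijection between SMILES tokens and contiguous 0-based integer indices.
#' Four special tokens are always present: the padding token `"<pad>"`
#' (index 0), the begin-of-sequence marker `"G"`, the end-of-sequence marker
#' `"E"`, and the mask token `"*"`.
#'
#' @slot tokens Character vector; position `i` holds the token with index
#'   `i - 1`.
#' @seealso [smilesVocabulary()], [encodeSequences()]
#' @export
setClass("SmilesVocabulary", representation(tokens = "character"))

setValidity("SmilesVocabulary", function(object) {
  msg <- character()
  if (anyDuplicated(object@tokens)) {
    msg <- c(msg, "tokens must be unique")
  }
  specials <- c("<pad>", "G", "E", "*")
  if (!all(specials %in% object@tokens)) {
    msg <- c(msg, paste("missing special token(s):",
                        paste(setdiff(specials, object@tokens),
                              collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Augmentation strategy configuration
#'
#' Holds the augmentation strategy and its controls: the perturbation
#' probability `p`, the augmentation fold `n` (the original string plus up
#' to `n - 1` augmented strings per molecule), the RNG seed, and the retry
#' budget for validity-enforced operations.
#'
#' @slot strategy One of `"enumeration"`, `"deletion"`, `"masking"`,
#'   `"bioisostere"`, `"self_training"`.
#' @slot variant Strategy variant (`"random"`, `"validity"`, `"protected"`
#'   for deletion; `"random"`, `"functional_group"` for masking; `"none"`
#'   otherwise).
#' @slot p Perturbation probability in `[0, 1]`.
#' @slot fold Augmentation fold, an integer `>= 1`.
#' @slot seed Integer RNG seed.
#' @slot max_attempts Retry budget per requested augmented string.
#' @seealso [augmentationConfig()], [augmentToFold()]
#' @export
setClass("AugmentationConfig",
         representation(strategy = "character", variant = "character",
                        p = "numeric", fold = "integer", seed = "integer",
                        max_attempts = "integer"))

.STRATEGIES <- c("enumeration", "deletion", "masking", "bioisostere",
                 "self_training")
.VARIANTS <- list(enumeration = "none",
                  deletion = c("random", "validity", "protected"),
                  masking = c("random", "functional_group"),
                  bioisostere = "none",
                  self_training = "none")

setValidity("AugmentationConfig", function(object) {
  msg <- character()
  if (!object@strategy %in% .STRATEGIES) {
    msg <- c(msg, paste("unknown strategy:", object@strategy))
  } else if (!object@variant %in% .VARIANTS[[object@strategy]]) {
    msg <- c(msg, paste0("variant '", object@variant,
                         "' not legal for strategy '", object@strategy, "'"))
  }
  if (length(object@p) != 1L || is.na(object@p) || object@p < 0 ||
      object@p > 1) {
    msg <- c(msg, "p must be a single probability in [0, 1]")
  }
  if (object@fold < 1L) msg <- c(msg, "fold must be >= 1")
  if (object@max_attempts < 1L) msg <- c(msg, "max_attempts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Augmented SMILES dataset
#'
#' Per source molecule, the original training string plus up to `fold - 1`
#' augmented strings, each tagged with its strategy, variant and syntactic
#' validity.  Molecules whose augmentation budget was exhausted before
#' reaching `fold - 1` distinct strings carry a saturation flag.
#'
#' @slot strings `data.frame` with one row per training string: `source_id`,
#'   `original`, `augmented`, `target` (the unmasked counterpart used as the
#'   training target; equals `augmented` except for masking), `strategy`,
#'   `variant`, `is_original`, `is_valid`.
#' @slot molecules `data.frame` with one row per source molecule:
#'   `source_id`, `original`, `n_augmented`, `saturated`.
#' @seealso [augmentToFold()], [makeTrainingPairs()]
#' @export
setClass("AugmentedSmiles",
         representation(strings = "data.frame", molecules = "data.frame"))

setValidity("AugmentedSmiles", function(object) {
  msg <- character()
  need <- c("source_id", "original", "augmented", "target", "strategy",
            "variant", "is_original", "is_valid")
  if (!all(need %in% names(object@strings))) {
    msg <- c(msg, "strings is missing required columns")
  } else {
    dup <- vapply(split(object@strings$augmented, object@strings$source_id),
                  anyDuplicated, 0L)
    if (any(dup > 0L)) {
      msg <- c(msg, "augmented strings must be unique within a molecule")
    }
  }
  if (!all(c("source_id", "original", "n_augmented", "saturated") %in%
           names(object@molecules))) {
    msg <- c(msg, "molecules is missing required columns")
  }
  if (length(msg)) msg else TRUE
})

#' Tokenized training pairs for the language model
#'
#' Marker-framed input/target token sequences.  For every strategy except
#' masking the input equals the target; masking rows pair the masked input
#' with the original, unmasked sequence of the same molecule.
#'
#' @slot input List of character token vectors (with `G`/`E` markers).
#' @slot target List of character token vectors, same lengths as `input`.
#' @slot vocab The [SmilesVocabulary-class] the pairs are encoded against.
#' @slot n_dropped Number of over-length strings excluded at construction.
#' @seealso [makeTrainingPairs()], [trainCLM()]
#' @export
setClass("TrainingPairSet",
         representation(input = "list", target = "list",
                        vocab = "SmilesVocabulary", n_dropped = "integer"))

setValidity("TrainingPairSet", function(object) {
  if (length(object@input) != length(object@target)) {
    return("input and target must have the same length")
  }
  same <- mapply(function(a, b) length(a) == length(b), object@input,
                 object@target)
  if (!all(same)) return("paired sequences must have equal token length")
  TRUE
})

#' Bioisosteric replacement table
#'
#' Maps canonical fragment keys (fragment SMILES with attachment points
#' stripped to bare `*`) to their most frequently reported replacements,
#' truncated to the top `k` by frequency.
#'
#' @slot entries Named list; each element is a `data.frame` with columns
#'   `replacement` (SMILES with `[n*]` attachment labels), `frequency`, and
#'   `arity`.
#' @slot top_k Maximum number of candidate replacements kept per key.
#' @seealso [readBioisostereTable()], [bioisostericSubstitute()]
#' @export
setClass("BioisostereTable",
         representation(entries = "list", top_k = "integer"))

setValidity("BioisostereTable", function(object) {
  ok <- vapply(object@entries, function(e) {
    is.data.frame(e) && all(c("replacement", "frequency", "arity") %in%
                            names(e)) &&
      nrow(e) <= object@top_k &&
      !is.unsorted(rev(e$frequency))
  }, logical(1))
  if (!all(ok)) {
    return("each entry must be a frequency-sorted data.frame of at most top_k rows")
  }
  TRUE
})

#' Trained chemical language model
#'
#' An LSTM next-token model over a SMILES vocabulary together with its
#' training history.  Sampling always uses the weights of the epoch with the
#' best validation loss.
#'
#' @slot params Named list of weight matrices (per-layer LSTM weights plus
#'   the softmax output layer).
#' @slot vocab The [SmilesVocabulary-class] the model predicts over.
#' @slot config Named list of training hyperparameters (see [clmConfig()]).
#' @slot history `data.frame` with per-epoch `train_loss` and `val_loss`.
#' @slot best_epoch Epoch whose weights are stored in `params`.
#' @seealso [trainCLM()], [sampleCLM()]
#' @export
setClass("TrainedCLM",
         representation(params = "list", vocab = "SmilesVocabulary",
                        config = "list", history = "data.frame",
                        best_epoch = "integer"))

#' Validity, uniqueness and novelty of a generated set
#'
#' @slot n_raw,n_valid,n_unique,n_novel Counts along the filtering chain
#'   (raw strings, syntactically valid molecules, distinct canonical forms,
#'   canonical forms absent from the training references).
#' @slot validity_pct,uniqueness_pct,novelty_pct The corresponding
#'   percentages: valid/raw, unique/valid, novel/unique.
#' @seealso [generationMetrics()]
#' @export
setClass("GenerationMetrics",
         representation(n_raw = "integer", n_valid = "integer",
                        n_unique = "integer", n_novel = "integer",
                        validity_pct = "numeric", uniqueness_pct = "numeric",
                        novelty_pct = "numeric"))

setValidity("GenerationMetrics", function(object) {
  chain <- c(object@n_raw, object@n_valid, object@n_unique, object@n_novel)
  if (is.unsorted(rev(chain))) {
    return("counts must satisfy n_raw >= n_valid >= n_unique >= n_novel")
  }
  pcts <- c(object@validity_pct, object@uniqueness_pct, object@novelty_pct)
  if (any(!is.na(pcts) & (pcts < 0 | pcts > 100))) {
    return("percentages must lie in [0, 100]")
  }
  TRUE
})

#' Descriptor-wise Kolmogorov-Smirnov report
#'
#' @slot table `data.frame` with one row per descriptor: `descriptor`, `ks`
#'   (the statistic in `[0, 1]`), `ks_x100` (the display scale used in the
#'   literature), `n_design`, `n_reference`.
#' @seealso [descriptorKSReport()], [ksDistance()]
#' @export
setClass("KSReport", representation(table = "data.frame"))

#' Scaffold diversity and novelty report
#'
#' @slot diversity_pct Distinct Bemis-Murcko scaffolds among valid designs,
#'   as a percentage of valid designs.
#' @slot novelty_ft_pct Distinct design scaffolds absent from the
#'   fine-tuning scaffold set, as a percentage of valid designs.
#' @slot novelty_pt_pct Same against the pre-training scaffolds (`NA` when
#'   no pre-training set was supplied).
#' @slot top_scaffold_matches `data.frame` comparing the fine-tuning set's
#'   most frequent scaffolds with their occurrence among the designs:
#'   `scaffold`, `ft_pct`, `design_pct`.
#' @slot n_valid Number of valid designs the percentages refer to.
#' @seealso [scaffoldReport()]
#' @export
setClass("ScaffoldReport",
         representation(diversity_pct = "numeric", novelty_ft_pct = "numeric",
                        novelty_pt_pct = "numeric",
                        top_scaffold_matches = "data.frame",
                        n_valid = "integer"))

#' Dataset curation policy
#'
#' @slot allowed_atoms Element symbols a molecule may contain (aromatic
#'   forms included implicitly).
#' @slot min_tokens,max_tokens Token-count bounds on the canonical SMILES
#'   (bounds are exclusive: strings shorter than `min_tokens` or longer than
#'   `max_tokens` are rejected).
#' @slot strip_salts Keep only the largest covalent fragment.
#' @slot strip_stereo Remove stereochemistry annotations.
#' @seealso [curationPolicy()], [curateSmiles()]
#' @export
setClass("CurationPolicy",
         representation(allowed_atoms = "character", min_tokens = "integer",
                        max_tokens = "integer", strip_salts = "logical",
                        strip_stereo = "logical"))

setValidity("CurationPolicy", function(object) {
  if (object@min_tokens >= object@max_tokens) {
    return("min_tokens must be smaller than max_tokens")
  }
  TRUE
})

#' Curated molecule set
#'
#' @slot records `data.frame` with one row per surviving molecule: `id`,
#'   `input_smiles`, `canonical_smiles`, `randomized_smiles`.
#' @slot rejections `data.frame` of rejected inputs with machine-readable
#'   reason codes (`PARSE`, `ATOM`, `LENGTH`, `DUP`).
#' @seealso [curateSmiles()]
#' @export
setClass("CuratedSmiles",
         representation(records = "data.frame", rejections = "data.frame"))

#' Realized scaffold-stratified split plan
#'
#' Size-nested training subsets with per-subset train/validation splits and
#' a disjoint, cluster-stratified test set.
#'
#' @slot sizes Subset sizes, ascending.
#' @slot subsets Named list of integer record indices, one per size; each
#'   smaller subset is contained in every larger one.
#' @slot train,val Named lists of index vectors partitioning each subset.
#' @slot test Integer indices of the held-out test set.
#' @slot clusters Integer cluster label per record.
#' @seealso [scaffoldClusterSplit()]
#' @export
setClass("SplitPlan",
         representation(sizes = "integer", subsets = "list", train = "list",
                        val = "list", test = "integer",
                        clusters = "integer"))

setValidity("SplitPlan", function(object) {
  msg <- character()
  if (length(object@sizes) > 1L) {
    for (i in seq_len(length(object@sizes) - 1L)) {
      if (!all(object@subsets[[i]] %in% object@subsets[[i + 1L]])) {
        msg <- c(msg, "subsets must be nested")
        break
      }
    }
  }
  for (i in seq_along(object@sizes)) {
    tr <- object@train[[i]]
    va <- object@val[[i]]
    if (length(intersect(tr, va)) > 0L) {
      msg <- c(msg, "train and validation indices must be disjoint")
    }
    if (!setequal(c(tr, va), object@subsets[[i]])) {
      msg <- c(msg, "train + val must partition the subset")
    }
    if (length(intersect(object@subsets[[i]], object@test)) > 0L) {
      msg <- c(msg, "test set must be disjoint from every subset")
    }
  }
  if (length(msg)) unique(msg) else TRUE
})
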