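## The chemical language model: an LSTM next-token model over the SMILES
## vocabulary, trained with teacher forcing, early stopping on validation
## cross-entropy, temperature sampling, and the self-training augmentation
## loop built on top of it.

#' Chemical language model configuration
#'
#' Hyperparameter container for [trainCLM()].  The full-scale
#' hyperparameter grid spans `n_layers` in \{2, 3\}, `hidden_units` in
#' \{256, 512\}, `learning_rate` in \{0.001, 0.005, 0.0001\} and
#' `batch_size` in \{32, 64, 128\}; pre-training uses 3 layers, 512 units,
#' learning rate 0.0005 and batch size 512.  Early stopping watches the
#' validation cross-entropy with patience 10 and minimum improvement
#' 0.0001.
#'
#' @param n_layers Number of stacked LSTM layers.
#' @param hidden_units Hidden state width per layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Sequences per gradient step.
#' @param max_epochs Epoch cap.
#' @param patience Epochs without sufficient improvement before stopping.
#' @param min_delta Minimum validation-loss improvement that resets
#'   patience.
#' @param clip_norm Optional global gradient-norm bound (`NULL` disables
#'   clipping).
#' @param seed Integer RNG seed; training is deterministic given it.
#' @return A validated named list of hyperparameters.
#' @export
clmConfig <- function(n_layers = 2L, hidden_units = 256L,
                      learning_rate = 0.001, batch_size = 64L,
                      max_epochs = 500L, patience = 10L, min_delta = 1e-4,
                      clip_norm = NULL, seed = 1L) {
  cfg <- list(n_layers = as.integer(n_layers),
              hidden_units = as.integer(hidden_units),
              learning_rate = as.numeric(learning_rate),
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              min_delta = as.numeric(min_delta),
              clip_norm = if (is.null(clip_norm)) NULL
                          else as.numeric(clip_norm),
              seed = as.integer(seed))
  stopifnot(cfg$n_layers >= 1L, cfg$hidden_units >= 1L,
            cfg$learning_rate > 0, cfg$batch_size >= 1L,
            cfg$max_epochs >= 0L, cfg$patience >= 1L, cfg$min_delta >= 0)
  cfg
}

#' Temperature-scaled softmax probabilities
#'
#' Converts logits `z` into sampling probabilities
#' `p_i = exp(z_i / T) / sum_j exp(z_j / T)`, computed with a max-shift for
#' numerical stability.  `T = 1` is plain multinomial softmax sampling;
#' `T < 1` sharpens the distribution towards the arg-max, `T > 1` flattens
#' it towards uniform.
#'
#' @param z Numeric vector of logits, or a matrix with one logit vector
#'   per row.
#' @param temperature Temperature `T > 0`.
#' @return Probabilities with the same shape as `z`; rows sum to 1.
#' @examples
#' temperatureProbabilities(c(0, log(3)), 1)
#' @export
temperatureProbabilities <- function(z, temperature = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("temperature must be a single value > 0", call. = FALSE)
  }
  if (!all(is.finite(z))) stop("logits must be finite", call. = FALSE)
  if (is.matrix(z)) return(.softmaxRows(z / temperature))
  zs <- z / temperature
  zs <- zs - max(zs)
  e <- exp(zs)
  e / sum(e)
}

#' Train a chemical language model
#'
#' Fits an LSTM next-token model with teacher forcing: at each position the
#' model receives the input tokens up to `t` and is scored on the target
#' token at `t + 1` (for masking pairs the target is the original, unmasked
#' sequence).  Padding positions contribute exactly zero to the
#' cross-entropy.  Training stops when the validation loss fails to improve
#' by `min_delta` for `patience` consecutive epochs, and the weights of the
#' best validation epoch are returned.  Deterministic given `config$seed`.
#'
#' @param pairs A [TrainingPairSet-class] of training sequences.
#' @param config A [clmConfig()] list.
#' @param val_pairs A [TrainingPairSet-class] over the same vocabulary used
#'   for early stopping.
#' @param init_params Internal: starting weights (used by [fineTuneCLM()]).
#' @return A [TrainedCLM-class].
#' @export
trainCLM <- function(pairs, config, val_pairs, init_params = NULL) {
  stopifnot(is(pairs, "TrainingPairSet"), is(val_pairs, "TrainingPairSet"))
  if (!identical(pairs@vocab@tokens, val_pairs@vocab@tokens)) {
    stop("training and validation pairs use different vocabularies",
         call. = FALSE)
  }
  if (length(pairs@input) == 0L || length(val_pairs@input) == 0L) {
    stop("empty training or validation set", call. = FALSE)
  }
  vocab <- pairs@vocab
  V <- vocabSize(vocab)
  withr::with_seed(config$seed, {
    params <- init_params %||%
      .initParams(V, config$hidden_units, config$n_layers)
    opt <- .adamInit(params)
    train <- .packPairs(pairs)
    val <- .packPairs(val_pairs)
    B <- nrow(train$input)
    best_loss <- Inf
    best_params <- params
    best_epoch <- 0L
    wait <- 0L
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    val_T <- max(val$steps)
    for (epoch in seq_len(config$max_epochs)) {
      batches <- .lengthBuckets(train$steps, config$batch_size)
      ep_loss <- 0
      ep_n <- 0
      for (rows in batches) {
        Tb <- max(train$steps[rows])
        res <- .lstmLossGrad(params,
                             train$input[rows, seq_len(Tb), drop = FALSE],
                             train$target[rows, seq_len(Tb), drop = FALSE],
                             train$mask[rows, seq_len(Tb), drop = FALSE])
        if (!is.finite(res$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        }
        upd <- .adamStep(params, res$grads, opt, config$learning_rate,
                         config$clip_norm)
        params <- upd$params
        opt <- upd$opt
        nm <- sum(train$mask[rows, ])
        ep_loss <- ep_loss + res$loss * nm
        ep_n <- ep_n + nm
      }
      val_loss <- .lstmLossGrad(params,
                                val$input[, seq_len(val_T), drop = FALSE],
                                val$target[, seq_len(val_T), drop = FALSE],
                                val$mask[, seq_len(val_T), drop = FALSE],
                                loss_only = TRUE)$loss
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = ep_loss / max(ep_n, 1),
                                  val_loss = val_loss))
      if (val_loss < best_loss) {
        best_loss_prev <- best_loss
        best_loss <- val_loss
        best_params <- params
        best_epoch <- epoch
        wait <- if (best_loss_prev - val_loss > config$min_delta) 0L
                else wait + 1L
      } else {
        wait <- wait + 1L
      }
      if (wait >= config$patience) break
    }
    new("TrainedCLM", params = best_params, vocab = vocab, config = config,
        history = history, best_epoch = best_epoch)
  })
}

#' Fine-tune a trained model
#'
#' Continues optimization from the weights of `base` on new pairs, with the
#' transfer-learning defaults: learning rate `5e-7`, gradient clipping norm
#' 1, and the same early-stopping rule as training.  `base` is not
#' modified.
#'
#' @param base A [TrainedCLM-class].
#' @param pairs,val_pairs [TrainingPairSet-class] objects over the same
#'   vocabulary as `base`.
#' @param ft_config Optional [clmConfig()] overriding the fine-tuning
#'   defaults.
#' @return A new [TrainedCLM-class].
#' @export
fineTuneCLM <- function(base, pairs, val_pairs, ft_config = NULL) {
  stopifnot(is(base, "TrainedCLM"))
  if (!identical(base@vocab@tokens, pairs@vocab@tokens)) {
    stop("vocabulary mismatch between base model and fine-tuning pairs",
         call. = FALSE)
  }
  cfg <- ft_config %||% clmConfig(n_layers = base@config$n_layers,
                                  hidden_units = base@config$hidden_units,
                                  learning_rate = 5e-7,
                                  batch_size = base@config$batch_size,
                                  clip_norm = 1,
                                  seed = base@config$seed)
  if (cfg$max_epochs == 0L) {
    return(new("TrainedCLM", params = base@params, vocab = base@vocab,
               config = cfg,
               history = data.frame(epoch = integer(0),
                                    train_loss = numeric(0),
                                    val_loss = numeric(0)),
               best_epoch = 0L))
  }
  trainCLM(pairs, cfg, val_pairs, init_params = base@params)
}

#' @describeIn trainCLM Per-epoch training history of a model.
#' @param model A [TrainedCLM-class].
#' @export
trainingHistory <- function(model) {
  stopifnot(is(model, "TrainedCLM"))
  model@history
}

#' @describeIn trainCLM Epoch whose weights the model carries.
#' @export
bestEpoch <- function(model) {
  stopifnot(is(model, "TrainedCLM"))
  model@best_epoch
}

## Effective sampling logits: the pad and begin tokens are never emitted,
## so their logits are removed from the distribution before temperature
## scaling (a numerical guard; both are untrained as targets).
.sampleMaskVector <- function(vocab) {
  !vocabTokens(vocab) %in% c("<pad>", "G")
}

#' Next-token distribution of a trained model
#'
#' Feeds `G` followed by `prefix` through the model and returns the
#' temperature-scaled probability of each candidate next token, restricted
#' to the tokens the sampler can emit (all but the padding and begin
#' markers).
#'
#' @param model A [TrainedCLM-class].
#' @param prefix Character vector of tokens already emitted (without
#'   markers); empty for the first sampling position.
#' @param temperature Sampling temperature.
#' @return Named probability vector over the emittable tokens.
#' @export
nextTokenProbabilities <- function(model, prefix = character(0),
                                   temperature = 1) {
  stopifnot(is(model, "TrainedCLM"))
  vocab <- model@vocab
  idx <- .tokenPositions(c("G", prefix), vocab)
  H <- nrow(model@params$Wy)
  state <- .zeroState(1L, H, .nLayers(model@params))
  for (t in seq_along(idx)) {
    res <- .lstmStep(model@params, .onehot(idx[t], vocabSize(vocab)), state)
    state <- res$state
  }
  keep <- .sampleMaskVector(vocab)
  z <- drop(res$logits)[keep]
  p <- temperatureProbabilities(z, temperature)
  setNames(p, vocabTokens(vocab)[keep])
}

## Core batched sampler.  Returns a list with the emitted strings and (for
## diagnostics) the matrix of raw token draws.  Runs under the caller's
## RNG state.
.clmSampleBatch <- function(model, n, temperature, max_len) {
  vocab <- model@vocab
  toks <- vocabTokens(vocab)
  V <- length(toks)
  H <- nrow(model@params$Wy)
  L <- .nLayers(model@params)
  keep <- .sampleMaskVector(vocab)
  g_idx <- .tokenPositions("G", vocab)
  e_idx <- .tokenPositions("E", vocab)
  state <- .zeroState(n, H, L)
  cur <- rep(g_idx, n)
  finished <- rep(FALSE, n)
  draws <- matrix(0L, n, max_len - 1L)
  max_steps <- max_len - 1L
  k <- sum(keep)
  cumsum_op <- matrix(0, k, k)
  cumsum_op[upper.tri(cumsum_op, diag = TRUE)] <- 1
  for (step in seq_len(max_steps)) {
    res <- .lstmStep(model@params, .onehot(cur, V), state)
    state <- res$state
    z <- res$logits[, keep, drop = FALSE] / temperature
    p <- .softmaxRows(z)
    cp <- p %*% cumsum_op
    u <- stats::runif(n)
    pick <- rowSums(cp < u) + 1L
    pick <- pmin(pick, ncol(p))
    idx <- which(keep)[pick]
    idx[finished] <- e_idx
    draws[, step] <- idx
    finished <- finished | idx == e_idx
    cur <- idx
    if (all(finished)) break
  }
  strings <- vapply(seq_len(n), function(s) {
    row <- draws[s, ]
    row <- row[row != 0L]
    stop_at <- which(row == e_idx)
    content <- if (length(stop_at)) row[seq_len(stop_at[1] - 1L)] else row
    ## cap content at max_len - 2 so G + content + E fits in max_len
    content <- utils::head(content, max_len - 2L)
    paste(toks[content], collapse = "")
  }, character(1))
  list(strings = strings, draws = draws)
}

#' Sample SMILES strings from a trained model
#'
#' Temperature sampling: generation starts from the begin marker `G`, each
#' next token is drawn from [temperatureProbabilities()] of the model's
#' logits, and a sequence stops at the end marker `E` or at `max_len`
#' tokens.  Raw strings are returned with markers stripped; syntactically
#' invalid strings are legitimate outputs and are scored downstream.
#'
#' @param model A [TrainedCLM-class].
#' @param n_samples Strings drawn per repeat.
#' @param temperature Sampling temperature `T > 0`.
#' @param max_len Maximum sequence length including markers.
#' @param repeats Number of independent sampling repeats (the reference
#'   protocol samples 1000 strings across 3 repeats); each repeat uses an
#'   independently derived seed.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A list of `repeats` character vectors of length `n_samples`.
#' @export
sampleCLM <- function(model, n_samples = 1000L, temperature = 1,
                      max_len = 150L, repeats = 1L, seed = NULL) {
  stopifnot(is(model, "TrainedCLM"), n_samples >= 1L, repeats >= 1L,
            max_len >= 3L)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  run <- function() {
    rep_seeds <- sample.int(.Machine$integer.max, repeats)
    lapply(rep_seeds, function(s) {
      withr::with_seed(s,
        .clmSampleBatch(model, n_samples, temperature, max_len)$strings)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Self-training augmentation
#'
#' Trains a model on the original (non-augmented, non-canonical) training
#' strings, samples from it at low temperature (`T = 0.5`), retains the
#' valid, unique and novel strings (canonical form absent from the training
#' set), and attaches up to `(fold - 1) * n` synthetic strings to the
#' dataset, distributed round-robin across source molecules.  Sampling
#' stops after drawing `budget_factor` times the requested number of
#' synthetic strings (saturation).
#'
#' @param smiles Character vector of training SMILES.
#' @param clm_config A [clmConfig()] list for the internal model.
#' @param fold Augmentation fold; `fold = 1` trains no model.
#' @param temperature Sampling temperature for synthetic strings.
#' @param budget_factor Sampling budget as a multiple of the requested
#'   number of synthetic strings.
#' @param val_fraction Fraction of molecules held out for early stopping.
#' @param seed Integer seed.
#' @param max_attempts Retained for fold-controller symmetry (saturation
#'   accounting).
#' @return An [AugmentedSmiles-class].
#' @export
selfTrainAugment <- function(smiles, clm_config, fold, temperature = 0.5,
                             budget_factor = 20L, val_fraction = 0.1,
                             seed = 1L, max_attempts = 20L) {
  cfg <- augmentationConfig("self_training", fold = fold, seed = seed,
                            max_attempts = max_attempts)
  withr::with_seed(seed,
    .selfTrainCore(smiles, cfg, clm_config, temperature, budget_factor,
                   val_fraction))
}

## Called by augmentToFold under its RNG state.
.selfTrainFold <- function(smiles, config, clm_config, val_fraction) {
  .selfTrainCore(smiles, config, clm_config, temperature = 0.5,
                 budget_factor = 20L, val_fraction = val_fraction)
}

.selfTrainCore <- function(smiles, config, clm_config, temperature,
                           budget_factor, val_fraction) {
  n <- length(smiles)
  need <- (config@fold - 1L) * n
  acc <- replicate(n, character(0), simplify = FALSE)
  if (need > 0L) {
    n_val <- max(1L, round(val_fraction * n))
    if (n_val >= n) stop("dataset too small for a validation split",
                         call. = FALSE)
    val_rows <- sample.int(n, n_val)
    base <- .buildAugmentedSmiles(smiles, replicate(n, character(0),
                                                    simplify = FALSE),
                                  replicate(n, character(0),
                                            simplify = FALSE), config)
    vocab <- smilesVocabulary(tokenizeSmiles(smiles, with_markers = TRUE))
    train_aug <- .subsetAugmented(base, setdiff(seq_len(n), val_rows))
    val_aug <- .subsetAugmented(base, val_rows)
    pairs <- makeTrainingPairs(train_aug, vocab)
    val_pairs <- makeTrainingPairs(val_aug, vocab)
    model <- trainCLM(pairs, clm_config, val_pairs)
    train_canon <- unique(canonicalizeSmiles(smiles))
    retained <- character(0)
    retained_canon <- character(0)
    drawn <- 0L
    budget <- budget_factor * need
    while (length(retained) < need && drawn < budget) {
      k <- min(max(need, 100L), budget - drawn)
      raw <- .clmSampleBatch(model, k, temperature, 150L)$strings
      drawn <- drawn + k
      raw <- raw[nzchar(raw)]
      raw <- setdiff(raw, c(smiles, retained))
      if (!length(raw)) next
      canon <- canonicalizeSmiles(raw, strict = FALSE)
      ok <- !is.na(canon) & !canon %in% c(train_canon, retained_canon) &
        !duplicated(canon)
      add <- raw[ok]
      add_canon <- canon[ok]
      if (length(add) > need - length(retained)) {
        take <- seq_len(need - length(retained))
        add <- add[take]
        add_canon <- add_canon[take]
      }
      retained <- c(retained, add)
      retained_canon <- c(retained_canon, add_canon)
    }
    if (length(retained)) {
      owner <- rep(seq_len(n), length.out = length(retained))
      for (j in seq_along(retained)) {
        acc[[owner[j]]] <- c(acc[[owner[j]]], retained[j])
      }
    }
  }
  .buildAugmentedSmiles(smiles, acc, acc, config)
}

## Restrict an AugmentedSmiles to a subset of source molecules (by row in
## the molecules table).
.subsetAugmented <- function(aug, rows) {
  mol <- aug@molecules[rows, , drop = FALSE]
  st <- aug@strings[aug@strings$source_id %in% mol$source_id, ,
                    drop = FALSE]
  rownames(mol) <- rownames(st) <- NULL
  new("AugmentedSmiles", strings = st, molecules = mol)
}
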