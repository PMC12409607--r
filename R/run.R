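## End-to-end orchestration: one experiment cell = curate -> augment ->
## train -> sample -> evaluate, driven by a serializable run configuration.

#' Build a run configuration
#'
#' Assembles the full configuration of one experiment cell with the
#' defaults used throughout the package.  The object is a plain named list
#' and serializes losslessly to JSON/YAML ([writeRunConfig()],
#' [readRunConfig()]); a run re-executed from its persisted configuration
#' and seed reproduces identical SMILES outputs.
#'
#' @param input Path to a SMILES line file, or a character vector of
#'   SMILES.
#' @param strategy,variant,p,fold,max_attempts Augmentation settings, see
#'   [augmentationConfig()].
#' @param clm [clmConfig()]-style list of model hyperparameters.
#' @param n_samples,temperature,max_len,repeats Sampling settings, see
#'   [sampleCLM()].
#' @param val_fraction Validation share of the curated molecules.
#' @param fg_library,bio_table Optional resource paths (`NULL` = bundled
#'   defaults where required).
#' @param top_k Most frequent training scaffolds to match in the report.
#' @param seed Global seed; every stage derives its own stream from it.
#' @param out_dir Optional output directory for artifacts.
#' @return A named list.
#' @export
runConfig <- function(input, strategy = "enumeration", variant = NULL,
                      p = NULL, fold = 1L, max_attempts = 20L,
                      clm = clmConfig(), n_samples = 1000L,
                      temperature = 1.0, max_len = 150L, repeats = 3L,
                      val_fraction = 0.1, fg_library = NULL,
                      bio_table = NULL, top_k = 5L, seed = 1L,
                      out_dir = NULL) {
  aug <- augmentationConfig(strategy, variant, p, fold, seed, max_attempts)
  list(input = input,
       augmentation = list(strategy = aug@strategy, variant = aug@variant,
                           p = aug@p, fold = aug@fold,
                           max_attempts = aug@max_attempts),
       clm = clm,
       sampling = list(n_samples = as.integer(n_samples),
                       temperature = as.numeric(temperature),
                       max_len = as.integer(max_len),
                       repeats = as.integer(repeats)),
       val_fraction = as.numeric(val_fraction),
       resources = list(fg_library = fg_library, bio_table = bio_table),
       top_k = as.integer(top_k),
       seed = as.integer(seed),
       out_dir = out_dir)
}

#' Serialize / deserialize a run configuration
#'
#' JSON is the native format; files ending in `.yml`/`.yaml` are read and
#' written as YAML when the yaml package is available.
#'
#' @param config A [runConfig()] list.
#' @param path File path.
#' @return `readRunConfig()` returns the configuration list;
#'   `writeRunConfig()` returns `path` invisibly.
#' @export
writeRunConfig <- function(config, path) {
  if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    writeLines(yaml::as.yaml(config), path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
}

## Derive independent sub-seeds from a global seed (kept below 2^31).
.deriveSeeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Run one experiment cell
#'
#' Executes the full pipeline at any scale: curate the input molecules,
#' split train/validation, augment the training strings with the
#' configured strategy, train the language model, sample with temperature
#' across repeats, and evaluate the pooled samples (generation metrics,
#' eight-descriptor KS report against the training molecules, scaffold
#' report).  When `config$out_dir` is set, samples, reports (JSON and
#' tab-separated tables) and the configuration itself are written there.
#'
#' @param config A [runConfig()] list.
#' @param base_model Optional [TrainedCLM-class] to fine-tune instead of
#'   training from scratch (transfer learning).
#' @return A list with elements `curated`, `augmented`, `model`, `samples`
#'   (list per repeat), `metrics`, `ks_report`, `scaffold_report`.
#' @export
runExperiment <- function(config, base_model = NULL) {
  stopifnot(is.list(config))
  seeds <- .deriveSeeds(config$seed, 6L)
  input <- config$input
  if (length(input) == 1L && file.exists(input)) {
    input <- readLines(input, warn = FALSE)
    input <- input[nzchar(input)]
    input <- sub("\t.*$", "", input)  # optional tab-separated ID column
  }
  if (!length(input)) stop("empty input", call. = FALSE)

  curated <- curateSmiles(input, seed = seeds[1])
  rec <- curatedRecords(curated)
  if (nrow(rec) < 10L) {
    stop("fewer than 10 molecules survive curation", call. = FALSE)
  }
  n_val <- max(1L, round(config$val_fraction * nrow(rec)))
  val_rows <- withr::with_seed(seeds[2], sample.int(nrow(rec), n_val))
  train_rec <- rec[-val_rows, , drop = FALSE]
  val_rec <- rec[val_rows, , drop = FALSE]

  aug_cfg <- augmentationConfig(config$augmentation$strategy,
                                config$augmentation$variant,
                                config$augmentation$p,
                                config$augmentation$fold,
                                seed = seeds[3],
                                max_attempts = config$augmentation$max_attempts)
  fg <- NULL
  if (aug_cfg@strategy == "masking" &&
      aug_cfg@variant == "functional_group") {
    fg <- readFunctionalGroups(config$resources$fg_library)
  }
  bt <- NULL
  if (aug_cfg@strategy == "bioisostere") {
    bt <- readBioisostereTable(config$resources$bio_table)
  }
  clm_cfg <- do.call(clmConfig, config$clm)
  clm_cfg$seed <- seeds[4]
  train_smiles <- stats::setNames(train_rec$randomized_smiles,
                                  train_rec$id)
  aug <- augmentToFold(train_smiles, aug_cfg, fg_library = fg,
                       bio_table = bt, clm_config = clm_cfg,
                       val_fraction = config$val_fraction)

  val_aug <- augmentToFold(stats::setNames(val_rec$randomized_smiles,
                                           val_rec$id),
                           augmentationConfig("enumeration", fold = 1L,
                                              seed = seeds[3]))
  vocab <- smilesVocabulary(tokenizeSmiles(
    c(aug@strings$augmented, aug@strings$target,
      val_aug@strings$augmented), with_markers = TRUE))
  pairs <- makeTrainingPairs(aug, vocab,
                             max_len = config$sampling$max_len)
  val_pairs <- makeTrainingPairs(val_aug, vocab,
                                 max_len = config$sampling$max_len)
  model <- if (is.null(base_model)) {
    trainCLM(pairs, clm_cfg, val_pairs)
  } else {
    fineTuneCLM(base_model, pairs, val_pairs)
  }

  samples <- sampleCLM(model, config$sampling$n_samples,
                       config$sampling$temperature,
                       config$sampling$max_len,
                       config$sampling$repeats, seed = seeds[5])
  pooled <- unlist(samples)
  train_canon <- unique(train_rec$canonical_smiles)
  metrics <- generationMetrics(pooled, train_canon)
  ks <- descriptorKSReport(pooled, train_canon)
  scaf <- scaffoldReport(pooled, train_canon, top_k = config$top_k)

  out <- list(curated = curated, augmented = aug, model = model,
              samples = samples, metrics = metrics, ks_report = ks,
              scaffold_report = scaf)
  if (!is.null(config$out_dir)) {
    .writeExperimentArtifacts(out, config)
  }
  out
}

.writeExperimentArtifacts <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  writeRunConfig(config, p("config.json"))
  for (r in seq_along(out$samples)) {
    writeLines(out$samples[[r]], p(sprintf("samples_rep%d.smi", r)))
  }
  writeAugmentedSmiles(out$augmented, p("augmented.tsv"))
  m <- out$metrics
  jsonlite::write_json(
    list(generation = as.list(metricValues(m)),
         scaffold = as.list(scaffoldValues(out$scaffold_report)),
         ks = stats::setNames(as.list(ksTable(out$ks_report)$ks),
                              ksTable(out$ks_report)$descriptor)),
    p("metrics.json"), auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(ksTable(out$ks_report), p("ks_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(topScaffoldMatches(out$scaffold_report),
                     p("top_scaffolds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
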