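## show() methods for the package's S4 containers.

setMethod("show", "SmilesVocabulary", function(object) {
  cat("SmilesVocabulary of", length(object@tokens), "tokens\n")
  cat("  ", paste(utils::head(object@tokens, 12), collapse = " "),
      if (length(object@tokens) > 12) "..." else "", "\n")
})

setMethod("show", "AugmentationConfig", function(object) {
  cat("AugmentationConfig:", object@strategy,
      if (object@variant != "none") paste0("(", object@variant, ")") else "",
      "\n")
  cat("  p =", object@p, " fold =", object@fold, " seed =", object@seed,
      " max_attempts =", object@max_attempts, "\n")
})

setMethod("show", "AugmentedSmiles", function(object) {
  n_mol <- nrow(object@molecules)
  n_aug <- sum(!object@strings$is_original)
  cat("AugmentedSmiles:", n_mol, "molecules,", n_aug,
      "augmented strings\n")
  cat("  strategy:", object@strings$strategy[1],
      if (object@strings$variant[1] != "none")
        paste0("(", object@strings$variant[1], ")") else "", "\n")
  cat("  achieved mean fold:",
      round(1 + n_aug / max(n_mol, 1L), 2), "\n")
  cat("  saturated molecules:", sum(object@molecules$saturated), "\n")
})

setMethod("show", "TrainingPairSet", function(object) {
  cat("TrainingPairSet:", length(object@input), "pairs, vocabulary of",
      length(object@vocab@tokens), "tokens\n")
  if (object@n_dropped > 0) {
    cat("  over-length strings dropped:", object@n_dropped, "\n")
  }
})

setMethod("show", "BioisostereTable", function(object) {
  cat("BioisostereTable:", length(object@entries), "fragment keys, top",
      object@top_k, "replacements each\n")
  for (k in utils::head(names(object@entries), 5)) {
    cat("  ", k, "->", nrow(object@entries[[k]]), "candidate(s)\n")
  }
  if (length(object@entries) > 5) cat("  ...\n")
})

setMethod("show", "TrainedCLM", function(object) {
  cat("TrainedCLM:", object@config$n_layers, "LSTM layer(s) x",
      object@config$hidden_units, "units, vocabulary of",
      length(object@vocab@tokens), "tokens\n")
  if (nrow(object@history)) {
    cat("  epochs run:", nrow(object@history), " best epoch:",
        object@best_epoch, " best val loss:",
        signif(min(object@history$val_loss), 4), "\n")
  }
})

setMethod("show", "GenerationMetrics", function(object) {
  cat("GenerationMetrics (n_raw =", object@n_raw, ")\n")
  cat(sprintf("  validity:   %5.1f%%  (%d valid)\n", object@validity_pct,
              object@n_valid))
  cat(sprintf("  uniqueness: %5.1f%%  (%d unique)\n", object@uniqueness_pct,
              object@n_unique))
  cat(sprintf("  novelty:    %5.1f%%  (%d novel)\n", object@novelty_pct,
              object@n_novel))
})

setMethod("show", "KSReport", function(object) {
  cat("KSReport over", nrow(object@table), "descriptors (n_design =",
      object@table$n_design[1], ", n_reference =",
      object@table$n_reference[1], ")\n")
  tab <- object@table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-18s KS = %.3f  (x100: %5.1f)\n", tab$descriptor[i],
                tab$ks[i], tab$ks_x100[i]))
  }
})

setMethod("show", "ScaffoldReport", function(object) {
  cat("ScaffoldReport (", object@n_valid, "valid designs )\n")
  cat(sprintf("  scaffold diversity:    %5.1f%%\n", object@diversity_pct))
  cat(sprintf("  scaffold novelty (FT): %5.1f%%\n", object@novelty_ft_pct))
  if (!is.na(object@novelty_pt_pct)) {
    cat(sprintf("  scaffold novelty (PT): %5.1f%%\n", object@novelty_pt_pct))
  }
})

setMethod("show", "CurationPolicy", function(object) {
  cat("CurationPolicy: atoms {",
      paste(object@allowed_atoms, collapse = ","), "}, ",
      object@min_tokens, "-", object@max_tokens, " tokens\n", sep = "")
})

setMethod("show", "CuratedSmiles", function(object) {
  cat("CuratedSmiles:", nrow(object@records), "molecules kept,",
      nrow(object@rejections), "rejected\n")
  if (nrow(object@rejections)) {
    print(table(object@rejections$reason))
  }
})

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan: nested subsets of size",
      paste(object@sizes, collapse = " < "), "\n")
  cat("  clusters:", length(unique(object@clusters)), " test size:",
      length(object@test), "\n")
})
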