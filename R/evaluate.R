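## Evaluation of generated SMILES sets: the validity / uniqueness / novelty
## chain, descriptor-wise Kolmogorov-Smirnov distances against a reference
## set, and Bemis-Murcko scaffold diversity / novelty.

#' Validity, uniqueness and novelty of generated strings
#'
#' Computes the filtering chain on a raw sample: validity is the percentage
#' of strings that sanitize to valid molecules; uniqueness the percentage
#' of distinct canonical forms among the valid ones (molecule-level, not
#' raw text); novelty the percentage of unique canonical forms absent from
#' the training references.  The denominators are, respectively, the raw,
#' valid and unique counts, so the chain
#' `n_raw >= n_valid >= n_unique >= n_novel` always holds.
#'
#' @param samples Character vector of raw generated strings (invalid
#'   strings allowed).
#' @param training_refs Character vector of canonical SMILES the novelty is
#'   measured against.
#' @return A [GenerationMetrics-class].
#' @export
generationMetrics <- function(samples, training_refs = character(0)) {
  stopifnot(is.character(samples))
  if (length(samples) == 0L) {
    stop("cannot compute metrics of an empty sample", call. = FALSE)
  }
  canon <- rep(NA_character_, length(samples))
  nonempty <- nzchar(samples) & !is.na(samples)
  if (any(nonempty)) {
    canon[nonempty] <- canonicalizeSmiles(samples[nonempty], strict = FALSE)
  }
  valid <- canon[!is.na(canon)]
  uniq <- unique(valid)
  novel <- setdiff(uniq, training_refs)
  new("GenerationMetrics",
      n_raw = length(samples), n_valid = length(valid),
      n_unique = length(uniq), n_novel = length(novel),
      validity_pct = 100 * length(valid) / length(samples),
      uniqueness_pct = if (length(valid)) 100 * length(uniq) / length(valid)
                       else NA_real_,
      novelty_pct = if (length(uniq)) 100 * length(novel) / length(uniq)
                    else NA_real_)
}

#' @describeIn generationMetrics Metrics as a named numeric vector.
#' @param x A [GenerationMetrics-class].
#' @export
metricValues <- function(x) {
  stopifnot(is(x, "GenerationMetrics"))
  c(n_raw = x@n_raw, n_valid = x@n_valid, n_unique = x@n_unique,
    n_novel = x@n_novel, validity_pct = x@validity_pct,
    uniqueness_pct = x@uniqueness_pct, novelty_pct = x@novelty_pct)
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' The supremum over `x` of the absolute difference between the two
#' empirical cumulative distribution functions; symmetric, in `[0, 1]`,
#' and invariant to common positive rescaling of both samples.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return The KS statistic.
#' @examples
#' ksDistance(c(1, 2), c(1, 2, 3))  # 1/3
#' @export
ksDistance <- function(sample_a, sample_b) {
  stopifnot(is.numeric(sample_a), is.numeric(sample_b))
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pts <- sort(unique(c(sample_a, sample_b)))
  Fa <- stats::ecdf(sample_a)(pts)
  Fb <- stats::ecdf(sample_b)(pts)
  max(abs(Fa - Fb))
}

.DESCRIPTOR_NAMES <- c("n_aliphatic_rings", "n_aromatic_rings", "mw",
                       "logp", "hbd", "hba", "tpsa", "n_rotatable_bonds")

#' Descriptor-wise KS report
#'
#' For each of the eight physico-chemical descriptors, the KS distance
#' between the valid de novo designs and a reference set (typically the
#' training molecules).  The `ks_x100` column carries the x100 display
#' scale used in the literature's tables.
#'
#' @param designs Character vector of generated strings; invalid strings
#'   are filtered out first.
#' @param reference Character vector of valid reference SMILES.
#' @return A [KSReport-class].
#' @export
descriptorKSReport <- function(designs, reference) {
  stopifnot(is.character(designs), is.character(reference),
            length(reference) >= 1L)
  canon <- rep(NA_character_, length(designs))
  nonempty <- nzchar(designs) & !is.na(designs)
  if (any(nonempty)) {
    canon[nonempty] <- canonicalizeSmiles(designs[nonempty], strict = FALSE)
  }
  valid <- canon[!is.na(canon)]
  if (length(valid) == 0L) {
    stop("no valid designs to evaluate", call. = FALSE)
  }
  d_des <- computeDescriptors(valid)
  d_ref <- computeDescriptors(reference)
  ks <- vapply(.DESCRIPTOR_NAMES, function(nm)
    ksDistance(d_des[[nm]], d_ref[[nm]]), numeric(1))
  tab <- data.frame(descriptor = .DESCRIPTOR_NAMES, ks = unname(ks),
                    ks_x100 = unname(100 * ks),
                    n_design = length(valid),
                    n_reference = length(reference),
                    stringsAsFactors = FALSE)
  new("KSReport", table = tab)
}

#' @describeIn descriptorKSReport The per-descriptor table of a report.
#' @param x A [KSReport-class].
#' @export
ksTable <- function(x) {
  stopifnot(is(x, "KSReport"))
  x@table
}

#' Scaffold diversity and novelty report
#'
#' All scaffold metrics use non-generic Bemis-Murcko scaffolds of the valid
#' designs; acyclic molecules map to the empty scaffold, counted as one
#' scaffold class.  Diversity is the number of distinct design scaffolds as
#' a percentage of valid designs; scaffold novelty is the number of
#' distinct design scaffolds absent from the fine-tuning (and, when given,
#' pre-training) scaffold sets, on the same denominator.  The top-scaffold
#' table compares the fine-tuning set's `top_k` most frequent scaffolds
#' with their occurrence among the designs.
#'
#' @param designs Character vector of generated strings; invalid strings
#'   are filtered out first.
#' @param ft_set Character vector of fine-tuning (training) SMILES.
#' @param pt_scaffolds Optional character vector of pre-training scaffold
#'   SMILES (already computed, as the pre-training set is typically large).
#' @param top_k Number of most frequent fine-tuning scaffolds to match.
#' @return A [ScaffoldReport-class].
#' @export
scaffoldReport <- function(designs, ft_set, pt_scaffolds = NULL,
                           top_k = 5L) {
  stopifnot(is.character(designs), is.character(ft_set),
            length(ft_set) >= 1L)
  canon <- rep(NA_character_, length(designs))
  nonempty <- nzchar(designs) & !is.na(designs)
  if (any(nonempty)) {
    canon[nonempty] <- canonicalizeSmiles(designs[nonempty], strict = FALSE)
  }
  valid <- canon[!is.na(canon)]
  if (length(valid) == 0L) {
    stop("no valid designs to evaluate", call. = FALSE)
  }
  des_scaf <- bemisMurckoScaffold(valid)
  ft_scaf <- bemisMurckoScaffold(ft_set)
  uniq <- unique(des_scaf)
  novel_ft <- setdiff(uniq, ft_scaf)
  n_valid <- length(valid)
  novelty_pt <- NA_real_
  if (!is.null(pt_scaffolds)) {
    novelty_pt <- 100 * length(setdiff(uniq, pt_scaffolds)) / n_valid
  }
  ft_freq <- sort(table(ft_scaf), decreasing = TRUE)
  top <- utils::head(names(ft_freq), top_k)
  matches <- data.frame(
    scaffold = top,
    ft_pct = 100 * as.numeric(ft_freq[top]) / length(ft_scaf),
    design_pct = vapply(top, function(sc)
      100 * sum(des_scaf == sc) / n_valid, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  new("ScaffoldReport",
      diversity_pct = 100 * length(uniq) / n_valid,
      novelty_ft_pct = 100 * length(novel_ft) / n_valid,
      novelty_pt_pct = novelty_pt,
      top_scaffold_matches = matches,
      n_valid = as.integer(n_valid))
}

#' @describeIn scaffoldReport Scaffold metrics as a named numeric vector.
#' @param x A [ScaffoldReport-class].
#' @export
scaffoldValues <- function(x) {
  stopifnot(is(x, "ScaffoldReport"))
  c(diversity_pct = x@diversity_pct, novelty_ft_pct = x@novelty_ft_pct,
    novelty_pt_pct = x@novelty_pt_pct, n_valid = x@n_valid)
}

#' @describeIn scaffoldReport The top-scaffold matching table.
#' @export
topScaffoldMatches <- function(x) {
  stopifnot(is(x, "ScaffoldReport"))
  x@top_scaffold_matches
}
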