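# Shared fixtures, built once per test run.  Everything is generated in
# code; no stored data files.

# small synthetic library used across module tests
fix_lib <- function(n = 40L, seed = 5L) generateFixtureLibrary(n, seed)

fg_default <- local({
  fg <- NULL
  function() {
    if (is.null(fg)) fg <<- readFunctionalGroups()
    fg
  }
})

bio_default <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- readBioisostereTable()
    tab
  }
})

# a closed toy language for memorization tests
toy_corpus <- function() {
  c("CCO", "CCN", "CCC", "CCF", "COC", "CCCl", "CC=O", "CC#N", "CCCO",
    "CCCN", "c1ccccc1", "c1ccncc1", "C1CCCCC1", "CC(C)O", "CC(C)N",
    "CCOC", "CCSC", "CC(N)=O", "CC(=O)O", "C1CCOC1")
}

# training pairs for a plain (non-augmented) corpus
plain_pairs <- function(corpus, vocab = NULL) {
  aug <- augmentToFold(corpus, augmentationConfig("enumeration", fold = 1L,
                                                  seed = 1L))
  if (is.null(vocab)) {
    vocab <- smilesVocabulary(tokenizeSmiles(corpus, with_markers = TRUE))
  }
  makeTrainingPairs(aug, vocab)
}

# brute-force ECDF sup-difference, the independent oracle for ksDistance
ks_bruteforce <- function(a, b) {
  pts <- c(a, b)
  d <- 0
  for (x in pts) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}
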