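test_that("token deletion follows its variant contracts", {
  toks <- tokenizeSmiles("C1CC(CO)C1")[[1]]
  # p = 0 is the identity for every variant
  for (v in c("random", "validity", "protected")) {
    res <- withr::with_seed(1, deleteTokens(toks, p = 0, variant = v))
    expect_false(res$rejected)
    expect_equal(res$tokens, toks)
  }
  # p = 1 protected keeps exactly the ring/branch tokens
  res <- withr::with_seed(1, deleteTokens(tokenizeSmiles("C1CC1")[[1]],
                                          p = 1, variant = "protected"))
  expect_equal(res$tokens, c("1", "1"))
  res2 <- withr::with_seed(1, deleteTokens(toks, p = 1,
                                           variant = "protected"))
  expect_equal(res2$tokens, c("1", "(", ")", "1"))
  expect_error(deleteTokens(toks, p = 1.5), "probability")
  expect_error(deleteTokens(c("G", "C", "E"), p = 0.1), "marker")
})

test_that("deleted fraction follows the binomial law", {
  toks <- rep("C", 20L)
  p <- 0.15
  n_trials <- 10000L
  frac <- withr::with_seed(42, vapply(seq_len(n_trials), function(i) {
    1 - length(smilesaugment:::.deleteDraw(toks, p, "random")) / 20
  }, numeric(1)))
  se <- sqrt(p * (1 - p) / 20 / n_trials)
  expect_lt(abs(mean(frac) - p), 3 * se)
})

test_that("validity-enforced deletion returns valid strings or rejections", {
  toks <- tokenizeSmiles("CCOC(=O)c1ccccc1")[[1]]
  res <- withr::with_seed(3, replicate(10, {
    r <- deleteTokens(toks, p = 0.1, variant = "validity",
                      max_attempts = 10L)
    if (r$rejected) NA_character_ else r$smiles
  }))
  accepted <- res[!is.na(res)]
  expect_gt(length(accepted), 0L)
  expect_true(all(isValidSmiles(accepted)))
  # an unsalvageable sequence is rejected, not an error
  r <- withr::with_seed(1, deleteTokens(c("1", "1"), p = 0.5,
                                        variant = "validity",
                                        max_attempts = 5L))
  expect_true(r$rejected)
  expect_null(r$tokens)
})

test_that("protected deletion never touches ring or branch tokens", {
  toks <- tokenizeSmiles("CC1(C)c2ccccc2C(=O)N1C")[[1]]
  prot <- toks[smilesaugment:::.isProtectedToken(toks)]
  for (p in c(0, 0.05, 0.3, 1)) {
    res <- withr::with_seed(7, deleteTokens(toks, p, "protected"))
    kept_prot <- res$tokens[smilesaugment:::.isProtectedToken(res$tokens)]
    expect_equal(kept_prot, prot)
  }
})

test_that("atom masking replaces atoms by '*' and nothing else", {
  expect_equal(as.character(withr::with_seed(1,
    maskAtoms("CCO", p = 0))), "CCO")
  m <- withr::with_seed(1, maskAtoms("CCO", p = 1))
  expect_equal(as.character(m), "***")
  # functional-group mode masks exactly the matched atoms at p = 1
  m2 <- withr::with_seed(1, maskAtoms("CC(=O)O", p = 1,
                                      mode = "functional_group",
                                      fg_library = fg_default()))
  expect_equal(as.character(m2), "C*(=*)*")
  expect_equal(attr(m2, "unmasked"), "CC(=O)O")
  # masked and unmasked differ only at '*' positions, same length
  lib <- fix_lib(15)
  mm <- withr::with_seed(2, maskAtoms(lib, p = 0.3))
  for (i in seq_along(lib)) {
    tk_m <- tokenizeSmiles(mm[i])[[1]]
    tk_u <- tokenizeSmiles(attr(mm, "unmasked")[i])[[1]]
    expect_equal(length(tk_m), length(tk_u))
    diff <- tk_m != tk_u
    expect_true(all(tk_m[diff] == "*"))
  }
  expect_error(maskAtoms("CCO", p = 0.5, mode = "functional_group"),
               "SMARTS")
})

test_that("masking preserves heavy-atom count and graph topology", {
  lib <- fix_lib(12)
  mm <- withr::with_seed(4, maskAtoms(lib, p = 0.25))
  info_orig <- smilesaugment:::rdkitBridge("atom_info",
                                           list(smiles = I(lib)))
  info_mask <- smilesaugment:::rdkitBridge("atom_info",
                                           list(smiles = I(as.character(mm))))
  expect_true(all(unlist(info_mask$valid)))
  expect_equal(unlist(info_mask$n_atoms), unlist(info_orig$n_atoms))
})

test_that("enumeration saturates and preserves identity", {
  expect_length(enumerateSmiles("C", 10L, seed = 1L), 0L)
  out <- enumerateSmiles("CCc1ccc(Cl)cc1C(=O)O", 8L, seed = 2L)
  expect_gt(length(out), 0L)
  expect_equal(anyDuplicated(out), 0L)
  expect_equal(unique(canonicalizeSmiles(out)),
               canonicalizeSmiles("CCc1ccc(Cl)cc1C(=O)O"))
  expect_false(any(out == "CCc1ccc(Cl)cc1C(=O)O"))
})

test_that("the fold controller enforces fold semantics", {
  lib <- fix_lib(10)
  # fold = 1: only originals
  a1 <- augmentToFold(lib, augmentationConfig("enumeration", fold = 1L,
                                              seed = 1L))
  expect_true(all(augmentedStrings(a1)$is_original))
  expect_equal(sourceMolecules(a1)$n_augmented, rep(0L, 10L))
  # a molecule with few variants saturates with the flag set
  a2 <- augmentToFold("CCO", augmentationConfig("enumeration", fold = 10L,
                                                seed = 1L))
  mol <- sourceMolecules(a2)
  expect_lt(mol$n_augmented, 9L)
  expect_true(mol$saturated)
  # per-molecule augmented strings are unique and differ from the original
  a3 <- augmentToFold(lib, augmentationConfig("deletion", "random",
                                              fold = 4L, seed = 2L))
  st <- augmentedStrings(a3)
  for (id in unique(st$source_id)) {
    rows <- st[st$source_id == id, ]
    expect_equal(anyDuplicated(rows$augmented), 0L)
    expect_false(any(rows$augmented[!rows$is_original] %in% lib))
  }
  # determinism: same seed, identical dataset
  cfg <- augmentationConfig("masking", "random", fold = 3L, seed = 5L)
  b1 <- augmentToFold(lib, cfg)
  b2 <- augmentToFold(lib, cfg)
  expect_identical(augmentedStrings(b1), augmentedStrings(b2))
})

test_that("training pairs pair masked inputs with unmasked targets", {
  lib <- fix_lib(8)
  aug <- augmentToFold(lib, augmentationConfig("masking", "random",
                                               fold = 3L, seed = 3L))
  pairs <- makeTrainingPairs(aug)
  expect_s4_class(pairs, "TrainingPairSet")
  st <- augmentedStrings(aug)
  masked_rows <- which(!st$is_original)
  expect_gt(length(masked_rows), 0L)
  for (k in seq_along(pairs@input)) {
    expect_length(pairs@input[[k]], length(pairs@target[[k]]))
    diff <- pairs@input[[k]] != pairs@target[[k]]
    expect_true(all(pairs@input[[k]][diff] == "*"))
  }
  # non-masking strategies give input == target
  aug2 <- augmentToFold(lib, augmentationConfig("deletion", "random",
                                                fold = 3L, seed = 3L))
  pairs2 <- makeTrainingPairs(aug2)
  expect_identical(pairs2@input, pairs2@target)
  # over-length strings are dropped and counted
  suppressMessages(pairs3 <- makeTrainingPairs(aug2, max_len = 12L))
  expect_equal(length(pairs3@input) + pairs3@n_dropped,
               length(pairs2@input))
  expect_gt(pairs3@n_dropped, 0L)
})
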