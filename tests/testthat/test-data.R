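test_that("curation rejects with machine-readable reason codes", {
  raw <- c("C[Si](C)C",          # disallowed atom
           "CCO",                # 3 tokens, too short
           "CCOC(=O)c1ccccc1",   # kept
           "c1ccccc1C(=O)OCC",   # duplicate of the former (same molecule)
           "C(C",                # unparsable
           "CC(=O)[O-].[Na+]",   # salt: desalted + neutralized, kept
           "F/C=C/c1ccccc1N")    # stereo stripped, kept
  cur <- curateSmiles(raw, seed = 2L)
  rej <- rejectionLog(cur)
  expect_equal(rej$reason[rej$input_smiles == "C[Si](C)C"], "ATOM")
  expect_equal(rej$reason[rej$input_smiles == "CCO"], "LENGTH")
  expect_equal(rej$reason[rej$input_smiles == "C(C"], "PARSE")
  expect_equal(rej$reason[rej$input_smiles == "c1ccccc1C(=O)OCC"], "DUP")
  rec <- curatedRecords(cur)
  expect_equal(nrow(rec), 3L)
  # desalting keeps the acetate, neutralized
  expect_equal(rec$canonical_smiles[rec$input_smiles ==
                                    "CC(=O)[O-].[Na+]"], "CC(=O)O")
  # stereochemistry is stripped
  expect_false(grepl("[/\\\\@]",
                     rec$canonical_smiles[rec$input_smiles ==
                                          "F/C=C/c1ccccc1N"]))
  # each survivor gets a randomized training representation
  expect_equal(canonicalizeSmiles(rec$randomized_smiles),
               rec$canonical_smiles)
})

test_that("curation is idempotent on its own output", {
  lib <- fix_lib(30)
  c1 <- curateSmiles(lib, seed = 1L)
  c2 <- curateSmiles(curatedRecords(c1)$canonical_smiles, seed = 1L)
  expect_equal(curatedRecords(c2)$canonical_smiles,
               curatedRecords(c1)$canonical_smiles)
  expect_equal(nrow(rejectionLog(c2)), 0L)
})

test_that("scaffold-stratified splits nest exactly and stay disjoint", {
  lib <- generateFixtureLibrary(320, seed = 13L)
  canon <- curatedRecords(curateSmiles(lib, seed = 1L))$canonical_smiles
  plan <- scaffoldClusterSplit(canon, sizes = c(60L, 120L, 240L),
                               test_size = 50L, n_clusters = 6L,
                               seed = 21L)
  s60 <- splitIndices(plan, 60); s120 <- splitIndices(plan, 120)
  s240 <- splitIndices(plan, 240)
  expect_length(s60, 60L)
  expect_length(s120, 120L)
  expect_true(all(s60 %in% s120) && all(s120 %in% s240))
  # train/val partition each subset; test disjoint from all subsets
  for (size in c(60, 120, 240)) {
    tr <- splitIndices(plan, size, "train")
    va <- splitIndices(plan, size, "val")
    expect_length(intersect(tr, va), 0L)
    expect_setequal(c(tr, va), splitIndices(plan, size))
  }
  expect_length(intersect(plan@test, s240), 0L)
  expect_length(plan@test, 50L)
  # stratification: subset cluster counts within 1 of proportional targets
  prop <- table(plan@clusters) / length(canon)
  for (size in c(60, 120, 240)) {
    counts <- table(factor(plan@clusters[splitIndices(plan, size)],
                           levels = names(prop)))
    expect_true(all(abs(counts - size * prop) <= 1))
  }
  # determinism
  plan2 <- scaffoldClusterSplit(canon, sizes = c(60L, 120L, 240L),
                                test_size = 50L, n_clusters = 6L,
                                seed = 21L)
  expect_identical(plan@subsets, plan2@subsets)
  expect_identical(plan@test, plan2@test)
  # more clusters than scaffold classes: reduced with a warning
  few <- c("CCCCCC", "CCCCCCC", "CCCCCCCC", "CCCCCCCCC")
  expect_warning(scaffoldClusterSplit(few, sizes = 2L, n_clusters = 10L,
                                      seed = 1L), "reducing")
})

test_that("similarity sets satisfy their pairwise bounds exhaustively", {
  lib <- generateFixtureLibrary(150, seed = 3L)
  hi <- similaritySets(lib, size = 10L, mode = "high", seed = 5L)
  expect_length(hi, 10L)
  m <- tanimotoMatrix(hi)
  expect_gte(min(m), 0.8)
  lo <- similaritySets(lib, size = 10L, mode = "low", seed = 5L)
  m2 <- tanimotoMatrix(lo)
  expect_lte(max(m2[upper.tri(m2)]), 0.4)
  # infeasible requests raise errors naming the achievable maximum
  expect_error(similaritySets(lib, size = length(lib) + 1L, mode = "low"),
               "available")
  expect_error(similaritySets(lib[1:40], size = 35L, mode = "high",
                              seed = 1L), "achievable maximum")
})

test_that("the fixture generator meets its contracts", {
  lib1 <- generateFixtureLibrary(120, seed = 9L)
  lib2 <- generateFixtureLibrary(120, seed = 9L)
  expect_identical(lib1, lib2)
  expect_equal(anyDuplicated(lib1), 0L)
  # 100% pass curation with the default policy
  cur <- curateSmiles(lib1, seed = 1L)
  expect_equal(nrow(curatedRecords(cur)), 120L)
  expect_equal(nrow(rejectionLog(cur)), 0L)
  # scaffold richness at library scale
  lib <- generateFixtureLibrary(500, seed = 2L)
  expect_gte(length(unique(bemisMurckoScaffold(lib))), 20L)
  # every functional group of the bundled SMARTS library is covered
  fg <- fg_default()
  sm <- smilesaugment:::rdkitBridge("smarts_matches",
                                    list(smiles = I(lib1),
                                         smarts = I(fg$smarts)))
  hits <- vapply(seq_along(fg$smarts), function(j)
    any(vapply(sm$matches, function(mm) length(mm[[j]]) > 0, logical(1))),
    logical(1))
  expect_true(all(hits))
  # at least one molecule carries a demo-table fragment key
  keys <- unlist(lapply(bricsDecompose(lib1[1:60]), `[[`, "key"))
  expect_gt(length(intersect(keys, bioisostereKeys(bio_default()))), 0L)
  expect_error(generateFixtureLibrary(10^6), "at most")
})
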