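test_that("canonicalization identifies molecules and is idempotent", {
  expect_equal(canonicalizeSmiles("OCC"), canonicalizeSmiles("CCO"))
  s <- canonicalizeSmiles("c1ccccc1CC(=O)O")
  expect_equal(canonicalizeSmiles(s), s)
  expect_error(canonicalizeSmiles("C(C"), "invalid SMILES")
  expect_equal(canonicalizeSmiles(c("CCO", "C(C"), strict = FALSE)[2],
               NA_character_)
  expect_equal(isValidSmiles(c("CCO", "C(C", "xyz")),
               c(TRUE, FALSE, FALSE))
})

test_that("randomized SMILES preserve molecular identity", {
  lib <- fix_lib(30)
  canon <- canonicalizeSmiles(lib)
  vars <- randomizeSmiles(lib, n_variants = 10L, seed = 7L)
  for (i in seq_along(lib)) {
    expect_equal(unique(canonicalizeSmiles(vars[[i]])), canon[i])
  }
  # single-atom molecule has a single representation
  expect_equal(unique(unlist(randomizeSmiles("C", 10L, seed = 1L))), "C")
  # a 10-heavy-atom molecule admits multiple distinct strings
  draws <- unlist(randomizeSmiles("CCc1ccc(O)cc1C", 200L, seed = 3L))
  expect_gte(length(unique(draws)), 2L)
})

test_that("the eight descriptors match known molecules", {
  d <- computeDescriptors(c("c1ccccc1", "CCO", "CCCC"))
  expect_named(d, c("n_aliphatic_rings", "n_aromatic_rings", "mw", "logp",
                    "hbd", "hba", "tpsa", "n_rotatable_bonds"))
  # benzene: one aromatic ring, no donors/acceptors
  expect_equal(d$n_aromatic_rings[1], 1)
  expect_equal(d$n_aliphatic_rings[1], 0)
  expect_equal(d$hbd[1], 0)
  expect_equal(d$hba[1], 0)
  # ethanol: one donor, no rotatable bonds
  expect_equal(d$hbd[2], 1)
  expect_equal(d$n_rotatable_bonds[2], 0)
  # pure hydrocarbon has zero polar surface area
  expect_equal(d$tpsa[3], 0)
  expect_true(all(d$mw > 0))
  # descriptors are a property of the molecule, not the SMILES form
  expect_equal(computeDescriptors("CCO"), computeDescriptors("OCC"))
  expect_error(computeDescriptors("C(C"), "invalid SMILES")
})

test_that("Bemis-Murcko scaffolds behave as ring-system extraction", {
  expect_equal(bemisMurckoScaffold("CCO"), "")
  expect_equal(bemisMurckoScaffold("CCc1ccccc1"),
               canonicalizeSmiles("c1ccccc1"))
  # idempotence
  sc <- bemisMurckoScaffold("CCc1ccc(CC(=O)O)cc1")
  expect_equal(bemisMurckoScaffold(sc), sc)
  # invariance to SMILES enumeration
  lib <- fix_lib(20)
  vars <- vapply(randomizeSmiles(lib, 1L, seed = 2L), `[`, character(1), 1L)
  expect_equal(bemisMurckoScaffold(vars), bemisMurckoScaffold(lib))
  # generic scaffolds abstract atom types
  expect_equal(bemisMurckoScaffold("c1ccncc1", generic = TRUE),
               bemisMurckoScaffold("c1ccccc1", generic = TRUE))
})

test_that("Tanimoto similarity is a proper similarity", {
  expect_equal(tanimotoSimilarity("CCO", "OCC"), 1)
  a <- "CCc1ccccc1"
  b <- "CCOC(=O)c1ccncc1"
  expect_equal(tanimotoSimilarity(a, b), tanimotoSimilarity(b, a))
  expect_lt(tanimotoSimilarity("C", "c1ccccc1"), 0.2)
  m <- tanimotoMatrix(c("CCO", "CCN", "c1ccccc1"))
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 3))
  expect_true(all(m >= 0 & m <= 1))
})
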