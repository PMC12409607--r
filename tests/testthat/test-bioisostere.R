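test_that("the replacement table keeps the top-k by frequency", {
  tab <- bio_default()
  # the acid key has 7 rows in the demo file; only the 5 most frequent stay
  acid <- tab@entries[["*C(=O)O"]]
  expect_equal(nrow(acid), 5L)
  expect_equal(acid$frequency, c(1000, 900, 800, 700, 600))
  expect_false(is.unsorted(rev(acid$frequency)))
  # top_k = 1 keeps exactly the modal replacement
  tab1 <- readBioisostereTable(top_k = 1L)
  expect_true(all(vapply(tab1@entries, nrow, 0L) == 1L))
  expect_equal(tab1@entries[["*C(=O)O"]]$replacement, "[1*]c1nnn[nH]1")
})

test_that("malformed table rows are handled as specified", {
  # arity-mismatch row skipped with a warning
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fragment\treplacement\tfrequency",
               "[1*]OC\t[1*]SC\t10",
               "[1*]O[2*]\t[1*]S\t99"), path)
  expect_warning(tab <- readBioisostereTable(path), "arity")
  expect_equal(bioisostereKeys(tab), "*OC")
  # empty file: empty table, substitution becomes the identity/rejection
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("fragment\treplacement\tfrequency", path2)
  tab2 <- readBioisostereTable(path2)
  expect_length(bioisostereKeys(tab2), 0L)
  expect_true(is.na(bioisostericSubstitute("c1ccccc1CC(=O)O", tab2, p = 1,
                                           seed = 1L)))
})

test_that("BRICS decomposition and reassembly round-trip", {
  # no BRICS bond: single fragment
  dec <- bricsDecompose("CC")[[1]]
  expect_equal(nrow(dec), 1L)
  expect_equal(dec$arity, 0L)
  # an amide is cut into at least two fragments
  expect_gte(nrow(bricsDecompose("CCC(=O)NCC")[[1]]), 2L)
  # reassembly reproduces the molecule over the whole fixture subset
  lib <- fix_lib(60)
  expect_equal(bricsReassemble(lib), canonicalizeSmiles(lib))
})

test_that("substitution rewrites matched fragments and nothing else", {
  # p = 0 never fires
  expect_true(is.na(bioisostericSubstitute("c1ccc(C(=O)O)cc1",
                                           bio_default(), p = 0,
                                           seed = 1L)))
  # a molecule with no table-matching fragments is rejected
  expect_true(is.na(bioisostericSubstitute("CC", bio_default(), p = 1,
                                           seed = 1L)))
  # single-entry table: carboxylic acid -> tetrazole
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fragment\treplacement\tfrequency",
               "[1*]C(=O)O\t[1*]c1nnn[nH]1\t100"), path)
  tet <- readBioisostereTable(path)
  out <- bioisostericSubstitute("c1ccc(C(=O)O)cc1", tet, p = 1, seed = 2L)
  expect_false(is.na(out))
  keys <- bricsDecompose(out)[[1]]$key
  expect_true("*c1nnn[nH]1" %in% keys)       # tetrazole introduced
  expect_false("*C(=O)O" %in% keys)          # acid gone
  expect_true("*c1ccccc1" %in% keys)         # untouched ring preserved
})

test_that("accepted substitutions are valid and p-monotone", {
  lib <- fix_lib(25)
  out <- bioisostericSubstitute(lib, bio_default(), p = 0.5, seed = 9L)
  accepted <- out[!is.na(out)]
  expect_gt(length(accepted), 0L)
  expect_true(all(isValidSmiles(accepted)))
  # acceptance rate is non-decreasing in p (Monte-Carlo over the library)
  rate <- vapply(c(0.1, 0.5, 1), function(p) {
    o <- bioisostericSubstitute(rep(lib, 4L), bio_default(), p = p,
                                seed = 31L)
    mean(!is.na(o))
  }, numeric(1))
  expect_true(!is.unsorted(rate))
})
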