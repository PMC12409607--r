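test_that("the validity/uniqueness/novelty chain is computed correctly", {
  m <- generationMetrics(c("CCO", "C(C"))
  expect_equal(m@validity_pct, 50)
  # CCO and OCC are the same molecule
  m2 <- generationMetrics(c("CCO", "OCC", "CCN"))
  expect_equal(m2@uniqueness_pct, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(m2@novelty_pct, 100)
  # everything already in the references: zero novelty
  m3 <- generationMetrics(c("CCO", "CCN"),
                          canonicalizeSmiles(c("CCO", "CCN")))
  expect_equal(m3@novelty_pct, 0)
  expect_error(generationMetrics(character(0)), "empty")
  v <- metricValues(m2)
  expect_true(v["n_raw"] >= v["n_valid"] &&
              v["n_valid"] >= v["n_unique"] &&
              v["n_unique"] >= v["n_novel"])
})

test_that("ksDistance equals the brute-force ECDF oracle", {
  expect_equal(ksDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ksDistance(c(1, 1, 1), c(2, 2, 2)), 1)
  expect_equal(ksDistance(c(1, 2), c(1, 2, 3)), 1 / 3, tolerance = 1e-15)
  withr::with_seed(7, for (i in 1:40) {
    a <- rnorm(sample(3:40, 1))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -2, 2))
    expect_equal(ksDistance(a, b), ks_bruteforce(a, b), tolerance = 1e-12)
    expect_equal(ksDistance(a, b), ksDistance(b, a))
    # scale consistency
    expect_equal(ksDistance(3 * a, 3 * b), ksDistance(a, b))
  })
  expect_error(ksDistance(numeric(0), 1), "non-empty")
})

test_that("the descriptor KS report covers all eight descriptors", {
  lib <- fix_lib(25)
  rep0 <- descriptorKSReport(lib, lib)
  tab <- ksTable(rep0)
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$ks, rep(0, 8))
  expect_equal(tab$ks_x100, 100 * tab$ks)
  # disjoint molecular-weight supports give KS = 1
  rep1 <- descriptorKSReport(rep("c1ccccc1", 5L), rep("CCCCCCCCCC", 5L))
  expect_equal(ksTable(rep1)$ks[ksTable(rep1)$descriptor == "mw"], 1)
  # invalid designs are filtered before computing descriptors
  rep2 <- descriptorKSReport(c(lib, "C(C"), lib)
  expect_equal(ksTable(rep2)$n_design[1], length(lib))
  expect_error(descriptorKSReport(c("C(C", "xx"), lib), "no valid")
})

test_that("scaffold metrics follow the report definitions", {
  # all-distinct scaffolds, none in the fine-tuning set
  designs <- c("c1ccncc1CC", "c1ccsc1CC", "C1CCCCC1CC")
  r <- scaffoldReport(designs, ft_set = "c1ccccc1")
  expect_equal(r@diversity_pct, 100)
  expect_equal(r@novelty_ft_pct, 100)
  # designs identical to the fine-tuning molecules: zero novelty
  r2 <- scaffoldReport("CCc1ccccc1", ft_set = "CCc1ccccc1")
  expect_equal(r2@novelty_ft_pct, 0)
  # 4 designs sharing a benzene scaffold + 1 acyclic -> 2 classes / 5
  designs3 <- c("CCc1ccccc1", "CCCc1ccccc1", "OCc1ccccc1", "NCc1ccccc1",
                "CCOCC")
  r3 <- scaffoldReport(designs3, ft_set = "c1ccccc1")
  expect_equal(r3@diversity_pct, 40)
  # pre-training novelty only reported when a PT set is given
  expect_true(is.na(r3@novelty_pt_pct))
  r4 <- scaffoldReport(designs3, ft_set = "c1ccccc1",
                       pt_scaffolds = canonicalizeSmiles("c1ccccc1"))
  expect_equal(r4@novelty_pt_pct, 100 * 1 / 5)
  # top-scaffold matching reports FT frequency and design occurrence
  tm <- topScaffoldMatches(r3)
  expect_equal(tm$scaffold[1], canonicalizeSmiles("c1ccccc1"))
  expect_equal(tm$ft_pct[1], 100)
  expect_equal(tm$design_pct[1], 80)
  # scaffold metrics are invariant to SMILES enumeration of the designs
  lib <- fix_lib(15)
  enum <- vapply(randomizeSmiles(lib, 1L, seed = 4L), `[`, character(1), 1L)
  expect_equal(scaffoldValues(scaffoldReport(enum, lib)),
               scaffoldValues(scaffoldReport(lib, lib)))
  expect_error(scaffoldReport("C(C", ft_set = "CCO"), "no valid")
})
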