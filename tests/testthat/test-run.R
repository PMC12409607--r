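test_that("run configurations round-trip byte-stably", {
  cfg <- runConfig(input = "in.smi", strategy = "deletion",
                   variant = "protected", fold = 3L,
                   clm = clmConfig(n_layers = 1L, hidden_units = 16L),
                   n_samples = 50L, repeats = 2L, seed = 7L)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeRunConfig(cfg, p1)
  writeRunConfig(readRunConfig(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  # YAML route
  py <- withr::local_tempfile(fileext = ".yaml")
  writeRunConfig(cfg, py)
  expect_equal(readRunConfig(py)$augmentation$strategy, "deletion")
})

test_that("a tiny experiment cell runs end to end reproducibly", {
  lib <- generateFixtureLibrary(400, seed = 17L)
  lib <- lib[nchar(lib) <= 18][1:80]       # short molecules converge fast
  out_dir <- withr::local_tempdir()
  cfg <- runConfig(input = lib, strategy = "enumeration", fold = 3L,
                   clm = clmConfig(n_layers = 1L, hidden_units = 64L,
                                   learning_rate = 0.005, batch_size = 32L,
                                   max_epochs = 25L),
                   n_samples = 50L, temperature = 1.0, max_len = 60L,
                   repeats = 2L, seed = 23L, out_dir = out_dir)
  res <- suppressMessages(runExperiment(cfg))
  # all three reports are emitted and well-formed
  expect_s4_class(res$metrics, "GenerationMetrics")
  expect_equal(nrow(ksTable(res$ks_report)), 8L)
  expect_s4_class(res$scaffold_report, "ScaffoldReport")
  v <- metricValues(res$metrics)
  expect_equal(unname(v["n_raw"]), 100)   # 50 samples x 2 repeats pooled
  expect_true(v["n_raw"] >= v["n_valid"] &&
              v["n_valid"] >= v["n_unique"] &&
              v["n_unique"] >= v["n_novel"])
  # per-repeat sample files plus pooled reports on disk
  expect_true(file.exists(file.path(out_dir, "samples_rep1.smi")))
  expect_true(file.exists(file.path(out_dir, "samples_rep2.smi")))
  expect_true(file.exists(file.path(out_dir, "metrics.json")))
  expect_true(file.exists(file.path(out_dir, "config.json")))
  # the persisted config and seed reproduce identical samples
  cfg2 <- readRunConfig(file.path(out_dir, "config.json"))
  cfg2$out_dir <- NULL
  res2 <- suppressMessages(runExperiment(cfg2))
  expect_identical(res$samples, res2$samples)
  expect_error(runExperiment(runConfig(input = character(0))), "empty")
})

test_that("the command-line front end drives the package", {
  cli <- system.file("cli", "smilesaugment", package = "smilesaugment")
  expect_true(nzchar(cli))
  # the child Rscript must see the library this package is installed in
  libs <- paste0("R_LIBS=", paste(.libPaths(),
                                  collapse = .Platform$path.sep))
  tmp <- withr::local_tempdir()
  out <- file.path(tmp, "lib.smi")
  res <- system2("Rscript", c(cli, "make-fixtures", "--n", "25", "--seed",
                              "3", "--out", out),
                 stdout = TRUE, stderr = TRUE, env = libs)
  expect_true(file.exists(out))
  expect_length(readLines(out), 25L)
  # unknown command exits with the usage status
  st <- suppressWarnings(system2("Rscript", c(cli, "frobnicate"),
                                 stdout = FALSE, stderr = FALSE,
                                 env = libs))
  expect_equal(st, 1L)
  # curate subcommand writes the record table and rejection log
  res2 <- system2("Rscript", c(cli, "curate", "--input", out,
                               "--out-prefix", file.path(tmp, "cur")),
                  stdout = TRUE, stderr = TRUE, env = libs)
  expect_true(file.exists(file.path(tmp, "cur.tsv")))
  expect_true(file.exists(file.path(tmp, "cur_rejections.tsv")))
})
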