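test_that("temperature softmax matches closed forms and limits", {
  expect_equal(temperatureProbabilities(c(0, 0), 1), c(0.5, 0.5))
  expect_equal(temperatureProbabilities(c(0, log(3)), 1), c(0.25, 0.75))
  p <- temperatureProbabilities(c(0, 1), 0.5)
  expect_equal(p, c(1 / (1 + exp(2)), exp(2) / (1 + exp(2))),
               tolerance = 1e-12)
  # conservation on random logit vectors
  withr::with_seed(1, for (i in 1:50) {
    z <- rnorm(sample(2:30, 1), sd = 5)
    expect_lt(abs(sum(temperatureProbabilities(z, runif(1, 0.1, 5))) - 1),
              1e-12)
  })
  # T -> Inf flattens to uniform, T -> 0 sharpens to the arg-max
  z <- c(1, 3, 2, -1)
  expect_equal(temperatureProbabilities(z, 100), rep(0.25, 4),
               tolerance = 0.05)
  expect_equal(temperatureProbabilities(z, 0.01), c(0, 1, 0, 0),
               tolerance = 1e-12)
  expect_error(temperatureProbabilities(z, 0), "> 0")
  expect_error(temperatureProbabilities(c(1, Inf), 1), "finite")
  # matrix input: row-wise
  m <- temperatureProbabilities(rbind(z, z * 2), 1)
  expect_equal(m[1, ], temperatureProbabilities(z, 1))
})

test_that("analytic LSTM gradients match numerical differentiation", {
  withr::local_seed(1)
  V <- 6L; H <- 4L
  params <- smilesaugment:::.initParams(V, H, 2L)
  B <- 2L; T_ <- 3L
  input <- matrix(sample(1:V, B * T_, TRUE), B, T_)
  target <- matrix(sample(1:V, B * T_, TRUE), B, T_)
  mask <- matrix(1, B, T_); mask[2, 3] <- 0
  res <- smilesaugment:::.lstmLossGrad(params, input, target, mask)
  eps <- 1e-6
  for (nm in names(params)) {
    ks <- sample(seq_along(params[[nm]]), min(6L, length(params[[nm]])))
    for (k in ks) {
      pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (smilesaugment:::.lstmLossGrad(pp, input, target, mask,
                                            loss_only = TRUE)$loss -
              smilesaugment:::.lstmLossGrad(pm, input, target, mask,
                                            loss_only = TRUE)$loss) /
             (2 * eps)
      expect_equal(res$grads[[nm]][k], num, tolerance = 1e-5)
    }
  }
})

test_that("padding positions contribute exactly zero loss", {
  withr::local_seed(2)
  V <- 6L; H <- 4L
  params <- smilesaugment:::.initParams(V, H, 1L)
  input <- matrix(sample(1:V, 6, TRUE), 2, 3)
  target <- matrix(sample(1:V, 6, TRUE), 2, 3)
  mask <- matrix(1, 2, 3)
  base <- smilesaugment:::.lstmLossGrad(params, input, target, mask,
                                        loss_only = TRUE)$loss
  ext <- smilesaugment:::.lstmLossGrad(params,
                                       cbind(input, matrix(0L, 2, 4)),
                                       cbind(target, matrix(0L, 2, 4)),
                                       cbind(mask, matrix(0, 2, 4)),
                                       loss_only = TRUE)$loss
  expect_identical(base, ext)
})

test_that("training stops early and keeps the best-validation weights", {
  corpus <- toy_corpus()[1:8]
  pairs <- plain_pairs(corpus)
  cfg <- clmConfig(n_layers = 1L, hidden_units = 16L, learning_rate = 0.05,
                   batch_size = 8L, max_epochs = 300L, patience = 5L,
                   seed = 3L)
  model <- trainCLM(pairs, cfg, pairs)
  h <- trainingHistory(model)
  expect_lt(nrow(h), cfg$max_epochs)          # patience exhausted
  expect_equal(bestEpoch(model), which.min(h$val_loss))
  expect_true(all(is.finite(h$train_loss)))
  # determinism
  model2 <- trainCLM(pairs, cfg, pairs)
  expect_identical(model@params, model2@params)
  expect_error(trainCLM(pairs, cfg,
                        plain_pairs(c("CCO", "CCCCN"),
                                    smilesVocabulary("CCOCN"))),
               "vocabular")
})

test_that("fine-tuning starts from the base weights and clips gradients", {
  corpus <- toy_corpus()[1:8]
  pairs <- plain_pairs(corpus)
  cfg <- clmConfig(n_layers = 1L, hidden_units = 16L, learning_rate = 0.05,
                   batch_size = 8L, max_epochs = 30L, seed = 3L)
  base <- trainCLM(pairs, cfg, pairs)
  # zero epochs: identical weights
  ft0 <- fineTuneCLM(base, pairs, pairs,
                     ft_config = clmConfig(n_layers = 1L,
                                           hidden_units = 16L,
                                           max_epochs = 0L))
  expect_identical(ft0@params, base@params)
  # default fine-tuning (lr 5e-7, clip 1) must not degrade the loss
  ft <- fineTuneCLM(base, pairs, pairs)
  expect_lte(min(trainingHistory(ft)$val_loss),
             min(trainingHistory(base)$val_loss) + ft@config$min_delta)
  expect_equal(ft@config$learning_rate, 5e-7)
  expect_equal(ft@config$clip_norm, 1)
  # base not mutated
  expect_identical(base@params, trainCLM(pairs, cfg, pairs)@params)
})

test_that("Adam clipping bounds the applied gradient norm", {
  params <- list(W = matrix(c(3, 4), 1), b = 0)
  grads <- list(W = matrix(c(30, 40), 1), b = 0)
  opt <- smilesaugment:::.adamInit(params)
  upd <- smilesaugment:::.adamStep(params, grads, opt, lr = 1,
                                   clip_norm = 1)
  # after clipping, the step direction reflects a unit-norm gradient
  expect_equal(upd$opt$m$W, matrix(0.1 * c(30, 40) / 50, 1))
})

test_that("sampling is deterministic, bounded, and marker-free", {
  pairs <- plain_pairs(toy_corpus())
  cfg <- clmConfig(n_layers = 1L, hidden_units = 24L, learning_rate = 0.02,
                   batch_size = 20L, max_epochs = 40L, seed = 5L)
  model <- trainCLM(pairs, cfg, pairs)
  s1 <- sampleCLM(model, n_samples = 50L, temperature = 1, max_len = 12L,
                  repeats = 2L, seed = 11L)
  s2 <- sampleCLM(model, n_samples = 50L, temperature = 1, max_len = 12L,
                  repeats = 2L, seed = 11L)
  expect_identical(s1, s2)
  expect_length(s1, 2L)
  expect_false(identical(s1[[1]], s1[[2]]))   # repeats are independent
  for (s in unlist(s1)) {
    if (nzchar(s)) {
      toks <- tokenizeSmiles(s)[[1]]
      expect_lte(length(toks), 10L)           # max_len - 2
      expect_false(any(toks %in% c("G", "E", "<pad>")))
    }
  }
  p <- nextTokenProbabilities(model, character(0), temperature = 0.5)
  expect_lt(abs(sum(p) - 1), 1e-12)
  expect_false(any(c("<pad>", "G") %in% names(p)))
})

test_that("self-training retains only valid, unique, novel strings", {
  corpus <- toy_corpus()
  cfg <- clmConfig(n_layers = 1L, hidden_units = 32L, learning_rate = 0.02,
                   batch_size = 20L, max_epochs = 60L, seed = 6L)
  aug <- selfTrainAugment(corpus, cfg, fold = 2L, seed = 8L)
  st <- augmentedStrings(aug)
  synth <- st$augmented[!st$is_original]
  if (length(synth)) {
    expect_true(all(isValidSmiles(synth)))
    canon <- canonicalizeSmiles(synth)
    expect_equal(anyDuplicated(canon), 0L)
    expect_false(any(canon %in% canonicalizeSmiles(corpus)))
  }
  # fold accounting holds
  expect_true(all(sourceMolecules(aug)$n_augmented <= 1L))
  # fold = 1 trains nothing and keeps the originals
  a1 <- selfTrainAugment(corpus, cfg, fold = 1L, seed = 8L)
  expect_true(all(augmentedStrings(a1)$is_original))
})
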