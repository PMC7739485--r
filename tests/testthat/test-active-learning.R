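test_that("uncertainty measures match their closed forms", {
  # maximal uncertainty at p = 0.5
  expect_equal(uncertaintyLC(rep(0.5, 4)), 0.5)
  expect_equal(uncertaintyEntropy(rep(0.5, 3)), log(2))
  expect_equal(uncertaintyGini(rep(0.5, 2)), 0.5)
  # full confidence -> zero, with 0 * log 0 := 0
  expect_equal(uncertaintyLC(c(0, 1, 1, 0)), 0)
  expect_equal(uncertaintyEntropy(c(1, 1)), 0)
  expect_equal(uncertaintyGini(c(0, 1)), 0)
  # hand evaluations
  expect_equal(uncertaintyLC(c(0.8, 0.6)), (0.2 + 0.4) / 2)
  expect_equal(uncertaintyEntropy(0.9),
               -(0.9 * log(0.9) + 0.1 * log(0.1)), tolerance = 1e-12)
  expect_equal(uncertaintyGini(c(0.9, 0.5)),
               (2 * 0.9 * 0.1 + 2 * 0.5 * 0.5) / 2, tolerance = 1e-12)
  expect_error(uncertaintyLC(numeric()), "empty")
  expect_error(uncertaintyGini(c(0.3, 1.2)), "\\[0, 1\\]")
})

test_that("lc <= gini <= entropy pointwise, all peaked at 0.5", {
  p <- seq(0, 1, by = 0.01)
  lc <- vapply(p, uncertaintyLC, numeric(1))
  gi <- vapply(p, uncertaintyGini, numeric(1))
  en <- vapply(p, uncertaintyEntropy, numeric(1))
  expect_true(all(lc <= gi + 1e-12))
  expect_true(all(gi <= en + 1e-12))
  expect_equal(which.max(lc), which(p == 0.5))
  expect_equal(which.max(gi), which(p == 0.5))
  expect_equal(which.max(en), which(p == 0.5))
  expect_equal(lc[p %in% c(0, 1)], c(0, 0))
})

test_that("batch selection takes the top-B with deterministic tie-breaks", {
  sc <- data.frame(candidate_set_id = c("c1", "c2", "c3"),
                   strategy = "gini", uncertainty = c(0.5, 0.3, 0.1),
                   stringsAsFactors = FALSE)
  expect_identical(selectBatch(sc, 2), c("c1", "c2"))
  # all-equal uncertainties: smallest ids win
  sc$uncertainty <- 0.2
  expect_identical(selectBatch(sc, 2), c("c1", "c2"))
  # B beyond the pool returns everything
  expect_identical(selectBatch(sc, 5), c("c1", "c2", "c3"))
  expect_identical(selectBatch(sc[0, ], 3), character())
  # invariant to presentation order
  expect_identical(selectBatch(sc[c(3, 1, 2), ], 2), c("c1", "c2"))
})

test_that("per-set uncertainty scoring groups predictions by query", {
  preds <- data.frame(
    nonstandard_id = c("a", "a", "b"),
    p_match = c(0.8, 0.6, 0.5), stringsAsFactors = FALSE)
  sc <- scoreUncertainty(preds, "lc")
  expect_equal(sc$uncertainty[sc$candidate_set_id == "a"], 0.3)
  expect_equal(sc$uncertainty[sc$candidate_set_id == "b"], 0.5)
})

test_that("the active-learning loop is seeded, monotone and leak-free", {
  gen <- smallSynthetic()
  split <- splitCorpus(gen$corpus, 0.7, 3)
  cfg <- fastConfig(epochs = 2L)
  h1 <- runALLoop(gen$corpus, gen$candidates, strategy = "gini",
                  config = cfg, testIds = split$test, batch_size = 30L,
                  rounds = 2L, seed = 17)
  h2 <- runALLoop(gen$corpus, gen$candidates, strategy = "gini",
                  config = cfg, testIds = split$test, batch_size = 30L,
                  rounds = 2L, seed = 17)
  expect_identical(h1, h2)
  expect_equal(h1$round, 1:2)
  # the labeled pool is a filtration growing by at most B per round
  expect_true(all(diff(h1$n_labeled) > 0))
  expect_true(all(diff(h1$n_labeled) <= 30))
  expect_true(all(h1$fraction_labeled <= 1))
  expect_error(runALLoop(gen$corpus, gen$candidates, strategy = "nope",
                         config = cfg, testIds = split$test,
                         batch_size = 5L, rounds = 1L, seed = 1))
})

test_that("one exhausting random round equals training on the full pool", {
  gen <- smallSynthetic()
  split <- splitCorpus(gen$corpus, 0.7, 3)
  cfg <- fastConfig(epochs = 2L)
  pool <- setdiff(gen$candidates@queryIds, split$test)
  h <- runALLoop(gen$corpus, gen$candidates, strategy = "random",
                 config = cfg, testIds = split$test,
                 batch_size = length(pool), rounds = 1L, seed = 4)
  expect_equal(h$fraction_labeled, 1)
  # reference: train directly on every pool pair with the same seeds
  gm <- goldMap(gen$corpus)
  trainPairs <- buildTrainingPairs(gen$candidates, gm, ids = pool)
  roundCfg <- cfg
  roundCfg$seed <- (cfg$seed + 7919L) %% .Machine$integer.max
  model <- trainEsim(esimModel(gen$corpus, roundCfg), gen$corpus,
                     trainPairs, config = roundCfg)
  testPairs <- buildTrainingPairs(gen$candidates, gm, ids = split$test)
  pr <- predictProba(model, gen$corpus, testPairs)
  expect_equal(h$test_f1,
               classificationMetrics(pr$p_match, testPairs$label)$f1,
               tolerance = 1e-12)
})

test_that("learning-curve area integrates a normalized trapezoid", {
  h <- data.frame(fraction_labeled = c(0.2, 0.4, 0.6),
                  test_f1 = c(0.5, 0.7, 0.8))
  expect_equal(learningCurveAUC(h),
               (0.2 * 0.6 + 0.2 * 0.75) / 0.4, tolerance = 1e-12)
})
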