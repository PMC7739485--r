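test_that("an untrained model predicts exactly 0.5 for every pair", {
  gen <- smallSynthetic()
  model <- esimModel(gen$corpus, fastConfig())
  pr <- predictProba(model, gen$corpus, head(gen$pairs, 12))
  expect_equal(pr$p_match, rep(0.5, 12))
})

test_that("predictions are deterministic, batch-independent and padding-invariant", {
  gen <- smallSynthetic()
  model <- smallTrainedModel()
  pairs <- head(gen$pairs, 20)
  p1 <- predictProba(model, gen$corpus, pairs)$p_match
  p2 <- predictProba(model, gen$corpus, pairs)$p_match
  expect_identical(p1, p2)
  # permuting the batch permutes the predictions identically
  perm <- sample(nrow(pairs))
  p3 <- predictProba(model, gen$corpus, pairs[perm, ])$p_match
  expect_equal(p3, p1[perm], tolerance = 1e-12)
  # a duplicated pair scores identically
  expect_equal(p1[1],
               predictProba(model, gen$corpus,
                            pairs[c(1, 1), ])$p_match[2])
  # appending padding ids (0) never changes p_match
  cfg <- model@config
  aIds <- textToTokenIds(model, combinedTexts(
    nonstandards(gen$corpus))[pairs$nonstandard_id])
  bIds <- textToTokenIds(model, combinedTexts(
    standards(gen$corpus))[pairs$standard_id])
  padded <- lapply(aIds, function(x) c(x, 0L, 0L, 0L))
  pPad <- labnorm:::esim_predict(model@params, length(model@vocab),
                                 cfg$embedding_dim, cfg$hidden_dim,
                                 cfg$mlp_hidden, padded, bIds,
                                 cfg$tie_weights)
  pRaw <- labnorm:::esim_predict(model@params, length(model@vocab),
                                 cfg$embedding_dim, cfg$hidden_dim,
                                 cfg$mlp_hidden, aIds, bIds,
                                 cfg$tie_weights)
  expect_equal(pPad, pRaw, tolerance = 1e-5)
})

test_that("training is seeded-deterministic and records its history", {
  gen <- smallSynthetic()
  pairs <- head(gen$pairs, 60)
  cfg <- fastConfig(epochs = 3L)
  m1 <- trainEsim(esimModel(gen$corpus, cfg), gen$corpus, pairs)
  m2 <- trainEsim(esimModel(gen$corpus, cfg), gen$corpus, pairs)
  expect_identical(m1@history$loss, m2@history$loss)
  expect_identical(m1@params, m2@params)
  expect_equal(nrow(m1@history), 3L)
})

test_that("first-epoch loss starts near ln 2 with the symmetric head", {
  gen <- smallSynthetic()
  pairs <- rbind(head(gen$pairs[gen$pairs$label == 1, ], 10),
                 head(gen$pairs[gen$pairs$label == 0, ], 10))
  cfg <- fastConfig(epochs = 1L, learning_rate = 1e-4, momentum = 0,
                    dropout = 0)
  m <- trainEsim(esimModel(gen$corpus, cfg), gen$corpus, pairs)
  expect_equal(m@history$loss[1], log(2), tolerance = 0.01)
})

test_that("training refuses single-class data", {
  gen <- smallSynthetic()
  onlyNeg <- head(gen$pairs[gen$pairs$label == 0, ], 10)
  expect_error(trainEsim(esimModel(gen$corpus, fastConfig()),
                         gen$corpus, onlyNeg), "positive and a negative")
})

test_that("validation-based selection keeps the best epoch", {
  gen <- smallSynthetic()
  pairs <- gen$pairs
  split <- splitCorpus(gen$corpus, 0.7, 5)
  tr <- buildTrainingPairs(gen$candidates, goldMap(gen$corpus),
                           ids = split$train)
  va <- buildTrainingPairs(gen$candidates, goldMap(gen$corpus),
                           ids = split$test)
  cfg <- fastConfig(epochs = 4L)
  m <- trainEsim(esimModel(gen$corpus, cfg), gen$corpus, tr, validation = va)
  expect_equal(sum(!is.na(m@history$val_f1)), 4L)
})

test_that("candidate classification thresholds, ranks and reports unmapped", {
  gen <- smallSynthetic()
  model <- smallTrainedModel()
  sub <- labnorm:::.subsetCandidates(gen$candidates,
                                     head(gen$candidates@queryIds, 15))
  maps <- classifyCandidates(model, gen$corpus, sub, threshold = 0.5)
  expect_true(all(maps$p_match > 0.5))
  # within each query, descending probability
  for (qid in unique(maps$nonstandard_id)) {
    p <- maps$p_match[maps$nonstandard_id == qid]
    expect_true(all(diff(p) <= 0))
  }
  expect_setequal(c(unique(maps$nonstandard_id), attr(maps, "unmapped")),
                  sub@queryIds)
  # an impossible threshold maps nothing
  none <- classifyCandidates(model, gen$corpus, sub, threshold = 1)
  expect_equal(nrow(none), 0L)
  expect_setequal(attr(none, "unmapped"), sub@queryIds)
})

test_that("training pairs follow the gold map and downsampling cap", {
  gen <- smallSynthetic()
  gm <- goldMap(gen$corpus)
  pairs <- buildTrainingPairs(gen$candidates, gm)
  expect_true(all(pairs$label %in% c(0L, 1L)))
  # a pair is positive iff it is the gold mapping
  expect_identical(pairs$label,
                   as.integer(pairs$standard_id == gm[pairs$nonstandard_id]))
  # at most one positive per query
  posPerQuery <- tapply(pairs$label, pairs$nonstandard_id, sum)
  expect_true(all(posPerQuery <= 1))
  capped <- buildTrainingPairs(gen$candidates, gm, negative_ratio = 2)
  expect_lte(sum(capped$label == 0), 2 * sum(capped$label == 1))
  expect_equal(sum(capped$label == 1), sum(pairs$label == 1))
})
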