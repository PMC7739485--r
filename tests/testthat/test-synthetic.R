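test_that("standard generation is deterministic and respects the spec", {
  spec <- syntheticSpec(n_standard = 25, seed = 77)
  s1 <- generateStandards(spec)
  s2 <- generateStandards(spec)
  expect_identical(s1$name, s2$name)
  expect_identical(s1$abbreviation, s2$abbreviation)
  expect_equal(nrow(s1), 25L)
  expect_equal(anyDuplicated(s1$name), 0L)
  tiny <- generateStandards(syntheticSpec(n_standard = 2, seed = 1))
  expect_equal(nrow(tiny), 2L)
  expect_false(tiny$name[1] == tiny$name[2])
})

test_that("zero rates reproduce the standard exactly; full rates never do", {
  quiet <- syntheticSpec(n_standard = 10, synonyms_min = 1, synonyms_max = 1,
                         char_edit_rate = 0, synonym_swap_rate = 0,
                         habit_rate = 0, abbrev_missing_rate = 0,
                         abbrev_perturb_rate = 0, seed = 5)
  std <- generateStandards(quiet)
  v <- generateVariants(std, quiet, seed = 6)
  expect_identical(v$name, std$name[match(v$gold_standard_id, std$id)])
  expect_identical(v$abbreviation,
                   std$abbreviation[match(v$gold_standard_id, std$id)])

  noisy <- syntheticSpec(n_standard = 10, synonyms_min = 2, synonyms_max = 2,
                         char_edit_rate = 0.3, seed = 5)
  stdN <- generateStandards(noisy)
  vN <- generateVariants(stdN, noisy, seed = 6)
  expect_true(all(vN$name != stdN$name[match(vN$gold_standard_id, stdN$id)]))

  # abbrev_missing_rate = 1 drops every abbreviation
  gone <- syntheticSpec(n_standard = 5, abbrev_missing_rate = 1, seed = 2)
  stdG <- generateStandards(gone)
  vG <- generateVariants(stdG, gone, seed = 3)
  expect_true(all(is.na(vG$abbreviation)))
})

test_that("variants stay closer to their own standard than to others", {
  spec <- syntheticSpec(n_standard = 40, seed = 21)
  dOwn <- c(); dOther <- c()
  for (s in 1:2) {
    spec$seed <- 21 + s
    std <- generateStandards(spec)
    v <- generateVariants(std, spec, seed = spec$seed + 100)
    own <- std$name[match(v$gold_standard_id, std$id)]
    set.seed(spec$seed)
    other <- std$name[sapply(match(v$gold_standard_id, std$id), function(i)
      sample(setdiff(seq_len(nrow(std)), i), 1))]
    dOwn <- c(dOwn, mapply(function(a, b) 1 - editSimilarity(a, b),
                           v$name, own))
    dOther <- c(dOther, mapply(function(a, b) 1 - editSimilarity(a, b),
                               v$name, other))
  }
  expect_lt(mean(dOwn), mean(dOther))
})

test_that("generated corpora are valid, fully labeled and reproducible", {
  spec <- syntheticSpec(n_standard = 20, seed = 9)
  g1 <- generateCorpus(spec)
  g2 <- generateCorpus(spec)
  expect_true(validObject(g1$corpus))
  # gold map is total on the non-standard side
  expect_true(all(!is.na(goldMap(g1$corpus))))
  expect_identical(nonstandards(g1$corpus), nonstandards(g2$corpus))
  expect_identical(g1$pairs, g2$pairs)
  # byte-identical corpus files under the same spec and seed
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeCorpus(g1$corpus, p1)
  writeCorpus(g2$corpus, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the shipped fixture corpus equals its generating spec", {
  fixture <- readCorpus(system.file("extdata", "fixture_corpus.tsv",
                                    package = "labnorm"))
  regen <- benchmarkFixture()$corpus
  expect_identical(standards(fixture), standards(regen))
  expect_identical(nonstandards(fixture), nonstandards(regen))
  expect_identical(goldMap(fixture), goldMap(regen))
})

test_that("the labeled pair pool mirrors the imbalance the recall stage creates", {
  gen <- smallSynthetic()
  nPos <- sum(gen$pairs$label == 1)
  nNeg <- sum(gen$pairs$label == 0)
  # at most one positive per non-standard indicator
  expect_lte(nPos, nrow(nonstandards(gen$corpus)))
  expect_gte(nNeg / nPos, 5)
})

test_that("retrieval sharpness degrades as character noise grows", {
  r1 <- vapply(1:2, function(s) {
    gen <- generateCorpus(syntheticSpec(n_standard = 30,
                                        char_edit_rate = 0.02,
                                        seed = 400 + s))
    recallAt(gen$candidates, goldMap(gen$corpus), k = 1)
  }, numeric(1))
  r2 <- vapply(1:2, function(s) {
    gen <- generateCorpus(syntheticSpec(n_standard = 30,
                                        char_edit_rate = 0.6,
                                        seed = 400 + s))
    recallAt(gen$candidates, goldMap(gen$corpus), k = 1)
  }, numeric(1))
  expect_gt(mean(r1), mean(r2))
})
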