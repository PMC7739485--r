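test_that("character tokenizer splits, normalizes and drops whitespace", {
  expect_identical(tokenizeChars("Na钠"), c("n", "a", "钠"))
  expect_identical(tokenizeChars("p H"), c("p", "h"))
  expect_identical(tokenizeChars("血清钠"), c("血", "清", "钠"))
  expect_error(tokenizeChars("   "), "empty")
})

test_that("tf-idf weights follow tf * log(|D|/(N_w+1)) with natural log", {
  # degenerate corpus: every token in 2 of 3 documents -> idf 0 everywhere
  idx <- buildTfIdfIndex(latinStandards(c("ab", "ac", "bc")))
  expect_equal(unname(idx@idf), c(0, 0, 0))
  expect_true(all(idx@docVectors == 0))

  # hand evaluation: idf(c) = ln(4/2); tf(c in "cc") = 1
  idx2 <- buildTfIdfIndex(latinStandards(c("aa", "ab", "bb", "cc")))
  expect_equal(idx2@idf[match("c", idx2@vocabulary)], log(2),
               tolerance = 1e-12)
  raw <- 1 * log(4 / 2)  # weight before L2 normalization
  expect_equal(as.numeric(idx2@docVectors[4, match("c", idx2@vocabulary)]),
               raw / abs(raw), tolerance = 1e-12)

  # single-document corpus: idf = ln(1/2) < 0, kept as the formula prints
  idx3 <- buildTfIdfIndex(latinStandards("ab"))
  expect_equal(unname(idx3@idf), rep(log(1 / 2), 2), tolerance = 1e-12)
  expect_true(all(idx3@docVectors@x < 0))
})

test_that("query vectors use index idf, ignore OOV, and normalize", {
  idx <- buildTfIdfIndex(latinStandards(c("aa", "ab", "bb", "cc")))
  # same pipeline as an indexed document
  expect_equal(tfidfVector(idx, "ab"),
               as.numeric(idx@docVectors[2, ]), tolerance = 1e-12)
  # all-OOV query -> zero vector
  expect_identical(tfidfVector(idx, "zz"),
                   numeric(length(idx@vocabulary)))
  # partially OOV query touches only in-vocabulary coordinates
  v <- tfidfVector(idx, "ca")
  nonzero <- which(v != 0)
  expect_identical(idx@vocabulary[nonzero], c("a", "c"))
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
})

test_that("topK matches a brute-force all-pairs cosine oracle", {
  set.seed(99)
  alphabet <- letters[1:6]
  for (rep in 1:25) {
    m <- sample(3:12, 1)
    docs <- vapply(seq_len(m), function(i)
      paste(sample(alphabet, sample(2:6, 1), replace = TRUE),
            collapse = ""), character(1))
    docs <- unique(docs)
    names(docs) <- sprintf("s%02d", seq_along(docs))
    query <- paste(sample(alphabet, sample(2:6, 1), replace = TRUE),
                   collapse = "")
    idx <- buildTfIdfIndex(latinStandards(docs))
    k <- sample(1:length(docs), 1)
    got <- topK(idx, query, k)
    want <- bruteForceTopK(docs, query, k)
    expect_identical(got$standard_id, want$standard_id)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("an identical query ranks its standard first with score 1", {
  docs <- c(s1 = "abc", s2 = "abd", s3 = "xyz")
  idx <- buildTfIdfIndex(latinStandards(docs))
  top <- topK(idx, "abc", 3)
  expect_identical(top$standard_id[1], "s01")
  expect_equal(top$score[1], 1, tolerance = 1e-12)
})

test_that("k beyond the corpus size returns the full ranking", {
  idx <- buildTfIdfIndex(latinStandards(c("ab", "cd")))
  expect_equal(nrow(topK(idx, "ab", 10)), 2L)
})

test_that("candidate union deduplicates, bounds length, and tags channels", {
  mk <- function(ids, scores) data.frame(standard_id = ids, score = scores,
                                         stringsAsFactors = FALSE)
  # disjoint 15 + 5 -> 20
  u <- unionCandidates(mk(sprintf("a%02d", 1:15), seq(1, 0.1, length = 15)),
                       mk(sprintf("b%02d", 1:5), seq(0.9, 0.5, length = 5)))
  expect_equal(nrow(u), 20L)
  expect_equal(anyDuplicated(u$standard_id), 0L)
  # identical lists -> k1 entries, all channel "both", max score kept
  same <- mk(c("x", "y"), c(0.8, 0.6))
  u2 <- unionCandidates(same, mk(c("x", "y"), c(0.5, 0.7)))
  expect_equal(nrow(u2), 2L)
  expect_true(all(u2$channel == "both"))
  expect_equal(u2$score[u2$standard_id == "x"], 0.8)
  expect_equal(u2$score[u2$standard_id == "y"], 0.7)
  # absent abbreviation -> name channel only
  u3 <- unionCandidates(same, NULL)
  expect_true(all(u3$channel == "name"))
  expect_error(unionCandidates(NULL, NULL), "empty")
})

test_that("within-channel candidate scores are non-increasing", {
  gen <- smallSynthetic()
  e <- candidateEntries(gen$candidates)
  for (qid in head(gen$candidates@queryIds, 20)) {
    g <- e[e$nonstandard_id == qid, ]
    for (ch in c("name", "abbreviation")) {
      s <- g$score[g$channel %in% c(ch, "both")]
      expect_true(all(diff(s) <= 1e-12))
    }
  }
})

test_that("candidate set sizes respect the k1..k1+k2 range", {
  gen <- smallSynthetic()
  len <- candidateSetLengths(gen$candidates)
  hasAb <- !is.na(nonstandards(gen$corpus)$abbreviation)
  expect_true(all(len >= 15), info = "at least k1 with |S| >= k1")
  expect_true(all(len <= 20))
  expect_true(all(len[!hasAb] == 15))
})

test_that("baseline similarities match hand computations", {
  expect_equal(baselineScore("edit_distance", "abc", "abc"), 1)
  expect_equal(baselineScore("edit_distance", "ab", "cd"), 0)
  # bow cosine of "aab" vs "ab": (2*1 + 1*1) / (sqrt(5) * sqrt(2))
  expect_equal(baselineScore("bow", "aab", "ab"), 3 / sqrt(10),
               tolerance = 1e-12)
  # bm25 of a query against its own single-token-overlap corpus is finite
  s <- baselineScore("bm25", "ab", c(d1 = "ab", d2 = "cd"))
  expect_length(s, 2)
  expect_true(s[1] > s[2])
})

test_that("recall and MRR follow their counting definitions", {
  e <- data.frame(
    nonstandard_id = rep(c("n1", "n2", "n3"), each = 2),
    standard_id = c("s1", "s2", "s2", "s3", "s1", "s2"),
    score = c(0.9, 0.8, 0.9, 0.8, 0.9, 0.8),
    channel = "name", stringsAsFactors = FALSE)
  cs <- new("CandidateSets", entries = e, queryIds = c("n1", "n2", "n3"))
  gmAll <- c(n1 = "s1", n2 = "s3", n3 = "s1")   # ranks 1, 2, 1
  expect_equal(recallAt(cs, gmAll), 1)
  expect_equal(meanReciprocalRank(cs, gmAll), (1 + 1 / 2 + 1) / 3)
  gmNone <- c(n1 = "s9", n2 = "s9", n3 = "s9")  # gold never recalled
  expect_equal(recallAt(cs, gmNone), 0)
  expect_equal(meanReciprocalRank(cs, gmNone), 0)
  gmPart <- c(n1 = "s1", n2 = "s9", n3 = "s2")  # present in 2 of 3
  expect_equal(recallAt(cs, gmPart), 2 / 3)
  # {1, NA, 2} -> (1 + 0 + 1/2) / 3
  expect_equal(meanReciprocalRank(cs, gmPart), (1 + 0 + 0.5) / 3)
  expect_error(recallAt(cs, c(n9 = "s1")), "n9")
})

test_that("recall@k is non-decreasing in k", {
  gen <- smallSynthetic()
  gm <- goldMap(gen$corpus)
  ks <- c(1, 2, 5, 10, 15, 20)
  r <- vapply(ks, function(k) recallAt(gen$candidates, gm, k), numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("vectorized baseline rankers match the pairwise scorers", {
  gen <- smallSynthetic()
  a <- nonstandards(gen$corpus)
  s <- standards(gen$corpus)
  for (m in c("edit", "bow")) {
    cands <- generateCandidates(gen$corpus, k1 = 8, k2 = 3, method = m)
    e <- candidateEntries(cands)
    e <- head(e[e$channel == "name", ], 40)
    ref <- vapply(seq_len(nrow(e)), function(i)
      baselineScore(if (m == "edit") "edit_distance" else "bow",
                    a$name[match(e$nonstandard_id[i], a$id)],
                    s$name[match(e$standard_id[i], s$id)]), numeric(1))
    expect_equal(e$score, ref, tolerance = 1e-12)
  }
})

test_that("retrieval works with every baseline method end to end", {
  gen <- smallSynthetic()
  gm <- goldMap(gen$corpus)
  for (method in c("edit", "bow", "bm25")) {
    cands <- generateCandidates(gen$corpus, k1 = 10, k2 = 3,
                                method = method)
    expect_s4_class(cands, "CandidateSets")
    # a character-overlap retriever must beat random guessing by far
    expect_gt(recallAt(cands, gm), 0.5)
  }
})
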