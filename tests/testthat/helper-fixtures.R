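# Shared fixtures, built once per test run and memoised.

.fixtureCache <- new.env(parent = emptyenv())

memoised <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, builder(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# A tiny hand-written corpus exercising CJK names, latin abbreviations and
# a missing abbreviation.
tinyCorpus <- function() {
  standards <- data.frame(
    id = c("s1", "s2", "s3"),
    name = c("血清钠", "血清钾",
             "酸碱度"),                 # serum Na / K / pH
    abbreviation = c("na", "k", "ph"),
    stringsAsFactors = FALSE)
  nonstandards <- data.frame(
    id = c("n1", "n2", "n3"),
    name = c("钠", "钾离子", "酸碱度"),
    abbreviation = c("na", NA, "PH"),
    stringsAsFactors = FALSE)
  indicatorCorpus(standards, nonstandards,
                  goldMap = c(n1 = "s1", n2 = "s2", n3 = "s3"))
}

# Small seeded synthetic corpus for classifier unit tests.
smallSynthetic <- function() {
  memoised("smallSynthetic", function()
    generateCorpus(syntheticSpec(n_standard = 30, seed = 301)))
}

# A fast ESIM configuration for unit tests.
fastConfig <- function(...) {
  defaults <- list(embedding_dim = 8L, hidden_dim = 6L, mlp_hidden = 12L,
                   epochs = 2L, batch_size = 8L, seed = 11L)
  override <- list(...)
  do.call(esimConfig, utils::modifyList(defaults, override))
}

# A small trained model over the small synthetic corpus.
smallTrainedModel <- function() {
  memoised("smallTrainedModel", function() {
    gen <- smallSynthetic()
    cfg <- esimConfig(embedding_dim = 16L, hidden_dim = 16L,
                      mlp_hidden = 32L, epochs = 12L, seed = 11L)
    trainEsim(esimModel(gen$corpus, cfg), gen$corpus, gen$pairs)
  })
}

# Corpus whose standards are plain latin strings, for hand-computed
# retrieval oracles.
latinStandards <- function(names, abbrevs = NULL) {
  data.frame(id = sprintf("s%02d", seq_along(names)), name = names,
             abbreviation = if (is.null(abbrevs)) NA_character_ else abbrevs,
             source_tag = "", stringsAsFactors = FALSE)
}

# Brute-force all-pairs cosine ranking oracle over character tf-idf,
# computed with dense vectors and no shared code with the index path
# beyond the tokenizer definition (one character per token).
bruteForceTopK <- function(docs, query, k) {
  toks <- lapply(docs, function(d) strsplit(d, "")[[1]])
  qtok <- strsplit(query, "")[[1]]
  vocab <- sort(unique(unlist(toks)))
  m <- length(docs)
  nw <- vapply(vocab, function(w)
    sum(vapply(toks, function(t) w %in% t, logical(1))), numeric(1))
  idf <- log(m / (nw + 1))
  vecFor <- function(t) {
    tf <- vapply(vocab, function(w) sum(t == w) / length(t), numeric(1))
    v <- tf * idf
    n <- sqrt(sum(v^2))
    if (n > 0) v / n else v
  }
  dv <- vapply(toks, vecFor, numeric(length(vocab)))
  qv <- vecFor(qtok[qtok %in% vocab])
  if (!length(qtok[qtok %in% vocab])) qv <- numeric(length(vocab))
  scores <- as.numeric(crossprod(dv, qv))
  ids <- names(docs)
  ord <- order(-scores, ids, method = "radix")
  take <- ord[seq_len(min(k, m))]
  data.frame(standard_id = ids[take], score = scores[take],
             stringsAsFactors = FALSE)
}

# Canonical fixture corpora, generated once per test run.
benchmarkFixture <- function() {
  memoised("benchmarkFixture", function()
    generateCorpus(fixtureSpec("benchmark")))
}

alFixture <- function() {
  memoised("alFixture", function()
    generateCorpus(fixtureSpec("active_learning")))
}
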