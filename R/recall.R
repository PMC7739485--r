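#' Character-level tokenization
#'
#' Splits normalized text into single unicode characters, dropping
#' whitespace. Retrieval is character-based: Chinese indicator names carry
#' most of their signal in shared characters, and a character tokenizer
#' needs no word segmenter.
#'
#' @param text a single string.
#' @return character vector of single-character tokens.
#' @examples
#' tokenizeChars("Na钠")  # "n" "a" "钠"
#' @export
tokenizeChars <- function(text) {
  stopifnot(length(text) == 1L)
  norm <- normalizeIndicatorText(text)
  chars <- strsplit(norm, "", fixed = FALSE)[[1L]]
  chars <- chars[!grepl("^\\s$", chars)]
  if (!length(chars))
    stop("text is empty after normalization: ", deparse(text))
  chars
}

.tokenizeMany <- function(texts) lapply(texts, tokenizeChars)

.channelValues <- function(standardTable, channel) {
  v <- if (channel == "name") standardTable$name else standardTable$abbreviation
  stats::setNames(v, standardTable$id)
}

#' Build a character tf-idf index over the standard set
#'
#' Each standard indicator's channel value (name or abbreviation) is one
#' document. Weighting: tf(d,w) = f(w,d)/|d|, idf(w) = log(|D|/(N_w+1))
#' with the natural log, weight = tf * idf; document vectors are
#' L2-normalized so the dot product of two vectors is their cosine.
#' Standards lacking the channel value are excluded from that channel's
#' index. A document whose every token has idf 0 yields an all-zero vector,
#' which is kept (its cosine with anything is 0).
#'
#' @param standardTable standard-indicator data.frame (see
#'   [IndicatorCorpus-class]), or an `IndicatorCorpus`.
#' @param channel `"name"` or `"abbreviation"`.
#' @return a [TfIdfIndex-class].
#' @export
buildTfIdfIndex <- function(standardTable, channel = c("name", "abbreviation")) {
  channel <- match.arg(channel)
  if (is(standardTable, "IndicatorCorpus"))
    standardTable <- standards(standardTable)
  vals <- .channelValues(standardTable, channel)
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("no standard indicator has a value on the ", channel, " channel")
  toks <- .tokenizeMany(vals)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)), method = "radix")
  vi <- stats::setNames(seq_along(vocab), vocab)
  m <- length(toks)
  docFreq <- integer(length(vocab))
  triplets <- vector("list", m)
  for (i in seq_len(m)) {
    tab <- table(toks[[i]])
    cols <- vi[names(tab)]
    docFreq[cols] <- docFreq[cols] + 1L
    triplets[[i]] <- list(j = unname(cols),
                          tf = as.numeric(tab) / length(toks[[i]]))
  }
  idf <- log(m / (docFreq + 1))
  iIdx <- rep.int(seq_len(m), vapply(triplets, function(t) length(t$j), 0L))
  jIdx <- unlist(lapply(triplets, `[[`, "j"), use.names = FALSE)
  w <- unlist(lapply(triplets, `[[`, "tf"), use.names = FALSE) * idf[jIdx]
  mat <- Matrix::sparseMatrix(i = iIdx, j = jIdx, x = w,
                              dims = c(m, length(vocab)))
  mat <- .l2NormalizeRows(mat)
  new("TfIdfIndex", vocabulary = vocab, docFreq = docFreq, idf = idf,
      docVectors = mat, docIds = names(vals), channel = channel)
}

.l2NormalizeRows <- function(mat) {
  nrm <- sqrt(Matrix::rowSums(mat^2))
  nrm[nrm == 0] <- 1  # all-zero vectors stay zero
  Matrix::Diagonal(x = 1 / nrm) %*% mat
}

#' Represent a query text as a tf-idf vector over an index's vocabulary
#'
#' Uses the index's idf weights; out-of-vocabulary characters contribute
#' nothing. The vector is L2-normalized unless all-zero.
#'
#' @param index a [TfIdfIndex-class].
#' @param text query string.
#' @return numeric vector of length `length(index@vocabulary)`.
#' @export
tfidfVector <- function(index, text) {
  toks <- tokenizeChars(text)
  v <- numeric(length(index@vocabulary))
  tab <- table(toks)
  pos <- match(names(tab), index@vocabulary)
  keep <- !is.na(pos)
  v[pos[keep]] <- (as.numeric(tab)[keep] / length(toks)) * index@idf[pos[keep]]
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Top-k most similar standards for a query text
#'
#' Scores are dot products of L2-normalized tf-idf vectors (cosine
#' similarity). Results are sorted by descending score; ties broken by
#' ascending standard id for determinism.
#'
#' @param index a [TfIdfIndex-class].
#' @param text query string on the index's channel.
#' @param k number of candidates to return (capped at the index size).
#' @return data.frame with columns `standard_id`, `score`.
#' @export
topK <- function(index, text, k) {
  stopifnot(k >= 1L)
  qv <- tfidfVector(index, text)
  scores <- as.numeric(index@docVectors %*% qv)
  ord <- order(-scores, index@docIds, method = "radix")
  take <- ord[seq_len(min(k, length(scores)))]
  data.frame(standard_id = index@docIds[take], score = scores[take],
             stringsAsFactors = FALSE)
}

#' Union of name-channel and abbreviation-channel candidates
#'
#' Merges a top-k1 name-channel list and a top-k2 abbreviation-channel list
#' into one candidate set. A standard found by both channels is kept once
#' with the larger score and channel `"both"`. The merged set is sorted by
#' descending score, ties by ascending standard id. Set sizes therefore
#' range from k1 (abbreviation absent or fully overlapping) to k1 + k2.
#'
#' @param nameList data.frame from [topK()] on the name channel (or NULL).
#' @param abbrevList data.frame from [topK()] on the abbreviation channel
#'   (or NULL when the query has no abbreviation).
#' @return data.frame with columns `standard_id`, `score`, `channel`.
#' @export
unionCandidates <- function(nameList, abbrevList = NULL) {
  empty <- function(x) is.null(x) || !nrow(x)
  if (empty(nameList) && empty(abbrevList))
    stop("both candidate lists are empty; indicator cannot be processed")
  tag <- function(x, ch) {
    if (empty(x)) return(NULL)
    x$channel <- ch
    x
  }
  all <- rbind(tag(nameList, "name"), tag(abbrevList, "abbreviation"))
  sp <- split(all, all$standard_id)
  merged <- do.call(rbind, lapply(sp, function(g) {
    data.frame(standard_id = g$standard_id[1L], score = max(g$score),
               channel = if (nrow(g) > 1L) "both" else g$channel[1L],
               stringsAsFactors = FALSE)
  }))
  ord <- order(-merged$score, merged$standard_id, method = "radix")
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Generate candidate sets for every non-standard indicator
#'
#' Runs the recall stage over a whole corpus: a tf-idf (or baseline) index
#' per channel over the standards, then per non-standard indicator the
#' union of the top-k1 name-channel and top-k2 abbreviation-channel hits.
#' Queries without an abbreviation use the name channel only.
#'
#' @param corpus an [IndicatorCorpus-class].
#' @param k1 name-channel candidates (default 15).
#' @param k2 abbreviation-channel candidates (default 5).
#' @param method `"tfidf"` (default) or one of the baselines
#'   `"edit"`, `"bow"`, `"bm25"`.
#' @param channels which channels to use; default both. `"name"` reproduces
#'   the name-only retrieval setting.
#' @return a [CandidateSets-class].
#' @export
generateCandidates <- function(corpus, k1 = 15L, k2 = 5L,
                               method = c("tfidf", "edit", "bow", "bm25"),
                               channels = c("name", "abbreviation")) {
  method <- match.arg(method)
  channels <- match.arg(channels, several.ok = TRUE)
  std <- standards(corpus)
  non <- nonstandards(corpus)
  if (!nrow(non)) stop("corpus has no non-standard indicators")
  useAbbrev <- "abbreviation" %in% channels &&
    any(!is.na(std$abbreviation))
  rankFun <- .channelRanker(method, std, "name")
  rankFunA <- if (useAbbrev) .channelRanker(method, std, "abbreviation")
  entries <- vector("list", nrow(non))
  for (i in seq_len(nrow(non))) {
    nl <- rankFun(non$name[i], k1)
    al <- if (useAbbrev && !is.na(non$abbreviation[i]))
      rankFunA(non$abbreviation[i], k2) else NULL
    u <- unionCandidates(nl, al)
    u$nonstandard_id <- non$id[i]
    entries[[i]] <- u
  }
  e <- do.call(rbind, entries)
  e <- e[, c("nonstandard_id", "standard_id", "score", "channel")]
  rownames(e) <- NULL
  new("CandidateSets", entries = e, queryIds = non$id)
}

# Returns function(text, k) -> data.frame(standard_id, score) for one
# channel under the given retrieval method.
.channelRanker <- function(method, standardTable, channel) {
  vals <- .channelValues(standardTable, channel)
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("no standard indicator has a value on the ", channel, " channel")
  if (method == "tfidf") {
    index <- buildTfIdfIndex(standardTable, channel)
    return(function(text, k) topK(index, text, k))
  }
  ids <- names(vals)
  scoreAll <- switch(method,
    edit = {
      docsNorm <- vapply(vals, function(d)
        paste(tokenizeChars(d), collapse = ""), character(1))
      docLen <- nchar(docsNorm)
      function(text) {
        q <- paste(tokenizeChars(text), collapse = "")
        d <- as.numeric(utils::adist(q, docsNorm)[1L, ])
        1 - d / pmax(nchar(q), docLen)
      }
    },
    bow = {
      toks <- .tokenizeMany(vals)
      vocab <- sort(unique(unlist(toks, use.names = FALSE)))
      counts <- vapply(toks, function(t)
        vapply(vocab, function(w) sum(t == w), numeric(1)),
        numeric(length(vocab)))
      counts <- matrix(counts, nrow = length(vocab))
      norms <- sqrt(colSums(counts^2))
      function(text) {
        qt <- tokenizeChars(text)
        qv <- vapply(vocab, function(w) sum(qt == w), numeric(1))
        qn <- sqrt(sum(table(qt)^2))  # norm includes OOV characters
        s <- as.numeric(crossprod(counts, qv))
        ifelse(norms > 0 & qn > 0, s / (norms * qn), 0)
      }
    },
    bm25 = {
      idx <- .bm25Index(vals)
      function(text) bm25Scores(idx, text)
    })
  function(text, k) {
    s <- unname(scoreAll(text))
    ord <- order(-s, ids, method = "radix")
    take <- ord[seq_len(min(k, length(s)))]
    data.frame(standard_id = ids[take], score = s[take],
               stringsAsFactors = FALSE)
  }
}

#' @rdname candidateSetLengths
#' @export
candidateEntries <- function(x) x@entries

#' Candidate-set sizes per query
#' @param x a [CandidateSets-class].
#' @return named integer vector of set sizes (0 for queries with no entry).
#' @export
candidateSetLengths <- function(x) {
  tab <- table(factor(x@entries$nonstandard_id, levels = x@queryIds))
  stats::setNames(as.integer(tab), x@queryIds)
}

# ---- retrieval baselines ---------------------------------------------------

#' String-similarity baselines for candidate retrieval
#'
#' `editSimilarity`: 1 - levenshtein(a, b) / max(|a|, |b|) over normalized
#' characters. `bowCosine`: cosine of raw character-count vectors.
#' `bm25Scores`: Okapi BM25 (k1 = 1.5, b = 0.75) of a query against a
#' character-tokenized document index built with `.bm25Index()`.
#'
#' @param a,b strings.
#' @return similarity score.
#' @export
editSimilarity <- function(a, b) {
  an <- paste(tokenizeChars(a), collapse = "")
  bn <- paste(tokenizeChars(b), collapse = "")
  d <- utils::adist(an, bn)[1L, 1L]
  1 - d / max(nchar(an), nchar(bn))
}

#' @rdname editSimilarity
#' @export
bowCosine <- function(a, b) {
  ta <- table(tokenizeChars(a)); tb <- table(tokenizeChars(b))
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(0)
  num <- sum(as.numeric(ta[common]) * as.numeric(tb[common]))
  num / (sqrt(sum(as.numeric(ta)^2)) * sqrt(sum(as.numeric(tb)^2)))
}

.bm25Index <- function(docs, k1 = 1.5, b = 0.75) {
  toks <- .tokenizeMany(docs)
  n <- length(toks)
  lens <- vapply(toks, length, 0L)
  df <- table(unlist(lapply(toks, unique), use.names = FALSE))
  idf <- log((n - as.numeric(df) + 0.5) / (as.numeric(df) + 0.5) + 1)
  names(idf) <- names(df)
  tf <- lapply(toks, function(t) table(t))
  list(toks = toks, tf = tf, lens = lens, avgLen = mean(lens), idf = idf,
       k1 = k1, b = b, ids = names(docs))
}

#' @rdname editSimilarity
#' @param index bm25 index from the internal builder.
#' @param query query string.
#' @export
bm25Scores <- function(index, query) {
  q <- unique(tokenizeChars(query))
  q <- q[q %in% names(index$idf)]
  scores <- numeric(length(index$toks))
  if (!length(q)) return(scores)
  for (i in seq_along(index$toks)) {
    tf <- index$tf[[i]]
    present <- q[q %in% names(tf)]
    if (!length(present)) next
    f <- as.numeric(tf[present])
    denom <- f + index$k1 *
      (1 - index$b + index$b * index$lens[i] / index$avgLen)
    scores[i] <- sum(index$idf[present] * f * (index$k1 + 1) / denom)
  }
  scores
}

#' Pairwise baseline similarity
#'
#' Convenience dispatcher over the retrieval baselines for a single pair of
#' strings (`edit_distance`, `bow`) or a query against a document set
#' (`bm25`, where `b` is a character vector of documents).
#'
#' @param method one of `"edit_distance"`, `"bow"`, `"bm25"`.
#' @param a query string.
#' @param b string (edit/bow) or named character vector of documents (bm25).
#' @return numeric score (scalar, or per-document vector for bm25).
#' @export
baselineScore <- function(method = c("edit_distance", "bow", "bm25"), a, b) {
  method <- match.arg(method)
  switch(method,
    edit_distance = editSimilarity(a, b),
    bow = bowCosine(a, b),
    bm25 = {
      if (is.null(names(b))) names(b) <- as.character(seq_along(b))
      bm25Scores(.bm25Index(b), a)
    })
}

# ---- retrieval metrics -----------------------------------------------------

.goldRanks <- function(candidateSets, goldMap, k = Inf) {
  goldMap <- goldMap[!is.na(goldMap)]
  e <- candidateEntries(candidateSets)
  missing <- setdiff(names(goldMap), candidateSets@queryIds)
  if (length(missing))
    stop("no candidate set for labeled non-standard id: ", missing[1L])
  vapply(names(goldMap), function(qid) {
    g <- e[e$nonstandard_id == qid, , drop = FALSE]
    if (is.finite(k)) g <- g[seq_len(min(k, nrow(g))), , drop = FALSE]
    r <- which(g$standard_id == goldMap[[qid]])
    if (length(r)) r[1L] else NA_integer_
  }, integer(1))
}

#' Retrieval recall: fraction of queries whose gold standard was recalled
#'
#' @param candidateSets a [CandidateSets-class].
#' @param goldMap named character vector (non-standard id -> standard id);
#'   `NA` entries (unlabeled) are ignored.
#' @param k evaluate only the top-k of each merged candidate set
#'   (default: the whole set).
#' @return fraction in `[0, 1]`.
#' @export
recallAt <- function(candidateSets, goldMap, k = Inf) {
  ranks <- .goldRanks(candidateSets, goldMap, k)
  if (!length(ranks)) stop("goldMap has no labeled entries")
  mean(!is.na(ranks))
}

#' Mean reciprocal rank of the gold standard
#'
#' Rank is 1-based over the score-sorted merged candidate set; a gold
#' standard absent from its set contributes reciprocal rank 0.
#'
#' @inheritParams recallAt
#' @return MRR in `[0, 1]`.
#' @export
meanReciprocalRank <- function(candidateSets, goldMap, k = Inf) {
  ranks <- .goldRanks(candidateSets, goldMap, k)
  if (!length(ranks)) stop("goldMap has no labeled entries")
  rr <- ifelse(is.na(ranks), 0, 1 / ranks)
  mean(rr)
}
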