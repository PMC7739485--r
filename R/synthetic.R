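# Synthetic indicator corpora. Real hospital indicator lists are private;
# the generator reproduces the statistical structure that drives the method
# instead: variants share most characters with their standard, synonym
# token groups emulate alternative translations of the same concept, habit
# rewordings permute or extend the token sequence, and abbreviations are
# noisy or missing. It makes no attempt at clinically meaningful Chinese.

#' Specification of a synthetic indicator corpus
#'
#' @param n_standard number of standard indicators (default 200).
#' @param synonyms_min,synonyms_max per-standard variant count range
#'   (default 1 to 6).
#' @param name_tokens_min,name_tokens_max number of concept tokens per
#'   standard name (default 2 to 4).
#' @param char_edit_rate per-character probability of a random
#'   substitution / deletion / insertion in a variant name (default 0.05).
#' @param synonym_table_size number of interchangeable token groups, each a
#'   concept with several "translations" (default 40).
#' @param synonym_swap_rate probability a group token in a variant is
#'   swapped for another member of its group (default 0.4).
#' @param habit_rate probability a variant gets a habit rewording: adjacent
#'   token swap, tail-token drop, or a prepended modifier (default 0.3).
#' @param abbrev_missing_rate probability a variant's abbreviation is
#'   absent (default 0.2).
#' @param abbrev_perturb_rate probability a present abbreviation is edited
#'   (truncation, letter substitution or insertion; default 0.3).
#' @param distractor_overlap in `[0, 1]`: larger values shrink the token
#'   inventory so unrelated standards share more characters (default 0.2).
#' @param seed integer seed; the same spec and seed give byte-identical
#'   corpora.
#' @return a named list with class `"syntheticSpec"`.
#' @export
syntheticSpec <- function(n_standard = 200L, synonyms_min = 1L,
                          synonyms_max = 6L, name_tokens_min = 2L,
                          name_tokens_max = 4L, char_edit_rate = 0.05,
                          synonym_table_size = 40L,
                          synonym_swap_rate = 0.4, habit_rate = 0.3,
                          abbrev_missing_rate = 0.2,
                          abbrev_perturb_rate = 0.3,
                          distractor_overlap = 0.2, seed = 1L) {
  rates <- c(char_edit_rate, synonym_swap_rate, habit_rate,
             abbrev_missing_rate, abbrev_perturb_rate, distractor_overlap)
  stopifnot(n_standard >= 2, synonyms_min >= 1,
            synonyms_max >= synonyms_min, name_tokens_min >= 1,
            name_tokens_max >= name_tokens_min,
            all(rates >= 0), all(rates <= 1))
  structure(list(
    n_standard = as.integer(n_standard),
    synonyms_min = as.integer(synonyms_min),
    synonyms_max = as.integer(synonyms_max),
    name_tokens_min = as.integer(name_tokens_min),
    name_tokens_max = as.integer(name_tokens_max),
    char_edit_rate = char_edit_rate,
    synonym_table_size = as.integer(synonym_table_size),
    synonym_swap_rate = synonym_swap_rate, habit_rate = habit_rate,
    abbrev_missing_rate = abbrev_missing_rate,
    abbrev_perturb_rate = abbrev_perturb_rate,
    distractor_overlap = distractor_overlap,
    seed = as.integer(seed)), class = "syntheticSpec")
}

# CJK-range character pool plus multi-character concept tokens and synonym
# groups; everything drawn from the seeded R stream.
.makeLexicon <- function(spec) {
  nTokens <- max(40L, round(2.5 * spec$n_standard *
                              (1 - 0.7 * spec$distractor_overlap)))
  # character inventory grows sublinearly with corpus size: real indicator
  # vocabularies reuse a compact set of clinical characters heavily, which
  # is what makes character-level retrieval (and its distractors) behave
  # the way it does
  nChars <- max(25L, round(8 * sqrt(spec$n_standard) *
                             (1 - 0.5 * spec$distractor_overlap)))
  cps <- sample(0x4E00:0x9FA5, nChars)
  charPool <- vapply(cps, intToUtf8, character(1))
  makeToken <- function() paste(sample(charPool, sample(1:3, 1L),
                                       replace = TRUE), collapse = "")
  tokens <- unique(replicate(nTokens, makeToken()))
  nGroups <- min(spec$synonym_table_size, length(tokens))
  groupBases <- if (nGroups) sample(tokens, nGroups) else character()
  groups <- lapply(groupBases, function(base) {
    alts <- unique(replicate(sample(1:3, 1L), makeToken()))
    c(base, alts)
  })
  names(groups) <- groupBases
  modifiers <- unique(replicate(6L, makeToken()))
  list(charPool = charPool, tokens = tokens, groups = groups,
       modifiers = modifiers)
}

#' Generate the standard side of a synthetic corpus
#'
#' Builds `n_standard` unique names, each a sequence of 2-4 multi-character
#' concept tokens, with a short latin abbreviation. Deterministic under the
#' spec's seed. The token lexicon (character pool, synonym groups, token
#' decompositions) is attached as attribute `"lexicon"` for
#' [generateVariants()].
#'
#' @param spec a [syntheticSpec()].
#' @return data.frame of standard indicators (see
#'   [IndicatorCorpus-class]) with attributes `"lexicon"` and
#'   `"tokenSeqs"`.
#' @export
generateStandards <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  lex <- .makeLexicon(spec)
  seqs <- list()
  names_seen <- character()
  groupBases <- names(lex$groups)
  while (length(seqs) < spec$n_standard) {
    k <- sample(spec$name_tokens_min:spec$name_tokens_max, 1L)
    # concepts with competing translations are common concepts: about half
    # of all name positions carry a synonym-group token, mirroring how
    # frequently real indicator names diverge by translation choice
    fromGroup <- length(groupBases) > 0 & stats::runif(k) < 0.5
    ts <- ifelse(fromGroup, sample(groupBases, k, replace = TRUE),
                 sample(lex$tokens, k))
    while (anyDuplicated(ts))
      ts[duplicated(ts)] <- sample(lex$tokens, sum(duplicated(ts)))
    nm <- paste(ts, collapse = "")
    if (nm %in% names_seen) next
    names_seen <- c(names_seen, nm)
    seqs[[length(seqs) + 1L]] <- ts
  }
  ids <- sprintf("S%04d", seq_len(spec$n_standard))
  abbrevs <- replicate(spec$n_standard,
                       paste(sample(letters, sample(1:4, 1L),
                                    replace = TRUE), collapse = ""))
  df <- data.frame(id = ids, name = names_seen, abbreviation = abbrevs,
                   source_tag = "standard", stringsAsFactors = FALSE)
  names(seqs) <- ids
  attr(df, "lexicon") <- lex
  attr(df, "tokenSeqs") <- seqs
  df
}

.editName <- function(name, rate, charPool) {
  chars <- strsplit(name, "")[[1L]]
  out <- character()
  for (ch in chars) {
    if (stats::runif(1) < rate) {
      op <- sample(c("sub", "del", "ins"), 1L)
      if (op == "sub") out <- c(out, sample(charPool, 1L))
      else if (op == "ins") out <- c(out, ch, sample(charPool, 1L))
      # del: drop the character
    } else out <- c(out, ch)
  }
  if (!length(out)) out <- chars[1L]  # never empty
  paste(out, collapse = "")
}

.perturbAbbrev <- function(ab) {
  op <- sample(c("trunc", "sub", "ins"), 1L)
  chars <- strsplit(ab, "")[[1L]]
  if (op == "trunc" && length(chars) > 1L)
    return(paste(chars[-length(chars)], collapse = ""))
  pos <- sample(seq_along(chars), 1L)
  if (op == "sub") chars[pos] <- sample(letters, 1L)
  else chars <- append(chars, sample(letters, 1L), after = pos)
  paste(chars, collapse = "")
}

#' Generate non-standard variants of standard indicators
#'
#' Each variant composes, in order: synonym-group token swaps (translation
#' variants), an optional habit rewording (adjacent-token swap, tail-token
#' drop, or prepended modifier), per-character random edits, and
#' abbreviation omission or perturbation. When every rate in the spec is
#' zero the variant is character-identical to its standard; otherwise a
#' variant that comes out identical is forced to differ by one character
#' substitution.
#'
#' @param standardTable output of [generateStandards()] (its `"lexicon"`
#'   attribute is required).
#' @param spec the [syntheticSpec()].
#' @param counts integer vector of variants per standard; default drawn
#'   from `synonyms_min:synonyms_max`.
#' @param seed optional seed; when `NULL` the current R random stream is
#'   consumed (as [generateCorpus()] does).
#' @return data.frame of non-standard indicators with a
#'   `gold_standard_id` column.
#' @export
generateVariants <- function(standardTable, spec, counts = NULL,
                             seed = NULL) {
  lex <- attr(standardTable, "lexicon")
  seqs <- attr(standardTable, "tokenSeqs")
  if (is.null(lex) || is.null(seqs))
    stop("standardTable must come from generateStandards()")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(standardTable)
  if (is.null(counts))
    counts <- sample(spec$synonyms_min:spec$synonyms_max, n, replace = TRUE)
  counts <- rep_len(counts, n)
  groupOf <- list()
  for (g in lex$groups) for (tok in g) groupOf[[tok]] <- g
  noisy <- spec$char_edit_rate > 0 || spec$synonym_swap_rate > 0 ||
    spec$habit_rate > 0
  rows <- list()
  for (i in seq_len(n)) {
    sid <- standardTable$id[i]
    stdName <- standardTable$name[i]
    stdAb <- standardTable$abbreviation[i]
    for (j in seq_len(counts[i])) {
      ts <- seqs[[sid]]
      for (t in seq_along(ts)) {
        grp <- groupOf[[ts[t]]]
        if (!is.null(grp) && stats::runif(1) < spec$synonym_swap_rate) {
          others <- setdiff(grp, ts[t])
          # translation preferences are skewed: one alternative rendering
          # of a concept dominates, rarer ones trail off (~1/rank)
          if (length(others))
            ts[t] <- sample(others, 1L,
                            prob = 1 / seq_along(others))
        }
      }
      if (stats::runif(1) < spec$habit_rate) {
        op <- sample(c("swap", "drop", "modifier"), 1L)
        if (op == "swap" && length(ts) >= 2L) {
          pos <- sample(seq_len(length(ts) - 1L), 1L)
          ts[c(pos, pos + 1L)] <- ts[c(pos + 1L, pos)]
        } else if (op == "drop" && length(ts) >= 3L) {
          ts <- ts[-length(ts)]
        } else {
          ts <- c(sample(lex$modifiers, 1L), ts)
        }
      }
      nm <- .editName(paste(ts, collapse = ""), spec$char_edit_rate,
                      lex$charPool)
      if (nm == stdName && noisy) {  # guarantee variant != standard
        chars <- strsplit(nm, "")[[1L]]
        pos <- sample(seq_along(chars), 1L)
        chars[pos] <- sample(setdiff(lex$charPool, chars[pos]), 1L)
        nm <- paste(chars, collapse = "")
      }
      ab <- if (is.na(stdAb) || stats::runif(1) < spec$abbrev_missing_rate) {
        NA_character_
      } else if (stats::runif(1) < spec$abbrev_perturb_rate) {
        .perturbAbbrev(stdAb)
      } else stdAb
      rows[[length(rows) + 1L]] <- data.frame(
        id = NA_character_, name = nm, abbreviation = ab,
        source_tag = sprintf("h%d", sample(8L, 1L)),
        gold_standard_id = sid, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$id <- sprintf("N%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Canonical study fixtures
#'
#' The two fixed synthetic corpora the package's own experiments run on:
#' `"benchmark"` (200 standards, 1-6 variants each, default noise) for the
#' retrieval and classification evaluations, and `"active_learning"` (120
#' standards, 1-4 variants each) for the scaled-down selection-strategy
#' comparison. Seeds are fixed so every analysis sees the same corpora; the
#' benchmark corpus is also shipped as
#' `system.file("extdata", "fixture_corpus.tsv", package = "labnorm")`.
#'
#' @param type which fixture.
#' @return a [syntheticSpec()].
#' @export
fixtureSpec <- function(type = c("benchmark", "active_learning")) {
  type <- match.arg(type)
  switch(type,
    benchmark = syntheticSpec(seed = 20201215L),
    active_learning = syntheticSpec(n_standard = 120L, synonyms_min = 1L,
                                    synonyms_max = 4L, name_tokens_min = 2L,
                                    name_tokens_max = 3L,
                                    seed = 20201216L))
}

#' Generate a full synthetic corpus with candidate sets and labeled pairs
#'
#' Runs [generateStandards()] and [generateVariants()], assembles an
#' [IndicatorCorpus-class] whose gold map links every variant to exactly
#' one standard, runs the recall stage (tf-idf, the given k1/k2) and labels
#' every candidate pair against the gold map.
#'
#' @param spec a [syntheticSpec()].
#' @param k1,k2 recall depths used to build the labeled pair pool.
#' @return list with elements `corpus` ([IndicatorCorpus-class]),
#'   `candidates` ([CandidateSets-class]), `pairs` (labeled candidate
#'   pairs) and `spec`.
#' @export
generateCorpus <- function(spec = syntheticSpec(), k1 = 15L, k2 = 5L) {
  std <- generateStandards(spec)
  variants <- generateVariants(std, spec, seed = spec$seed + 1L)
  gm <- stats::setNames(variants$gold_standard_id, variants$id)
  corpus <- indicatorCorpus(std, variants[, c("id", "name", "abbreviation",
                                              "source_tag")], gm)
  candidates <- generateCandidates(corpus, k1 = k1, k2 = k2)
  pairs <- buildTrainingPairs(candidates, goldMap(corpus))
  list(corpus = corpus, candidates = candidates, pairs = pairs, spec = spec)
}
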