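#' Candidate-set uncertainty measures
#'
#' Each non-standard indicator owns a candidate set of predicted synonymy
#' probabilities p (one per candidate pair). Because set sizes differ, each
#' measure is the mean over the set's candidates (length-normalized):
#'
#' * least confidence: `mean(1 - pmax(p, 1 - p))`, in `[0, 0.5]`;
#' * Shannon entropy: `mean(-(p log p + (1-p) log(1-p)))` with natural log
#'   and `0 log 0 = 0`, in `[0, log 2]`;
#' * gini index: `mean(2 p (1 - p))`, in `[0, 0.5]` — the probability that
#'   two consecutive draws from the predicted label distribution disagree.
#'
#' All three vanish when every prediction is certain (p in \{0, 1\}) and
#' peak at p = 0.5.
#'
#' @param p numeric vector of probabilities for one candidate set.
#' @return a single uncertainty value.
#' @export
uncertaintyLC <- function(p) {
  .checkProbs(p)
  mean(1 - pmax(p, 1 - p))
}

#' @rdname uncertaintyLC
#' @export
uncertaintyEntropy <- function(p) {
  .checkProbs(p)
  term <- function(q) ifelse(q <= 0, 0, q * log(q))
  mean(-(term(p) + term(1 - p)))
}

#' @rdname uncertaintyLC
#' @export
uncertaintyGini <- function(p) {
  .checkProbs(p)
  mean(2 * p * (1 - p))
}

.checkProbs <- function(p) {
  if (!length(p)) stop("empty candidate set has no uncertainty")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
}

.uncertaintyFun <- function(strategy) {
  switch(strategy,
         lc = uncertaintyLC,
         entropy = uncertaintyEntropy,
         gini = uncertaintyGini,
         stop("unknown strategy: ", strategy))
}

#' Score every candidate set's uncertainty under a strategy
#'
#' @param predictions data.frame with `nonstandard_id` and `p_match`
#'   (one row per candidate pair).
#' @param strategy `"lc"`, `"entropy"` or `"gini"`.
#' @return data.frame `candidate_set_id`, `strategy`, `uncertainty`.
#' @export
scoreUncertainty <- function(predictions,
                             strategy = c("gini", "lc", "entropy")) {
  strategy <- match.arg(strategy)
  f <- .uncertaintyFun(strategy)
  sp <- split(predictions$p_match, predictions$nonstandard_id)
  data.frame(candidate_set_id = names(sp),
             strategy = strategy,
             uncertainty = vapply(sp, f, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the next annotation batch
#'
#' The B candidate sets with the highest uncertainty (all of them when the
#' pool is smaller than B); ties broken by ascending candidate-set id, so
#' selection does not depend on presentation order. The random strategy
#' draws uniformly without replacement from the current R random stream.
#'
#' @param scores data.frame from [scoreUncertainty()], or for
#'   `strategy = "random"` a character vector / data.frame of pool ids.
#' @param B batch size.
#' @param strategy `"uncertainty"` (use the scores) or `"random"`.
#' @return character vector of selected candidate-set ids.
#' @export
selectBatch <- function(scores, B, strategy = c("uncertainty", "random")) {
  strategy <- match.arg(strategy)
  if (strategy == "random") {
    ids <- if (is.data.frame(scores)) scores$candidate_set_id else scores
    if (!length(ids)) return(character())
    return(sample(ids, min(B, length(ids))))
  }
  if (!nrow(scores)) return(character())
  ord <- order(-scores$uncertainty, scores$candidate_set_id,
               method = "radix")
  scores$candidate_set_id[ord[seq_len(min(B, nrow(scores)))]]
}

#' Simulate the pool-based active-learning loop
#'
#' Starting from an unlabeled pool of candidate sets, each round: select a
#' batch of B sets (randomly in the first round, by the chosen strategy
#' afterwards), reveal their gold labels (simulating the expert annotator),
#' retrain the classifier from scratch on all revealed pairs, evaluate
#' pair-level F1 on the held-out test split, and score the remaining pool's
#' uncertainties for the next round. Fully seeded: the same seed reproduces
#' the same history.
#'
#' @param corpus an [IndicatorCorpus-class] with gold labels.
#' @param candidateSets a [CandidateSets-class] over all non-standards.
#' @param strategy `"random"`, `"lc"`, `"entropy"` or `"gini"`.
#' @param config an [esimConfig()] used for every retraining.
#' @param testIds non-standard ids held out for evaluation; must be
#'   disjoint from the pool.
#' @param batch_size sets revealed per round (default 100).
#' @param rounds number of rounds; default exhausts the pool.
#' @param seed master seed for selection randomness; per-round model seeds
#'   derive from it.
#' @param threshold decision threshold for F1 (default 0.5).
#' @param negative_ratio optional cap on negatives per positive when
#'   building each round's training pairs (see [buildTrainingPairs()]);
#'   default keeps all.
#' @param min_updates optional fixed optimization budget per retraining:
#'   each round's epoch count is raised (up to 150) so at least this many
#'   SGD updates happen, so early rounds with few labeled pairs still
#'   train to convergence. Default `NULL` uses `config$epochs` as is.
#' @param warm_start reuse the previous round's parameters instead of
#'   retraining from scratch (default FALSE).
#' @return data.frame with one row per round: `round`, `n_labeled`,
#'   `fraction_labeled`, `test_f1`.
#' @export
runALLoop <- function(corpus, candidateSets,
                      strategy = c("random", "lc", "entropy", "gini"),
                      config = esimConfig(), testIds,
                      batch_size = 100L, rounds = NULL, seed = 1L,
                      threshold = 0.5, negative_ratio = NULL,
                      min_updates = NULL, warm_start = FALSE) {
  strategy <- match.arg(strategy)
  gm <- goldMap(corpus)
  poolIds <- setdiff(candidateSets@queryIds[
    candidateSets@queryIds %in% names(gm)[!is.na(gm)]], testIds)
  if (any(testIds %in% poolIds)) stop("test ids leak into the pool")
  if (!length(poolIds)) stop("empty active-learning pool")
  if (is.null(rounds)) rounds <- ceiling(length(poolIds) / batch_size)
  testPairs <- buildTrainingPairs(candidateSets, gm, ids = testIds)
  # the vocabulary is corpus-determined, so token ids can be computed once
  # and reused by every round's training and scoring
  template <- esimModel(corpus, config)
  idCache <- textToTokenIds(template,
                            c(combinedTexts(standards(corpus)),
                              combinedTexts(nonstandards(corpus))))
  cachedIds <- function(ids) idCache[ids]
  predictCached <- function(model, pairs) {
    cfg <- model@config
    as.numeric(esim_predict(model@params, length(model@vocab),
                            cfg$embedding_dim, cfg$hidden_dim,
                            cfg$mlp_hidden,
                            cachedIds(pairs$nonstandard_id),
                            cachedIds(pairs$standard_id),
                            isTRUE(cfg$tie_weights),
                            isTRUE(cfg$use_projection)))
  }
  trainCached <- function(cfg, pairs, init = NULL) {
    if (is.null(init))
      init <- esim_init_params(length(template@vocab), cfg$embedding_dim,
                               cfg$hidden_dim, cfg$mlp_hidden, cfg$seed,
                               isTRUE(cfg$tie_weights),
                               isTRUE(cfg$use_projection))
    fit <- esim_train(
      init,
      length(template@vocab), cfg$embedding_dim, cfg$hidden_dim,
      cfg$mlp_hidden, cachedIds(pairs$nonstandard_id),
      cachedIds(pairs$standard_id), as.integer(pairs$label), cfg$epochs,
      cfg$batch_size, cfg$learning_rate, cfg$momentum, cfg$dropout,
      cfg$seed, cfg$grad_clip, list(), list(), integer(),
      isTRUE(cfg$tie_weights), cfg$lr_decay_every, cfg$lr_decay_factor,
      isTRUE(cfg$use_projection))
    initialize(template, config = unclass(cfg),
               params = as.numeric(fit$params),
               history = data.frame(epoch = seq_len(cfg$epochs),
                                    loss = fit$loss, val_f1 = fit$val_f1))
  }
  labeled <- character()
  nextBatch <- NULL
  model <- NULL
  history <- vector("list", rounds)
  set.seed(seed)
  for (r in seq_len(rounds)) {
    pool <- setdiff(poolIds, labeled)
    if (!length(pool)) {
      history[[r]] <- NULL
      next
    }
    batch <- if (r == 1L || strategy == "random" || is.null(nextBatch)) {
      selectBatch(sort(pool), batch_size, strategy = "random")
    } else nextBatch
    labeled <- c(labeled, batch)
    trainPairs <- buildTrainingPairs(candidateSets, gm, ids = labeled,
                                     negative_ratio = negative_ratio,
                                     seed = seed + r)
    roundCfg <- config
    roundCfg$seed <- (config$seed + 7919L * r) %% .Machine$integer.max
    if (!is.null(min_updates)) {
      batches <- ceiling(nrow(trainPairs) / config$batch_size)
      roundCfg$epochs <- max(config$epochs,
                             min(150L, ceiling(min_updates / batches)))
    }
    warmInit <- if (warm_start && !is.null(model)) model@params else NULL
    model <- trainCached(roundCfg, trainPairs, init = warmInit)
    f1 <- classificationMetrics(predictCached(model, testPairs),
                                testPairs$label, threshold)$f1
    remaining <- setdiff(poolIds, labeled)
    nextBatch <- NULL
    if (length(remaining) && strategy != "random") {
      poolPairs <- candidateEntries(candidateSets)
      poolPairs <- poolPairs[poolPairs$nonstandard_id %in% remaining, ,
                             drop = FALSE]
      poolPairs$p_match <- predictCached(model, poolPairs)
      sc <- scoreUncertainty(poolPairs, strategy)
      nextBatch <- selectBatch(sc, batch_size)
    }
    history[[r]] <- data.frame(
      round = r, n_labeled = length(labeled),
      fraction_labeled = length(labeled) / length(poolIds),
      test_f1 = f1)
  }
  out <- do.call(rbind, history)
  rownames(out) <- NULL
  out
}

#' Compare active-learning selection strategies on one corpus
#'
#' Runs [runALLoop()] for each strategy and replicate seed on a shared
#' train/test split, and trains a reference model on the full pool
#' (per seed) for the "all data" F1 the curves are compared against.
#'
#' @param corpus a labeled [IndicatorCorpus-class].
#' @param candidateSets optional pre-computed [CandidateSets-class];
#'   computed with defaults when missing.
#' @param strategies strategies to compare.
#' @param seeds replicate seeds.
#' @param config an [esimConfig()] used for every training.
#' @param batch_size,rounds,threshold,negative_ratio,min_updates,warm_start
#'   forwarded to [runALLoop()] (and, for `negative_ratio`/`min_updates`,
#'   applied to the full-pool reference training as well).
#' @param split_ratio,split_seed the shared train/test split.
#' @return list with `curves` (long data.frame: seed, strategy, round,
#'   n_labeled, fraction_labeled, test_f1), `full_f1` (per-seed F1 of a
#'   model trained on the entire pool) and `split`.
#' @export
compareALStrategies <- function(corpus, candidateSets = NULL,
                                strategies = c("random", "lc", "entropy",
                                               "gini"),
                                seeds = 1:5, config = esimConfig(),
                                batch_size = 100L, rounds = NULL,
                                split_ratio = 0.7, split_seed = 1L,
                                threshold = 0.5, negative_ratio = NULL,
                                min_updates = NULL, warm_start = FALSE) {
  if (is.null(candidateSets))
    candidateSets <- generateCandidates(corpus)
  split <- splitCorpus(corpus, split_ratio, split_seed)
  gm <- goldMap(corpus)
  pool <- setdiff(candidateSets@queryIds[
    candidateSets@queryIds %in% names(gm)[!is.na(gm)]], split$test)
  testPairs <- buildTrainingPairs(candidateSets, gm, ids = split$test)
  curves <- list()
  fullF1 <- numeric(length(seeds))
  for (si in seq_along(seeds)) {
    s <- seeds[si]
    for (strategy in strategies) {
      h <- runALLoop(corpus, candidateSets, strategy = strategy,
                     config = config, testIds = split$test,
                     batch_size = batch_size, rounds = rounds, seed = s,
                     threshold = threshold,
                     negative_ratio = negative_ratio,
                     min_updates = min_updates, warm_start = warm_start)
      curves[[length(curves) + 1L]] <-
        cbind(seed = s, strategy = strategy, h)
    }
    fullCfg <- config
    fullCfg$seed <- (config$seed + 31L * s) %% .Machine$integer.max
    fullPairs <- buildTrainingPairs(candidateSets, gm, ids = pool,
                                    negative_ratio = negative_ratio,
                                    seed = s)
    if (!is.null(min_updates)) {
      # match the reference's optimization budget to one AL run's
      # cumulative training: under warm starting a run accumulates about
      # rounds x min_updates updates in total
      nRounds <- if (is.null(rounds))
        ceiling(length(pool) / batch_size) else rounds
      refUpdates <- if (warm_start) nRounds * min_updates else min_updates
      batches <- ceiling(nrow(fullPairs) / config$batch_size)
      fullCfg$epochs <- max(config$epochs,
                            min(300L, ceiling(refUpdates / batches)))
    }
    model <- trainEsim(esimModel(corpus, fullCfg), corpus, fullPairs,
                       config = fullCfg)
    pr <- predictProba(model, corpus, testPairs)
    fullF1[si] <- classificationMetrics(pr$p_match, testPairs$label,
                                        threshold)$f1
  }
  out <- do.call(rbind, curves)
  rownames(out) <- NULL
  list(curves = out, full_f1 = stats::setNames(fullF1, seeds),
       split = split)
}

#' Smallest labeled fraction reaching a target F1
#'
#' For one learning curve, the first labeled fraction whose test F1 meets
#' `target`; `NA` when never reached.
#'
#' @param history data.frame from [runALLoop()].
#' @param target F1 level to reach.
#' @return labeled fraction, or `NA`.
#' @export
fractionToReach <- function(history, target) {
  hit <- which(history$test_f1 >= target)
  if (!length(hit)) return(NA_real_)
  history$fraction_labeled[hit[1L]]
}

#' Area under the F1-versus-labeled-fraction curve
#'
#' Trapezoidal area of a learning curve produced by [runALLoop()],
#' normalized by the fraction range covered; used to compare selection
#' strategies.
#'
#' @param history data.frame from [runALLoop()].
#' @return scalar area.
#' @export
learningCurveAUC <- function(history) {
  x <- history$fraction_labeled
  y <- history$test_f1
  if (length(x) < 2L) return(mean(y))
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  auc / (x[length(x)] - x[1L])
}
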