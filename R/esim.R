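#' ESIM classifier configuration
#'
#' Hyper-parameters of the sequence-pair classifier. Training uses
#' minibatch SGD on cross-entropy; this optimizer choice is fixed.
#'
#' @param embedding_dim character-embedding width (default 64).
#' @param hidden_dim BiLSTM hidden width per direction (default 64).
#' @param mlp_hidden width of the MLP hidden layer (default 128).
#' @param dropout dropout probability on the pooled vector and the MLP
#'   hidden layer during training, in `[0, 1)` (default 0.2).
#' @param learning_rate SGD learning rate (default 0.1).
#' @param momentum SGD momentum coefficient (default 0.9; 0 recovers plain
#'   SGD).
#' @param epochs training epochs (default 10).
#' @param batch_size minibatch size (default 32).
#' @param max_len maximum character sequence length; longer combined texts
#'   are truncated (default 32).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout; two runs with the same seed are bit-identical.
#' @param grad_clip global gradient-norm clip; 0 disables (default 5).
#' @param lr_decay_every halve-style step decay interval in epochs; 0
#'   disables (default 20).
#' @param lr_decay_factor multiplicative decay applied every
#'   `lr_decay_every` epochs (default 0.5).
#' @param use_projection apply a shared ReLU feedforward projection that
#'   reduces the enhanced representation from 8*hidden to hidden before the
#'   composition BiLSTMs (default TRUE). The projection carries most of the
#'   regularization benefit at small training scale: without it the
#'   composition layer dominates the parameter count and overfits.
#' @param tie_weights share the encoder (and composer) BiLSTM weights
#'   between query and hypothesis (default TRUE). Shared weights put both
#'   sides' states in one representation space, so attention recognizes
#'   matching characters even in unseen combinations, which generalizes far
#'   better on small training sets; set FALSE for fully separate
#'   parameter sets per side.
#' @return a named list with class `"esimConfig"`.
#' @export
esimConfig <- function(embedding_dim = 64L, hidden_dim = 64L,
                       mlp_hidden = 128L, dropout = 0.2,
                       learning_rate = 0.1, momentum = 0.9, epochs = 10L,
                       batch_size = 32L, max_len = 32L, seed = 1L,
                       grad_clip = 5, tie_weights = TRUE,
                       use_projection = TRUE,
                       lr_decay_every = 20L, lr_decay_factor = 0.5) {
  stopifnot(embedding_dim >= 1, hidden_dim >= 1, mlp_hidden >= 1,
            dropout >= 0, dropout < 1, learning_rate > 0, epochs >= 1,
            batch_size >= 1, max_len >= 1, momentum >= 0, momentum < 1)
  structure(list(
    embedding_dim = as.integer(embedding_dim),
    hidden_dim = as.integer(hidden_dim),
    mlp_hidden = as.integer(mlp_hidden),
    dropout = dropout, learning_rate = learning_rate, momentum = momentum,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    max_len = as.integer(max_len), seed = as.integer(seed),
    grad_clip = grad_clip, tie_weights = isTRUE(tie_weights),
    use_projection = isTRUE(use_projection),
    lr_decay_every = as.integer(lr_decay_every),
    lr_decay_factor = lr_decay_factor,
    optimizer = "SGD"), class = "esimConfig")
}

.esimVocab <- function(texts) {
  chars <- sort(unique(unlist(lapply(texts, tokenizeChars),
                              use.names = FALSE)), method = "radix")
  c("<unk>", chars)
}

#' Initialize an (untrained) ESIM model over a corpus
#'
#' Builds the character vocabulary from the combined name+abbreviation
#' texts of both corpus sides and initializes parameters. The softmax head
#' starts at zero, so an untrained model predicts p = 0.5 for every pair.
#'
#' @param corpus an [IndicatorCorpus-class] (vocabulary source).
#' @param config an [esimConfig()].
#' @return an [EsimModel-class].
#' @export
esimModel <- function(corpus, config = esimConfig()) {
  texts <- c(combinedTexts(standards(corpus)),
             combinedTexts(nonstandards(corpus)))
  vocab <- .esimVocab(texts)
  params <- esim_init_params(length(vocab), config$embedding_dim,
                             config$hidden_dim, config$mlp_hidden,
                             config$seed, isTRUE(config$tie_weights),
                             isTRUE(config$use_projection))
  new("EsimModel", config = unclass(config), vocab = vocab,
      params = as.numeric(params),
      history = data.frame(epoch = integer(), loss = numeric(),
                           val_f1 = numeric()))
}

#' Convert texts to token-id sequences for an ESIM model
#'
#' Characters outside the model vocabulary map to the `<unk>` id (1);
#' sequences longer than `max_len` are truncated. Padding is id 0 and is
#' ignored by the model, so appending padding never changes a prediction.
#'
#' @param model an [EsimModel-class].
#' @param texts character vector.
#' @return list of integer vectors.
#' @export
textToTokenIds <- function(model, texts) {
  maxLen <- model@config$max_len
  lapply(texts, function(tx) {
    toks <- tokenizeChars(tx)
    ids <- match(toks, model@vocab)
    ids[is.na(ids)] <- 1L
    ids[seq_len(min(length(ids), maxLen))]
  })
}

.pairTexts <- function(corpus, pairs) {
  nonTexts <- combinedTexts(nonstandards(corpus))
  stdTexts <- combinedTexts(standards(corpus))
  if (!all(pairs$nonstandard_id %in% names(nonTexts)))
    stop("pair refers to unknown non-standard id")
  if (!all(pairs$standard_id %in% names(stdTexts)))
    stop("pair refers to unknown standard id")
  list(a = unname(nonTexts[pairs$nonstandard_id]),
       b = unname(stdTexts[pairs$standard_id]))
}

#' Train the ESIM classifier on labeled candidate pairs
#'
#' Query (a) is the non-standard indicator's combined text; hypothesis (b)
#' is the standard's. Optimized with minibatch SGD on cross-entropy. When
#' `validation` pairs are given, per-epoch validation F1 is tracked and the
#' best-epoch parameters are kept.
#'
#' @param model an [EsimModel-class] (untrained or warm start).
#' @param corpus the [IndicatorCorpus-class] providing the texts.
#' @param pairs data.frame with `nonstandard_id`, `standard_id`,
#'   `label` (0/1). Must contain both classes.
#' @param validation optional data.frame of the same shape.
#' @param config overrides the model's stored config when supplied.
#' @return the trained [EsimModel-class] with `@history` filled.
#' @export
trainEsim <- function(model, corpus, pairs, validation = NULL,
                      config = NULL) {
  cfg <- if (is.null(config)) model@config else unclass(config)
  if (!nrow(pairs)) stop("no training pairs")
  labs <- as.integer(pairs$label)
  if (length(unique(labs)) < 2L)
    stop("training pairs must contain both a positive and a negative class")
  tx <- .pairTexts(corpus, pairs)
  aIds <- textToTokenIds(model, tx$a)
  bIds <- textToTokenIds(model, tx$b)
  if (is.null(validation)) {
    valA <- list(); valB <- list(); valL <- integer()
  } else {
    vtx <- .pairTexts(corpus, validation)
    valA <- textToTokenIds(model, vtx$a)
    valB <- textToTokenIds(model, vtx$b)
    valL <- as.integer(validation$label)
  }
  fit <- esim_train(model@params, length(model@vocab), cfg$embedding_dim,
                    cfg$hidden_dim, cfg$mlp_hidden, aIds, bIds, labs,
                    cfg$epochs, cfg$batch_size, cfg$learning_rate,
                    cfg$momentum, cfg$dropout, cfg$seed, cfg$grad_clip,
                    valA, valB, valL, isTRUE(cfg$tie_weights),
                    if (is.null(cfg$lr_decay_every)) 0L else
                      cfg$lr_decay_every,
                    if (is.null(cfg$lr_decay_factor)) 0.5 else
                      cfg$lr_decay_factor,
                    isTRUE(cfg$use_projection))
  hist <- data.frame(epoch = seq_len(cfg$epochs), loss = fit$loss,
                     val_f1 = fit$val_f1)
  initialize(model, config = cfg, params = as.numeric(fit$params),
             history = hist)
}

#' Predict synonymy probabilities for indicator pairs
#'
#' @param model a trained [EsimModel-class].
#' @param corpus the [IndicatorCorpus-class] providing the texts.
#' @param pairs data.frame with `nonstandard_id`, `standard_id`.
#' @return the pairs with a `p_match` column (probability of synonymy);
#'   deterministic given fixed parameters.
#' @export
predictProba <- function(model, corpus, pairs) {
  out <- pairs[, c("nonstandard_id", "standard_id"), drop = FALSE]
  if (!nrow(pairs)) {
    out$p_match <- numeric()
    return(out)
  }
  tx <- .pairTexts(corpus, pairs)
  cfg <- model@config
  out$p_match <- as.numeric(esim_predict(
    model@params, length(model@vocab), cfg$embedding_dim, cfg$hidden_dim,
    cfg$mlp_hidden, textToTokenIds(model, tx$a), textToTokenIds(model, tx$b),
    isTRUE(cfg$tie_weights), isTRUE(cfg$use_projection)))
  rownames(out) <- NULL
  out
}

#' Classify candidate sets into standard-indicator mappings
#'
#' Scores every candidate pair; pairs with `p_match > threshold` are
#' returned ranked by descending probability within each query. Queries
#' where no candidate passes map to nothing (listed in the `"unmapped"`
#' attribute).
#'
#' @param model a trained [EsimModel-class].
#' @param corpus the corpus providing the texts.
#' @param candidateSets a [CandidateSets-class] from the recall stage.
#' @param threshold decision threshold on p_match (default 0.5).
#' @return data.frame `nonstandard_id`, `standard_id`, `p_match` sorted by
#'   query id then descending probability; attribute `"unmapped"` holds the
#'   query ids with no accepted candidate.
#' @export
classifyCandidates <- function(model, corpus, candidateSets,
                               threshold = 0.5) {
  e <- candidateEntries(candidateSets)
  preds <- predictProba(model, corpus, e)
  keep <- preds[preds$p_match > threshold, , drop = FALSE]
  ord <- order(keep$nonstandard_id, -keep$p_match, keep$standard_id)
  keep <- keep[ord, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "unmapped") <- setdiff(candidateSets@queryIds,
                                    keep$nonstandard_id)
  keep
}

#' Build labeled training pairs from candidate sets
#'
#' Positives are (non-standard, gold standard) pairs where the gold
#' standard was recalled into the candidate set; every other candidate of a
#' labeled query is a negative. Queries without a gold label are skipped.
#' The resulting label distribution is heavily negative (roughly one
#' positive per candidate-set size), which is the imbalance the classifier
#' must cope with; `negative_ratio` optionally downsamples negatives to at
#' most `negative_ratio` per positive.
#'
#' @param candidateSets a [CandidateSets-class].
#' @param goldMap named character vector (non-standard id -> standard id).
#' @param ids optional subset of non-standard ids to use (e.g. a train
#'   split).
#' @param negative_ratio optional cap on negatives per positive; default
#'   keeps all.
#' @param seed seed for the downsampling draw.
#' @return data.frame `nonstandard_id`, `standard_id`, `label`.
#' @export
buildTrainingPairs <- function(candidateSets, goldMap, ids = NULL,
                               negative_ratio = NULL, seed = 1L) {
  e <- candidateEntries(candidateSets)
  goldMap <- goldMap[!is.na(goldMap)]
  keepIds <- names(goldMap)
  if (!is.null(ids)) keepIds <- intersect(keepIds, ids)
  e <- e[e$nonstandard_id %in% keepIds, , drop = FALSE]
  if (!nrow(e)) stop("no labeled candidate pairs")
  e$label <- as.integer(e$standard_id == goldMap[e$nonstandard_id])
  if (!is.null(negative_ratio)) {
    nPos <- sum(e$label == 1L)
    nKeep <- min(sum(e$label == 0L), ceiling(negative_ratio * nPos))
    negIdx <- which(e$label == 0L)
    set.seed(seed)
    e <- e[sort(c(which(e$label == 1L), sample(negIdx, nKeep))), ,
           drop = FALSE]
  }
  out <- e[, c("nonstandard_id", "standard_id", "label")]
  rownames(out) <- NULL
  out
}

#' Inspect the full ESIM forward pass for one pair
#'
#' Runs the model on one (query, hypothesis) pair and returns every
#' intermediate quantity, with sequence positions as rows: the contextual
#' encodings, the attention score matrix and weights, aligned and enhanced
#' representations, composed states, the pooled vector and the class
#' probabilities.
#'
#' @param model an [EsimModel-class].
#' @param a,b texts, or integer token-id vectors when `tokenized = TRUE`.
#' @param tokenized interpret `a`/`b` as token ids directly.
#' @return named list of intermediates.
#' @export
esimForward <- function(model, a, b, tokenized = FALSE) {
  cfg <- model@config
  if (!tokenized) {
    a <- textToTokenIds(model, a)[[1L]]
    b <- textToTokenIds(model, b)[[1L]]
  }
  raw <- esim_forward_debug(model@params, length(model@vocab),
                            cfg$embedding_dim, cfg$hidden_dim,
                            cfg$mlp_hidden, as.integer(a), as.integer(b),
                            isTRUE(cfg$tie_weights),
                            isTRUE(cfg$use_projection))
  within(list(), {
    p <- as.numeric(raw$p)
    logits <- as.numeric(raw$logits)
    hidden <- as.numeric(raw$hidden)
    v <- as.numeric(raw$v)
    vb <- t(raw$vb); va <- t(raw$va)
    mb <- t(raw$mb); ma <- t(raw$ma)
    btilde <- t(raw$btilde); atilde <- t(raw$atilde)
    beta <- raw$beta; alpha <- raw$alpha
    e <- raw$e
    bhat <- t(raw$bhat); ahat <- t(raw$ahat)
  })
}
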