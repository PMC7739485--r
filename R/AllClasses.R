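#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix sparseMatrix Diagonal rowSums
#' @useDynLib labnorm, .registration = TRUE
NULL

#' IndicatorCorpus: a partitioned collection of laboratory indicators
#'
#' Holds the standard vocabulary (the normalization targets) and the
#' non-standard indicators (the variant surface forms to be mapped), plus an
#' optional gold mapping from non-standard ids to standard ids used for
#' training and evaluation.
#'
#' Both `standards` and `nonstandards` are data.frames with columns
#' `id`, `name`, `abbreviation` (`NA` when absent) and `source_tag`.
#' Text is NFKC-normalized with latin characters lowercased, so that e.g.
#' a full-width "PH" and "ph" compare equal.
#'
#' @slot standards data.frame of standard indicators.
#' @slot nonstandards data.frame of non-standard indicators.
#' @slot goldMap named character vector mapping non-standard ids to their
#'   gold standard id; `NA` for unlabeled indicators. Names cover all
#'   non-standard ids.
#'
#' @seealso [readCorpus()], [writeCorpus()], [generateCorpus()]
#' @export
setClass("IndicatorCorpus",
  representation(
    standards    = "data.frame",
    nonstandards = "data.frame",
    goldMap      = "character"
  )
)

.validIndicatorTable <- function(df, what) {
  required <- c("id", "name", "abbreviation", "source_tag")
  if (!all(required %in% names(df)))
    return(sprintf("%s must have columns %s", what,
                   paste(required, collapse = ", ")))
  if (anyDuplicated(df$id))
    return(sprintf("duplicate id in %s: %s", what,
                   df$id[duplicated(df$id)][1L]))
  if (nrow(df) && any(!nzchar(trimws(df$name))))
    return(sprintf("empty name in %s (row %d)", what,
                   which(!nzchar(trimws(df$name)))[1L]))
  ab <- df$abbreviation
  if (nrow(df) && any(!is.na(ab) & !nzchar(trimws(ab))))
    return(sprintf("%s: abbreviation present but empty (use NA for absent)",
                   what))
  TRUE
}

setValidity("IndicatorCorpus", function(object) {
  v <- .validIndicatorTable(object@standards, "standards")
  if (!isTRUE(v)) return(v)
  v <- .validIndicatorTable(object@nonstandards, "nonstandards")
  if (!isTRUE(v)) return(v)
  common <- intersect(object@standards$id, object@nonstandards$id)
  if (length(common))
    return(sprintf("id present on both sides: %s", common[1L]))
  gm <- object@goldMap
  if (!setequal(names(gm), object@nonstandards$id))
    return("goldMap names must be exactly the non-standard ids")
  bad <- gm[!is.na(gm) & !(gm %in% object@standards$id)]
  if (length(bad))
    return(sprintf("gold standard id not among standards: %s", bad[1L]))
  TRUE
})

#' @describeIn IndicatorCorpus-class number of indicators (both sides)
#' @param x,object an `IndicatorCorpus`
#' @export
setMethod("length", "IndicatorCorpus", function(x)
  nrow(x@standards) + nrow(x@nonstandards))

setMethod("show", "IndicatorCorpus", function(object) {
  gm <- object@goldMap
  cat(sprintf(
    "IndicatorCorpus: %d standards, %d non-standards (%d with gold labels)\n",
    nrow(object@standards), nrow(object@nonstandards), sum(!is.na(gm))))
})

#' TfIdfIndex: a character-level tf-idf index over a standard vocabulary
#'
#' For one channel (`name` or `abbreviation`) of a standard-indicator set,
#' stores the character vocabulary, document frequencies, idf weights and
#' L2-normalized tf-idf document vectors. Built by [buildTfIdfIndex()];
#' queried through [tfidfVector()] and [topK()].
#'
#' The weighting follows tf(d,w) = f(w,d)/|d| and
#' idf(w) = log(|D| / (N_w + 1)) with the natural logarithm, where N_w is the
#' number of documents containing w. Note the +1 in the denominator makes
#' idf negative for tokens present in every document of a small corpus;
#' such weights are kept as the formula produces them.
#'
#' @slot vocabulary character vector of tokens; position = column index.
#' @slot docFreq integer vector N_w per token.
#' @slot idf numeric vector of idf weights per token.
#' @slot docVectors sparse dgCMatrix (documents x vocabulary) of
#'   L2-normalized tf-idf weights.
#' @slot docIds character vector of standard ids, one per row.
#' @slot channel `"name"` or `"abbreviation"`.
#' @export
setClass("TfIdfIndex",
  representation(
    vocabulary = "character",
    docFreq    = "integer",
    idf        = "numeric",
    docVectors = "Matrix",
    docIds     = "character",
    channel    = "character"
  )
)

setValidity("TfIdfIndex", function(object) {
  nv <- length(object@vocabulary)
  if (length(object@docFreq) != nv || length(object@idf) != nv)
    return("docFreq and idf must align with vocabulary")
  if (ncol(object@docVectors) != nv)
    return("docVectors column count must equal vocabulary size")
  if (nrow(object@docVectors) != length(object@docIds))
    return("docVectors row count must equal number of doc ids")
  if (length(object@docFreq) && any(object@docFreq < 1L))
    return("every vocabulary token must occur in at least one document")
  m <- nrow(object@docVectors)
  expected <- log(m / (object@docFreq + 1))
  if (nv && max(abs(object@idf - expected)) > 1e-12)
    return("idf weights inconsistent with log(|D|/(N_w+1))")
  if (!(object@channel %in% c("name", "abbreviation")))
    return("channel must be 'name' or 'abbreviation'")
  TRUE
})

setMethod("show", "TfIdfIndex", function(object) {
  cat(sprintf("TfIdfIndex (%s channel): %d documents, %d-token vocabulary\n",
              object@channel, nrow(object@docVectors),
              length(object@vocabulary)))
  if (length(object@idf) && min(object@idf) < 0)
    cat("  note: some idf weights are negative (token in every document)\n")
})

#' CandidateSets: per-query candidate standard indicators with scores
#'
#' The result of the recall stage: for every non-standard indicator, the
#' union of the top-k1 name-channel and top-k2 abbreviation-channel standard
#' candidates. A candidate retrieved by both channels appears once, with the
#' larger of its two scores and channel `"both"`.
#'
#' @slot entries data.frame with columns `nonstandard_id`, `standard_id`,
#'   `score`, `channel`; sorted within each query by descending score, ties
#'   by ascending standard id.
#' @slot queryIds character vector of the non-standard ids covered.
#' @export
setClass("CandidateSets",
  representation(entries = "data.frame", queryIds = "character")
)

setValidity("CandidateSets", function(object) {
  e <- object@entries
  required <- c("nonstandard_id", "standard_id", "score", "channel")
  if (!all(required %in% names(e)))
    return(sprintf("entries must have columns %s",
                   paste(required, collapse = ", ")))
  if (!all(e$nonstandard_id %in% object@queryIds))
    return("entries reference a non-standard id not in queryIds")
  if (anyDuplicated(e[, c("nonstandard_id", "standard_id")]))
    return("duplicate (nonstandard_id, standard_id) pair in entries")
  if (!all(e$channel %in% c("name", "abbreviation", "both")))
    return("channel must be one of name/abbreviation/both")
  TRUE
})

setMethod("show", "CandidateSets", function(object) {
  len <- candidateSetLengths(object)
  cat(sprintf(
    "CandidateSets: %d queries, candidate-set sizes %d..%d (mean %.1f)\n",
    length(object@queryIds),
    if (length(len)) min(len) else 0L, if (length(len)) max(len) else 0L,
    if (length(len)) mean(len) else 0))
})

#' @describeIn CandidateSets-class number of queries covered
#' @param x a `CandidateSets`
#' @export
setMethod("length", "CandidateSets", function(x) length(x@queryIds))

#' EsimModel: a trained (or initialized) ESIM sequence-pair classifier
#'
#' Wraps the flat parameter vector of the enhanced sequential inference
#' model together with its configuration and character vocabulary. The
#' architecture: a shared character embedding table; two BiLSTM input
#' encoders (one for the query, one for the hypothesis); dot-product soft
#' attention producing aligned representations; enhancement
#' [x; x~; x - x~; x * x~]; two composition BiLSTMs; masked average and max
#' pooling; a one-hidden-layer MLP with two-way softmax output.
#'
#' @slot config list, see [esimConfig()].
#' @slot vocab character vector of tokens; position = token id. Position 1
#'   is the out-of-vocabulary token `"<unk>"`.
#' @slot params numeric parameter vector (layout managed by the C++ core).
#' @slot history data.frame of per-epoch training loss (and validation F1
#'   when a validation split was supplied).
#' @export
setClass("EsimModel",
  representation(
    config  = "list",
    vocab   = "character",
    params  = "numeric",
    history = "data.frame"
  )
)

setValidity("EsimModel", function(object) {
  cfg <- object@config
  needed <- c("embedding_dim", "hidden_dim", "mlp_hidden")
  if (!all(needed %in% names(cfg)))
    return("config must contain embedding_dim, hidden_dim, mlp_hidden")
  expected <- esim_param_count(length(object@vocab),
                               cfg$embedding_dim, cfg$hidden_dim,
                               cfg$mlp_hidden, isTRUE(cfg$tie_weights),
                               isTRUE(cfg$use_projection))
  if (length(object@params) != expected)
    return(sprintf("parameter vector has length %d, expected %d",
                   length(object@params), expected))
  TRUE
})

setMethod("show", "EsimModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "EsimModel: |vocab|=%d, embedding=%d, hidden=%d/dir, mlp=%d (%d params)\n",
    length(object@vocab), cfg$embedding_dim, cfg$hidden_dim, cfg$mlp_hidden,
    length(object@params)))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                max(object@history$epoch),
                object@history$loss[nrow(object@history)]))
  else cat("  untrained (initialized parameters)\n")
})
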