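# Reference implementations of the ESIM building blocks on plain matrices
# (rows = sequence positions, columns = features). These are the documented
# algebra of the model; the trained classifier runs the same computations in
# compiled code, and the test suite checks the two against each other.

#' ESIM building blocks
#'
#' `attentionScores`: the attention score matrix e with
#' `e[i, j] = ahat[i, ] . bhat[j, ]`. Masked positions (beyond the true
#' lengths) are set to `-Inf` so they receive zero attention weight.
#'
#' `alignedRepresentations`: soft alignments. Each query position i gets
#' `atilde[i, ] = sum_j softmax_j(e[i, ]) * bhat[j, ]`, and each hypothesis
#' position j gets `btilde[j, ] = sum_i softmax_i(e[, j]) * ahat[i, ]`.
#'
#' `enhanceRepresentations`: the enhanced representation
#' `[x; xt; x - xt; x * xt]` (column-wise concatenation; `*` element-wise).
#'
#' `maskedMeanPool` / `maskedMaxPool`: column means / maxima over the first
#' `len` rows, ignoring padded positions.
#'
#' @param ahat,bhat contextual state matrices (positions x features).
#' @param lenA,lenB true (unpadded) lengths; default all rows.
#' @param e attention score matrix from `attentionScores`.
#' @param x,xt a representation and its aligned counterpart.
#' @param m state matrix (positions x features).
#' @param len true length.
#' @name esimBlocks
NULL

#' @rdname esimBlocks
#' @export
attentionScores <- function(ahat, bhat, lenA = nrow(ahat),
                            lenB = nrow(bhat)) {
  stopifnot(ncol(ahat) == ncol(bhat))
  e <- ahat %*% t(bhat)
  if (lenA < nrow(ahat)) e[(lenA + 1):nrow(e), ] <- -Inf
  if (lenB < nrow(bhat)) e[, (lenB + 1):ncol(e)] <- -Inf
  e
}

.softmaxRows <- function(e) {
  mx <- apply(e, 1L, function(r) max(r[is.finite(r)]))
  w <- exp(sweep(e, 1L, mx))
  w[is.infinite(e) & e < 0] <- 0   # masked positions get zero weight
  sweep(w, 1L, rowSums(w), "/")
}

#' @rdname esimBlocks
#' @export
alignedRepresentations <- function(e, ahat, bhat) {
  alpha <- .softmaxRows(e)        # rows: over hypothesis positions
  beta <- t(.softmaxRows(t(e)))   # cols: over query positions
  list(atilde = alpha %*% bhat,
       btilde = t(beta) %*% ahat,
       alpha = alpha, beta = beta)
}

#' @rdname esimBlocks
#' @export
enhanceRepresentations <- function(x, xt) {
  if (!identical(dim(x), dim(xt)))
    stop("representation and alignment must have identical shape")
  cbind(x, xt, x - xt, x * xt)
}

#' @rdname esimBlocks
#' @export
maskedMeanPool <- function(m, len = nrow(m)) {
  stopifnot(len >= 1, len <= nrow(m))
  colMeans(m[seq_len(len), , drop = FALSE])
}

#' @rdname esimBlocks
#' @export
maskedMaxPool <- function(m, len = nrow(m)) {
  stopifnot(len >= 1, len <= nrow(m))
  apply(m[seq_len(len), , drop = FALSE], 2L, max)
}
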