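# The ESIM building blocks: the plain-R reference algebra, agreement of the
# compiled forward pass with it, and the analytic gradient against finite
# differences.

test_that("attention scores are pairwise dot products with masking", {
  set.seed(1)
  ahat <- matrix(rnorm(6), 2, 3)
  bhat <- matrix(rnorm(9), 3, 3)
  e <- attentionScores(ahat, bhat)
  for (i in 1:2) for (j in 1:3)
    expect_equal(e[i, j], sum(ahat[i, ] * bhat[j, ]), tolerance = 1e-12)
  # zero state row -> zero score row (pre-masking)
  ahat[1, ] <- 0
  expect_equal(attentionScores(ahat, bhat)[1, ], rep(0, 3))
  # masked positions get -Inf
  em <- attentionScores(ahat, bhat, lenA = 1, lenB = 2)
  expect_true(all(is.infinite(em[2, ]) & em[2, ] < 0))
  expect_true(all(is.infinite(em[, 3]) & em[, 3] < 0))
})

test_that("aligned representations are softmax-weighted sums", {
  set.seed(2)
  ahat <- matrix(rnorm(8), 2, 4)
  # singleton hypothesis: every query position aligns to it exactly
  bhat1 <- matrix(rnorm(4), 1, 4)
  al <- alignedRepresentations(attentionScores(ahat, bhat1), ahat, bhat1)
  expect_equal(al$atilde[1, ], bhat1[1, ], tolerance = 1e-12)
  expect_equal(al$atilde[2, ], bhat1[1, ], tolerance = 1e-12)
  # uniform scores: alignment is the plain mean
  bhat <- matrix(rnorm(12), 3, 4)
  alu <- alignedRepresentations(matrix(0, 2, 3), ahat, bhat)
  expect_equal(alu$atilde[1, ], colMeans(bhat), tolerance = 1e-12)
  # hand-computed 2x2 scalar-ish case
  e <- matrix(c(1, 0, 0, 2), 2, 2)
  b2 <- matrix(c(1, 2, 3, 4), 2, 2)
  al2 <- alignedRepresentations(e, matrix(0, 2, 2), b2)
  w11 <- exp(1) / (exp(1) + exp(0))
  expect_equal(al2$atilde[1, ],
               w11 * b2[1, ] + (1 - w11) * b2[2, ], tolerance = 1e-12)
  # attention weights are distributions
  expect_equal(rowSums(al$alpha), rep(1, 2), tolerance = 1e-9)
  expect_equal(colSums(al2$beta), rep(1, 2), tolerance = 1e-9)
})

test_that("enhancement concatenates [x; xt; x - xt; x * xt]", {
  set.seed(3)
  x <- matrix(rnorm(12), 3, 4)
  xt <- matrix(rnorm(12), 3, 4)
  m <- enhanceRepresentations(x, xt)
  expect_equal(dim(m), c(3L, 16L))
  expect_equal(m[, 1:4], x)
  expect_equal(m[, 5:8], xt)
  expect_equal(m[, 9:12], x - xt)
  expect_equal(m[, 13:16], x * xt)
  # identity alignment zeroes the difference block
  expect_true(all(enhanceRepresentations(x, x)[, 9:12] == 0))
  # zero alignment: [x; 0; x; 0]
  m0 <- enhanceRepresentations(x, xt * 0)
  expect_equal(m0[, 9:12], x)
  expect_true(all(m0[, c(5:8, 13:16)] == 0))
  expect_error(enhanceRepresentations(x, xt[1:2, ]), "shape")
})

test_that("masked pooling matches per-row loops and singleton identities", {
  set.seed(4)
  m <- matrix(rnorm(20), 5, 4)
  # singleton sequence: avg == max == the single state
  expect_equal(maskedMeanPool(m, 1), m[1, ])
  expect_equal(maskedMaxPool(m, 1), m[1, ])
  # constant states: avg == max == the constant
  cm <- matrix(rep(c(1, -2, 0.5, 3), each = 5), 5, 4)
  expect_equal(maskedMeanPool(cm), cm[1, ])
  expect_equal(maskedMaxPool(cm), cm[1, ])
  # true-length masking equals an explicit loop over kept rows
  for (len in c(2, 3, 5)) {
    expect_equal(maskedMeanPool(m, len),
                 apply(m[seq_len(len), ], 2, mean))
    expect_equal(maskedMaxPool(m, len),
                 apply(m[seq_len(len), ], 2, max))
  }
})

test_that("the compiled forward pass reproduces the block algebra", {
  gen <- smallSynthetic()
  cfg <- fastConfig()
  model <- esimModel(gen$corpus, cfg)
  a <- c(3L, 7L, 5L, 2L)
  b <- c(6L, 4L, 9L)
  fw <- esimForward(model, a, b, tokenized = TRUE)
  # encoder output shapes: (len, 2 * hidden)
  expect_equal(dim(fw$ahat), c(4L, 12L))
  expect_equal(dim(fw$bhat), c(3L, 12L))
  # attention scores equal dot products of the states it produced
  expect_equal(fw$e, attentionScores(fw$ahat, fw$bhat), tolerance = 1e-12)
  # attention rows/cols are probability distributions
  expect_equal(rowSums(fw$alpha), rep(1, 4), tolerance = 1e-6)
  expect_equal(colSums(fw$beta), rep(1, 3), tolerance = 1e-6)
  # aligned representations equal the reference computation
  al <- alignedRepresentations(fw$e, fw$ahat, fw$bhat)
  expect_equal(fw$atilde, al$atilde, tolerance = 1e-12)
  expect_equal(fw$btilde, al$btilde, tolerance = 1e-12)
  # enhancement blocks recompose exactly
  expect_equal(fw$ma, enhanceRepresentations(fw$ahat, fw$atilde),
               tolerance = 1e-12)
  expect_equal(fw$mb, enhanceRepresentations(fw$bhat, fw$btilde),
               tolerance = 1e-12)
  # pooled vector = [avg_a; max_a; avg_b; max_b] over composed states
  expect_equal(fw$v,
               c(maskedMeanPool(fw$va), maskedMaxPool(fw$va),
                 maskedMeanPool(fw$vb), maskedMaxPool(fw$vb)),
               tolerance = 1e-12)
  # probabilities normalize
  expect_equal(sum(fw$p), 1, tolerance = 1e-9)
})

test_that("with a shared encoder, identical inputs give a symmetric score matrix", {
  gen <- smallSynthetic()
  model <- esimModel(gen$corpus, fastConfig())  # tie_weights default TRUE
  a <- c(2L, 8L, 4L)
  fw <- esimForward(model, a, a, tokenized = TRUE)
  expect_equal(fw$e, t(fw$e), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  V <- 9L; d <- 4L; h <- 3L; m <- 5L
  a <- list(c(2L, 5L, 3L), c(4L, 4L, 7L, 2L))
  b <- list(c(3L, 6L), c(8L, 2L, 5L))
  y <- c(1L, 0L)
  eps <- 1e-5
  for (tied in c(TRUE, FALSE)) {
    set.seed(42)
    params <- as.numeric(labnorm:::esim_init_params(V, d, h, m, 7L, tied))
    params <- params + rnorm(length(params), sd = 0.05)
    g <- labnorm:::esim_loss_grad(params, V, d, h, m, a, b, y, tied)$grad
    idx <- sample(length(params), 70)
    num <- vapply(idx, function(i) {
      p1 <- params; p1[i] <- p1[i] + eps
      p2 <- params; p2[i] <- p2[i] - eps
      (labnorm:::esim_loss_grad(p1, V, d, h, m, a, b, y, tied)$loss -
         labnorm:::esim_loss_grad(p2, V, d, h, m, a, b, y, tied)$loss) /
        (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - g[idx])), 1e-8)
  }
})
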