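test_that("positional encoding matches the literal scalar definition", {
  # closed-form spot values
  pe0 <- positionalEncoding(0, 8)
  expect_equal(pe0[c(1, 3, 5, 7)], rep(0, 4))  # sin(0) at even coords
  expect_equal(pe0[c(2, 4, 6, 8)], rep(1, 4))  # cos(0) at odd coords
  expect_equal(positionalEncoding(1, 6)[1], sin(1), tolerance = 1e-12)
  expect_equal(positionalEncoding(1, 6)[2], cos(1), tolerance = 1e-12)

  # scalar double-loop oracle over pos 0..10, all coordinates
  e <- 12
  for (pos in 0:10) {
    got <- positionalEncoding(pos, e)
    for (i in 0:(e - 1)) {
      want <- if (i %% 2 == 0) sin(pos / 10000^(i / e))
              else cos(pos / 10000^((i - 1) / e))
      expect_equal(got[i + 1], want, tolerance = 1e-12)
    }
  }
})

test_that("masking hides the right number of tokens and never touches [CLS] or [PAD]", {
  e <- data.frame(from = "a", to = "b", weight = 1)
  vocab <- buildVocabulary(list(e))
  sp <- graphMLM:::specialIds(vocab)
  walk10 <- tokenizeSequence(rep(c(1L, 2L), 5), vocab)
  set.seed(2)
  masked <- applyMask(list(walk10), 0.20, vocab)[[1]]
  expect_equal(sum(masked@maskFlags), 2L)  # 20% of 10 maskable
  expect_equal(sum(masked@tokenIds == sp[["mask"]]), 2L)

  # minimum-mask rule: tiny rate still masks one token
  masked2 <- applyMask(list(walk10), 0.01, vocab)[[1]]
  expect_equal(sum(masked2@maskFlags), 1L)

  # [CLS] (and padded positions) never masked over many draws
  padded <- new("TokenizedSequence",
                tokenIds = c(sp[["cls"]], 1L, 2L, sp[["pad"]], sp[["pad"]]),
                positions = 0:4, maskFlags = rep(FALSE, 5),
                originalIds = c(sp[["cls"]], 1L, 2L, sp[["pad"]], sp[["pad"]]))
  for (i in 1:50) {
    m <- applyMask(list(padded), 0.5, vocab)[[1]]
    expect_false(m@maskFlags[1])
    expect_true(all(m@tokenIds[4:5] == sp[["pad"]]))
    expect_true(all(which(m@maskFlags) %in% 2:3))
  }
})

test_that("self-attention reduces to known closed forms", {
  set.seed(3)
  d <- 6L
  H <- matrix(rnorm(4 * d), 4, d)
  Wv <- matrix(rnorm(d * d), d, d)
  Wq <- matrix(rnorm(d * d), d, d)
  Wk <- matrix(rnorm(d * d), d, d)

  # single token: softmax over one score is 1, output is its V projection
  out1 <- selfAttention(H[1, , drop = FALSE], Wq, Wk, Wv, nHeads = 2L)
  expect_equal(out1, H[1, , drop = FALSE] %*% Wv, tolerance = 1e-12)

  # zero query/key projections: uniform attention, rows = column mean of V
  z <- matrix(0, d, d)
  outU <- selfAttention(H, z, z, Wv, nHeads = 2L)
  V <- H %*% Wv
  expect_equal(outU, matrix(colMeans(V), 4, d, byrow = TRUE),
               tolerance = 1e-12)

  # identical tokens give identical output rows
  Hsame <- matrix(rep(H[1, ], 3), 3, d, byrow = TRUE)
  outS <- selfAttention(Hsame, Wq, Wk, Wv, nHeads = 3L)
  expect_equal(outS[1, ], outS[2, ], tolerance = 1e-12)
  expect_equal(outS[2, ], outS[3, ], tolerance = 1e-12)
})

test_that("feed-forward layer applies ReLU between the two linear maps", {
  I2 <- diag(2)
  expect_equal(feedForward(c(0.5, 2), I2, c(0, 0), I2, c(0, 0)), c(0.5, 2))
  expect_equal(feedForward(c(-1, -3), I2, c(0, 0), I2, c(0, 0)), c(0, 0))
  # hand computation: ReLU([1, -2] + [0, 1]) = [1, 0]
  expect_equal(feedForward(c(1, -2), I2, c(0, 1), I2, c(0, 0)), c(1, 0))
})

test_that("masked-token cross-entropy matches closed forms and a hand-rolled oracle", {
  e <- data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1)
  vocab <- buildVocabulary(list(e))  # M = 3 node classes
  mkBatch <- function(ids, maskPos) {
    s <- tokenizeSequence(ids, vocab)
    flags <- rep(FALSE, length(s@tokenIds))
    flags[maskPos] <- TRUE
    new("TokenizedSequence", tokenIds = s@tokenIds, positions = s@positions,
        maskFlags = flags, originalIds = s@originalIds)
  }
  # perfect prediction -> loss 0
  b1 <- list(mkBatch(c(1L, 2L), 2L))
  lg <- array(0, c(1, 3, 3))
  lg[1, 2, 1] <- 1e4  # near-certain mass on the true class
  expect_equal(mlmLoss(lg, b1, "sum"), 0, tolerance = 1e-10)

  # uniform prediction -> ln M
  expect_equal(mlmLoss(array(0, c(1, 3, 3)), b1, "sum"), log(3),
               tolerance = 1e-12)

  # k positions at probability 1/2 -> k ln 2 (two classes tied at the top)
  b2 <- list(mkBatch(c(1L, 2L, 3L), c(2L, 3L)))
  lg2 <- array(-1e4, c(1, 4, 3))
  lg2[1, 2, c(1, 2)] <- 0  # true class 1 tied with class 2
  lg2[1, 3, c(2, 3)] <- 0  # true class 2 tied with class 3
  expect_equal(mlmLoss(lg2, b2, "sum"), 2 * log(2), tolerance = 1e-10)

  # random logits vs hand-rolled -sum y log p; mean reduction divides by k
  set.seed(8)
  lg3 <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  b3 <- list(mkBatch(c(1L, 2L, 3L), c(2L, 4L)), mkBatch(c(3L, 1L, 2L), 3L))
  oracle <- 0
  for (bi in seq_along(b3)) for (l in which(b3[[bi]]@maskFlags)) {
    p <- exp(lg3[bi, l, ]) / sum(exp(lg3[bi, l, ]))
    oracle <- oracle - log(p[b3[[bi]]@originalIds[l]])
  }
  expect_equal(mlmLoss(lg3, b3, "sum"), oracle, tolerance = 1e-10)
  expect_equal(mlmLoss(lg3, b3, "mean_over_masked"), oracle / 3,
               tolerance = 1e-10)
  expect_error(mlmLoss(lg3, list(mkBatch(c(1L, 2L), integer(0))), "sum"),
               "no masked")
})

test_that("propagation matches the dense (1-a)WX + aX oracle and its limits", {
  # alpha = 1 is the identity
  e <- data.frame(from = "a", to = "b", weight = 1)
  nw <- walkNetwork(e, buildVocabulary(list(e)))
  X <- matrix(c(1, 0), 2, 1)
  expect_identical(propagateEmbeddings(X, nw, 1), X)
  # two-node hand computation
  expect_equal(propagateEmbeddings(X, nw, 0.5), matrix(c(0.5, 0.5), 2, 1))
  expect_error(propagateEmbeddings(X, nw, 1.5), "alpha")

  # constant rows are fixed points on regular graphs
  nm <- sprintf("r%d", 1:6)
  ring <- data.frame(from = nm, to = c(nm[-1], nm[1]), weight = 1)
  nwr <- walkNetwork(ring, buildVocabulary(list(ring)))
  Xc <- matrix(2.5, 6, 3)
  expect_equal(propagateEmbeddings(Xc, nwr, 0.3), Xc, tolerance = 1e-12)

  # random 20-node graphs vs dense brute-force product, special rows fixed
  set.seed(21)
  for (rep in 1:3) {
    n <- 20
    nm <- sprintf("x%02d", 1:n)
    pr <- t(combn(n, 2))
    keep <- runif(nrow(pr)) < 0.2
    ed <- data.frame(from = nm[pr[keep, 1]], to = nm[pr[keep, 2]],
                     weight = runif(sum(keep), 0.2, 2))
    vv <- buildVocabulary(list(ed))
    nw <- walkNetwork(ed, vv)
    alpha <- runif(1)
    X <- matrix(rnorm((n + 3) * 4), n + 3, 4)
    got <- propagateEmbeddings(X, nw, alpha)
    W <- as.matrix(normalizedAdjacency(nw))
    dense <- (1 - alpha) * W %*% X[1:n, ] + alpha * X[1:n, ]
    pres <- presentNodes(nw)
    expect_lt(max(abs(got[1:n, ][pres, ] - dense[pres, ])), 1e-10)
    expect_identical(got[1:n, ][!pres, ], X[1:n, ][!pres, ])  # isolated rows
    expect_identical(got[(n + 1):(n + 3), ], X[(n + 1):(n + 3), ])  # specials
  }
})

test_that("the compiled encoder forward pass equals the plain-R composition of the ops", {
  tm <- tinyModel()
  set.seed(5)
  sp <- tm$n + 1:3  # cls, mask, pad (1-based)
  tokens <- rbind(c(sp[1], sample.int(tm$n, 4, replace = TRUE)),
                  c(sp[1], sample.int(tm$n, 2, replace = TRUE), sp[3], sp[3]))
  PE <- positionalEncoding(0:(ncol(tokens) - 1), tm$cfg@e)
  cpp <- graphMLM:::.cppForward(tm$model, tm$cfgList, tokens - 1L, PE, FALSE)
  L <- ncol(tokens)
  d <- 2L * tm$cfg@e
  ref <- graphMLM:::rEncoderForward(tm$model, tm$cfgList, tokens - 1L, PE)
  for (b in 1:2) for (l in 1:L) {
    if (tokens[b, l] == sp[3]) next  # padded positions carry no meaning
    expect_equal(cpp$H[(b - 1) * L + l, ], ref[b, l, ], tolerance = 1e-8)
  }
})
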