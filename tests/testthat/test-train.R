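# small SBM used by the fast training-behaviour checks
smallTrainFixture <- function(seed = 13L) {
  sbm <- generateSBMCollection(nNodes = 40L, nModules = 4L, pIn = 0.5,
                               pOut = 0.05, T = 2L, dropout = 0.1,
                               seed = seed)
  corp <- generateCorpus(sbm$collection, reps = 3L, length = 6L, seed = seed)
  list(sbm = sbm, corp = corp)
}

test_that("zero-epoch training returns the initialised embedding table", {
  fx <- smallTrainFixture()
  cfg <- transformerConfig(e = 8L, nBlocks = 1L, nHeads = 2L, ffnHidden = 16L,
                           epochs = 0L, seed = 4L)
  enc <- trainEncoder(fx$sbm$collection, fx$corp, cfg)
  init <- graphMLM:::initModel(cfg, length(vocabulary(fx$sbm$collection)))
  expect_equal(unname(enc@embedding), init$X, tolerance = 1e-15)
  expect_length(lossTrace(enc), 0)
})

test_that("training is reproducible under a fixed seed and differs across seeds", {
  fx <- smallTrainFixture()
  cfg <- transformerConfig(e = 8L, nBlocks = 1L, nHeads = 2L, ffnHidden = 16L,
                           epochs = 3L, batchSize = 16L, seed = 4L)
  e1 <- trainEncoder(fx$sbm$collection, fx$corp, cfg)
  e2 <- trainEncoder(fx$sbm$collection, fx$corp, cfg)
  expect_identical(lossTrace(e1), lossTrace(e2))
  expect_identical(e1@embedding, e2@embedding)
  cfg2 <- transformerConfig(e = 8L, nBlocks = 1L, nHeads = 2L,
                            ffnHidden = 16L, epochs = 3L, batchSize = 16L,
                            seed = 5L)
  e3 <- trainEncoder(fx$sbm$collection, fx$corp, cfg2)
  expect_false(identical(lossTrace(e1), lossTrace(e3)))
})

test_that("early training loss decreases monotonically with restart-only propagation", {
  base <- fixtureIntegrated(101L)
  cfg <- fixtureConfig(101L, epochs = 5L)
  cfg@alpha <- 1  # restart-only: the mixing term is disabled
  enc <- trainEncoder(base$sbm$collection, base$corpus, cfg)
  tr <- lossTrace(enc)
  expect_length(tr, 5L)
  expect_true(all(diff(tr) <= 0))
})

test_that("analytic gradients match central finite differences on a toy model", {
  tm <- tinyModel(nNodes = 5L, e = 4L, nBlocks = 1L, nHeads = 2L, ffn = 8L)
  set.seed(31)
  sp <- tm$n + 1:3
  # two sequences of a 5-token model, one masked position each
  tokens <- rbind(c(sp[1], 2L, 4L, 1L, 3L),
                  c(sp[1], 5L, 1L, 2L, 2L))
  maskFlag <- rbind(c(0L, 0L, 1L, 0L, 0L),
                    c(0L, 0L, 0L, 1L, 0L))
  targets <- tokens
  masked <- tokens
  masked[maskFlag == 1L] <- sp[2]
  PE <- positionalEncoding(0:4, tm$cfg@e)
  g <- graphMLM:::.cppLossGrad(tm$model, tm$cfgList, masked - 1L, maskFlag,
                               targets - 1L, PE, FALSE)
  lossAt <- function(model) graphMLM:::.cppLossGrad(
    model, tm$cfgList, masked - 1L, maskFlag, targets - 1L, PE, FALSE)$loss
  h <- 1e-5
  relErr <- function(analytic, fd) abs(analytic - fd) / max(abs(fd), 1e-2)
  # embedding entries (includes rows used as context, [MASK] and [CLS])
  rows <- c(2L, 5L, sp[1], sp[2])
  for (r in rows) for (cc in c(1L, 3L)) {
    up <- tm$model; up$X[r, cc] <- up$X[r, cc] + h
    dn <- tm$model; dn$X[r, cc] <- dn$X[r, cc] - h
    fd <- (lossAt(up) - lossAt(dn)) / (2 * h)
    expect_lt(relErr(g$X[r, cc], fd), 1e-4)
  }
  # a few attention and decoder entries for good measure
  for (idx in list(c(1L, 2L), c(3L, 7L))) {
    up <- tm$model; up$blocks[[1]]$Wq[idx[1], idx[2]] <-
      up$blocks[[1]]$Wq[idx[1], idx[2]] + h
    dn <- tm$model; dn$blocks[[1]]$Wq[idx[1], idx[2]] <-
      dn$blocks[[1]]$Wq[idx[1], idx[2]] - h
    fd <- (lossAt(up) - lossAt(dn)) / (2 * h)
    expect_lt(relErr(g$blocks[[1]]$Wq[idx[1], idx[2]], fd), 1e-4)
  }
  up <- tm$model; up$Wd[2, 3] <- up$Wd[2, 3] + h
  dn <- tm$model; dn$Wd[2, 3] <- dn$Wd[2, 3] - h
  expect_lt(relErr(g$Wd[2, 3], (lossAt(up) - lossAt(dn)) / (2 * h)), 1e-4)
})

test_that("sequence embeddings have model width, are deterministic, and see token order", {
  fx <- smallTrainFixture()
  cfg <- transformerConfig(e = 8L, nBlocks = 1L, nHeads = 2L, ffnHidden = 16L,
                           epochs = 2L, batchSize = 16L, seed = 4L)
  enc <- trainEncoder(fx$sbm$collection, fx$corp, cfg)
  nm <- nodeNames(enc@vocab)
  p <- nm[c(1, 5, 9, 2)]
  v1 <- sequenceEmbeddings(enc, list(p, p))
  expect_equal(dim(v1), c(2L, 16L))  # 2e under concatenated encodings
  expect_equal(v1[1, ], v1[2, ])     # identical sequences, identical vectors
  vr <- sequenceEmbeddings(enc, list(rev(p)))
  expect_false(isTRUE(all.equal(v1[1, ], vr[1, ])))  # order matters
  expect_error(sequenceEmbeddings(enc, list(c("nope", nm[1]))), "unknown")
})

test_that("node embeddings and their text round-trip preserve vocabulary order", {
  fx <- smallTrainFixture()
  cfg <- transformerConfig(e = 8L, nBlocks = 1L, nHeads = 2L, ffnHidden = 16L,
                           epochs = 1L, seed = 4L)
  enc <- trainEncoder(fx$sbm$collection, fx$corp, cfg)
  emb <- nodeEmbeddings(enc)
  expect_equal(dim(emb), c(40L, 8L))
  expect_identical(rownames(emb), nodeNames(enc@vocab))
  f <- tempfile()
  writeEmbeddings(enc, f)
  back <- readEmbeddings(f)
  expect_identical(rownames(back), rownames(emb))
  expect_equal(back, emb, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("config objects validate their constraints and read from YAML", {
  expect_error(transformerConfig(maskRate = 0), "maskRate")
  expect_error(transformerConfig(alpha = 1.2), "alpha")
  expect_error(transformerConfig(e = 9L, nHeads = 4L), "divisible")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("e: 16", "nBlocks: 2", "alpha: 0.3", "epochs: 7"), f)
  cfg <- readTransformerConfig(f)
  expect_equal(cfg@e, 16L)
  expect_equal(cfg@alpha, 0.3)
  expect_equal(cfg@epochs, 7L)
  writeLines("notAKey: 1", f)
  expect_error(readTransformerConfig(f), "unknown config key")
})
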