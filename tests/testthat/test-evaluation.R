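test_that("adjusted mutual information reproduces reference values and its identities", {
  # frozen reference values (scikit-learn adjusted_mutual_info_score,
  # arithmetic normaliser) on fixed partitions
  a1 <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  b1 <- c(1, 1, 2, 2, 2, 3, 3, 3, 1, 3)
  expect_equal(amiScore(a1, b1), 0.23728877770133558, tolerance = 1e-12)
  a3 <- c(3, 0, 1, 2, 3, 3, 3, 3, 0, 1, 2, 3, 0, 1, 2, 2, 2, 0, 3, 2, 0, 0,
          3, 3, 0, 0, 3, 3, 2, 2, 3, 0, 0, 3, 1, 0, 0, 3, 1, 0, 3, 1, 0, 2,
          0, 1, 2, 2, 0, 2, 1, 3, 3, 3, 0, 3, 0, 1, 0, 0)
  b3 <- c(2, 1, 0, 0, 0, 2, 1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 2, 1, 1, 1, 1,
          1, 2, 2, 2, 1, 2, 0, 0, 1, 1, 1, 0, 2, 2, 0, 0, 1, 0, 0, 0, 0, 2,
          2, 2, 1, 2, 1, 0, 0, 1, 0, 2, 2, 1, 2, 1, 0, 1)
  expect_equal(amiScore(a3, b3), -0.026107020548781768, tolerance = 1e-12)

  # identity and symmetry on random partitions
  set.seed(17)
  for (i in 1:5) {
    u <- sample.int(6, 80, replace = TRUE)
    v <- sample.int(4, 80, replace = TRUE)
    expect_equal(amiScore(u, u), 1)
    expect_equal(amiScore(u, v), amiScore(v, u), tolerance = 1e-12)
  }

  # chance correction: permuted labels score near zero at n = 200
  set.seed(18)
  clus <- rep(1:5, each = 40)
  amis <- replicate(20, amiScore(clus, sample(clus)))
  expect_lt(mean(abs(amis)), 0.05)
})

test_that("module detection recovers one-hot module structure perfectly", {
  set.seed(23)
  genes <- sprintf("g%03d", 1:60)
  modules <- rep(paste0("M", 1:4), each = 15)
  emb <- model.matrix(~ 0 + factor(modules))
  rownames(emb) <- genes
  std <- new("FunctionalStandard", genes = genes,
             labels = as.list(modules), source = "planted")
  res <- suppressMessages(moduleDetection(emb, std))
  expect_equal(res$bestAMI, 1.0, tolerance = 1e-12)
  expect_true(all(c("metric", "linkage", "k") %in% names(res$best)))
  expect_equal(res$bestAMI, max(res$sweep$ami))  # best is the sweep max
  # the sweep spans the full grid
  expect_setequal(unique(res$sweep$metric), c("cosine", "euclidean"))
  expect_setequal(unique(res$sweep$linkage), c("average", "complete"))
  expect_error(suppressMessages(
    moduleDetection(emb[1, , drop = FALSE], std)), "2 genes")
})

test_that("function prediction separates noiseless indicators and filters rare labels", {
  set.seed(29)
  genes <- sprintf("g%03d", 1:120)
  labs <- sample(paste0("F", 1:3), 120, replace = TRUE)
  emb <- model.matrix(~ 0 + factor(labs)) + 0  # one-hot features
  rownames(emb) <- genes
  std <- new("FunctionalStandard", genes = genes, labels = as.list(labs),
             source = "t")
  res <- functionPredictionCV(emb, std, folds = 5L, nTrees = 60L, seed = 1L)
  expect_gte(res$meanMacroF1, 0.99)
  expect_length(res$perFold, 5L)

  # a 5%-frequency label is excluded from scoring at the 10% threshold
  labs2 <- labs
  labs2[1:6] <- "RARE"  # 6 / 120 = 5%
  std2 <- new("FunctionalStandard", genes = genes, labels = as.list(labs2),
              source = "t")
  res2 <- functionPredictionCV(emb, std2, folds = 5L, nTrees = 60L, seed = 1L)
  expect_false("RARE" %in% res2$labels)
  expect_error(functionPredictionCV(emb, std2, folds = 5L,
                                    minLabelFreq = 0.99), "threshold")
})

test_that("macro F1 under label shuffling stays within the permutation null", {
  set.seed(37)
  n <- 120
  genes <- sprintf("g%03d", 1:n)
  emb <- matrix(rnorm(n * 6), n, 6, dimnames = list(genes, NULL))
  labs <- sample(paste0("F", 1:2), n, replace = TRUE)
  # null distribution: labels shuffled independently of the features
  nullF1 <- replicate(20, {
    std <- new("FunctionalStandard", genes = genes,
               labels = as.list(sample(labs)), source = "null")
    functionPredictionCV(emb, std, folds = 3L, nTrees = 40L,
                         seed = 1L)$meanMacroF1
  })
  std <- new("FunctionalStandard", genes = genes, labels = as.list(labs),
             source = "obs")
  obs <- functionPredictionCV(emb, std, folds = 3L, nTrees = 40L,
                              seed = 1L)$meanMacroF1
  expect_lt(abs(obs - mean(nullF1)), 3 * sd(nullF1) + 1e-8)
})

test_that("macro F1 is invariant to relabelling the label set", {
  set.seed(41)
  genes <- sprintf("g%03d", 1:90)
  labs <- sample(c("A", "B", "C"), 90, replace = TRUE)
  emb <- model.matrix(~ 0 + factor(labs)) + matrix(rnorm(270, sd = 0.3), 90)
  rownames(emb) <- genes
  s1 <- new("FunctionalStandard", genes = genes, labels = as.list(labs),
            source = "a")
  ren <- c(A = "zz9", B = "k", C = "m")
  s2 <- new("FunctionalStandard", genes = genes,
            labels = as.list(unname(ren[labs])), source = "b")
  r1 <- functionPredictionCV(emb, s1, folds = 3L, nTrees = 50L, seed = 2L)
  r2 <- functionPredictionCV(emb, s2, folds = 3L, nTrees = 50L, seed = 2L)
  expect_equal(r1$meanMacroF1, r2$meanMacroF1, tolerance = 1e-12)
})

test_that("one-vs-rest macro AUC hits its closed-form extremes", {
  set.seed(43)
  n <- 150
  y <- factor(sample(c(-1, 0, 1), n, replace = TRUE), levels = c(-1, 0, 1))
  # perfectly separable features
  Xsep <- model.matrix(~ 0 + y)
  res <- rfMacroAUC(Xsep, y, folds = 5L, nTrees = 60L, seed = 3L)
  expect_gte(res$macroAUC, 0.99)
  # uninformative (constant) features: every AUC near 1/2
  Xflat <- matrix(1, n, 3)
  res2 <- rfMacroAUC(Xflat, y, folds = 5L, nTrees = 60L, seed = 3L)
  expect_lt(abs(res2$macroAUC - 0.5), 0.1)
  # an absent class is reported NA and excluded from the macro mean
  y2 <- factor(sample(c(0, 1), n, replace = TRUE), levels = c(-1, 0, 1))
  expect_warning(res3 <- rfMacroAUC(matrix(rnorm(n * 2), n), y2,
                                    folds = 3L, nTrees = 40L, seed = 3L),
                 "absent")
  expect_true(is.na(res3$perClassAUC[["-1"]]))
  expect_false(is.na(res3$macroAUC))
})

test_that("path synthesis labels endpoints and matches exhaustive enumeration", {
  # single edge, effect 'up' at the endpoint
  e <- data.frame(from = "a", to = "b", weight = 1)
  nw <- walkNetwork(e, buildVocabulary(list(e)))
  ps <- suppressMessages(pathSynthesis(nw, "a", c(b = "up"), maxLength = 2L))
  expect_equal(length(ps), 1L)
  expect_equal(ps@paths[[1]], c("a", "b"))
  expect_equal(ps@labels, 1L)

  # no effects mapping: everything labelled 0
  ps0 <- suppressMessages(pathSynthesis(nw, "a", character(0), maxLength = 2L))
  expect_true(all(ps0@labels == 0L))

  # 10-node random graph: path count equals igraph's exhaustive enumeration
  set.seed(47)
  nm <- letters[1:10]
  pr <- t(combn(10, 2))
  keep <- runif(nrow(pr)) < 0.3
  ed <- data.frame(from = nm[pr[keep, 1]], to = nm[pr[keep, 2]], weight = 1)
  vv <- buildVocabulary(list(ed))
  nw2 <- walkNetwork(ed, vv)
  g <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE,
                                     vertices = nodeNames(vv))
  for (src in nodeNames(vv)[c(1, 4)]) {
    got <- suppressMessages(
      pathSynthesis(nw2, src, maxLength = 4L, perSourceCap = 100000L))
    oracle <- igraph::all_simple_paths(g, from = src, cutoff = 4)
    expect_equal(length(got), length(oracle))
    # same set of paths, not just the same count
    key <- function(x) paste(x, collapse = ">")
    expect_setequal(vapply(got@paths, key, character(1)),
                    vapply(oracle, function(p) key(names(p)), character(1)))
  }
})

test_that("standards and labelled paths survive their text round-trips", {
  std <- new("FunctionalStandard", genes = c("g1", "g2", "g3"),
             labels = list("A", c("A", "B"), "B"), source = "x")
  f <- tempfile()
  writeFunctionalStandard(std, f)
  back <- readFunctionalStandard(f)
  expect_equal(back@genes, std@genes)
  expect_equal(lapply(back@labels, sort), lapply(std@labels, sort))

  # GMT-style reader
  g <- tempfile()
  writeLines(c("SetA\tdesc\tg1\tg2", "SetB\tdesc\tg2\tg3"), g)
  gmt <- readFunctionalStandard(g)
  expect_equal(gmt@genes, c("g1", "g2", "g3"))
  expect_equal(gmt@labels[[2]], c("SetA", "SetB"))

  lp <- new("LabeledPathSet", paths = list(c("a", "b"), c("b", "c", "a")),
            labels = c(1L, -1L))
  f2 <- tempfile()
  writeLabeledPaths(lp, f2)
  back2 <- readLabeledPaths(f2)
  expect_equal(back2@paths, lp@paths)
  expect_equal(back2@labels, lp@labels)
})
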