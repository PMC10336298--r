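#' @include AllClasses.R AllGenerics.R train.R
NULL

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected mutual information,
#' `AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`, with the expected MI
#' taken over the hypergeometric model of random partitions with fixed
#' cluster sizes (arithmetic-mean normaliser). 1 means identical
#' partitions; independent partitions score near 0.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Scalar AMI in \[-1, 1\].
#' @export
amiScore <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  N <- length(a)
  ct <- table(a, b)
  ai <- rowSums(ct)
  bj <- colSums(ct)
  # mutual information
  nz <- which(ct > 0, arr.ind = TRUE)
  nij <- ct[nz]
  mi <- sum(nij / N * log(N * nij / (ai[nz[, 1]] * bj[nz[, 2]])))
  hu <- -sum(ai / N * log(ai / N))
  hv <- -sum(bj / N * log(bj / N))
  # expected MI under the permutation (hypergeometric) model
  lf <- lfactorial(0:N)
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - N)
      hi <- min(ai[i], bj[j])
      if (hi < lo) next
      k <- lo:hi
      lp <- lf[ai[i] + 1] + lf[bj[j] + 1] + lf[N - ai[i] + 1] +
        lf[N - bj[j] + 1] - lf[N + 1] - lf[k + 1] - lf[ai[i] - k + 1] -
        lf[bj[j] - k + 1] - lf[N - ai[i] - bj[j] + k + 1]
      emi <- emi + sum(k / N * log(N * k / (ai[i] * bj[j])) * exp(lp))
    }
  }
  denom <- (hu + hv) / 2 - emi
  eps <- .Machine$double.eps
  denom <- if (denom < 0) min(denom, -eps) else max(denom, eps)
  (mi - emi) / denom
}

#' Module detection by clustering an embedding
#'
#' Hierarchically clusters the embedding under every combination of
#' distance metric, linkage and cut size in the sweep, scores each flat
#' clustering against the standard's module labels by adjusted mutual
#' information, and returns the best configuration with the full sweep
#' table. Genes carrying several module labels enter the flat comparison
#' under their first label; genes of the standard without an embedding row
#' are dropped with a message.
#'
#' @param embeddings `n x e` numeric matrix with gene row names (or a
#'   [WalkEncoder-class]).
#' @param standard A [FunctionalStandard-class] of module labels.
#' @param metrics Distance metrics, subset of `c("cosine", "euclidean")`.
#' @param linkages Linkage methods, subset of `c("average", "complete")`.
#' @param ks Cluster counts to cut at; default `2:min(50, n/4)`.
#' @return List with `bestAMI`, `best` (metric/linkage/k), and `sweep`
#'   (a `data.frame`).
#' @export
moduleDetection <- function(embeddings, standard,
                            metrics = c("cosine", "euclidean"),
                            linkages = c("average", "complete"),
                            ks = NULL) {
  if (is(embeddings, "WalkEncoder")) embeddings <- nodeEmbeddings(embeddings)
  common <- intersect(standard@genes, rownames(embeddings))
  dropped <- setdiff(standard@genes, common)
  if (length(dropped))
    message(length(dropped), " standard gene(s) without embedding dropped")
  if (length(common) < 2) stop("fewer than 2 genes shared with the standard")
  lab <- vapply(standard@labels[match(common, standard@genes)], `[`,
                character(1), 1L)
  multi <- sum(lengths(standard@labels[match(common, standard@genes)]) > 1)
  if (multi > 0)
    message(multi, " gene(s) with multiple module labels: first label used")
  X <- embeddings[common, , drop = FALSE]
  if (is.null(ks)) ks <- 2:max(2, min(50, floor(nrow(X) / 4)))
  rows <- list()
  best <- list(ami = -Inf)
  for (metric in metrics) {
    D <- if (metric == "cosine") cosineDist(X) else stats::dist(X)
    for (linkage in linkages) {
      hc <- stats::hclust(D, method = linkage)
      cuts <- stats::cutree(hc, k = ks)
      for (ki in seq_along(ks)) {
        ami <- amiScore(cuts[, ki], lab)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, linkage = linkage, k = ks[ki], ami = ami)
        if (ami > best$ami)
          best <- list(ami = ami, metric = metric, linkage = linkage,
                       k = ks[ki])
      }
    }
  }
  sweep <- do.call(rbind, rows)
  list(bestAMI = best$ami,
       best = best[c("metric", "linkage", "k")],
       sweep = sweep)
}

# greedy iterative stratification for multi-label folds (rarest label
# first; samples assigned to the fold with the largest remaining demand
# for that label)
iterativeStratification <- function(Y, folds) {
  n <- nrow(Y)
  fold <- rep(NA_integer_, n)
  demand <- matrix(colSums(Y) / folds, folds, ncol(Y), byrow = TRUE)
  capacity <- rep(n / folds, folds)
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    counts <- colSums(Y[remaining, , drop = FALSE])
    active <- which(counts > 0)
    if (length(active) == 0) {
      for (i in which(remaining)) {
        f <- which.max(capacity)
        fold[i] <- f
        capacity[f] <- capacity[f] - 1
      }
      break
    }
    l <- active[which.min(counts[active])]
    for (i in which(remaining & Y[, l] == 1)) {
      cand <- which(demand[, l] == max(demand[, l]))
      if (length(cand) > 1) cand <- cand[which.max(capacity[cand])]
      f <- cand[1]
      fold[i] <- f
      demand[f, Y[i, ] == 1] <- demand[f, Y[i, ] == 1] - 1
      capacity[f] <- capacity[f] - 1
      remaining[i] <- FALSE
    }
  }
  fold
}

f1Binary <- function(truth, pred) {
  tp <- sum(truth & pred)
  denom <- 2 * tp + sum(!truth & pred) + sum(truth & !pred)
  if (denom == 0) 0 else 2 * tp / denom
}

#' Multi-label gene-function prediction under cross-validation
#'
#' Labels rarer than `minLabelFreq` (fraction of scored genes) are
#' filtered out to allow proper stratification; the remaining multi-label
#' problem is split by seeded iterative stratification into `folds` folds,
#' a random forest is trained per label on the embedding features of each
#' training fold, and performance is the macro F1 (unweighted mean of
#' per-label F1) on each test fold.
#'
#' @param embeddings Gene-named feature matrix (or [WalkEncoder-class]).
#' @param standard A [FunctionalStandard-class].
#' @param folds Number of CV folds (default 5).
#' @param minLabelFreq Minimum label frequency (default 0.10).
#' @param nTrees Random-forest size (default 500).
#' @param seed Integer seed for the fold split and the forests.
#' @return List with `perFold` (numeric vector) and `meanMacroF1`.
#' @export
functionPredictionCV <- function(embeddings, standard, folds = 5L,
                                 minLabelFreq = 0.10, nTrees = 500L,
                                 seed = 1L) {
  if (is(embeddings, "WalkEncoder")) embeddings <- nodeEmbeddings(embeddings)
  stopifnot(folds >= 2)
  common <- intersect(standard@genes, rownames(embeddings))
  dropped <- setdiff(standard@genes, common)
  if (length(dropped))
    message(length(dropped), " standard gene(s) without embedding dropped")
  labs <- standard@labels[match(common, standard@genes)]
  allLabs <- sort(unique(unlist(labs)), method = "radix")
  Y <- vapply(allLabs, function(l)
    as.integer(vapply(labs, function(x) l %in% x, logical(1))),
    integer(length(common)))
  Y <- matrix(Y, nrow = length(common),
              dimnames = list(common, allLabs))
  keep <- colMeans(Y) >= minLabelFreq
  if (!any(keep))
    stop("all labels fall below the frequency threshold ", minLabelFreq)
  Y <- Y[, keep, drop = FALSE]
  # canonical, name-independent column order so that renaming the label set
  # cannot change the fold split or the RNG stream feeding the forests
  canon <- order(colSums(Y), apply(Y, 2, paste, collapse = ""))
  Y <- Y[, canon, drop = FALSE]
  X <- embeddings[common, , drop = FALSE]
  withSeed(seed, {
    ord <- sample.int(nrow(Y))  # shuffle before the greedy assignment
    fold <- integer(nrow(Y))
    fold[ord] <- iterativeStratification(Y[ord, , drop = FALSE], folds)
    perFold <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      te <- !tr
      f1s <- vapply(colnames(Y), function(l) {
        ytr <- factor(Y[tr, l], levels = c(0, 1))
        if (length(unique(ytr)) < 2) {
          pred <- rep(levels(ytr)[which.max(table(ytr))], sum(te))
        } else {
          rf <- randomForest::randomForest(
            x = X[tr, , drop = FALSE], y = ytr, ntree = nTrees)
          pred <- as.character(predict(rf, X[te, , drop = FALSE]))
        }
        f1Binary(Y[te, l] == 1, pred == "1")
      }, numeric(1))
      mean(f1s)
    }, numeric(1))
  })
  list(perFold = perFold, meanMacroF1 = mean(perFold),
       labels = colnames(Y))
}

# class-stratified fold assignment for single-label problems
stratifiedFolds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Pathway-level classification from sequence embeddings
#'
#' Embeds every labelled path through the trained encoder's `[CLS]`
#' aggregator, trains a random-forest classifier of the path label
#' (-1/0/1) under stratified cross-validation, and reports one-vs-rest ROC
#' AUCs per class plus their unweighted (macro) mean, computed on the
#' pooled out-of-fold class probabilities. The "layman" baseline --
#' per-node embeddings averaged along the path -- is evaluated under the
#' identical protocol for comparison. Classes absent from the data are
#' reported as `NA` with a warning and excluded from the macro mean.
#'
#' @param paths A [LabeledPathSet-class].
#' @param encoder A trained [WalkEncoder-class].
#' @param folds Number of CV folds (default 5).
#' @param nTrees Random-forest size (default 500).
#' @param seed Integer seed.
#' @param baseline Also run the averaged-node-feature baseline
#'   (default `TRUE`).
#' @return List with elements `cls` and (optionally) `layman`, each holding
#'   `perClassAUC`, `macroAUC` and `roc` (the [pROC::roc] objects).
#' @export
pathwayClassification <- function(paths, encoder, folds = 5L, nTrees = 500L,
                                  seed = 1L, baseline = TRUE) {
  stopifnot(is(paths, "LabeledPathSet"), folds >= 2)
  y <- factor(paths@labels, levels = c(-1L, 0L, 1L))
  featCls <- sequenceEmbeddings(encoder, paths)
  emb <- nodeEmbeddings(encoder)
  featLay <- t(vapply(paths@paths, function(p)
    colMeans(emb[p, , drop = FALSE]), numeric(ncol(emb))))
  out <- list(cls = rfMacroAUC(featCls, y, folds, nTrees, seed))
  if (baseline) out$layman <- rfMacroAUC(featLay, y, folds, nTrees, seed)
  out
}

#' Macro one-vs-rest ROC AUC of a random forest under cross-validation
#'
#' The classification protocol behind [pathwayClassification()], usable
#' with any feature matrix: a multi-class random forest is trained under
#' seeded class-stratified `folds`-fold cross-validation, class
#' probabilities are pooled out-of-fold, and each class contributes a
#' one-vs-rest ROC AUC; the macro AUC is their unweighted mean. Classes
#' absent from the data yield `NA` with a warning and are excluded from
#' the macro mean.
#'
#' @param X Numeric feature matrix, one row per observation.
#' @param y Factor of class labels (all intended levels set).
#' @param folds,nTrees,seed Protocol parameters.
#' @return List with `perClassAUC`, `macroAUC` and `roc` (per-class
#'   [pROC::roc] objects on the pooled out-of-fold probabilities).
#' @export
rfMacroAUC <- function(X, y, folds = 5L, nTrees = 500L, seed = 1L) {
  stopifnot(is.factor(y), nrow(X) == length(y))
  prob <- matrix(NA_real_, length(y), nlevels(y),
                 dimnames = list(NULL, levels(y)))
  withSeed(seed, {
    fold <- stratifiedFolds(as.integer(y), folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]
      varying <- apply(Xtr, 2, function(cc) any(cc != cc[1]))
      ytr <- droplevels(y[tr])
      if (!any(varying) || nlevels(ytr) < 2) {
        # nothing to split on: fall back to the training-fold class priors
        pri <- table(ytr) / sum(tr)
        prob[!tr, names(pri)] <- matrix(pri, sum(!tr), length(pri),
                                        byrow = TRUE)
      } else {
        rf <- randomForest::randomForest(x = Xtr[, varying, drop = FALSE],
                                         y = ytr, ntree = nTrees)
        p <- predict(rf, X[!tr, varying, drop = FALSE], type = "prob")
        prob[!tr, colnames(p)] <- p
      }
    }
  })
  prob[is.na(prob)] <- 0
  rocs <- lapply(levels(y), function(cl) {
    pos <- y == cl
    if (!any(pos) || all(pos)) return(NULL)
    pROC::roc(response = as.integer(pos), predictor = prob[, cl],
              levels = c(0, 1), direction = "<", quiet = TRUE)
  })
  names(rocs) <- levels(y)
  aucs <- vapply(rocs, function(r)
    if (is.null(r)) NA_real_ else as.numeric(pROC::auc(r)), numeric(1))
  if (anyNA(aucs))
    warning("class(es) absent from the data: AUC undefined, macro over the rest")
  list(perClassAUC = aucs, macroAUC = mean(aucs, na.rm = TRUE), roc = rocs)
}

#' Enumerate labelled source-to-effect paths in a network
#'
#' Enumerates simple paths (bounded depth-first, capped per source) of 1 to
#' `maxLength` edges from each source node. A path ending at gene `g` is
#' labelled `+1` when `effects[g] == "up"`, `-1` when `"down"`, and `0`
#' otherwise.
#'
#' @param network A [WalkNetwork-class].
#' @param sources Character vector of source gene names.
#' @param effects Named character vector mapping genes to `"up"`/`"down"`
#'   (may be empty).
#' @param maxLength Maximum path length in edges (default 4).
#' @param perSourceCap Maximum paths per source (default 1000).
#' @return A [LabeledPathSet-class]; per-class counts are reported via
#'   `message()`.
#' @export
pathSynthesis <- function(network, sources, effects = character(0),
                          maxLength = 4L, perSourceCap = 1000L) {
  vocab <- network@vocab
  nbrs <- transitionTable(network)
  srcIds <- match(sources, vocab@nodes)
  if (anyNA(srcIds)) stop("unknown source gene(s)")
  pathsOut <- list()
  for (s in srcIds) {
    if (is.null(nbrs[[s]])) next
    count <- 0L
    # iterative DFS over simple paths
    stack <- list(list(path = s, onpath = s))
    while (length(stack) && count < perSourceCap) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (length(fr$path) > 1) {
        pathsOut[[length(pathsOut) + 1L]] <- fr$path
        count <- count + 1L
      }
      if (length(fr$path) <= maxLength) {
        last <- fr$path[length(fr$path)]
        t <- nbrs[[last]]
        if (!is.null(t)) {
          nxt <- setdiff(t$nbr, fr$onpath)
          for (v in rev(nxt))
            stack[[length(stack) + 1L]] <-
              list(path = c(fr$path, v), onpath = c(fr$onpath, v))
        }
      }
    }
  }
  labs <- vapply(pathsOut, function(p) {
    g <- vocab@nodes[p[length(p)]]
    eff <- effects[g]
    if (!is.na(eff) && eff == "up") 1L
    else if (!is.na(eff) && eff == "down") -1L
    else 0L
  }, integer(1))
  message("paths per class: ",
          paste(names(table(factor(labs, levels = c(-1, 0, 1)))),
                table(factor(labs, levels = c(-1, 0, 1))),
                sep = "=", collapse = ", "))
  new("LabeledPathSet",
      paths = lapply(pathsOut, function(p) vocab@nodes[p]),
      labels = labs)
}

#' Read a functional standard from two-column or GMT-style text
#'
#' Two-column format: `gene TAB label`, one pair per line. GMT format
#' (detected by >= 3 tab-separated fields): `set_name TAB description TAB
#' member...`, one set per line.
#'
#' @param path Input file.
#' @param format `"auto"`, `"pairs"` or `"gmt"`.
#' @param source Provenance tag stored on the object.
#' @return A [FunctionalStandard-class].
#' @export
readFunctionalStandard <- function(path, format = c("auto", "pairs", "gmt"),
                                   source = basename(path)) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t")
  if (format == "auto")
    format <- if (all(lengths(parts) == 2)) "pairs" else "gmt"
  if (format == "pairs") {
    gene <- vapply(parts, `[`, character(1), 1L)
    lab <- vapply(parts, `[`, character(1), 2L)
  } else {
    gene <- unlist(lapply(parts, function(p) p[-(1:2)]))
    lab <- unlist(lapply(parts, function(p) rep(p[1], length(p) - 2L)))
  }
  genes <- sort(unique(gene), method = "radix")
  labels <- lapply(genes, function(g) unique(lab[gene == g]))
  new("FunctionalStandard", genes = genes, labels = labels, source = source)
}

#' Write a functional standard as two-column text
#' @param standard A [FunctionalStandard-class].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeFunctionalStandard <- function(standard, path) {
  gene <- rep(standard@genes, lengths(standard@labels))
  lab <- unlist(standard@labels)
  writeLines(paste(gene, lab, sep = "\t"), path)
  invisible(path)
}

#' Read labelled paths: one path per line, names TAB label
#' @param path Input file (`gene gene ... TAB label`, label in -1/0/1).
#' @return A [LabeledPathSet-class].
#' @export
readLabeledPaths <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 2)) stop("each line must be 'path TAB label'")
  p <- lapply(parts, function(x) strsplit(trimws(x[1]), "[ ]+")[[1]])
  l <- as.integer(vapply(parts, `[`, character(1), 2L))
  new("LabeledPathSet", paths = p, labels = l)
}

#' Write labelled paths in the format read by [readLabeledPaths()]
#' @param paths A [LabeledPathSet-class].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeLabeledPaths <- function(paths, path) {
  writeLines(vapply(seq_along(paths@paths), function(i)
    paste0(paste(paths@paths[[i]], collapse = " "), "\t", paths@labels[i]),
    character(1)), path)
  invisible(path)
}

#' @describeIn LabeledPathSet-class Number of paths.
#' @param x A `LabeledPathSet`.
#' @export
setMethod("length", "LabeledPathSet", function(x) length(x@paths))

setMethod("show", "LabeledPathSet", function(object) {
  tb <- table(factor(object@labels, levels = c(-1, 0, 1)))
  cat("LabeledPathSet:", length(object@paths), "paths (",
      paste(names(tb), tb, sep = ":", collapse = ", "), ")\n")
})

setMethod("show", "FunctionalStandard", function(object) {
  cat("FunctionalStandard '", object@source, "': ", length(object@genes),
      " genes, ", length(unique(unlist(object@labels))), " labels\n",
      sep = "")
})
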