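#' @include AllClasses.R AllGenerics.R encoder-ops.R walks.R
#' @useDynLib graphMLM, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a transformer configuration
#'
#' Defaults follow small-transformer practice: 4 blocks, 4 heads,
#' feed-forward hidden width 4x the model width, dropout 0.1, Adam with
#' learning rate 1e-3, batch 64, mask rate 20%, embedding size 128,
#' restart probability 0.5, positional encodings concatenated to the token
#' embeddings (model width `2e`).
#'
#' @param e Embedding dimension.
#' @param nBlocks,nHeads Encoder depth and heads.
#' @param ffnHidden Feed-forward hidden width; `NULL` means 4x model width.
#' @param maskRate Masked fraction per sentence, in (0, 1).
#' @param alpha Propagation restart probability in \[0, 1\].
#' @param peMode `"concat"` or `"add"`.
#' @param batchSize,epochs,learningRate,dropout,seed Training parameters.
#' @return A [TransformerConfig-class].
#' @export
transformerConfig <- function(e = 128L, nBlocks = 4L, nHeads = 4L,
                              ffnHidden = NULL, maskRate = 0.20,
                              alpha = 0.5, peMode = c("concat", "add"),
                              batchSize = 64L, epochs = 100L,
                              learningRate = 1e-3, dropout = 0.1,
                              seed = 1L) {
  peMode <- match.arg(peMode)
  d <- if (peMode == "concat") 2L * as.integer(e) else as.integer(e)
  if (is.null(ffnHidden)) ffnHidden <- 4L * d
  new("TransformerConfig", e = as.integer(e), nBlocks = as.integer(nBlocks),
      nHeads = as.integer(nHeads), ffnHidden = as.integer(ffnHidden),
      maskRate = maskRate, alpha = alpha, peMode = peMode,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      learningRate = learningRate, dropout = dropout,
      seed = as.integer(seed))
}

#' Read a transformer configuration from a YAML file
#'
#' Keys mirror the arguments of [transformerConfig()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return A [TransformerConfig-class].
#' @export
readTransformerConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(transformerConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(transformerConfig, vals)
}

modelWidth <- function(config) {
  if (config@peMode == "concat") 2L * config@e else config@e
}

# engine-facing config list
cfgList <- function(config, n) {
  list(e = config@e, heads = config@nHeads,
       concat = config@peMode == "concat", dropout = config@dropout,
       M = as.integer(n))
}

# Xavier-uniform for the transformer layers; the embedding table and the
# decoder are initialised uniformly in +-1/sqrt(e)
initModel <- function(config, n) {
  e <- config@e
  d <- modelWidth(config)
  f <- config@ffnHidden
  xav <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  withSeed(config@seed, {
    lim <- 1 / sqrt(e)
    X <- matrix(stats::runif((n + 3L) * e, -lim, lim), n + 3L, e)
    blocks <- lapply(seq_len(config@nBlocks), function(i)
      list(Wq = xav(d, d), Wk = xav(d, d), Wv = xav(d, d),
           W1 = xav(d, f), b1 = rep(0, f), W2 = xav(f, d), b2 = rep(0, d)))
    Wd <- matrix(stats::runif(d * n, -lim, lim), d, n)
    list(X = X, blocks = blocks, Wd = Wd, bd = rep(0, n))
  })
}

#' Train the masked-walk encoder on a network collection
#'
#' Per epoch: (1) the embedding table is propagated over one input network
#' (round-robin in collection order) by a single random-walk-with-restart
#' step `X' = (1 - alpha) W X + alpha X`; (2) the corpus is shuffled and
#' batched; (3) per batch, 20% (by default) of the non-`[CLS]`/`[PAD]`
#' tokens are hidden behind `[MASK]` and the encoder plus a linear decoder
#' predict their identities under cross-entropy; all weights and the
#' embedding table are updated by Adam. The exported node embedding is the
#' table state after the final epoch, which includes that epoch's
#' propagation.
#'
#' @param collection A [NetworkCollection-class].
#' @param corpus A [WalkCorpus-class] over the same vocabulary.
#' @param config A [TransformerConfig-class].
#' @param propagate Set `FALSE` to disable the per-epoch propagation (the
#'   ablation arm); training is otherwise identical.
#' @param verbose Print the per-epoch loss.
#' @return A [WalkEncoder-class].
#' @export
trainEncoder <- function(collection, corpus, config = transformerConfig(),
                         propagate = TRUE, verbose = FALSE) {
  stopifnot(is(collection, "NetworkCollection"), is(corpus, "WalkCorpus"))
  if (!identical(corpus@vocab@nodes, collection@vocab@nodes))
    stop("corpus and collection vocabularies differ")
  if (length(corpus) == 0) stop("corpus is empty")
  validObject(config)
  n <- length(collection@vocab@nodes)
  tokens <- corpusTokenMatrix(corpus)
  model <- initModel(config, n)
  PE <- positionalEncoding(0:(ncol(tokens) - 1L), config@e)
  WList <- lapply(collection@networks, function(nw) nw@W)
  presList <- lapply(collection@networks,
                     function(nw) which(presentNodes(nw)) - 1L)
  fit <- .cppTrain(tokens, unname(WList), unname(presList), model,
                   cfgList(config, n), PE, config@epochs, config@batchSize,
                   config@maskRate, config@alpha, config@learningRate,
                   propagate, TRUE, config@seed)
  if (verbose && length(fit$lossTrace))
    message("epoch losses: ", paste(signif(fit$lossTrace, 4), collapse = " "))
  m <- fit$model
  emb <- m$X
  rownames(emb) <- c(collection@vocab@nodes, "[CLS]", "[MASK]", "[PAD]")
  new("WalkEncoder", config = config, vocab = collection@vocab,
      embedding = emb, blocks = m$blocks,
      decoder = list(Wd = m$Wd, bd = m$bd),
      lossTrace = as.numeric(fit$lossTrace),
      networkNames = vapply(collection@networks, function(x) x@name,
                            character(1)))
}

#' @rdname nodeEmbeddings
#' @export
setMethod("nodeEmbeddings", "WalkEncoder", function(x) {
  n <- length(x@vocab@nodes)
  x@embedding[seq_len(n), , drop = FALSE]
})

#' @rdname lossTrace
#' @export
setMethod("lossTrace", "WalkEncoder", function(x) x@lossTrace)

setMethod("show", "WalkEncoder", function(object) {
  cat("WalkEncoder: ", length(object@vocab@nodes), " nodes, e=",
      object@config@e, ", ", object@config@nBlocks, " blocks, ",
      length(object@lossTrace), " epochs trained", sep = "")
  if (length(object@lossTrace))
    cat(", final loss ", signif(utils::tail(object@lossTrace, 1), 4), sep = "")
  cat("\n")
})

#' Sequence ([CLS]) embeddings of node paths
#'
#' Runs the trained encoder without masking and returns the final hidden
#' state at position 0 (the `[CLS]` aggregator) for each path. The output
#' width is the model width (`2e` under `peMode = "concat"`, `e` under
#' `"add"`).
#'
#' @param encoder A trained [WalkEncoder-class].
#' @param paths List of character vectors of node names (or a
#'   [LabeledPathSet-class]), or a single character vector.
#' @return `length(paths) x d` numeric matrix.
#' @export
sequenceEmbeddings <- function(encoder, paths) {
  if (is(paths, "LabeledPathSet")) paths <- paths@paths
  if (is.character(paths)) paths <- list(paths)
  vocab <- encoder@vocab
  ids <- lapply(paths, function(p) {
    m <- match(p, vocab@nodes)
    if (anyNA(m)) stop("unknown node in path: ", paste(p[is.na(m)], collapse = ", "))
    m
  })
  sp <- specialIds(vocab)
  L <- max(lengths(ids)) + 1L
  tok <- matrix(sp[["pad"]], length(ids), L)
  tok[, 1] <- sp[["cls"]]
  for (i in seq_along(ids)) tok[i, 1L + seq_along(ids[[i]])] <- ids[[i]]
  cfg <- cfgList(encoder@config, length(vocab@nodes))
  PE <- positionalEncoding(0:(L - 1L), encoder@config@e)
  model <- list(X = unname(encoder@embedding), blocks = encoder@blocks,
                Wd = encoder@decoder$Wd, bd = encoder@decoder$bd)
  out <- .cppForward(model, cfg, tok - 1L, PE, FALSE)
  H <- out$H
  # row b*L + 1 is position 0 of sequence b
  cls <- H[(seq_along(ids) - 1L) * L + 1L, , drop = FALSE]
  rownames(cls) <- names(paths)
  cls
}

#' Write node embeddings as tab-separated text
#'
#' First column the node name, then `e` float columns.
#'
#' @param encoder A [WalkEncoder-class] (or a named embedding matrix).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeEmbeddings <- function(encoder, path) {
  emb <- if (is(encoder, "WalkEncoder")) nodeEmbeddings(encoder) else encoder
  df <- data.frame(node = rownames(emb), emb, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an embedding matrix written by [writeEmbeddings()]
#' @param path Tab-separated embeddings file.
#' @return Numeric matrix with node-name row names.
#' @export
readEmbeddings <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- NULL
  m
}
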