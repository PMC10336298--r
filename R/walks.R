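#' @include AllClasses.R AllGenerics.R network-io.R
NULL

# adjacency list for sampling: per node, neighbour ids and the cumulative
# probability table used for inverse-CDF draws
transitionTable <- function(network) {
  s <- Matrix::summary(methods::as(network@A, "TsparseMatrix"))
  ord <- order(s$i, s$j)
  i <- s$i[ord]; j <- s$j[ord]; x <- s$x[ord]
  nbr <- split(j, i)
  wts <- split(x, i)
  n <- length(network@vocab@nodes)
  tab <- vector("list", n)
  for (k in seq_along(nbr)) {
    node <- as.integer(names(nbr)[k])
    w <- wts[[k]]
    tab[[node]] <- list(nbr = nbr[[k]], cum = cumsum(w) / sum(w))
  }
  tab
}

#' Sample one weight-biased random walk
#'
#' From the current node the walk steps to neighbour `v` with probability
#' `w(u,v) / sum_v' w(u,v')`. The walk has exactly `length` nodes counting
#' the start; it can never halt early because every visited node was
#' reached over an edge of an undirected graph. Draws come from R's global
#' RNG stream (seed with [set.seed()] for reproducibility).
#'
#' @param network A [WalkNetwork-class].
#' @param start Node name or 1-based id; must have degree > 0.
#' @param length Number of nodes in the walk (>= 1).
#' @return Integer vector of node ids.
#' @export
sampleWalk <- function(network, start, length = 10L) {
  if (is.character(start)) start <- match(start, network@vocab@nodes)
  if (is.na(start) || start < 1 || start > length(network@vocab@nodes))
    stop("unknown start node")
  if (length < 1) stop("walk length must be >= 1")
  tab <- transitionTable(network)
  if (is.null(tab[[start]])) stop("start node has degree 0 in this network")
  walk <- integer(length)
  walk[1] <- as.integer(start)
  cur <- as.integer(start)
  if (length > 1) for (s in 2:length) {
    t <- tab[[cur]]
    cur <- t$nbr[findInterval(stats::runif(1), t$cum) + 1L]
    walk[s] <- cur
  }
  walk
}

# advance many walks on one network in lockstep; starts is an integer vector
# of start ids, all with degree > 0. Returns an S x len matrix.
lockstepWalks <- function(tab, starts, len) {
  S <- length(starts)
  out <- matrix(NA_integer_, S, len)
  out[, 1] <- starts
  if (len == 1 || S == 0) return(out)
  cur <- starts
  for (s in 2:len) {
    groups <- split(seq_len(S), cur)
    nxt <- integer(S)
    for (g in seq_along(groups)) {
      node <- as.integer(names(groups)[g])
      rows <- groups[[g]]
      t <- tab[[node]]
      pick <- findInterval(stats::runif(length(rows)), t$cum) + 1L
      nxt[rows] <- t$nbr[pick]
    }
    out[, s] <- nxt
    cur <- nxt
  }
  out
}

#' Generate the random-walk sentence corpus for a network collection
#'
#' Two corpus modes are supported. `per_union_node` (default): every
#' vocabulary node contributes exactly `reps` walks, each started in a
#' network containing that node chosen uniformly at random, so the corpus
#' holds exactly `reps * n` sentences; a node isolated in every network
#' contributes `reps` singleton walks (tokenised with `[PAD]` padding).
#' `per_network`: every node with degree > 0 in network `t` contributes
#' `reps` walks from that network, giving `reps * sum_t n_t` sentences.
#' Walks are shuffled before batching; the whole procedure is a
#' deterministic function of `seed`.
#'
#' @param collection A [NetworkCollection-class].
#' @param reps Walks per node (default 10).
#' @param length Nodes per walk (default 10).
#' @param corpusMode `"per_union_node"` or `"per_network"`.
#' @param seed Integer seed.
#' @return A [WalkCorpus-class].
#' @export
generateCorpus <- function(collection, reps = 10L, length = 10L,
                           corpusMode = c("per_union_node", "per_network"),
                           seed = 1L) {
  corpusMode <- match.arg(corpusMode)
  stopifnot(reps >= 1, length >= 1)
  vocab <- collection@vocab
  n <- base::length(vocab@nodes)
  T <- base::length(collection@networks)
  presence <- vapply(collection@networks, presentNodes, logical(n))
  presence <- matrix(presence, nrow = n)
  if (!any(presence)) stop("no eligible start node in any network")
  withSeed(seed, {
    tabs <- lapply(collection@networks, transitionTable)
    if (corpusMode == "per_union_node") {
      netOf <- matrix(NA_integer_, n, reps)
      for (i in seq_len(n)) {
        cand <- which(presence[i, ])
        if (base::length(cand))
          netOf[i, ] <- cand[sample.int(base::length(cand), reps, replace = TRUE)]
      }
      startNode <- rep(seq_len(n), each = reps)
      startNet <- as.integer(t(netOf))
      S <- base::length(startNode)
      walks <- matrix(NA_integer_, S, length)
      lens <- rep(length, S)
      iso <- is.na(startNet)
      walks[iso, 1] <- startNode[iso]
      lens[iso] <- 1L
      for (t in seq_len(T)) {
        rows <- which(!iso & startNet == t)
        if (base::length(rows))
          walks[rows, ] <- lockstepWalks(tabs[[t]], startNode[rows], length)
      }
      sources <- startNet
    } else {
      blocks <- list(); srcs <- integer(0)
      for (t in seq_len(T)) {
        starts <- rep(which(presence[, t]), each = reps)
        if (base::length(starts) == 0) next
        blocks[[base::length(blocks) + 1L]] <-
          lockstepWalks(tabs[[t]], starts, length)
        srcs <- c(srcs, rep(t, base::length(starts)))
      }
      if (base::length(blocks) == 0) stop("no eligible start node in any network")
      walks <- do.call(rbind, blocks)
      sources <- srcs
      lens <- rep(length, nrow(walks))
    }
    ord <- sample.int(nrow(walks))
    new("WalkCorpus", walks = walks[ord, , drop = FALSE],
        sources = as.integer(sources[ord]), lengths = as.integer(lens[ord]),
        repsPerNode = as.integer(reps), walkLength = as.integer(length),
        seed = as.integer(seed), vocab = vocab)
  })
}

#' Tokenise a walk for the encoder
#'
#' Prepends the `[CLS]` token id, assigns positions `0..L`, and initialises
#' all mask flags to `FALSE` (masking happens per batch during training).
#'
#' @param walk Integer vector of node ids (1-based, in vocabulary range).
#' @param vocab The [NodeVocabulary-class].
#' @return A [TokenizedSequence-class] of length `length(walk) + 1`.
#' @export
tokenizeSequence <- function(walk, vocab) {
  if (length(walk) == 0) stop("cannot tokenise an empty walk")
  n <- length(vocab@nodes)
  if (any(is.na(walk)) || any(walk < 1) || any(walk > n))
    stop("walk node id out of vocabulary range")
  sp <- specialIds(vocab)
  ids <- as.integer(c(sp["cls"], walk))
  L <- length(ids)
  new("TokenizedSequence", tokenIds = ids, positions = 0:(L - 1L),
      maskFlags = rep(FALSE, L), originalIds = ids)
}

# corpus -> 0-based token matrix for the C++ engine: [CLS] first, walk ids,
# [PAD] beyond the realised length
corpusTokenMatrix <- function(corpus) {
  sp <- specialIds(corpus@vocab)
  m <- corpus@walks
  m[is.na(m)] <- sp["pad"]
  cbind(rep(sp[["cls"]], nrow(m)), m) - 1L
}

#' Write a corpus as a plain-text sentences file
#'
#' One walk per line: space-separated node names followed by a
#' `#source=<index>` comment.
#'
#' @param corpus A [WalkCorpus-class].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeCorpus <- function(corpus, path) {
  nm <- corpus@vocab@nodes
  lines <- vapply(seq_len(nrow(corpus@walks)), function(i) {
    ids <- corpus@walks[i, seq_len(corpus@lengths[i])]
    src <- corpus@sources[i]
    paste0(paste(nm[ids], collapse = " "), " #source=",
           ifelse(is.na(src), "NA", src))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sentences file written by [writeCorpus()]
#'
#' @param path Sentences file.
#' @param vocab The [NodeVocabulary-class] naming the nodes.
#' @return A [WalkCorpus-class] (generation parameters are set to `NA`).
#' @export
readCorpus <- function(path, vocab) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  src <- rep(NA_integer_, length(lines))
  hasSrc <- grepl("#source=", lines, fixed = TRUE)
  src[hasSrc] <- suppressWarnings(
    as.integer(sub(".*#source=", "", lines[hasSrc])))
  body <- trimws(sub("#.*$", "", lines))
  toks <- strsplit(body, "[ \t]+")
  lens <- lengths(toks)
  L <- max(lens)
  walks <- matrix(NA_integer_, length(toks), L)
  for (i in seq_along(toks)) {
    ids <- match(toks[[i]], vocab@nodes)
    if (anyNA(ids)) stop("unknown node name on line ", i)
    walks[i, seq_len(lens[i])] <- ids
  }
  new("WalkCorpus", walks = walks, sources = src, lengths = as.integer(lens),
      repsPerNode = NA_integer_, walkLength = as.integer(L),
      seed = NA_integer_, vocab = vocab)
}

#' @describeIn WalkCorpus-class Number of walks in the corpus.
#' @param x A `WalkCorpus`.
#' @export
setMethod("length", "WalkCorpus", function(x) nrow(x@walks))

setMethod("show", "WalkCorpus", function(object) {
  cat("WalkCorpus:", nrow(object@walks), "walks of length",
      object@walkLength, "over", length(object@vocab@nodes), "nodes\n")
})
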