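#' @include AllClasses.R AllGenerics.R network-io.R walks.R
NULL

#' Generate a multi-network collection with planted modules
#'
#' Stochastic block model over one vocabulary of `nNodes` genes split into
#' `nModules` (near-)equal planted modules. Each of the `T` networks first
#' drops a random `dropout` fraction of the nodes (those become degree-0
#' there, creating the partial overlap typical of heterogeneous network
#' collections), then draws each within-module pair as an edge with
#' probability `pIn` and each between-module pair with probability `pOut`.
#' Edge weights are constant 1 or uniform in `weightRange`. The whole
#' collection is a deterministic function of `seed`.
#'
#' @param nNodes,nModules Vocabulary size and number of planted modules.
#' @param pIn,pOut Within-/between-module edge probabilities
#'   (`0 <= pOut < pIn <= 1`).
#' @param T Number of networks.
#' @param dropout Per-network node-dropout fraction in \[0, 1).
#' @param weightRange `NULL` for unit weights, else `c(lo, hi)`.
#' @param seed Integer seed.
#' @return List with `collection` (a [NetworkCollection-class]), `standard`
#'   (a [FunctionalStandard-class] of planted module labels) and
#'   `membership` (named integer vector).
#' @export
generateSBMCollection <- function(nNodes = 200L, nModules = 5L, pIn = 0.3,
                                  pOut = 0.02, T = 3L, dropout = 0.2,
                                  weightRange = NULL, seed = 1L) {
  stopifnot(pOut >= 0, pOut < pIn, pIn <= 1, dropout >= 0, dropout < 1,
            T >= 1, nModules >= 1, nNodes >= nModules)
  genes <- sprintf("g%04d", seq_len(nNodes))
  membership <- rep(seq_len(nModules), length.out = nNodes)
  names(membership) <- genes
  vocab <- new("NodeVocabulary", nodes = genes)  # already sorted
  pairs <- utils::combn(nNodes, 2)
  same <- membership[pairs[1, ]] == membership[pairs[2, ]]
  pEdge <- ifelse(same, pIn, pOut)
  withSeed(seed, {
    nets <- lapply(seq_len(T), function(t) {
      nDrop <- floor(dropout * nNodes)
      dropped <- if (nDrop > 0) sample.int(nNodes, nDrop) else integer(0)
      alive <- !(pairs[1, ] %in% dropped | pairs[2, ] %in% dropped)
      draw <- stats::runif(ncol(pairs)) < pEdge & alive
      if (!any(draw)) stop("SBM parameters produced an empty network")
      w <- if (is.null(weightRange)) rep(1, sum(draw))
           else stats::runif(sum(draw), weightRange[1], weightRange[2])
      edges <- data.frame(from = genes[pairs[1, draw]],
                          to = genes[pairs[2, draw]],
                          weight = w, stringsAsFactors = FALSE)
      walkNetwork(edges, vocab, name = paste0("sbm", t))
    })
    collection <- newNetworkCollection(nets, vocab)
    standard <- new("FunctionalStandard", genes = genes,
                    labels = as.list(paste0("M", membership)),
                    source = "planted")
    list(collection = collection, standard = standard,
         membership = membership)
  })
}

#' Generate labelled paths whose label depends on endpoint modules
#'
#' Paths are random walks sampled across the collection (start node and
#' source network uniform over eligible pairs). The label is a
#' deterministic function of the ordered pair of endpoint modules: with
#' modules numbered `1..k`, a walk from module `c` ending in module
#' `c + 1 (mod k)` is labelled `+1`, one ending in `c - 1 (mod k)` is
#' labelled `-1`, and every other walk 0 -- so direction matters and
#' order-blind path features cannot resolve the sign. The nonzero class
#' share is steered to `targetNonzero` by resampling: for each path a
#' nonzero outcome is requested with probability `targetNonzero` and walks
#' are redrawn (up to `maxTries`) until the realised label class matches,
#' which makes the realised nonzero count Binomial(`nPaths`,
#' `targetNonzero`) up to the rare exhaustion of tries.
#'
#' @param collection A [NetworkCollection-class].
#' @param membership Named integer module vector (as returned by
#'   [generateSBMCollection()]).
#' @param nPaths Number of paths to generate.
#' @param pathLength Nodes per path (default 5, i.e. 4 edges).
#' @param targetNonzero Desired nonzero label fraction (default 0.18).
#' @param seed Integer seed.
#' @param maxTries Redraw budget per path (default 200).
#' @return A [LabeledPathSet-class].
#' @export
generateLabeledPaths <- function(collection, membership, nPaths = 1000L,
                                 pathLength = 5L, targetNonzero = 0.18,
                                 seed = 1L, maxTries = 200L) {
  k <- max(membership)
  if (k < 2) stop("need at least 2 modules to label paths")
  vocab <- collection@vocab
  n <- length(vocab@nodes)
  mem <- membership[vocab@nodes]
  presence <- vapply(collection@networks, presentNodes, logical(n))
  presence <- matrix(presence, nrow = n)
  eligible <- which(rowSums(presence) > 0)
  if (!length(eligible)) stop("no eligible start nodes")
  labelOf <- function(w) {
    sc <- mem[w[1]]; tc <- mem[w[length(w)]]
    if ((tc - sc) %% k == 1) 1L else if ((sc - tc) %% k == 1) -1L else 0L
  }
  withSeed(seed, {
    tabs <- lapply(collection@networks, transitionTable)
    drawWalk <- function() {
      s <- eligible[sample.int(length(eligible), 1L)]
      t <- which(presence[s, ])
      t <- t[sample.int(length(t), 1L)]
      w <- s
      cur <- s
      for (i in seq_len(pathLength - 1L)) {
        tt <- tabs[[t]][[cur]]
        cur <- tt$nbr[findInterval(stats::runif(1), tt$cum) + 1L]
        w <- c(w, cur)
      }
      w
    }
    paths <- vector("list", nPaths)
    labs <- integer(nPaths)
    for (i in seq_len(nPaths)) {
      wantNonzero <- stats::runif(1) < targetNonzero
      w <- drawWalk(); l <- labelOf(w)
      tries <- 1L
      while ((l != 0) != wantNonzero && tries < maxTries) {
        w <- drawWalk(); l <- labelOf(w)
        tries <- tries + 1L
      }
      paths[[i]] <- vocab@nodes[w]
      labs[i] <- l
    }
    new("LabeledPathSet", paths = paths, labels = labs)
  })
}
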