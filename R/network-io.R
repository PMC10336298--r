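#' @include AllClasses.R AllGenerics.R
NULL

#' Read a weighted edge list from a plain-text file
#'
#' Lines hold `node_a node_b [weight]` separated by whitespace or tabs;
#' lines starting with `#` (and blank lines) are ignored. Two-column lines
#' receive `defaultWeight`. Duplicate `(a,b)`/`(b,a)` pairs are collapsed
#' keeping the maximum weight, so symmetrised input files are handled
#' idempotently. Self-edges are dropped with a warning: the walk and
#' normalisation definitions assume simple graphs.
#'
#' @param path Path to the edge-list file.
#' @param defaultWeight Weight assigned to two-column lines (default 1).
#' @return A `data.frame` with columns `from`, `to`, `weight`.
#' @export
readWeightedEdgeList <- function(path, defaultWeight = 1.0) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0) stop("no edges in ", path)
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad))
    stop("malformed line ", idx[bad[1]], " in ", path,
         ": expected 2 or 3 fields, got ", nf[bad[1]])
  from <- vapply(parts, `[`, character(1), 1L)
  to <- vapply(parts, `[`, character(1), 2L)
  w <- rep(defaultWeight, length(parts))
  has3 <- nf == 3L
  if (any(has3)) {
    wv <- suppressWarnings(as.numeric(vapply(parts[has3], `[`, character(1), 3L)))
    if (anyNA(wv)) {
      badw <- idx[has3][which(is.na(wv))[1]]
      stop("malformed line ", badw, " in ", path, ": weight does not parse")
    }
    w[has3] <- wv
  }
  if (any(w < 0)) stop("negative edge weight in ", path)
  edgeFrame(from, to, w)
}

# canonicalise parsed edges: order endpoints, drop self-edges, collapse
# duplicates keeping the max weight
edgeFrame <- function(from, to, weight) {
  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    from <- from[!self]; to <- to[!self]; weight <- weight[!self]
  }
  if (length(from) == 0)
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(weight, key, max)
  ord <- sort(names(w), method = "radix")
  ab <- strsplit(ord, "\r", fixed = TRUE)
  data.frame(from = vapply(ab, `[`, character(1), 1L),
             to = vapply(ab, `[`, character(1), 2L),
             weight = as.numeric(w[ord]), stringsAsFactors = FALSE)
}

#' Build the shared vocabulary from parsed edge lists
#'
#' The vocabulary covers the union (default) or intersection of node names
#' across the lists, sorted lexicographically (C locale) so that token ids
#' are reproducible across runs and machines.
#'
#' @param edgeLists A list of edge `data.frame`s as returned by
#'   [readWeightedEdgeList()].
#' @param mode `"union"` or `"intersection"`.
#' @return A [NodeVocabulary-class].
#' @export
buildVocabulary <- function(edgeLists, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (length(edgeLists) == 0) stop("need at least one edge list")
  sets <- lapply(edgeLists, function(e) unique(c(e$from, e$to)))
  nodes <- Reduce(if (mode == "union") union else intersect, sets)
  if (length(nodes) == 0) stop("empty node ", mode)
  new("NodeVocabulary", nodes = sort(nodes, method = "radix"))
}

#' Construct a network over a shared vocabulary
#'
#' Builds the symmetric sparse adjacency `A` (zero diagonal) and the
#' normalised matrix `W = D^{-1/2} A D^{-1/2}` once, with the convention
#' that rows/columns of isolated nodes are zero. Nodes of the vocabulary
#' absent from `edges` are retained with zero rows.
#'
#' @param edges Edge `data.frame` (`from`, `to`, `weight`).
#' @param vocab The shared [NodeVocabulary-class].
#' @param name Optional network label.
#' @return A [WalkNetwork-class].
#' @export
walkNetwork <- function(edges, vocab, name = "network") {
  n <- length(vocab@nodes)
  i <- match(edges$from, vocab@nodes)
  j <- match(edges$to, vocab@nodes)
  keep <- !is.na(i) & !is.na(j)
  if (!all(keep)) {
    # intersection-mode vocabularies legitimately exclude some endpoints
    i <- i[keep]; j <- j[keep]
  }
  w <- edges$weight[keep]
  pos <- w > 0
  i <- i[pos]; j <- j[pos]; w <- w[pos]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  deg <- Matrix::rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  W <- Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
  new("WalkNetwork", vocab = vocab, A = methods::as(A, "CsparseMatrix"),
      W = methods::as(W, "CsparseMatrix"), name = name)
}

#' Read a collection of edge-list files into a NetworkCollection
#'
#' @param paths Character vector of edge-list file paths.
#' @param defaultWeight Passed to [readWeightedEdgeList()].
#' @param vocabMode `"union"` (default) or `"intersection"` of node sets.
#' @return A [NetworkCollection-class].
#' @export
readNetworkCollection <- function(paths, defaultWeight = 1.0,
                                  vocabMode = "union") {
  edgeLists <- lapply(paths, readWeightedEdgeList, defaultWeight = defaultWeight)
  vocab <- buildVocabulary(edgeLists, mode = vocabMode)
  nets <- mapply(function(e, p) walkNetwork(e, vocab, name = basename(p)),
                 edgeLists, paths, SIMPLIFY = FALSE)
  newNetworkCollection(nets, vocab)
}

#' Assemble a NetworkCollection from WalkNetwork objects
#' @param networks List of [WalkNetwork-class] sharing one vocabulary.
#' @param vocab The shared [NodeVocabulary-class].
#' @return A [NetworkCollection-class].
#' @export
newNetworkCollection <- function(networks, vocab) {
  names(networks) <- vapply(networks, function(x) x@name, character(1))
  new("NetworkCollection", networks = networks, vocab = vocab)
}

#' Write a sparse matrix as 0-based coordinate text (row, col, value)
#' @param m A sparse matrix (`A` or `W`).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeSparseTriplets <- function(m, path) {
  s <- Matrix::summary(methods::as(m, "TsparseMatrix"))
  df <- data.frame(row = s$i - 1L, col = s$j - 1L, value = s$x)
  df <- df[order(df$row, df$col), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname vocabulary
#' @export
setMethod("vocabulary", "WalkNetwork", function(x) x@vocab)
#' @rdname vocabulary
#' @export
setMethod("vocabulary", "NetworkCollection", function(x) x@vocab)
#' @rdname vocabulary
#' @export
setMethod("vocabulary", "WalkCorpus", function(x) x@vocab)
#' @rdname vocabulary
#' @export
setMethod("vocabulary", "WalkEncoder", function(x) x@vocab)

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "NodeVocabulary", function(x) x@nodes)
#' @rdname nodeNames
#' @export
setMethod("nodeNames", "WalkNetwork", function(x) x@vocab@nodes)
#' @rdname nodeNames
#' @export
setMethod("nodeNames", "NetworkCollection", function(x) x@vocab@nodes)

#' @rdname adjacency
#' @export
setMethod("adjacency", "WalkNetwork", function(x) x@A)

#' @rdname normalizedAdjacency
#' @export
setMethod("normalizedAdjacency", "WalkNetwork", function(x) x@W)

#' @rdname nodeDegrees
#' @export
setMethod("nodeDegrees", "WalkNetwork", function(x) {
  d <- Matrix::rowSums(x@A)
  names(d) <- x@vocab@nodes
  d
})

#' @rdname presentNodes
#' @export
setMethod("presentNodes", "WalkNetwork", function(x) Matrix::rowSums(x@A) > 0)

#' @describeIn NodeVocabulary-class Number of node tokens (specials excluded).
#' @param x A `NodeVocabulary`.
#' @export
setMethod("length", "NodeVocabulary", function(x) length(x@nodes))

#' @describeIn NetworkCollection-class Number of networks.
#' @param x A `NetworkCollection`.
#' @export
setMethod("length", "NetworkCollection", function(x) length(x@networks))

#' @describeIn NetworkCollection-class Extract one network.
#' @param i Index or name.
#' @export
setMethod("[[", "NetworkCollection", function(x, i) x@networks[[i]])

setMethod("show", "NodeVocabulary", function(object) {
  cat("NodeVocabulary of", length(object@nodes), "nodes (+3 special tokens)\n")
})

setMethod("show", "WalkNetwork", function(object) {
  ne <- length(object@A@x) / 2
  cat("WalkNetwork '", object@name, "': ", sum(presentNodes(object)),
      " present / ", length(object@vocab@nodes), " vocabulary nodes, ",
      format(ne, big.mark = ","), " edges\n", sep = "")
})

setMethod("show", "NetworkCollection", function(object) {
  cat("NetworkCollection of", length(object@networks), "networks over",
      length(object@vocab@nodes), "nodes\n")
  for (nw in object@networks) show(nw)
})
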