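#' @include AllClasses.R
NULL

#' Vocabulary accessor
#' @param x An object holding a [NodeVocabulary-class].
#' @return The `NodeVocabulary`.
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' Node names accessor
#' @param x A vocabulary-bearing object.
#' @return Character vector of node names in id order.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Weighted adjacency accessor
#' @param x A [WalkNetwork-class].
#' @return The sparse symmetric weight matrix `A`.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Symmetric-normalised adjacency
#'
#' Returns `W = D^{-1/2} A D^{-1/2}`, with rows and columns of degree-0
#' nodes set to zero (the `0^{-1/2} := 0` convention for isolated nodes).
#' The largest-magnitude eigenvalue of `W` is at most 1.
#'
#' @param x A [WalkNetwork-class].
#' @return Sparse `n x n` matrix.
#' @export
setGeneric("normalizedAdjacency", function(x) standardGeneric("normalizedAdjacency"))

#' Weighted node degrees
#' @param x A [WalkNetwork-class].
#' @return Numeric vector `D_ii = sum_j A_ij` over the full vocabulary.
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' Which vocabulary nodes are present (degree > 0) in a network
#' @param x A [WalkNetwork-class].
#' @return Logical vector over the vocabulary.
#' @export
setGeneric("presentNodes", function(x) standardGeneric("presentNodes"))

#' Node embeddings of a trained encoder
#'
#' The node rows of the trained embedding table (special tokens excluded),
#' ordered and named by the vocabulary.
#'
#' @param x A [WalkEncoder-class].
#' @return `n x e` numeric matrix with node-name row names.
#' @export
setGeneric("nodeEmbeddings", function(x) standardGeneric("nodeEmbeddings"))

#' Per-epoch training loss trace
#' @param x A [WalkEncoder-class].
#' @return Numeric vector, one mean masked-token cross-entropy per epoch.
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))
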