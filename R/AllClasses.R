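#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t rowSums diag colSums
NULL

#' Node vocabulary shared by a collection of networks
#'
#' An ordered set of unique node (gene) identifiers defining the integer
#' token ids used throughout the package. Node tokens occupy ids
#' `1..length(x)`; three special tokens -- `[CLS]`, `[MASK]` and `[PAD]` --
#' are placed immediately after the node ids.
#'
#' @slot nodes Character vector of unique, lexicographically sorted node
#'   names.
#' @export
setClass("NodeVocabulary", representation(nodes = "character"))

setValidity("NodeVocabulary", function(object) {
  n <- object@nodes
  if (length(n) == 0) return("vocabulary is empty")
  if (anyDuplicated(n)) return("node names must be unique")
  if (any(!nzchar(n))) return("node names must be non-empty strings")
  if (any(n %in% c("[CLS]", "[MASK]", "[PAD]")))
    return("node names collide with special tokens")
  TRUE
})

#' A single weighted undirected network over a shared vocabulary
#'
#' Stores the symmetric weighted adjacency matrix `A` over the full
#' vocabulary (nodes absent from this network simply have zero rows), plus
#' the symmetric degree-normalised matrix `W = D^{-1/2} A D^{-1/2}` used by
#' the propagation step. Rows/columns of `W` belonging to degree-0 nodes
#' are zero by convention.
#'
#' @slot vocab A [NodeVocabulary-class].
#' @slot A Sparse symmetric `n x n` weight matrix (`Matrix::dgCMatrix`).
#' @slot W Sparse symmetric normalised adjacency, same shape.
#' @slot name Character label (usually the source file name).
#' @export
setClass("WalkNetwork",
         representation(vocab = "NodeVocabulary", A = "Matrix",
                        W = "Matrix", name = "character"))

setValidity("WalkNetwork", function(object) {
  n <- length(object@vocab@nodes)
  if (!all(dim(object@A) == c(n, n))) return("A has wrong dimensions")
  if (!all(dim(object@W) == c(n, n))) return("W has wrong dimensions")
  if (length(object@A@x) && any(object@A@x < 0))
    return("edge weights must be nonnegative")
  TRUE
})

#' An ordered collection of networks sharing one vocabulary
#'
#' @slot networks List of [WalkNetwork-class] objects.
#' @slot vocab The shared [NodeVocabulary-class].
#' @export
setClass("NetworkCollection",
         representation(networks = "list", vocab = "NodeVocabulary"))

setValidity("NetworkCollection", function(object) {
  if (length(object@networks) < 1) return("collection must hold >= 1 network")
  ok <- vapply(object@networks, function(nw)
    is(nw, "WalkNetwork") && identical(nw@vocab@nodes, object@vocab@nodes),
    logical(1))
  if (!all(ok)) return("all networks must share the collection vocabulary")
  TRUE
})

#' A corpus of random-walk sentences
#'
#' Walks are stored row-wise as 1-based node ids; rows shorter than
#' `walkLength` (walks started at nodes isolated in every network) are
#' right-padded with `NA` and later tokenised as `[PAD]`.
#'
#' @slot walks Integer matrix, one walk per row.
#' @slot sources Integer vector: index of the network each walk was drawn
#'   from (`NA` for vocabulary nodes isolated everywhere).
#' @slot lengths Integer vector of realised walk lengths.
#' @slot repsPerNode,walkLength,seed Generation parameters.
#' @slot vocab The [NodeVocabulary-class] the ids refer to.
#' @export
setClass("WalkCorpus",
         representation(walks = "matrix", sources = "integer",
                        lengths = "integer", repsPerNode = "integer",
                        walkLength = "integer", seed = "integer",
                        vocab = "NodeVocabulary"))

setValidity("WalkCorpus", function(object) {
  if (nrow(object@walks) != length(object@sources)) return("sources length mismatch")
  if (nrow(object@walks) != length(object@lengths)) return("lengths length mismatch")
  TRUE
})

#' A tokenised walk ready for the encoder
#'
#' `[CLS]` is prepended at position 0 and is never masked; `maskFlags`
#' starts all-`FALSE` (masking is applied per batch during training).
#'
#' @slot tokenIds Integer token ids, `[CLS]` first.
#' @slot positions Integer positions `0..L`.
#' @slot maskFlags Logical per position.
#' @slot originalIds Pre-masking token ids.
#' @export
setClass("TokenizedSequence",
         representation(tokenIds = "integer", positions = "integer",
                        maskFlags = "logical", originalIds = "integer"))

setValidity("TokenizedSequence", function(object) {
  L <- length(object@tokenIds)
  if (L < 2) return("a tokenized sequence needs [CLS] plus >= 1 token")
  if (length(object@positions) != L || length(object@maskFlags) != L ||
      length(object@originalIds) != L) return("field lengths differ")
  if (!identical(object@positions, 0:(L - 1L))) return("positions must be 0..L")
  if (object@maskFlags[1]) return("[CLS] must never be masked")
  TRUE
})

#' Architecture and training hyperparameters
#'
#' @slot e Embedding dimension (default 128).
#' @slot nBlocks Number of encoder blocks (default 4).
#' @slot nHeads Attention heads (default 4).
#' @slot ffnHidden Feed-forward hidden width (default 4x model width).
#' @slot maskRate Fraction of maskable tokens hidden per sentence
#'   (default 0.20).
#' @slot alpha Restart probability of the per-epoch propagation
#'   (default 0.5).
#' @slot peMode `"concat"` (positional encoding appended, model width `2e`)
#'   or `"add"`.
#' @slot batchSize,epochs,learningRate,dropout,seed Training parameters.
#' @export
setClass("TransformerConfig",
         representation(e = "integer", nBlocks = "integer", nHeads = "integer",
                        ffnHidden = "integer", maskRate = "numeric",
                        alpha = "numeric", peMode = "character",
                        batchSize = "integer", epochs = "integer",
                        learningRate = "numeric", dropout = "numeric",
                        seed = "integer"))

setValidity("TransformerConfig", function(object) {
  if (object@maskRate <= 0 || object@maskRate >= 1)
    return("maskRate must lie in (0, 1)")
  if (object@alpha < 0 || object@alpha > 1) return("alpha must lie in [0, 1]")
  if (!object@peMode %in% c("concat", "add")) return("peMode must be concat or add")
  d <- if (object@peMode == "concat") 2L * object@e else object@e
  if (d %% object@nHeads != 0L)
    return("model width must be divisible by nHeads")
  if (object@epochs < 0) return("epochs must be >= 0")
  TRUE
})

#' A trained masked-walk encoder
#'
#' The fitted artifact: the node/special-token embedding table (the trained
#' `Embedding` layer, exported after the final epoch), the transformer block
#' weights, the decoder projection onto node classes, and the per-epoch mean
#' training loss.
#'
#' @slot config The [TransformerConfig-class] used.
#' @slot vocab The [NodeVocabulary-class].
#' @slot embedding `(n + 3) x e` matrix; node rows in vocabulary order,
#'   then `[CLS]`, `[MASK]`, `[PAD]`.
#' @slot blocks List of per-block weight lists (`Wq, Wk, Wv, W1, b1, W2, b2`).
#' @slot decoder List with `Wd` (`d x n`) and `bd`.
#' @slot lossTrace Numeric per-epoch mean cross-entropy per masked token.
#' @slot networkNames Names of the networks used for propagation, in
#'   round-robin order.
#' @export
setClass("WalkEncoder",
         representation(config = "TransformerConfig", vocab = "NodeVocabulary",
                        embedding = "matrix", blocks = "list",
                        decoder = "list", lossTrace = "numeric",
                        networkNames = "character"))

#' Gene-to-label functional standard
#'
#' @slot genes Character vector of gene names.
#' @slot labels List (parallel to `genes`) of character label vectors; every
#'   gene carries at least one label.
#' @slot source Character tag describing provenance (e.g. `"planted"`).
#' @export
setClass("FunctionalStandard",
         representation(genes = "character", labels = "list",
                        source = "character"))

setValidity("FunctionalStandard", function(object) {
  if (length(object@genes) != length(object@labels))
    return("genes and labels differ in length")
  if (anyDuplicated(object@genes)) return("duplicate gene entries")
  nl <- lengths(object@labels)
  if (any(nl == 0)) return("every gene needs >= 1 label")
  if (any(!nzchar(unlist(object@labels)))) return("labels must be non-empty")
  TRUE
})

#' Labelled paths for pathway-level classification
#'
#' @slot paths List of character vectors (node name sequences, length >= 2).
#' @slot labels Integer vector in `{-1, 0, 1}`.
#' @export
setClass("LabeledPathSet",
         representation(paths = "list", labels = "integer"))

setValidity("LabeledPathSet", function(object) {
  if (length(object@paths) != length(object@labels)) return("length mismatch")
  if (any(lengths(object@paths) < 2)) return("paths must have length >= 2")
  if (!all(object@labels %in% c(-1L, 0L, 1L)))
    return("labels must lie in {-1, 0, 1}")
  TRUE
})
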