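# internal helpers

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round-half-up, used for the per-sentence mask count so that the R-side
# masking operation and the C++ training loop agree on ties
roundHalfUp <- function(x) as.integer(floor(x + 0.5))

# special-token ids (1-based) for a vocabulary of n nodes
specialIds <- function(vocab) {
  n <- length(vocab@nodes)
  c(cls = n + 1L, mask = n + 2L, pad = n + 3L)
}

# cosine distance matrix (1 - cosine similarity) as a stats::dist object;
# zero-norm rows are treated as orthogonal to everything
cosineDist <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  xs <- x / nrm
  sim <- tcrossprod(xs)
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  stats::as.dist(1 - sim)
}
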