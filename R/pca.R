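#' Principal component analysis of one omics block
#'
#' Truncated SVD of the (feature-centred) block. Scores are sample-space
#' projections (samples x components), loadings are feature weights
#' (features x components, orthonormal columns). The explained-variance
#' fraction of component k is its squared singular value over the total sum
#' of squares of the block. Component signs are fixed deterministically: the
#' largest-magnitude loading entry of each component is made positive.
#'
#' @param d an [omics_dataset]; features should already be mean-centred
#'   (a warning is issued otherwise).
#' @param n_components number of components, at most `min(dim(d))`.
#' @return an object of class `component_model` with elements `scores`
#'   (samples x k, `scores %*% t(loadings)` is the best rank-k approximation
#'   of the transposed block), `loadings` (features x k),
#'   `explained_variance_fraction`, `singular_values`, `sample_ids`,
#'   `feature_ids`.
#' @export
pca <- function(d, n_components) {
  stopifnot(inherits(d, "omics_dataset"))
  k <- as.integer(n_components)
  if (k < 1L || k > min(dim(d$values))) {
    stopf("n_components = %d outside 1..min(dim) = %d", k, min(dim(d$values)))
  }
  if (max(abs(rowMeans(d$values))) > 1e-8) {
    warnf("block '%s' does not look feature-centred; PCA assumes centred input", d$name)
  }
  s <- svd(d$values, nu = k, nv = k)
  total_ss <- sum(d$values^2)
  dk <- s$d[seq_len(k)]
  loadings <- s$u
  scores <- s$v %*% diag(dk, k, k)
  # deterministic sign: largest-|loading| entry positive, per component
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- d$feature_ids
  rownames(scores) <- d$sample_ids
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = scores,
    loadings = loadings,
    explained_variance_fraction = dk^2 / total_ss,
    singular_values = dk,
    sample_ids = d$sample_ids,
    feature_ids = d$feature_ids,
    block = d$name
  ), class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf("<component_model '%s'> %d components, cumulative EV %.1f%%\n",
              x$block, ncol(x$scores), 100 * sum(x$explained_variance_fraction)))
  invisible(x)
}
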