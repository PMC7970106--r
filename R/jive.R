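#' Joint-and-individual decomposition of aligned omics blocks
#'
#' Decomposes each block as `X_i = J_i + A_i + R_i`: a joint part whose
#' sample-space structure (row space) is shared across blocks and has rank at
#' most `joint_rank`; an individual part of rank at most `individual_ranks[i]`
#' orthogonal (in sample space) to the joint structure; and a residual.
#' Estimation alternates (a) a rank-`r` truncated SVD of the stacked
#' `X_i - A_i` matrices for the joint part and (b) per-block truncated SVDs of
#' `(X_i - J_i)` projected onto the orthocomplement of the joint row space for
#' the individual parts, until the relative change in total residual sum of
#' squares falls below `tol`.
#'
#' Blocks must be sample-aligned (identical `sample_ids` in identical order)
#' and should be centred and block-scaled (see
#' [center_and_frobenius_scale()]) so that no block dominates the stacked fit.
#'
#' @param blocks list of >= 2 aligned [omics_dataset] objects.
#' @param joint_rank nonnegative joint rank `r`.
#' @param individual_ranks nonnegative integer per block.
#' @param tol convergence tolerance on the relative change of total residual
#'   sum of squares.
#' @param max_iter iteration cap; non-convergence returns the current fit with
#'   `converged = FALSE` and a warning.
#' @return an object of class `jive_model`: lists `J`, `A`, `R` of per-block
#'   matrices, `joint_rank`, `individual_ranks`, `joint_scores` (samples x r,
#'   right singular vectors of the stacked joint part scaled by singular
#'   values), `objective_trace` (residual SS per iteration, non-increasing),
#'   `converged`, `sample_ids`, `block_names`.
#' @export
jive_decompose <- function(blocks, joint_rank, individual_ranks,
                           tol = 1e-8, max_iter = 500L) {
  if (!is.list(blocks) || length(blocks) < 2L) stopf("need >= 2 blocks")
  lapply(blocks, function(b) stopifnot(inherits(b, "omics_dataset")))
  sids <- blocks[[1L]]$sample_ids
  for (b in blocks[-1L]) {
    if (!identical(b$sample_ids, sids)) {
      stopf("blocks are not sample-aligned; align explicitly before decomposing")
    }
  }
  n <- length(sids)
  m <- length(blocks)
  r <- as.integer(joint_rank)
  ri <- as.integer(individual_ranks)
  if (length(ri) != m) stopf("individual_ranks must have one entry per block")
  if (r < 0L || any(ri < 0L)) stopf("ranks must be nonnegative")
  if (r + max(ri) > n) stopf("joint_rank + max individual rank exceeds sample count")

  X <- lapply(blocks, function(b) b$values)
  p <- vapply(X, nrow, integer(1))
  J <- lapply(X, function(x) matrix(0, nrow(x), n, dimnames = dimnames(x)))
  A <- J
  Vj <- matrix(0, n, 0L)  # joint row-space basis (samples x r)
  joint_d <- numeric(0)
  joint_v <- matrix(0, n, 0L)

  obj <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iters <- if (r == 0L || all(ri == 0L)) 1L else max_iter
  for (it in seq_len(iters)) {
    # joint step: rank-r SVD of stacked (X - A)
    if (r > 0L) {
      stacked <- do.call(rbind, mapply(function(x, a) x - a, X, A, SIMPLIFY = FALSE))
      sj <- svd_trunc(stacked, r)
      Vj <- sj$v
      joint_d <- sj$d
      joint_v <- sj$v
      off <- cumsum(c(0L, p))
      for (i in seq_len(m)) {
        J[[i]] <- sj$approx[(off[i] + 1L):off[i + 1L], , drop = FALSE]
        dimnames(J[[i]]) <- dimnames(X[[i]])
      }
    }
    # individual step: per block, rank-r_i SVD orthogonal to joint row space
    for (i in seq_len(m)) {
      if (ri[i] > 0L) {
        resid <- X[[i]] - J[[i]]
        if (ncol(Vj) > 0L) resid <- resid - (resid %*% Vj) %*% t(Vj)
        A[[i]] <- svd_trunc(resid, ri[i])$approx
        dimnames(A[[i]]) <- dimnames(X[[i]])
      }
    }
    rss <- sum(vapply(seq_len(m), function(i) sum((X[[i]] - J[[i]] - A[[i]])^2), numeric(1)))
    obj <- c(obj, rss)
    if (is.finite(prev) && prev > 0 && (prev - rss) / prev < tol) {
      converged <- TRUE
      break
    }
    if (rss == 0) { converged <- TRUE; break }
    prev <- rss
  }
  if (iters == 1L) converged <- TRUE
  if (!converged) warnf("decomposition did not converge in %d iterations", max_iter)

  R <- mapply(function(x, j, a) x - j - a, X, J, A, SIMPLIFY = FALSE)
  joint_scores <- if (r > 0L) joint_v %*% diag(joint_d, r, r) else matrix(0, n, 0L)
  rownames(joint_scores) <- sids
  if (r > 0L) colnames(joint_scores) <- paste0("J", seq_len(r))
  structure(list(
    joint_rank = r, individual_ranks = ri,
    J = J, A = A, R = R,
    joint_scores = joint_scores,
    joint_basis = Vj,
    objective_trace = obj,
    converged = converged,
    sample_ids = sids,
    block_names = vapply(blocks, `[[`, character(1), "name")
  ), class = "jive_model")
}

#' @export
print.jive_model <- function(x, ...) {
  cat(sprintf("<jive_model> joint rank %d, individual ranks (%s), %s after %d iteration(s)\n",
              x$joint_rank, paste(x$individual_ranks, collapse = ","),
              if (x$converged) "converged" else "NOT converged",
              length(x$objective_trace)))
  invisible(x)
}

#' Serialize / load a fitted decomposition
#'
#' Writes each per-block `J`/`A`/`R` matrix as TSV plus a JSON manifest with
#' ranks, convergence status and the objective trace.
#'
#' @param model a [jive_decompose()] fit.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_jive_model <- function(model, dir) {
  stopifnot(inherits(model, "jive_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(model$J)) {
    nm <- model$block_names[i]
    for (part in c("J", "A", "R")) {
      mat <- model[[part]][[i]]
      df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
      utils::write.table(df, file.path(dir, sprintf("%s_%s.tsv", nm, part)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  scores <- data.frame(sample_id = model$sample_ids, model$joint_scores, check.names = FALSE)
  utils::write.table(scores, file.path(dir, "joint_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    joint_rank = model$joint_rank,
    individual_ranks = model$individual_ranks,
    block_names = model$block_names,
    converged = model$converged,
    objective_trace = model$objective_trace
  )
  jsonlite::write_json(manifest, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Principal angles between two subspaces
#'
#' Utility for scoring subspace recovery: the angles (in degrees) between the
#' column spaces of two bases.
#'
#' @param a,b matrices whose columns span the subspaces (same row count).
#' @return numeric vector of principal angles in degrees, increasing.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(a)); qb <- qr.Q(qr(b))
  s <- svd(crossprod(qa, qb))$d
  s <- pmin(pmax(s, -1), 1)
  sort(acos(s) * 180 / pi)
}
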