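#' Select joint and individual ranks by permutation testing
#'
#' Sequential permutation test on singular values, with the null built from
#' column-wise (sample) permutations applied independently within each block:
#' permutation leaves every within-block spectrum intact but destroys
#' cross-block sample coupling, so only structure genuinely shared across
#' blocks clears the threshold. For two blocks the joint statistic is the
#' singular value spectrum of the cross-block product `X1 X2^T`, in which a
#' rank-k joint structure appears as k singular values at the *product* of
#' its per-block strengths while block-specific components enter only
#' through chance sample-space alignment — far better separation than the
#' stacked-matrix spectrum, where strong block-specific components sit in
#' the null at full strength (with more than two blocks the stacked spectrum
#' is used as a fallback). Candidate k is accepted while its observed
#' singular value exceeds the `(1 - alpha)` quantile of the null's largest
#' singular value; the first failure stops the scan. Individual ranks: after
#' removing the estimated joint part, each block's residual singular values
#' are compared against the largest singular values of nulls built by
#' permuting entries independently within each feature row (destroying
#' sample-space low-rank structure while preserving per-feature
#' distributions).
#'
#' @param blocks list of >= 2 aligned, centred/scaled [omics_dataset]s.
#' @param n_perm number of permutations (>= 20; quantiles are unstable below).
#' @param alpha test level per candidate component.
#' @param seed RNG seed; the session RNG state is untouched.
#' @param max_rank cap on candidate ranks (default `min(n_samples, 20)`).
#' @return list with `joint_rank` and `individual_ranks`.
#' @export
select_model_jive <- function(blocks, n_perm = 100L, alpha = 0.05, seed = NULL,
                              max_rank = NULL) {
  if (!is.list(blocks) || length(blocks) < 2L) stopf("need >= 2 blocks (joint rank undefined for one)")
  if (n_perm < 20L) stopf("n_perm = %d too small; quantiles unstable below 20", n_perm)
  sids <- blocks[[1L]]$sample_ids
  for (b in blocks[-1L]) if (!identical(b$sample_ids, sids)) stopf("blocks are not sample-aligned")
  n <- length(sids)
  X <- lapply(blocks, function(b) b$values)
  kmax <- as.integer(max_rank %||% min(n - 1L, 20L))

  with_seed(seed, {
    stacked <- do.call(rbind, X)
    if (length(X) == 2L) {
      # X1 X2^T has the same singular values as R1 R2^T for X_i = Q_i R_i,
      # and column permutation acts on R_i alone: X[, p] = Q (R[, p])
      R1 <- qr.R(qr(X[[1L]]))
      R2 <- qr.R(qr(X[[2L]]))
      sv_obs <- svd(tcrossprod(R1, R2), nu = 0, nv = 0)$d[seq_len(kmax)]
      sv1_null <- vapply(seq_len(n_perm), function(b) {
        svd(tcrossprod(R1[, sample.int(n), drop = FALSE], R2), nu = 0, nv = 0)$d[1L]
      }, numeric(1))
    } else {
      sv_obs <- svd(stacked, nu = 0, nv = 0)$d[seq_len(kmax)]
      sv1_null <- vapply(seq_len(n_perm), function(b) {
        perm <- do.call(rbind, lapply(X, function(x) x[, sample.int(n), drop = FALSE]))
        svd(perm, nu = 0, nv = 0)$d[1L]
      }, numeric(1))
    }
    r <- sequential_rank(sv_obs, sv1_null, alpha)

    ri <- integer(length(X))
    if (r > 0L) {
      Jfit <- svd_trunc(stacked, r)
      off <- cumsum(c(0L, vapply(X, nrow, integer(1))))
      resid <- lapply(seq_along(X), function(i) {
        X[[i]] - Jfit$approx[(off[i] + 1L):off[i + 1L], , drop = FALSE]
      })
    } else {
      resid <- X
    }
    for (i in seq_along(X)) {
      ki <- min(kmax, n - r, nrow(resid[[i]]))
      if (ki == 0L) next
      sv_o <- svd(resid[[i]], nu = 0, nv = 0)$d[seq_len(ki)]
      sv1_n <- vapply(seq_len(n_perm), function(b) {
        shuffled <- t(apply(resid[[i]], 1L, sample))
        svd(shuffled, nu = 0, nv = 0)$d[1L]
      }, numeric(1))
      ri[i] <- sequential_rank(sv_o, sv1_n, alpha)
    }
  })
  list(joint_rank = r, individual_ranks = ri)
}

# accept components while observed sv exceeds the (1-alpha) quantile of the
# null's largest singular value
sequential_rank <- function(sv_obs, sv1_null, alpha) {
  q <- stats::quantile(sv1_null, probs = 1 - alpha, names = FALSE, type = 8)
  k <- 0L
  for (j in seq_along(sv_obs)) {
    if (is.na(sv_obs[j]) || sv_obs[j] <= q) break
    k <- j
  }
  k
}

#' Select shared/distinctive component counts via PCA + canonical correlation
#'
#' Cross-check for [select_model_jive()]. Each block is reduced by PCA,
#' retaining components until the cumulative explained variance reaches
#' `var_threshold` (capped at `max_components`; canonical correlations between
#' score sets whose combined dimension approaches the sample count are
#' spuriously close to 1, so the cap defaults to `n_samples %/% 4`). The
#' number of shared components is the count of canonical-correlation pairs
#' between the two per-block score sets with correlation at least
#' `corr_threshold`; distinctive counts are the per-block remainders.
#'
#' @param blocks list of exactly 2 aligned, centred [omics_dataset]s.
#' @param var_threshold cumulative explained-variance target in (0, 1].
#' @param corr_threshold canonical-correlation cutoff in (0, 1].
#' @param max_components per-block cap on retained components.
#' @return list with `joint_rank`, `individual_ranks`, `canonical_correlations`,
#'   `per_block_components`.
#' @export
select_model_pca_gca <- function(blocks, var_threshold = 0.8, corr_threshold = 0.8,
                                 max_components = NULL) {
  if (!is.list(blocks) || length(blocks) != 2L) stopf("PCA-GCA selection is defined for exactly 2 blocks")
  if (var_threshold <= 0 || var_threshold > 1) stopf("var_threshold outside (0,1]")
  if (corr_threshold <= 0 || corr_threshold > 1) stopf("corr_threshold outside (0,1]")
  sids <- blocks[[1L]]$sample_ids
  if (!identical(blocks[[2L]]$sample_ids, sids)) stopf("blocks are not sample-aligned")
  n <- length(sids)
  cap <- as.integer(max_components %||% max(2L, n %/% 4L))

  scores <- lapply(blocks, function(b) {
    s <- svd(b$values, nu = 0)
    ev <- s$d^2 / sum(s$d^2)
    k <- which(cumsum(ev) >= var_threshold)[1L]
    if (is.na(k)) k <- length(ev)
    k <- min(k, cap, n - 1L)
    s$v[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  })
  k1 <- ncol(scores[[1L]]); k2 <- ncol(scores[[2L]])
  cc <- stats::cancor(scores[[1L]], scores[[2L]])
  shared <- sum(cc$cor >= corr_threshold)
  list(joint_rank = shared,
       individual_ranks = c(k1 - shared, k2 - shared),
       canonical_correlations = cc$cor,
       per_block_components = c(k1, k2))
}
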