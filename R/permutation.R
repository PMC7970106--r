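#' Build a joint permutation plan across datasets
#'
#' Generates `B` sample permutations to be applied to the outcome (and
#' covariates) of every dataset. In `overlap` mode all datasets must share an
#' identical sample set and one permutation of those samples is applied to
#' every dataset, preserving the cross-omic sample coupling that the combined
#' null requires. In `all_samples` mode, samples shared by all datasets are
#' permuted jointly exactly as in overlap mode, while dataset-exclusive
#' samples are permuted among themselves within their own dataset — exclusive
#' samples never receive another dataset's labels, and the restriction of any
#' permutation to the shared samples is identical across datasets.
#'
#' @param sample_ids_list list of character vectors: the sample ids of each
#'   dataset, in dataset column order.
#' @param mode `"overlap"` or `"all_samples"`.
#' @param B number of permutations (>= 20; below 100 raises a granularity
#'   warning).
#' @param seed RNG seed; the plan is bit-identical across runs for a fixed
#'   seed.
#' @return an object of class `permutation_plan`: for each dataset an
#'   `n_d x B` integer matrix `perms[[d]]` where column `b` maps sample
#'   position `i` to the source position whose labels it receives.
#' @export
joint_permutations <- function(sample_ids_list, mode = c("overlap", "all_samples"),
                               B = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  B <- as.integer(B)
  if (B < 20L) stopf("B = %d is too small for a permutation test (need >= 20)", B)
  if (B < 100L) warnf("B = %d gives coarse p-value granularity (smallest p = %.3f)", B, 1 / (B + 1))
  if (!is.list(sample_ids_list) || length(sample_ids_list) < 1L) stopf("need at least one dataset")
  shared <- Reduce(intersect, sample_ids_list)
  if (mode == "overlap") {
    same <- all(vapply(sample_ids_list, function(s) setequal(s, shared), logical(1)))
    if (!same) stopf("overlap mode requires identical sample sets; use mode = 'all_samples' or align first")
  }
  if (length(shared) < 2L && mode == "overlap") stopf("fewer than 2 shared samples")

  n_shared <- length(shared)
  perms <- with_seed(seed, {
    # joint permutations of the shared samples: for each b a permutation of
    # shared positions, expressed on ids so it transfers across datasets
    shared_perm <- replicate(B, sample.int(n_shared), simplify = "array")
    lapply(sample_ids_list, function(sids) {
      n <- length(sids)
      is_sh <- sids %in% shared
      pos_sh <- which(is_sh)
      pos_ex <- which(!is_sh)
      # dataset positions of each shared id, in the canonical `shared` order
      sh_idx <- match(shared, sids)
      out <- matrix(NA_integer_, n, B)
      for (b in seq_len(B)) {
        pb <- seq_len(n)
        # shared sample at canonical slot j takes labels of shared slot shared_perm[j, b]
        pb[sh_idx] <- sh_idx[shared_perm[, b]]
        if (length(pos_ex) > 1L) pb[pos_ex] <- pos_ex[sample.int(length(pos_ex))]
        out[, b] <- pb
      }
      rownames(out) <- sids
      out
    })
  })
  structure(list(mode = mode, B = B, seed = seed,
                 sample_ids = sample_ids_list, shared = shared, perms = perms),
            class = "permutation_plan")
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat(sprintf("<permutation_plan> mode=%s, B=%d, %d dataset(s), %d shared samples\n",
              x$mode, x$B, length(x$perms), length(x$shared)))
  invisible(x)
}

#' Permutation p-values for one dataset under a joint plan
#'
#' Computes the observed statistic per feature, recomputes it under every
#' permutation of the plan (outcome and covariates permuted jointly), and
#' converts statistics to p-values two-sidedly via absolute value. The
#' observed p-value uses the add-one estimator
#' `p = (1 + #\{b: |T*_b| >= |T_obs|\}) / (B + 1)`, so p is never 0 and lies
#' in `[1/(B+1), 1]`. Each permutation additionally receives a pseudo
#' p-value by ranking its statistic within the full permutation distribution
#' with the observed statistic left in, which makes observed and permuted
#' combined statistics exchangeable under the null — the property the global
#' NPC p-value relies on.
#'
#' @param engine `"lm"`, `"lm_moderated"`, `"cox"`, or a function
#'   `f(values_matrix, design_pieces)` returning one finite statistic per
#'   feature.
#' @param d an [omics_dataset].
#' @param design an [npc_design].
#' @param plan a [joint_permutations()] plan.
#' @param dataset_index which dataset of the plan `d` corresponds to.
#' @return list with `observed_stat`, `observed_p` (features), and `pseudo_p`
#'   (features x B matrix).
#' @export
permutation_pvalues <- function(engine, d, design, plan, dataset_index = 1L) {
  stopifnot(inherits(d, "omics_dataset"), inherits(design, "npc_design"),
            inherits(plan, "permutation_plan"))
  P <- plan$perms[[dataset_index]]
  if (!identical(rownames(P), d$sample_ids)) {
    stopf("plan dataset %d does not cover block '%s' samples in order", dataset_index, d$name)
  }
  fn <- resolve_engine(engine)
  X <- d$values
  obs <- fn(X, design_pieces(design, d$sample_ids))
  B <- plan$B
  Tperm <- matrix(NA_real_, nrow(X), B, dimnames = list(rownames(X), NULL))
  n_fail <- 0L
  for (b in seq_len(B)) {
    Tperm[, b] <- tryCatch(fn(X, design_pieces(design, d$sample_ids, perm = P[, b])),
                           error = function(e) { n_fail <<- n_fail + 1L; rep(NaN, nrow(X)) })
  }
  if (n_fail > 0.1 * B) stopf("engine failed on %d of %d permutations", n_fail, B)
  pv <- pvalues_from_stats(obs, Tperm)
  list(observed_stat = obs, observed_p = pv$observed_p, pseudo_p = pv$pseudo_p)
}

#' Convert observed + permuted statistics to (pseudo) p-values
#'
#' Pure counting core of the permutation scheme, exposed for testing and for
#' custom engines: two-sided via `abs()`, add-one observed estimator,
#' leave-observed-in pseudo p-values. Non-finite statistics are treated as
#' no evidence (p = 1).
#'
#' @param observed numeric vector of observed statistics (length F).
#' @param permuted F x B matrix of permuted statistics.
#' @param two_sided take absolute values first (default).
#' @return list with `observed_p` (length F) and `pseudo_p` (F x B).
#' @export
pvalues_from_stats <- function(observed, permuted, two_sided = TRUE) {
  stopifnot(is.matrix(permuted), length(observed) == nrow(permuted))
  B <- ncol(permuted)
  S <- cbind(observed, permuted)
  if (two_sided) S <- abs(S)
  S[is.na(S)] <- -Inf  # failed fits (NaN/NA) carry no evidence; +/-Inf is evidence
  Pall <- t(apply(S, 1L, top_rank_p))
  if (nrow(permuted) == 1L) Pall <- matrix(Pall, nrow = 1L)
  list(observed_p = stats::setNames(Pall[, 1L], names(observed)),
       pseudo_p = Pall[, -1L, drop = FALSE])
}
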