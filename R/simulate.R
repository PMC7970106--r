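# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes, plus the ground truth needed to score estimators.
# All generators are pure functions of (parameters, seed): fixed seed gives
# bit-identical output, and the session RNG state is never touched.

# sample-space basis orthogonal to the constant vector (so generated feature
# rows are exactly mean-centred) and to `avoid`'s columns
orthonormal_sample_basis <- function(n, k, avoid = NULL) {
  base <- cbind(rep(1, n) / sqrt(n), avoid)
  G <- matrix(stats::rnorm(n * k), n, k)
  G <- G - base %*% crossprod(base, G)
  qr.Q(qr(G))[, seq_len(k), drop = FALSE]
}

#' Simulate paired omics blocks with shared low-rank structure
#'
#' Builds `X_i = J_i + A_i + E_i`: a joint part whose sample-space factors
#' are shared across blocks, a block-specific part with sample-space factors
#' orthogonal to the joint ones (and to each other), and i.i.d. Gaussian
#' noise scaled per block so that `||J_i + A_i||_F^2 / ||E_i||_F^2 = snr`.
#' Every signal component has equal Frobenius norm, and all sample-space
#' factors are orthogonal to the constant vector, so blocks are exactly
#' feature-centred.
#'
#' @param n_samples number of samples.
#' @param features_per_block integer vector of per-block feature counts.
#' @param joint_rank shared rank `r` (>= 0).
#' @param individual_ranks block-specific ranks.
#' @param snr signal-to-noise ratio `||signal||_F^2 / ||noise||_F^2` per
#'   block; `Inf` gives noiseless blocks.
#' @param seed RNG seed.
#' @return list with `blocks` (list of [omics_dataset]s) and `truth`
#'   (joint sample basis `V`, per-block individual bases `W`, the ranks, and
#'   the per-block signal parts `J`, `A`).
#' @export
simulate_joint_blocks <- function(n_samples = 40L, features_per_block = c(100L, 100L),
                                  joint_rank = 2L, individual_ranks = c(1L, 3L),
                                  snr = 10, seed = NULL) {
  n <- as.integer(n_samples)
  p <- as.integer(features_per_block)
  r <- as.integer(joint_rank)
  ri <- as.integer(individual_ranks)
  if (length(ri) != length(p)) stopf("individual_ranks must match features_per_block")
  if (r + max(ri) + 1L > n) stopf("ranks infeasible for %d samples", n)
  if (any(r + ri > pmin(p, n))) stopf("ranks infeasible for block dimensions")

  with_seed(seed, {
    V <- if (r > 0L) orthonormal_sample_basis(n, r) else matrix(0, n, 0L)
    sids <- sprintf("s%03d", seq_len(n))
    blocks <- vector("list", length(p))
    W <- J <- A <- vector("list", length(p))
    for (i in seq_along(p)) {
      fids <- sprintf("%s_f%04d", c("a", "b", "c", "d")[i], seq_len(p[i]))
      Ji <- matrix(0, p[i], n)
      if (r > 0L) {
        L <- matrix(stats::rnorm(p[i] * r), p[i], r)
        L <- sweep(L, 2L, sqrt(colSums(L^2)), "/")   # unit-norm components
        Ji <- L %*% t(V)
      }
      Wi <- if (ri[i] > 0L) orthonormal_sample_basis(n, ri[i], avoid = V) else matrix(0, n, 0L)
      Ai <- matrix(0, p[i], n)
      if (ri[i] > 0L) {
        M <- matrix(stats::rnorm(p[i] * ri[i]), p[i], ri[i])
        M <- sweep(M, 2L, sqrt(colSums(M^2)), "/")
        Ai <- M %*% t(Wi)
      }
      signal <- Ji + Ai
      Xi <- signal
      if (is.finite(snr)) {
        E <- matrix(stats::rnorm(p[i] * n), p[i], n)
        E <- E - rowMeans(E)
        E <- E * sqrt(sum(signal^2) / (snr * sum(E^2)))
        Xi <- signal + E
      }
      dimnames(Xi) <- list(fids, sids)
      blocks[[i]] <- omics_dataset(Xi, name = paste0("block_", letters[i]))
      W[[i]] <- Wi; J[[i]] <- Ji; A[[i]] <- Ai
    }
    list(blocks = blocks,
         truth = list(V = V, W = W, J = J, A = A,
                      joint_rank = r, individual_ranks = ri, snr = snr))
  })
}

#' Simulate a two-group design with paired differential features
#'
#' Two omics blocks on the same samples; feature `i` of block A is linked to
#' feature `i` of block B through gene `G_i` (a 1:1 mapping of all
#' features). The first `n_true_pairs` pairs carry a mean shift of
#' `effect_per_block` (in units of the noise SD) in group 2, in both blocks;
#' the per-feature noise of linked features is correlated across blocks at
#' `cross_corr`. The split-effect regime — per-block effects too weak for
#' single-omic detection but jointly informative — is the setting where
#' combining evidence across omics pays off.
#'
#' @param n_per_group samples per group (two groups).
#' @param n_features features per block (= mapped pairs).
#' @param n_true_pairs number of truly differential pairs.
#' @param effect_per_block standardised mean shift per block.
#' @param cross_corr noise correlation between linked features, in `[0, 1)`.
#' @param seed RNG seed.
#' @return list with `block_a`, `block_b` ([omics_dataset]s), `mapping`
#'   ([feature_mapping]), `meta` ([sample_metadata] with categorical
#'   `group`), and `truth` (true pair indices, genes, effect size).
#' @export
simulate_paired_differential <- function(n_per_group = 20L, n_features = 200L,
                                         n_true_pairs = 30L, effect_per_block = 0.4,
                                         cross_corr = 0.3, seed = NULL) {
  if (n_true_pairs > n_features) stopf("n_true_pairs exceeds n_features")
  if (cross_corr < 0 || cross_corr >= 1) stopf("cross_corr outside [0, 1)")
  n <- 2L * as.integer(n_per_group)
  f <- as.integer(n_features)

  with_seed(seed, {
    sids <- sprintf("s%03d", seq_len(n))
    group <- rep(c("g1", "g2"), each = n_per_group)
    Z1 <- matrix(stats::rnorm(f * n), f, n)
    Z2 <- matrix(stats::rnorm(f * n), f, n)
    Xa <- Z1
    Xb <- cross_corr * Z1 + sqrt(1 - cross_corr^2) * Z2
    idx_true <- seq_len(n_true_pairs)
    shift <- matrix(0, f, n)
    shift[idx_true, group == "g2"] <- effect_per_block
    Xa <- Xa + shift
    Xb <- Xb + shift
    fa <- sprintf("a_f%04d", seq_len(f))
    fb <- sprintf("b_f%04d", seq_len(f))
    genes <- sprintf("G%04d", seq_len(f))
    dimnames(Xa) <- list(fa, sids)
    dimnames(Xb) <- list(fb, sids)
    mapping <- feature_mapping(
      data.frame(gene = genes, feature_a = fa, feature_b = fb,
                 stringsAsFactors = FALSE),
      retain_all = TRUE
    )
    meta <- sample_metadata(sids, list(group = group),
                            types = c(group = "categorical"))
    list(block_a = omics_dataset(Xa, name = "block_a"),
         block_b = omics_dataset(Xb, name = "block_b"),
         mapping = mapping, meta = meta,
         truth = list(true_pairs = idx_true, true_genes = genes[idx_true],
                      effect = effect_per_block, cross_corr = cross_corr))
  })
}

#' Simulate an omics block with a survival outcome
#'
#' Exponential event times with hazard proportional to
#' `exp(beta * u + 0.02 * age)`, where `u` averages the `n_true` causal
#' features (scaled by `1/sqrt(n_true)` so the linear predictor keeps unit
#' variance; with `n_true = 1` the single causal feature enters with
#' coefficient exactly `beta`). Age is drawn N(58, 10), matching a typical
#' adult oncology cohort. Censoring times are uniform with the upper bound
#' calibrated on the realised event times so the achieved censoring fraction
#' matches the target to within 1/n.
#'
#' @param n_samples number of samples.
#' @param n_features features in the block.
#' @param n_true number of causal features (the first `n_true`).
#' @param beta log-hazard coefficient of the causal signal.
#' @param censoring_fraction target fraction censored, below 0.95.
#' @param seed RNG seed.
#' @return list with `block` ([omics_dataset]), `meta` ([sample_metadata]
#'   with numeric `age` and time-to-event `survival`), and `truth`
#'   (causal indices, per-feature coefficient, realised censoring fraction).
#' @export
simulate_survival_omics <- function(n_samples = 200L, n_features = 100L,
                                    n_true = 1L, beta = 1, censoring_fraction = 0.3,
                                    seed = NULL) {
  if (censoring_fraction >= 0.95) stopf("censoring_fraction >= 0.95 leaves too few events")
  if (n_true > n_features) stopf("n_true exceeds n_features")
  n <- as.integer(n_samples)
  f <- as.integer(n_features)

  with_seed(seed, {
    sids <- sprintf("s%03d", seq_len(n))
    fids <- sprintf("x_f%04d", seq_len(f))
    X <- matrix(stats::rnorm(f * n), f, n, dimnames = list(fids, sids))
    age <- stats::rnorm(n, mean = 58, sd = 10)
    u <- if (n_true > 0L) colSums(X[seq_len(n_true), , drop = FALSE]) / sqrt(n_true) else rep(0, n)
    lp <- beta * u + 0.02 * age
    haz <- 0.01 * exp(lp - mean(lp))
    etime <- stats::rexp(n, rate = haz)
    if (censoring_fraction > 0) {
      U <- stats::runif(n)
      frac <- function(cmax) mean(etime > cmax * U) - censoring_fraction
      # realised censoring is monotone decreasing in cmax; bracket then solve
      hi <- max(etime) * 2
      cmax <- tryCatch(stats::uniroot(frac, c(1e-8, hi))$root, error = function(e) hi)
      ctime <- cmax * U
      status <- as.numeric(etime <= ctime)
      time <- pmin(etime, ctime)
    } else {
      status <- rep(1, n)
      time <- etime
    }
    time <- pmax(time, 1e-8)
    meta <- sample_metadata(
      sids,
      list(age = age, survival = list(time = time, event = status)),
      types = c(age = "numeric", survival = "time_to_event")
    )
    list(block = omics_dataset(X, name = "block_surv"), meta = meta,
         truth = list(true_features = fids[seq_len(n_true)],
                      beta_per_feature = if (n_true > 0L) beta / sqrt(n_true) else 0,
                      realized_censoring = mean(status == 0)))
  })
}

#' Simulate a gene-set collection with planted cluster structure
#'
#' Gene sets fall into `n_clusters` groups; each cluster owns a disjoint
#' core gene pool, and every set draws a `within_overlap` fraction of its
#' genes from its cluster's pool and the remainder uniformly from the
#' universe. All sets carry simulated enrichment p-values below 0.05 and at
#' least `min_size` genes, so they pass the standard significance/size
#' filters.
#'
#' @param n_sets number of gene sets (split as evenly as possible across
#'   clusters).
#' @param universe_size number of genes in the universe.
#' @param n_clusters planted cluster count.
#' @param within_overlap fraction of each set drawn from its cluster pool,
#'   in `[0, 1]`.
#' @param size_range inclusive range of set sizes to draw from.
#' @param pool_size core genes per cluster pool.
#' @param seed RNG seed.
#' @return list with `collection` ([gene_set_collection]) and `truth`
#'   (planted labels, pools, universe).
#' @export
simulate_gene_set_collection <- function(n_sets = 45L, universe_size = 500L,
                                         n_clusters = 3L, within_overlap = 0.7,
                                         size_range = c(10L, 30L), pool_size = 40L,
                                         seed = NULL) {
  if (within_overlap < 0 || within_overlap > 1) stopf("within_overlap outside [0, 1]")
  if (n_clusters * pool_size > universe_size) stopf("cluster pools exceed the universe")
  min_size <- 3L

  with_seed(seed, {
    universe <- sprintf("g%05d", seq_len(universe_size))
    pools <- split(universe[seq_len(n_clusters * pool_size)],
                   rep(seq_len(n_clusters), each = pool_size))
    labels <- rep(seq_len(n_clusters), length.out = n_sets)
    sets <- lapply(seq_len(n_sets), function(i) {
      m <- max(min_size, sample(seq(size_range[1L], size_range[2L]), 1L))
      n_core <- round(within_overlap * m)
      core <- sample(pools[[labels[i]]], min(n_core, pool_size))
      filler <- if (m - length(core) > 0L) sample(universe, m - length(core)) else character(0)
      list(set_id = sprintf("S%03d", i),
           description = sprintf("planted cluster %d", labels[i]),
           genes = unique(c(core, filler)),
           p_value = stats::runif(1L, 0, 0.049),
           source_analysis = "simulated")
    })
    list(collection = gene_set_collection(sets),
         truth = list(labels = labels, pools = pools, universe = universe,
                      within_overlap = within_overlap))
  })
}
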