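# per-omic PCA, joint decomposition, model selection, associations

test_that("pca reproduces the truncated SVD and fixes signs", {
  set.seed(11)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:10)))
  X <- X - rowMeans(X)
  d <- omics_dataset(X)
  fit <- pca(d, 3)
  sv <- svd(X)
  best <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  expect_lt(max(abs(fit$loadings %*% t(fit$scores) - best)), 1e-8)
  # orthonormal loadings, non-increasing fractions, deterministic signs
  expect_equal(crossprod(fit$loadings), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(fit$explained_variance_fraction), 1 + 1e-10)
  for (j in 1:3) expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)

  # rank-1 input: first component explains everything
  u <- rnorm(15); v <- rnorm(8)
  r1 <- outer(u - mean(u) * 0, v)  # rows are multiples of v
  r1 <- r1 - rowMeans(r1)
  dimnames(r1) <- list(sprintf("f%02d", 1:15), sprintf("s%02d", 1:8))
  f1 <- pca(omics_dataset(r1), 2)
  expect_equal(f1$explained_variance_fraction[1], 1, tolerance = 1e-10)

  expect_error(pca(d, 11), "n_components")
  expect_warning(pca(omics_dataset(X + 5), 2), "centred")
})

test_that("jive_decompose satisfies its invariants and degenerate cases", {
  sim <- simulate_joint_blocks(n_samples = 30, features_per_block = c(40, 50),
                               joint_rank = 2, individual_ranks = c(1, 2),
                               snr = 5, seed = 21)
  sc <- lapply(sim$blocks, center_and_frobenius_scale)
  m <- jive_decompose(sc, 2, c(1, 2))
  expect_true(m$converged)
  # exact reconstruction identity
  for (i in 1:2) {
    expect_equal(m$J[[i]] + m$A[[i]] + m$R[[i]], sc[[i]]$values, tolerance = 1e-10)
    expect_lte(qr(m$J[[i]])$rank, 2)
    expect_lte(qr(m$A[[i]])$rank, c(1, 2)[i])
  }
  # joint-individual orthogonality on the stacked matrices
  Js <- do.call(rbind, m$J); As <- do.call(rbind, m$A)
  expect_lt(max(abs(Js %*% t(As))), 1e-6)
  # monotone objective
  expect_true(all(diff(m$objective_trace) <= 1e-12))

  # individual_ranks all 0: joint equals rank-r SVD of the stacked matrix
  m0 <- jive_decompose(sc, 2, c(0, 0))
  stacked <- rbind(sc[[1]]$values, sc[[2]]$values)
  sv <- svd(stacked)
  best <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  expect_equal(do.call(rbind, m0$J), best, tolerance = 1e-8, ignore_attr = TRUE)
  expect_length(m0$objective_trace, 1L)

  # joint rank 0: per-block PCA
  mI <- jive_decompose(sc, 0, c(1, 2))
  for (i in 1:2) {
    svi <- svd(sc[[i]]$values)
    ki <- c(1, 2)[i]
    besti <- svi$u[, 1:ki, drop = FALSE] %*% diag(svi$d[1:ki], ki, ki) %*%
      t(svi$v[, 1:ki, drop = FALSE])
    expect_equal(mI$A[[i]], besti, tolerance = 1e-8, ignore_attr = TRUE)
  }

  # misaligned blocks rejected
  b2 <- sc[[2]]
  b2$sample_ids <- rev(b2$sample_ids)
  colnames(b2$values) <- b2$sample_ids
  expect_error(jive_decompose(list(sc[[1]], b2), 1, c(0, 0)), "aligned")
})

test_that("jive recovers planted joint structure at high SNR", {
  angles <- vapply(201:205, function(seed) {
    sim <- simulate_joint_blocks(snr = 10, seed = seed)
    sc <- lapply(sim$blocks, center_and_frobenius_scale)
    m <- jive_decompose(sc, 2, c(1, 3))
    max(principal_angles(m$joint_basis, sim$truth$V))
  }, numeric(1))
  expect_true(all(angles < 5))

  # relative Frobenius error of the joint part under block scaling, at cohort
  # scale (error floor ~ 1/sqrt(n); at n = 40 the floor sits at 0.11-0.13,
  # see the methods vignette)
  sim <- simulate_joint_blocks(n_samples = 100, snr = 10, seed = 303)
  sc <- lapply(sim$blocks, center_and_frobenius_scale)
  m <- jive_decompose(sc, 2, c(1, 3))
  for (i in 1:2) {
    scale_i <- sqrt(sum(sim$blocks[[i]]$values^2))
    Jtrue <- sim$truth$J[[i]] / scale_i
    expect_lt(sqrt(sum((m$J[[i]] - Jtrue)^2) / sum(Jtrue^2)), 0.1)
  }
})

test_that("model selection recovers ranks and behaves under the null", {
  # truth (reduced seeds here; the full 20-seed sweep is in acceptance)
  ok <- vapply(1:5, function(s) {
    sim <- simulate_joint_blocks(seed = s)
    sc <- lapply(sim$blocks, center_and_frobenius_scale)
    sel <- select_model_jive(sc, n_perm = 50, seed = s + 100)
    identical(c(sel$joint_rank, sel$individual_ranks), c(2L, 1L, 3L))
  }, logical(1))
  expect_gte(mean(ok), 0.8)

  # pure noise: no joint rank
  r0 <- vapply(1:5, function(s) {
    set.seed(s + 40)
    mk <- function(p, pre) omics_dataset(matrix(rnorm(p * 30), p, 30,
      dimnames = list(paste0(pre, 1:p), sprintf("s%02d", 1:30))))
    sc <- lapply(list(mk(50, "f"), mk(60, "g")), center_and_frobenius_scale)
    select_model_jive(sc, n_perm = 50, seed = s + 7)$joint_rank
  }, integer(1))
  expect_gte(mean(r0 == 0), 0.8)

  expect_error(select_model_jive(list(toy_block()), n_perm = 50), ">= 2 blocks")
  expect_error(select_model_jive(list(toy_block(), toy_block()), n_perm = 10), "too small")
})

test_that("PCA-GCA selection counts shared components", {
  sim <- simulate_joint_blocks(seed = 7)
  sc <- lapply(sim$blocks, center_and_frobenius_scale)
  sel <- select_model_pca_gca(sc, corr_threshold = 0.8)
  expect_identical(sel$joint_rank, 2L)

  # identical blocks: everything shared
  self <- select_model_pca_gca(list(sc[[1]], sc[[1]]))
  expect_equal(self$joint_rank, self$per_block_components[1])
  expect_true(all(self$individual_ranks == 0))

  # independent blocks: nothing shared at a strict threshold
  zero <- vapply(1:5, function(s) {
    set.seed(s + 900)
    mk <- function(p, pre) omics_dataset(matrix(rnorm(p * 40), p, 40,
      dimnames = list(paste0(pre, 1:p), sprintf("s%02d", 1:40))))
    sc0 <- lapply(list(mk(50, "f"), mk(60, "g")), center_and_frobenius_scale)
    select_model_pca_gca(sc0, corr_threshold = 0.9)$joint_rank
  }, integer(1))
  expect_gte(mean(zero == 0), 0.8)

  expect_error(select_model_pca_gca(sc, var_threshold = 0), "var_threshold")
  expect_error(select_model_pca_gca(sc, corr_threshold = 1.2), "corr_threshold")
})

test_that("associate_components picks tests by type and adjusts correctly", {
  # hand-checkable Kruskal-Wallis: ranks 1..6 split into two groups of 3
  scores <- matrix(1:6, ncol = 1, dimnames = list(sprintf("s%03d", 1:6), "PC1"))
  meta <- sample_metadata(sprintf("s%03d", 1:6),
                          list(group = rep(c("g1", "g2"), each = 3)))
  tab <- associate_components(scores, meta)
  expect_equal(tab$statistic, 3.857, tolerance = 1e-3)
  expect_identical(tab$test, "kruskal_wallis")

  # monotone numeric variable: Spearman rho = 1
  meta2 <- sample_metadata(sprintf("s%03d", 1:6), list(v = c(2, 4, 7, 9, 12, 20)))
  tab2 <- associate_components(scores, meta2)
  expect_equal(tab2$statistic, 1)
  expect_identical(tab2$test, "spearman")

  # cox on survival agrees with the score test machinery, bonferroni exact
  set.seed(31)
  n <- 40
  sc3 <- matrix(rnorm(2 * n), n, 2, dimnames = list(sprintf("s%03d", 1:n), c("PC1", "PC2")))
  meta3 <- sample_metadata(sprintf("s%03d", 1:n),
                           list(group = sample(c("a", "b"), n, TRUE),
                                surv = list(time = rexp(n) + 0.1,
                                            event = rbinom(n, 1, 0.7))))
  tab3 <- associate_components(sc3, meta3, correction = "bonferroni")
  m <- sum(!is.na(tab3$p_value))
  expect_equal(tab3$p_adjusted, pmin(1, tab3$p_value * m))
  expect_true(all(tab3$p_adjusted >= tab3$p_value, na.rm = TRUE))
  expect_setequal(unique(tab3$test), c("kruskal_wallis", "cox"))

  # single-level categorical: NA row, excluded from the correction count
  meta4 <- sample_metadata(sprintf("s%03d", 1:6), list(g = rep("only", 6), v = 1:6))
  expect_warning(tab4 <- associate_components(scores, meta4), "single level")
  expect_true(is.na(tab4$p_value[tab4$variable == "g"]))
  expect_equal(tab4$p_adjusted[tab4$variable == "v"],
               tab4$p_value[tab4$variable == "v"])  # m = 1
})

test_that("association p-values are uniform under the null", {
  set.seed(17)
  n <- 60
  ps <- replicate(100, {
    scores <- matrix(rnorm(n), ncol = 1, dimnames = list(sprintf("s%03d", 1:n), "PC1"))
    meta <- sample_metadata(sprintf("s%03d", 1:n),
                            list(group = sample(rep(c("a", "b", "c"), length.out = n))))
    associate_components(scores, meta)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
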