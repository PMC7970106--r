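# permutation plans, p-value machinery, combination, and the full NPC pipeline

test_that("joint_permutations couples shared samples and partitions exclusives", {
  ids <- sprintf("s%02d", 1:10)
  # overlap: the same permutation applied to every dataset
  plan <- joint_permutations(list(ids, ids), mode = "overlap", B = 25, seed = 4)
  expect_identical(plan$perms[[1]], plan$perms[[2]])
  expect_true(all(apply(plan$perms[[1]], 2, sort) == seq_along(ids)))

  # all_samples: restriction to shared ids identical; exclusives stay put
  ids_a <- c(ids, "xa1", "xa2", "xa3")
  ids_b <- c(ids, "xb1", "xb2")
  plan2 <- joint_permutations(list(ids_a, ids_b), mode = "all_samples", B = 25, seed = 4)
  Pa <- plan2$perms[[1]]; Pb <- plan2$perms[[2]]
  for (b in c(1, 13, 25)) {
    # shared slot i receives labels of the same shared id in both datasets
    expect_identical(ids_a[Pa[1:10, b]], ids_b[Pb[1:10, b]])
    # exclusive samples only exchange labels among themselves
    expect_true(all(Pa[11:13, b] %in% 11:13))
    expect_true(all(Pb[11:12, b] %in% 11:12))
  }

  # determinism
  plan3 <- joint_permutations(list(ids_a, ids_b), mode = "all_samples", B = 25, seed = 4)
  expect_identical(plan2$perms, plan3$perms)

  # mode/size guards
  expect_error(joint_permutations(list(ids_a, ids_b), mode = "overlap", B = 25),
               "identical sample sets")
  expect_error(joint_permutations(list(ids, ids), B = 10), "too small")
  expect_warning(joint_permutations(list(ids, ids), B = 50, seed = 1), "granularity")
})

test_that("pvalues_from_stats implements the add-one leave-observed-in estimator", {
  # B = 99, exactly 4 permuted |T| >= |T_obs|  ->  p = 5/100 = 0.05
  obs <- 2
  perm <- matrix(c(rep(3, 4), seq(0.01, 1.9, length.out = 95)), nrow = 1)
  pv <- pvalues_from_stats(obs, perm)
  expect_equal(unname(pv$observed_p), 0.05)

  # observed strictly largest -> floor 1/(B+1)
  pv2 <- pvalues_from_stats(10, matrix(runif(99), 1))
  expect_equal(unname(pv2$observed_p), 1 / 100)

  # bounds and exchangeability: pooled pseudo-p of a null feature are the
  # ranks 1..(B+1) over (B+1), i.e. a uniform grid
  set.seed(6)
  all_stats <- rnorm(100)
  pv3 <- pvalues_from_stats(all_stats[1], matrix(all_stats[-1], 1))
  pooled <- c(pv3$observed_p, pv3$pseudo_p[1, ])
  expect_setequal(round(pooled * 100), 1:100)
  expect_true(all(pooled >= 1 / 100 & pooled <= 1))

  # NaN statistics are treated as no evidence
  pv4 <- pvalues_from_stats(NaN, matrix(rnorm(50), 1))
  expect_equal(unname(pv4$observed_p), 1)
})

test_that("combining functions match their closed forms", {
  expect_equal(combine_pvalues(c(1, 1), "fisher"), 0)
  expect_equal(combine_pvalues(c(0.25, 0.75), "liptak"), 0, tolerance = 1e-12)
  expect_equal(combine_pvalues(c(0.05, 0.05), "fisher"), -4 * log(0.05), tolerance = 1e-12)
  expect_equal(combine_pvalues(c(0.05, 0.05), "fisher"), 11.983, tolerance = 1e-3)
  expect_equal(combine_pvalues(c(0.2, 0.7), "tippett"), 0.8)
  expect_equal(combine_pvalues(c(NA, 0.3), "fisher"), -2 * log(0.3))
  expect_error(combine_pvalues(c(0, 0.5), "fisher"), "0, 1")
  expect_error(combine_pvalues(NA_real_, "fisher"), "no p-values")
})

test_that("parametric combination equals its closed forms", {
  # fisher k=2 at p=(0.5,0.5): T = -4 log(0.5) = 2.7726, chi2(4) tail
  expect_equal(parametric_combination(c(0.5, 0.5), "fisher"),
               pchisq(-4 * log(0.5), 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(parametric_combination(c(0.5, 0.5), "fisher"), 0.5966, tolerance = 1e-3)
  # no-evidence tuple
  expect_equal(parametric_combination(c(1, 1), "tippett"), 1)
  # arity-1 reduces to the p itself, all methods
  for (m in c("fisher", "liptak", "tippett")) {
    expect_equal(parametric_combination(matrix(c(0.123, NA), 1), m), 0.123,
                 tolerance = 1e-12)
  }
  # matches chi-square survival on a grid (pure-function identity)
  P <- cbind(runif(20, 0.01, 1), runif(20, 0.01, 1))
  expect_equal(parametric_combination(P, "fisher"),
               pchisq(-2 * rowSums(log(P)), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("omics_npc: arity-1 tuples return their own permutation p exactly", {
  sim <- simulate_paired_differential(n_per_group = 10, n_features = 30,
                                      n_true_pairs = 5, seed = 3)
  designs <- npc_design(sim$meta, "group")
  map1 <- feature_mapping(data.frame(
    gene = c("GX", "GY", "GZ"),
    feature_a = c("a_f0001", NA, "a_f0007"),
    feature_b = c(NA, "b_f0002", "b_f0007")
  ), retain_all = TRUE)
  npc <- omics_npc(list(sim$block_a, sim$block_b), map1, designs,
                   engines = "lm", B = 100, seed = 9)
  pa <- npc$per_block[[1]]$p_perm
  names(pa) <- npc$per_block[[1]]$feature
  pb <- npc$per_block[[2]]$p_perm
  names(pb) <- npc$per_block[[2]]$feature
  for (m in npc$methods) {
    cm <- npc$combined[npc$combined$method == m, ]
    expect_equal(cm$p_global[cm$gene == "GX"], unname(pa["a_f0001"]), tolerance = 1e-12)
    expect_equal(cm$p_global[cm$gene == "GY"], unname(pb["b_f0002"]), tolerance = 1e-12)
  }
  # p bounds for every tuple and method
  expect_true(all(npc$combined$p_global >= 1 / 101 & npc$combined$p_global <= 1))
  expect_true(all(npc$combined$p_adjusted >= npc$combined$p_global))
})

test_that("omics_npc is deterministic and tippett is dominated by single p", {
  sim <- simulate_paired_differential(n_per_group = 10, n_features = 40,
                                      n_true_pairs = 10, effect_per_block = 0.8, seed = 13)
  designs <- npc_design(sim$meta, "group")
  run <- function() omics_npc(list(sim$block_a, sim$block_b), sim$mapping, designs,
                              engines = "lm", B = 100, seed = 21)
  n1 <- run(); n2 <- run()
  expect_identical(n1$combined, n2$combined)
  expect_identical(n1$per_block, n2$per_block)

  # tippett dominance, union-bound form: the permutation count behind the
  # tippett global p sums at most the per-block counts at min(pa, pb), so
  # p_tippett <= k * min p + granularity (the k = 1 form claimed in some
  # descriptions is false for moderate p under the exchangeable null)
  tip <- n1$combined[n1$combined$method == "tippett", ]
  pa <- n1$per_block[[1]]$p_perm[match(tip$feature_a, n1$per_block[[1]]$feature)]
  pb <- n1$per_block[[2]]$p_perm[match(tip$feature_b, n1$per_block[[2]]$feature)]
  expect_true(all(tip$p_global <= 2 * pmin(pa, pb, na.rm = TRUE) + 2 / 101))
  # and at the floor the pass-through is tight
  floor_idx <- which(pmin(pa, pb) <= 1 / 101)
  if (length(floor_idx) > 0) {
    expect_true(all(tip$p_global[floor_idx] <= pmin(pa, pb)[floor_idx] + 2 / 101))
  }
})

test_that("omics_npc drops unknown tuples and validates inputs", {
  sim <- simulate_paired_differential(n_per_group = 8, n_features = 10,
                                      n_true_pairs = 2, seed = 44)
  designs <- npc_design(sim$meta, "group")
  bad_map <- feature_mapping(data.frame(
    gene = c("G1", "G2"),
    feature_a = c("a_f0001", "nope"),
    feature_b = c("b_f0001", "alsono")
  ), retain_all = TRUE)
  expect_warning(
    npc <- omics_npc(list(sim$block_a, sim$block_b), bad_map, designs,
                     engines = "lm", B = 30, seed = 2),
    "absent"
  )
  expect_equal(nrow(npc$tuples), 1L)

  all_bad <- feature_mapping(data.frame(gene = "G", feature_a = "zz", feature_b = "ww"),
                             retain_all = TRUE)
  expect_error(suppressWarnings(
    omics_npc(list(sim$block_a, sim$block_b), all_bad, designs, engines = "lm",
              B = 30, seed = 2)
  ), "no usable tuples")
})

test_that("count_novel_features implements the set difference", {
  sim <- simulate_paired_differential(n_per_group = 10, n_features = 20,
                                      n_true_pairs = 4, effect_per_block = 2.5, seed = 55)
  designs <- npc_design(sim$meta, "group")
  npc <- omics_npc(list(sim$block_a, sim$block_b), sim$mapping, designs,
                   engines = "lm", B = 200, seed = 6, methods = "fisher")
  cm <- npc$combined
  sig_tuples <- cm$p_adjusted < 0.05
  # construct single-omic p so that block a has one already-known feature
  pa <- setNames(rep(1, 20), npc$per_block[[1]]$feature)
  pb <- setNames(rep(1, 20), npc$per_block[[2]]$feature)
  implicated_a <- unique(na.omit(cm$feature_a[sig_tuples]))
  expect_gt(length(implicated_a), 0)  # strong effect: some pairs are significant
  pa[implicated_a[1]] <- 0.001
  counts <- count_novel_features(npc, list(pa, pb), alpha = 0.05)
  expect_equal(counts$novel[1], length(implicated_a) - 1L)
  expect_equal(counts$significant_single, c(1L, 0L))
  expect_equal(counts$significant_pairs, rep(sum(sig_tuples), 2))

  # no significant tuples -> novel 0 everywhere
  npc0 <- omics_npc(list(sim$block_a, sim$block_b), sim$mapping, designs,
                    engines = "lm", B = 30, seed = 6, methods = "fisher")
  npc0$combined$p_adjusted <- 1
  c0 <- count_novel_features(npc0, list(pa, pb))
  expect_equal(c0$novel, c(0L, 0L))
})
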