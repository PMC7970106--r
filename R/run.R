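# Pipeline orchestration: each step is a function of a validated config list,
# writes TSV/GMT/JSON artifacts plus a JSON run manifest, and is deterministic
# given the config seed. A `threads` knob is accepted for interface parity but
# treated as a concurrency hint only: results never depend on it.

run_config_defaults <- function() {
  list(
    out_dir = ".",
    seed = 1L,
    threads = 1L,
    n_components = 3L,
    correction = "bonferroni",
    rank_method = "jive_permutation",   # or "pca_gca"
    n_perm = 100L,
    alpha = 0.05,
    perms = 1000L,
    methods = c("fisher", "liptak", "tippett"),
    adjust = "bh",
    mode = "overlap",
    engine = "lm",
    min_genes = 3L,
    k_max = 10L,
    n_ref = 50L,
    inputs = list()
  )
}

#' Validate a run configuration
#'
#' Merges user settings over the step defaults (permutations = 1000,
#' methods = Fisher/Liptak/Tippett, alpha = 0.05, BH adjustment,
#' min_genes = 3) and rejects unknown keys.
#'
#' @param config named list of settings, or a path to a JSON config file.
#' @return the merged config list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, config)
  merged$seed <- as.integer(merged$seed)
  merged
}

write_manifest <- function(cfg, stage, outputs, extra = list()) {
  inputs <- unlist(cfg$inputs, use.names = TRUE)
  checksums <- if (length(inputs) > 0L) as.list(tools::md5sum(inputs)) else list()
  manifest <- c(list(stage = stage, seed = cfg$seed, config = cfg,
                     input_md5 = checksums, outputs = outputs), extra)
  path <- file.path(cfg$out_dir, sprintf("%s_manifest.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

load_blocks <- function(cfg) {
  paths <- cfg$inputs$blocks
  if (is.null(paths) || length(paths) < 1L) stopf("config inputs$blocks is required")
  nm <- names(paths) %||% paste0("block_", seq_along(paths))
  lapply(seq_along(paths), function(i) {
    if (!file.exists(paths[[i]])) stopf("input not found: %s", paths[[i]])
    read_omics_matrix(paths[[i]], name = nm[i])
  })
}

#' Step 1: per-omic exploration
#'
#' Reads each block and the metadata, centres/scales, runs [pca()], tests
#' component-metadata associations, and writes one association TSV per block
#' plus a manifest.
#'
#' @param config see [run_config()]; requires `inputs$blocks` (named TSV
#'   paths) and `inputs$metadata`.
#' @return (invisibly) list of association tables, one per block.
#' @export
run_explore <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- load_blocks(cfg)
  meta <- read_sample_metadata(cfg$inputs$metadata %||% stopf("config inputs$metadata is required"))
  outputs <- character(0)
  tables <- list()
  for (b in blocks) {
    scaled <- center_and_frobenius_scale(b)
    fit <- pca(scaled, n_components = min(cfg$n_components, min(dim(scaled$values))))
    m <- subset_samples(meta, b$sample_ids)
    tab <- associate_components(fit$scores, m, correction = cfg$correction)
    path <- file.path(cfg$out_dir, sprintf("explore_%s_associations.tsv", b$name))
    utils::write.table(cbind(block = b$name, tab), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    ev <- data.frame(component = colnames(fit$scores),
                     explained_variance = fit$explained_variance_fraction)
    evp <- file.path(cfg$out_dir, sprintf("explore_%s_variance.tsv", b$name))
    utils::write.table(ev, evp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, path, evp)
    tables[[b$name]] <- tab
    message(sprintf("[explore] block %s: %d features, %d samples, %d tests",
                    b$name, nrow(b$values), ncol(b$values), nrow(tab)))
  }
  write_manifest(cfg, "explore", outputs)
  invisible(tables)
}

#' Step 2: joint decomposition
#'
#' Aligns the two blocks on common samples, centres/scales, selects ranks
#' (permutation test by default, canonical-correlation cross-check with
#' `rank_method = "pca_gca"`), fits [jive_decompose()], writes the model
#' directory and the component-metadata association table.
#'
#' @param config see [run_config()]; requires `inputs$blocks` (2 paths) and
#'   optionally `inputs$metadata` for associations.
#' @return (invisibly) the fitted [jive_decompose()] model.
#' @export
run_decompose <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- load_blocks(cfg)
  if (length(blocks) != 2L) stopf("decompose expects exactly 2 blocks")
  al <- align_common_samples(blocks[[1L]], blocks[[2L]])
  scaled <- lapply(list(al$a, al$b), center_and_frobenius_scale)
  ranks <- if (cfg$rank_method == "pca_gca") {
    select_model_pca_gca(scaled)
  } else {
    select_model_jive(scaled, n_perm = cfg$n_perm, alpha = cfg$alpha, seed = cfg$seed)
  }
  r <- max(ranks$joint_rank, 0L)
  ri <- pmax(ranks$individual_ranks, 0L)
  model <- jive_decompose(scaled, joint_rank = r, individual_ranks = ri)
  mdir <- file.path(cfg$out_dir, "jive_model")
  write_jive_model(model, mdir)
  outputs <- mdir
  if (!is.null(cfg$inputs$metadata) && model$joint_rank > 0L) {
    meta <- subset_samples(read_sample_metadata(cfg$inputs$metadata), model$sample_ids)
    tab <- associate_components(model$joint_scores, meta, correction = cfg$correction)
    path <- file.path(cfg$out_dir, "decompose_associations.tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    outputs <- c(outputs, path)
  }
  message(sprintf("[decompose] selected joint rank %d, individual (%s)",
                  ranks$joint_rank, paste(ranks$individual_ranks, collapse = ",")))
  write_manifest(cfg, "decompose", outputs,
                 extra = list(selected_ranks = ranks[c("joint_rank", "individual_ranks")]))
  invisible(model)
}

#' Step 3: integrative differential analysis
#'
#' Reads two blocks, the metadata, and the feature mapping; runs
#' [omics_npc()] with the configured outcome/covariates and writes the
#' per-tuple result TSV plus manifest.
#'
#' @param config see [run_config()]; requires `inputs$blocks` (2 paths),
#'   `inputs$metadata`, `inputs$mapping`, and `inputs$outcome` (metadata
#'   variable name; `inputs$covariates` optional).
#' @return (invisibly) the [omics_npc()] result.
#' @export
run_npc <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- load_blocks(cfg)
  if (length(blocks) != 2L) stopf("npc expects exactly 2 blocks")
  if (cfg$mode == "overlap") {
    al <- align_common_samples(blocks[[1L]], blocks[[2L]])
    blocks <- list(al$a, al$b)
  }
  meta <- read_sample_metadata(cfg$inputs$metadata %||% stopf("config inputs$metadata is required"))
  mapping <- read_feature_mapping(cfg$inputs$mapping %||% stopf("config inputs$mapping is required"))
  outcome <- cfg$inputs$outcome %||% stopf("config inputs$outcome is required")
  covariates <- cfg$inputs$covariates %||% character(0)
  designs <- lapply(blocks, function(b) {
    npc_design(subset_samples(meta, b$sample_ids), outcome, covariates)
  })
  npc <- omics_npc(blocks, mapping, designs, engines = cfg$engine,
                   methods = cfg$methods, B = cfg$perms, seed = cfg$seed,
                   mode = cfg$mode, adjust = cfg$adjust)
  path <- file.path(cfg$out_dir, "npc_result.tsv")
  write_npc_result(npc, path)
  message(sprintf("[npc] %d tuples x %d methods, B=%d, mode=%s",
                  nrow(npc$tuples), length(cfg$methods), npc$B, npc$mode))
  write_manifest(cfg, "npc", path)
  invisible(npc)
}

#' Step 4: gene-set summarisation
#'
#' Reads one or more labelled GMT collections with matching query gene
#' lists, computes ORA p-values, filters on significance/size, builds the
#' relative-risk matrix over the pooled filtered sets, clusters with
#' gap-statistic model selection, and writes the RR matrix, assignments, gap
#' curve and cross-analysis membership matrix.
#'
#' @param config see [run_config()]; requires `inputs$gene_sets` (named GMT
#'   paths) and `inputs$queries` (named paths to one-gene-per-line query
#'   lists, same names).
#' @return (invisibly) the [cluster_rr()] assignment.
#' @export
run_cluster <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gmt_paths <- cfg$inputs$gene_sets %||% stopf("config inputs$gene_sets is required")
  query_paths <- cfg$inputs$queries %||% stopf("config inputs$queries is required")
  labels <- names(gmt_paths) %||% paste0("analysis_", seq_along(gmt_paths))
  filtered <- list()
  for (i in seq_along(gmt_paths)) {
    coll <- read_gmt(gmt_paths[[i]], source_analysis = labels[i])
    query <- readLines(query_paths[[i]], warn = FALSE)
    query <- unique(query[nzchar(query)])
    coll <- ora_collection(coll, query, source_analysis = labels[i])
    filtered[[labels[i]]] <- filter_gene_sets(coll, alpha = cfg$alpha,
                                              min_genes = cfg$min_genes)
  }
  # unique set ids across analyses: same id in two analyses is one row in the
  # membership matrix and clusters on its first occurrence's gene content
  all_sets <- unlist(lapply(unname(filtered), function(x) unname(x$sets)), recursive = FALSE)
  first <- !duplicated(vapply(all_sets, `[[`, character(1), "set_id"))
  rrcoll <- gene_set_collection(all_sets[first])
  rr <- rr_matrix(rrcoll)
  assign <- cluster_rr(rr, k_max = cfg$k_max, n_ref = cfg$n_ref, seed = cfg$seed)
  outputs <- character(0)
  p1 <- file.path(cfg$out_dir, "cluster_rr_matrix.tsv")
  utils::write.table(data.frame(set_id = rr$set_ids, rr$values, check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(cfg$out_dir, "cluster_assignments.tsv")
  utils::write.table(data.frame(set_id = assign$set_ids, cluster = assign$cluster_labels),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, p1, p2)
  if (!is.null(assign$gap_curve)) {
    p3 <- file.path(cfg$out_dir, "cluster_gap_curve.tsv")
    utils::write.table(assign$gap_curve, p3, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p3)
  }
  if (length(filtered) >= 2L) {
    memb <- cross_analysis_membership(filtered)
    p4 <- file.path(cfg$out_dir, "cluster_membership.tsv")
    utils::write.table(data.frame(set_id = rownames(memb),
                                  ifelse(memb, "yes", "no"), check.names = FALSE),
                       p4, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p4)
  }
  message(sprintf("[cluster] %d sets -> k=%d clusters", length(rr$set_ids), assign$k))
  write_manifest(cfg, "cluster", outputs, extra = list(selected_k = assign$k))
  invisible(assign)
}

#' Generate a synthetic scenario on disk
#'
#' Writes the outputs of one generator in exactly the formats the readers
#' consume (TSV matrices/metadata/mapping, GMT), plus a ground-truth JSON.
#'
#' @param config see [run_config()]; `inputs$scenario` one of
#'   `"joint_blocks"`, `"paired_differential"`, `"survival"`, `"gene_sets"`;
#'   optional `inputs$params` (named list passed to the generator).
#' @return (invisibly) the generator output.
#' @export
run_simulate <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scenario <- cfg$inputs$scenario %||% stopf("config inputs$scenario is required")
  params <- cfg$inputs$params %||% list()
  params$seed <- cfg$seed
  out <- cfg$out_dir
  res <- switch(scenario,
    joint_blocks = {
      sim <- do.call(simulate_joint_blocks, params)
      for (b in sim$blocks) write_omics_matrix(b, file.path(out, paste0(b$name, ".tsv")))
      sim
    },
    paired_differential = {
      sim <- do.call(simulate_paired_differential, params)
      write_omics_matrix(sim$block_a, file.path(out, "block_a.tsv"))
      write_omics_matrix(sim$block_b, file.path(out, "block_b.tsv"))
      write_feature_mapping(sim$mapping, file.path(out, "mapping.tsv"))
      write_sample_metadata(sim$meta, file.path(out, "metadata.tsv"))
      sim
    },
    survival = {
      sim <- do.call(simulate_survival_omics, params)
      write_omics_matrix(sim$block, file.path(out, "block_surv.tsv"))
      write_sample_metadata(sim$meta, file.path(out, "metadata.tsv"))
      sim
    },
    gene_sets = {
      sim <- do.call(simulate_gene_set_collection, params)
      write_gmt(sim$collection, file.path(out, "gene_sets.gmt"))
      write_gene_set_table(sim$collection, file.path(out, "gene_sets.tsv"))
      sim
    },
    stopf("unknown scenario '%s'", scenario)
  )
  jsonlite::write_json(res$truth, file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_manifest(cfg, "simulate", out)
  invisible(res)
}
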