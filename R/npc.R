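#' Non-parametric combination of evidence across two omics blocks
#'
#' The integrative differential-analysis step. Each block is analysed
#' separately with its statistic engine under a joint permutation scheme
#' ([joint_permutations()]); per-feature permutation p-values and
#' leave-observed-in pseudo p-values are computed
#' ([permutation_pvalues()]); for every gene-referenced tuple of the mapping
#' and every combining method the per-omic p-values are merged into one
#' combined statistic, whose permutation distribution (built from the pseudo
#' p-values) yields a global p-value
#' `(1 + #\{b: T*_b >= T_obs\}) / (B + 1)`; finally p-values are adjusted
#' across tuples per method. Tuples with a single present feature reduce
#' exactly to that feature's own permutation p-value under every method.
#'
#' With `mode = "overlap"` both blocks must hold the identical sample set
#' (aligned); `mode = "all_samples"` additionally uses samples profiled in
#' only one block, permuting shared samples jointly and exclusive samples
#' within their own block.
#'
#' @param datasets list of exactly 2 [omics_dataset]s.
#' @param mapping a [feature_mapping]; tuples referencing features absent
#'   from the blocks are dropped with a warning.
#' @param designs an [npc_design], or a list of 2 (one per block; required in
#'   `all_samples` mode when the blocks carry different sample sets).
#' @param engines engine spec per block (`"lm"`, `"lm_moderated"`, `"cox"`,
#'   or a function); a single value is recycled.
#' @param methods combining methods to evaluate.
#' @param B number of permutations.
#' @param seed RNG seed (results are bit-identical for a fixed seed).
#' @param mode permutation mode, see above.
#' @param adjust `"bh"` (default) or `"bonferroni"` adjustment across tuples.
#' @return an object of class `npc_result`: `$tuples` (the retained mapping
#'   rows), `$per_block` (per block: observed statistic and permutation
#'   p-value per feature), `$combined` (data frame, one row per tuple x
#'   method: `method`, `statistic`, `p_global`, `p_adjusted`), plus `B`,
#'   `seed`, `mode`, `methods`.
#' @export
omics_npc <- function(datasets, mapping, designs, engines = "lm",
                      methods = c("fisher", "liptak", "tippett"),
                      B = 1000L, seed = NULL, mode = c("overlap", "all_samples"),
                      adjust = c("bh", "bonferroni")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  methods <- match.arg(methods, c("fisher", "liptak", "tippett"), several.ok = TRUE)
  if (!is.list(datasets) || length(datasets) != 2L) stopf("exactly 2 blocks are supported")
  lapply(datasets, function(d) stopifnot(inherits(d, "omics_dataset")))
  stopifnot(inherits(mapping, "feature_mapping"))
  if (inherits(designs, "npc_design")) designs <- list(designs, designs)
  if (length(engines) == 1L) engines <- list(engines, engines) else engines <- as.list(engines)

  # drop tuples referencing unknown features
  tup <- mapping$tuples
  known_a <- is.na(tup$feature_a) | tup$feature_a %in% datasets[[1L]]$feature_ids
  known_b <- is.na(tup$feature_b) | tup$feature_b %in% datasets[[2L]]$feature_ids
  # a tuple side that is unknown becomes absent; fully unknown tuples are dropped
  tup$feature_a[!known_a] <- NA
  tup$feature_b[!known_b] <- NA
  if (any(!known_a | !known_b)) {
    warnf("%d tuple side(s) reference features absent from the blocks; treated as absent",
          sum(!known_a) + sum(!known_b))
  }
  keep <- !(is.na(tup$feature_a) & is.na(tup$feature_b))
  tup <- tup[keep, , drop = FALSE]
  if (nrow(tup) == 0L) stopf("no usable tuples after dropping unknown features")
  rownames(tup) <- NULL

  plan <- joint_permutations(lapply(datasets, `[[`, "sample_ids"),
                             mode = mode, B = B, seed = seed)
  per_block <- lapply(1:2, function(i) {
    permutation_pvalues(engines[[i]], datasets[[i]], designs[[i]], plan,
                        dataset_index = i)
  })
  names(per_block) <- vapply(datasets, `[[`, character(1), "name")

  # tuples x (B + 1) matrices of (pseudo) p-values per side, NA = absent
  side_p <- function(i, feats) {
    pb <- per_block[[i]]
    full <- cbind(pb$observed_p, pb$pseudo_p)
    out <- matrix(NA_real_, length(feats), ncol(full))
    present <- !is.na(feats)
    out[present, ] <- full[match(feats[present], names(pb$observed_p)), , drop = FALSE]
    out
  }
  Pa <- side_p(1L, tup$feature_a)
  Pb <- side_p(2L, tup$feature_b)

  combined <- do.call(rbind, lapply(methods, function(m) {
    Tall <- combine_2block(Pa, Pb, m)                     # tuples x (B+1)
    Tobs <- Tall[, 1L]
    exceed <- rowSums(Tall[, -1L, drop = FALSE] >= Tobs)
    p_global <- (1 + exceed) / (B + 1)
    p_adj <- if (adjust == "bh") stats::p.adjust(p_global, method = "BH")
             else pmin(1, p_global * length(p_global))
    data.frame(tuple = seq_len(nrow(tup)), gene = tup$gene,
               feature_a = tup$feature_a, feature_b = tup$feature_b,
               method = m, statistic = Tobs,
               p_global = p_global, p_adjusted = p_adj,
               stringsAsFactors = FALSE)
  }))
  rownames(combined) <- NULL

  structure(list(
    tuples = tup,
    per_block = lapply(per_block, function(pb) {
      data.frame(feature = names(pb$observed_p),
                 statistic = unname(pb$observed_stat),
                 p_perm = unname(pb$observed_p), stringsAsFactors = FALSE)
    }),
    combined = combined,
    B = as.integer(B), seed = seed, mode = mode, methods = methods,
    adjust = adjust
  ), class = "npc_result")
}

# combined statistics for two p-matrices (tuples x (B+1)), NA = absent side
combine_2block <- function(Pa, Pb, method) {
  switch(method,
    fisher = {
      La <- -2 * log(Pa); La[is.na(Pa)] <- 0
      Lb <- -2 * log(Pb); Lb[is.na(Pb)] <- 0
      La + Lb
    },
    liptak = {
      Qa <- stats::qnorm(1 - Pa); Qa[is.na(Pa)] <- 0
      Qb <- stats::qnorm(1 - Pb); Qb[is.na(Pb)] <- 0
      Qa + Qb
    },
    tippett = {
      Ma <- 1 - Pa; Ma[is.na(Pa)] <- -Inf
      Mb <- 1 - Pb; Mb[is.na(Pb)] <- -Inf
      pmax(Ma, Mb)
    },
    stopf("unknown combining method '%s'", method)
  )
}

#' @export
print.npc_result <- function(x, ...) {
  sig <- tapply(x$combined$p_adjusted < 0.05, x$combined$method, sum)
  cat(sprintf("<npc_result> %d tuples, B=%d, mode=%s; adjusted-significant at 0.05: %s\n",
              nrow(x$tuples), x$B, x$mode,
              paste(sprintf("%s=%d", names(sig), sig), collapse = ", ")))
  invisible(x)
}

#' Write an NPC result as TSV plus a JSON run manifest
#'
#' @param npc an [omics_npc()] result.
#' @param path output TSV (one row per tuple x method); the manifest is
#'   written alongside with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_npc_result <- function(npc, path) {
  stopifnot(inherits(npc, "npc_result"))
  utils::write.table(npc$combined, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  manifest <- list(B = npc$B, seed = npc$seed, mode = npc$mode,
                   methods = npc$methods, adjust = npc$adjust,
                   n_tuples = nrow(npc$tuples))
  jsonlite::write_json(manifest, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Count features discovered only through combination
#'
#' Reproduces the per-block accounting of integration gain: a feature is
#' "novel" if it belongs to a tuple whose combined (NPC) adjusted p-value
#' falls below `alpha` while its own single-omic adjusted p-value does not.
#'
#' @param npc an [omics_npc()] result.
#' @param single_omic_p list of 2 named numeric vectors: per-block adjusted
#'   (or raw, caller's choice) single-omic p-values per feature.
#' @param alpha significance threshold in (0, 1).
#' @param method which combining method's adjusted p-values define tuple
#'   significance.
#' @return data frame, one row per block: `block`, `significant_single`,
#'   `significant_pairs`, `novel`.
#' @export
count_novel_features <- function(npc, single_omic_p, alpha = 0.05, method = "fisher") {
  stopifnot(inherits(npc, "npc_result"))
  if (alpha <= 0 || alpha >= 1) stopf("alpha outside (0,1)")
  cm <- npc$combined[npc$combined$method == method, , drop = FALSE]
  if (nrow(cm) == 0L) stopf("method '%s' not present in the result", method)
  sig <- cm$p_adjusted < alpha
  out <- lapply(1:2, function(i) {
    col <- if (i == 1L) "feature_a" else "feature_b"
    implicated <- unique(stats::na.omit(cm[[col]][sig]))
    sp <- single_omic_p[[i]]
    single_sig <- names(sp)[!is.na(sp) & sp < alpha]
    data.frame(block = names(npc$per_block)[i],
               significant_single = length(single_sig),
               significant_pairs = sum(sig),
               novel = length(setdiff(implicated, single_sig)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
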