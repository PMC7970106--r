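#' Construct a cross-omic feature mapping
#'
#' A mapping is a table of gene-referenced tuples `(gene, feature_a,
#' feature_b)` linking features of two omics blocks through a shared gene
#' namespace (e.g. a miRNA and a target mRNA, or a CpG and its gene).
#' `NA` marks an absent side; every tuple must have at least one present
#' feature, and when `retain_all` is `FALSE` both must be present.
#'
#' @param tuples data frame with character columns `gene`, `feature_a`,
#'   `feature_b` (`NA` = absent).
#' @param retain_all whether one-sided tuples are permitted.
#' @return an object of class `feature_mapping`.
#' @export
feature_mapping <- function(tuples, retain_all = TRUE) {
  need <- c("gene", "feature_a", "feature_b")
  if (!is.data.frame(tuples) || !all(need %in% colnames(tuples))) {
    stopf("'tuples' must be a data frame with columns gene, feature_a, feature_b")
  }
  tuples <- data.frame(lapply(tuples[need], as.character), stringsAsFactors = FALSE)
  if (nrow(tuples) == 0L) stopf("mapping has zero tuples")
  if (anyNA(tuples$gene)) stopf("mapping tuples must carry a reference gene")
  absent_both <- is.na(tuples$feature_a) & is.na(tuples$feature_b)
  if (any(absent_both)) stopf("tuple for gene '%s' has no features", tuples$gene[absent_both][1L])
  if (!retain_all && any(is.na(tuples$feature_a) | is.na(tuples$feature_b))) {
    stopf("retain_all = FALSE but one-sided tuples present")
  }
  key <- paste(tuples$gene, tuples$feature_a, tuples$feature_b, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate tuple for gene '%s'", tuples$gene[duplicated(key)][1L])
  rownames(tuples) <- NULL
  structure(list(tuples = tuples, retain_all = retain_all), class = "feature_mapping")
}

#' @export
print.feature_mapping <- function(x, ...) {
  n1 <- sum(is.na(x$tuples$feature_a) | is.na(x$tuples$feature_b))
  cat(sprintf("<feature_mapping> %d tuples (%d one-sided), retain_all=%s\n",
              nrow(x$tuples), n1, x$retain_all))
  invisible(x)
}

#' Combine two per-omic gene mappings into cross-omic tuples
#'
#' Given `feature -> gene` tables for two blocks, emits one tuple per
#' `(gene, feature_a, feature_b)` combination where both features map to the
#' gene (the full cross product for many-to-many genes). With
#' `retain_all = TRUE`, genes mapped in only one table contribute one-sided
#' tuples so no mapped feature is silently lost.
#'
#' @param map_a,map_b data frames with columns `feature`, `gene`.
#' @param retain_all keep genes present in only one table.
#' @return a [feature_mapping].
#' @export
combine_mappings <- function(map_a, map_b, retain_all = TRUE) {
  chk <- function(m, nm) {
    if (!is.data.frame(m) || !all(c("feature", "gene") %in% colnames(m)) || nrow(m) == 0L) {
      stopf("'%s' must be a non-empty data frame with columns feature, gene", nm)
    }
    unique(data.frame(feature = as.character(m$feature), gene = as.character(m$gene),
                      stringsAsFactors = FALSE))
  }
  map_a <- chk(map_a, "map_a"); map_b <- chk(map_b, "map_b")
  names(map_a) <- c("feature_a", "gene")
  names(map_b) <- c("feature_b", "gene")
  merged <- merge(map_a, map_b, by = "gene", all = retain_all, sort = TRUE)
  if (!retain_all) merged <- merged[!is.na(merged$feature_a) & !is.na(merged$feature_b), , drop = FALSE]
  if (nrow(merged) == 0L) stopf("no tuples produced; gene namespaces do not overlap")
  merged <- merged[order(merged$gene, merged$feature_a, merged$feature_b, na.last = TRUE), ]
  feature_mapping(merged[, c("gene", "feature_a", "feature_b")], retain_all = retain_all)
}

#' Read / write feature mappings as TSV
#'
#' Three tab-separated columns `gene`, `feature_a`, `feature_b`; empty cells
#' denote absent features.
#'
#' @param path TSV file path.
#' @param retain_all passed to [feature_mapping()].
#' @return [read_feature_mapping()] returns a [feature_mapping];
#'   [write_feature_mapping()] returns `path` invisibly.
#' @export
read_feature_mapping <- function(path, retain_all = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", ""))
  feature_mapping(df, retain_all = retain_all)
}

#' @rdname read_feature_mapping
#' @param mapping a [feature_mapping].
#' @export
write_feature_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "feature_mapping"))
  utils::write.table(mapping$tuples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
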