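#' Construct an omics data block
#'
#' An `omics_dataset` is one omics block: a numeric matrix with features on
#' rows and samples on columns, plus a block label. This is the layout used by
#' every downstream operation; matrices are never transposed silently.
#'
#' @param values numeric matrix, rows = features, columns = samples. Must have
#'   unique, non-empty row and column names and contain only finite values.
#' @param name label for the block (e.g. `"mRNA"`, `"miRNA"`).
#' @param na_action `"error"` (default) rejects missing values at construction;
#'   `"drop_features"` removes every feature row containing a missing value and
#'   reports how many were dropped.
#' @return an object of class `omics_dataset` with elements `name`, `values`,
#'   `feature_ids`, `sample_ids`.
#' @export
omics_dataset <- function(values, name = "omic", na_action = c("error", "drop_features")) {
  na_action <- match.arg(na_action)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix (features x samples)")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) stopf("empty matrix for block '%s'", name)
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || anyNA(fid) || any(fid == "")) stopf("feature ids (rownames) missing in block '%s'", name)
  if (is.null(sid) || anyNA(sid) || any(sid == "")) stopf("sample ids (colnames) missing in block '%s'", name)
  if (anyDuplicated(fid)) stopf("duplicate feature id '%s' in block '%s'", fid[duplicated(fid)][1L], name)
  if (anyDuplicated(sid)) stopf("duplicate sample id '%s' in block '%s'", sid[duplicated(sid)][1L], name)
  if (anyNA(values)) {
    if (na_action == "error") {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stopf("missing value at feature '%s', sample '%s' in block '%s' (use na_action = 'drop_features' to drop)",
            fid[bad[1L]], sid[bad[2L]], name)
    }
    keep <- rowSums(is.na(values)) == 0L
    message(sprintf("block '%s': dropped %d of %d features with missing values",
                    name, sum(!keep), length(keep)))
    values <- values[keep, , drop = FALSE]
    if (nrow(values) == 0L) stopf("all features dropped in block '%s'", name)
    fid <- rownames(values)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stopf("non-finite value at feature '%s', sample '%s' in block '%s'",
          fid[bad[1L]], sid[bad[2L]], name)
  }
  structure(
    list(name = name, values = values, feature_ids = fid, sample_ids = sid),
    class = "omics_dataset"
  )
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset '%s'> %d features x %d samples\n",
              x$name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$values)

#' Read an omics matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds feature ids. All remaining cells must be numeric.
#'
#' @param path TSV file path.
#' @inheritParams omics_dataset
#' @return an [omics_dataset].
#' @export
read_omics_matrix <- function(path, name = "omic", na_action = c("error", "drop_features")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stopf("empty matrix in %s", path)
  fid <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(num) & !(is.na(raw) | raw %in% c("NA", ""))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("non-numeric cell '%s' at row %d, column '%s' in %s",
          raw[idx[1L], idx[2L]], idx[1L], colnames(raw)[idx[2L]], path)
  }
  rownames(num) <- fid
  colnames(num) <- colnames(raw)
  omics_dataset(num, name = name, na_action = na_action)
}

#' Write an omics matrix as TSV
#'
#' Inverse of [read_omics_matrix()]: header row of sample ids, first column
#' `feature_id`, full numeric precision.
#'
#' @param d an [omics_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(d, path) {
  stopifnot(inherits(d, "omics_dataset"))
  df <- data.frame(feature_id = d$feature_ids, d$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict two blocks to their common samples
#'
#' Joint analyses require the two blocks to be observed on the same samples,
#' in the same order. This returns both blocks restricted to the intersection
#' of their sample sets, ordered as in `a`. At least two shared samples are
#' required.
#'
#' @param a,b [omics_dataset] objects.
#' @return a list with elements `a` and `b`, sample-aligned.
#' @export
align_common_samples <- function(a, b) {
  stopifnot(inherits(a, "omics_dataset"), inherits(b, "omics_dataset"))
  shared <- intersect(a$sample_ids, b$sample_ids)
  if (length(shared) < 2L) {
    stopf("blocks '%s' and '%s' share %d sample(s); at least 2 required",
          a$name, b$name, length(shared))
  }
  shared <- a$sample_ids[a$sample_ids %in% shared]  # keep a's ordering
  sub <- function(d) {
    if (identical(d$sample_ids, shared)) return(d)
    omics_dataset(d$values[, shared, drop = FALSE], name = d$name)
  }
  list(a = sub(a), b = sub(b))
}

#' Centre features and scale a block to unit Frobenius norm
#'
#' Each feature (row) is mean-centred; the whole block is then divided by its
#' Frobenius norm, so the sum of all squared entries is 1. Scaling whole
#' blocks (rather than individual features) equalises block influence in the
#' joint decomposition regardless of feature count. A per-feature unit
#' sum-of-squares variant is available via `per_feature = TRUE`; there,
#' zero-variance features stay all-zero.
#'
#' @param d an [omics_dataset] with at least 2 samples.
#' @param per_feature scale each centred feature to unit sum of squares
#'   instead of scaling the block.
#' @return a centred, scaled [omics_dataset].
#' @export
center_and_frobenius_scale <- function(d, per_feature = FALSE) {
  stopifnot(inherits(d, "omics_dataset"))
  if (ncol(d$values) < 2L) stopf("block '%s' needs >= 2 samples to centre", d$name)
  x <- d$values - rowMeans(d$values)
  if (per_feature) {
    ss <- rowSums(x^2)
    nz <- ss > 0
    x[nz, ] <- x[nz, , drop = FALSE] / sqrt(ss[nz])
  } else {
    fro2 <- sum(x^2)
    if (fro2 == 0) stopf("block '%s' is constant; nothing left to scale after centring", d$name)
    x <- x / sqrt(fro2)
  }
  omics_dataset(x, name = d$name)
}
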