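#' Gene-set collections
#'
#' A `gene_set_collection` is an ordered list of gene sets, each with a unique
#' id, a free-text description, a set of gene identifiers, an optional
#' enrichment p-value, and a label naming the analysis it came from. P-values
#' are attached by [ora_fisher()] / [ora_collection()] or carried in from an
#' external enrichment run.
#'
#' @param sets list of lists with elements `set_id`, `description`, `genes`,
#'   and optionally `p_value`, `source_analysis`.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (length(sets) == 0L) stopf("empty gene-set collection")
  ids <- vapply(sets, function(s) as.character(s$set_id), character(1))
  if (anyDuplicated(ids)) stopf("duplicate gene-set id '%s'", ids[duplicated(ids)][1L])
  sets <- lapply(sets, function(s) {
    genes <- unique(as.character(s$genes))
    if (length(genes) < 1L) stopf("gene set '%s' is empty", s$set_id)
    p <- s$p_value
    if (!is.null(p) && (!is.numeric(p) || is.na(p) || p < 0 || p > 1)) {
      stopf("gene set '%s': p_value must lie in [0,1]", s$set_id)
    }
    list(set_id = as.character(s$set_id),
         description = as.character(s$description %||% ""),
         genes = genes,
         p_value = if (is.null(p)) NA_real_ else as.numeric(p),
         source_analysis = as.character(s$source_analysis %||% ""))
  })
  names(sets) <- ids
  structure(list(sets = sets), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$genes), integer(1))
  cat(sprintf("<gene_set_collection> %d sets, gene-set sizes %d..%d\n",
              length(x$sets), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

set_ids <- function(x) names(x$sets)

#' Read a GMT file
#'
#' Standard GMT: one gene set per line, tab-separated fields
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are dropped.
#'
#' @param path GMT file path.
#' @param source_analysis label recorded on every set read.
#' @return a [gene_set_collection].
#' @export
read_gmt <- function(path, source_analysis = "") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("empty GMT file: %s", path)
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stopf("GMT line %d has %d fields; need set id, description, >= 1 gene", i, length(f))
    list(set_id = f[1L], description = f[2L], genes = f[-(1:2)],
         source_analysis = source_analysis)
  })
  gene_set_collection(sets)
}

#' Write a collection as GMT
#'
#' P-values are not representable in GMT; use [write_gene_set_table()] to keep
#' them alongside.
#'
#' @param collection a [gene_set_collection].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$set_id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Tabular view of a collection
#'
#' @param collection a [gene_set_collection].
#' @return data frame with one row per set: `set_id`, `description`,
#'   `n_genes`, `p_value`, `source_analysis`, `genes` (comma-separated).
#' @export
as_gene_set_table <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  data.frame(
    set_id = vapply(collection$sets, `[[`, character(1), "set_id"),
    description = vapply(collection$sets, `[[`, character(1), "description"),
    n_genes = vapply(collection$sets, function(s) length(s$genes), integer(1)),
    p_value = vapply(collection$sets, `[[`, numeric(1), "p_value"),
    source_analysis = vapply(collection$sets, `[[`, character(1), "source_analysis"),
    genes = vapply(collection$sets, function(s) paste(s$genes, collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @rdname as_gene_set_table
#' @param path output TSV path.
#' @export
write_gene_set_table <- function(collection, path) {
  utils::write.table(as_gene_set_table(collection), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname as_gene_set_table
#' @export
read_gene_set_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  sets <- lapply(seq_len(nrow(df)), function(i) {
    list(set_id = df$set_id[i], description = df$description[i],
         genes = strsplit(df$genes[i], ",", fixed = TRUE)[[1L]],
         p_value = if (is.na(df$p_value[i])) NULL else df$p_value[i],
         source_analysis = df$source_analysis[i])
  })
  gene_set_collection(sets)
}
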