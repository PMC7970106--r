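#' Construct a sample metadata table
#'
#' Holds per-sample variables typed as `categorical`, `numeric`, or
#' `time_to_event`. The type drives which association test and which
#' statistic engine a variable can feed: Kruskal-Wallis for categorical,
#' Spearman for numeric, Cox regression for time-to-event.
#'
#' @param sample_ids unique sample identifiers (one row per sample).
#' @param variables named list; each element is either an atomic vector of
#'   length `length(sample_ids)` (categorical/numeric) or, for time-to-event
#'   variables, a list with components `time` (positive durations) and
#'   `event` (0/1 indicators).
#' @param types optional named character vector giving the type of each
#'   variable (`"categorical"`, `"numeric"`, `"time_to_event"`). When omitted,
#'   numeric vectors are typed `numeric`, everything else `categorical`, and
#'   `list(time=, event=)` elements `time_to_event`.
#' @return an object of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_ids, variables, types = NULL) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (n == 0L) stopf("no samples")
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample id '%s' in metadata", sample_ids[duplicated(sample_ids)][1L])
  }
  if (length(variables) == 0L || is.null(names(variables)) || any(names(variables) == "")) {
    stopf("'variables' must be a non-empty named list")
  }
  out <- list()
  vtypes <- character(0)
  for (nm in names(variables)) {
    v <- variables[[nm]]
    ty <- if (!is.null(types) && nm %in% names(types)) types[[nm]] else NA_character_
    if (is.list(v) && all(c("time", "event") %in% names(v))) {
      ty <- if (is.na(ty)) "time_to_event" else ty
      if (ty != "time_to_event") stopf("variable '%s': time/event payload requires type time_to_event", nm)
      tm <- as.numeric(v$time); ev <- as.numeric(v$event)
      if (length(tm) != n || length(ev) != n) stopf("variable '%s': time/event length mismatch", nm)
      if (any(!is.finite(tm)) || any(tm <= 0)) stopf("variable '%s': times must be positive", nm)
      if (!all(ev %in% c(0, 1))) stopf("variable '%s': event indicator must be 0/1", nm)
      out[[nm]] <- list(time = tm, event = ev)
    } else {
      if (length(v) != n) stopf("variable '%s': length %d != %d samples", nm, length(v), n)
      if (is.na(ty)) ty <- if (is.numeric(v)) "numeric" else "categorical"
      if (ty == "numeric") {
        out[[nm]] <- as.numeric(v)
      } else if (ty == "categorical") {
        out[[nm]] <- as.factor(v)
      } else {
        stopf("variable '%s': unknown type '%s'", nm, ty)
      }
    }
    vtypes[nm] <- if (is.list(out[[nm]])) "time_to_event" else if (is.numeric(out[[nm]])) "numeric" else "categorical"
  }
  structure(list(sample_ids = sample_ids, variables = out, types = vtypes),
            class = "sample_metadata")
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("<sample_metadata> %d samples, %d variables (%s)\n",
              length(x$sample_ids), length(x$variables),
              paste(sprintf("%s:%s", names(x$types), unname(x$types)), collapse = ", ")))
  invisible(x)
}

#' Subset and reorder metadata to a set of samples
#'
#' @param meta a [sample_metadata].
#' @param sample_ids samples to keep, in the requested order; all must exist.
#' @return a [sample_metadata] restricted to `sample_ids`.
#' @export
subset_samples <- function(meta, sample_ids) {
  stopifnot(inherits(meta, "sample_metadata"))
  idx <- match(sample_ids, meta$sample_ids)
  if (anyNA(idx)) stopf("unknown sample id '%s'", sample_ids[is.na(idx)][1L])
  vars <- lapply(meta$variables, function(v) {
    if (is.list(v)) list(time = v$time[idx], event = v$event[idx]) else v[idx]
  })
  sample_metadata(sample_ids, vars, types = meta$types)
}

#' Read sample metadata from TSV
#'
#' First column must hold sample ids. A time-to-event variable `x` is encoded
#' as the column pair `x.time` / `x.event`. Remaining columns are typed
#' numeric when fully numeric, categorical otherwise, unless overridden via
#' `types`.
#'
#' @param path TSV file path.
#' @param types optional named character vector of variable types.
#' @return a [sample_metadata].
#' @export
read_sample_metadata <- function(path, types = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stopf("empty metadata table in %s", path)
  sid <- as.character(df[[1L]])
  cols <- colnames(df)[-1L]
  vars <- list()
  consumed <- character(0)
  for (nm in cols) {  # declaration order preserved
    if (nm %in% consumed) next
    if (grepl("\\.time$", nm)) {
      base <- sub("\\.time$", "", nm)
      ecol <- paste0(base, ".event")
      if (ecol %in% cols) {
        vars[[base]] <- list(time = df[[nm]], event = df[[ecol]])
        consumed <- c(consumed, nm, ecol)
        next
      }
    }
    vars[[nm]] <- df[[nm]]
  }
  sample_metadata(sid, vars, types = types)
}

#' Write sample metadata as TSV
#'
#' Inverse of [read_sample_metadata()]; time-to-event variables become
#' `.time`/`.event` column pairs. Column order is deterministic (variable
#' declaration order).
#'
#' @param meta a [sample_metadata].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "sample_metadata"))
  df <- data.frame(sample_id = meta$sample_ids, stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(meta$variables)) {
    v <- meta$variables[[nm]]
    if (is.list(v)) {
      df[[paste0(nm, ".time")]] <- v$time
      df[[paste0(nm, ".event")]] <- v$event
    } else {
      df[[nm]] <- if (is.factor(v)) as.character(v) else v
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Pull one variable aligned to `sample_ids`; returns list(values=..., type=...)
get_variable <- function(meta, name, sample_ids = NULL) {
  if (!name %in% names(meta$variables)) stopf("unknown metadata variable '%s'", name)
  v <- meta$variables[[name]]
  ty <- meta$types[[name]]
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, meta$sample_ids)
    if (anyNA(idx)) stopf("metadata is missing sample '%s'", sample_ids[is.na(idx)][1L])
    v <- if (is.list(v)) list(time = v$time[idx], event = v$event[idx]) else v[idx]
  }
  list(values = v, type = ty)
}
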