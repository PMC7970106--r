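#' Associate component scores with sample metadata
#'
#' One test per (component, variable) pair, chosen by variable type:
#' Kruskal-Wallis (with tie correction) for categorical variables, Spearman
#' correlation with the large-sample t approximation for numeric variables,
#' and the univariate Cox score (log-rank-type) test for time-to-event
#' variables. P-values are adjusted across all tests in the table.
#'
#' @param scores samples x components numeric matrix (e.g. `$scores` of a
#'   [pca()] fit or `$joint_scores` of a [jive_decompose()] fit), rows in
#'   the same sample order as `meta`.
#' @param meta a [sample_metadata] whose sample order matches `scores` rows
#'   (checked via rownames when present).
#' @param correction `"bonferroni"` (default, `p_adj = min(1, m p)` with `m`
#'   the number of valid tests) or `"bh"`.
#' @return data frame with columns `component`, `variable`, `test`,
#'   `statistic`, `p_value`, `p_adjusted`. Degenerate variables (one level)
#'   yield `NA` p-values, excluded from the correction count, with a warning.
#' @export
associate_components <- function(scores, meta, correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  stopifnot(is.matrix(scores), inherits(meta, "sample_metadata"))
  if (nrow(scores) != length(meta$sample_ids)) {
    stopf("scores have %d rows but metadata has %d samples", nrow(scores), length(meta$sample_ids))
  }
  if (!is.null(rownames(scores)) && !identical(rownames(scores), meta$sample_ids)) {
    stopf("score rows and metadata samples are not in the same order")
  }
  comp_names <- colnames(scores) %||% paste0("PC", seq_len(ncol(scores)))

  rows <- list()
  for (j in seq_len(ncol(scores))) {
    x <- scores[, j]
    for (nm in names(meta$variables)) {
      v <- meta$variables[[nm]]
      ty <- meta$types[[nm]]
      res <- switch(ty,
        categorical = {
          f <- droplevels(as.factor(v))
          if (nlevels(f) < 2L) {
            warnf("variable '%s' has a single level; association undefined", nm)
            list(test = "kruskal_wallis", statistic = NA_real_, p = NA_real_)
          } else {
            kw <- stats::kruskal.test(x, f)
            list(test = "kruskal_wallis", statistic = unname(kw$statistic), p = kw$p.value)
          }
        },
        numeric = {
          rho <- stats::cor(rank(x), rank(v))
          n <- length(x)
          if (abs(rho) >= 1) {
            list(test = "spearman", statistic = rho, p = 0)
          } else {
            tval <- rho * sqrt((n - 2) / (1 - rho^2))
            list(test = "spearman", statistic = rho,
                 p = 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE))
          }
        },
        time_to_event = {
          sc <- cox_score_test(x, v$time, v$event)
          list(test = "cox", statistic = sc$statistic, p = sc$p_value)
        },
        stopf("unknown variable type '%s'", ty)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp_names[j], variable = nm, test = res$test,
        statistic = res$statistic, p_value = res$p,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  valid <- !is.na(tab$p_value)
  m <- sum(valid)
  tab$p_adjusted <- NA_real_
  if (m > 0L) {
    tab$p_adjusted[valid] <- if (correction == "bonferroni") {
      pmin(1, tab$p_value[valid] * m)
    } else {
      stats::p.adjust(tab$p_value[valid], method = "BH")
    }
  }
  tab
}
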