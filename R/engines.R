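#' Specify an analysis design for the statistic engines
#'
#' Binds an outcome variable and optional covariates (both named in a
#' [sample_metadata]) into the design each engine evaluates per feature.
#'
#' @param meta a [sample_metadata].
#' @param outcome metadata variable of interest (categorical with two levels
#'   or numeric for the linear-model engine; time-to-event for the Cox
#'   engine).
#' @param covariates character vector of adjustment variables (e.g. age);
#'   must not contain the outcome.
#' @return an object of class `npc_design`.
#' @export
npc_design <- function(meta, outcome, covariates = character(0)) {
  stopifnot(inherits(meta, "sample_metadata"))
  if (outcome %in% covariates) stopf("outcome '%s' cannot also be a covariate", outcome)
  for (nm in c(outcome, covariates)) {
    if (!nm %in% names(meta$variables)) stopf("variable '%s' not present in metadata", nm)
  }
  structure(list(meta = meta, outcome = outcome, covariates = covariates),
            class = "npc_design")
}

# Design pieces aligned to a sample order, with metadata rows permuted by
# `perm` (a permutation of sample positions) when given. Outcome and
# covariates are permuted jointly so their mutual relationship is preserved
# and only the feature-outcome link is broken.
design_pieces <- function(design, sample_ids, perm = NULL) {
  meta <- design$meta
  idx <- match(sample_ids, meta$sample_ids)
  if (anyNA(idx)) stopf("metadata is missing sample '%s'", sample_ids[is.na(idx)][1L])
  if (!is.null(perm)) idx <- idx[perm]
  out <- meta$variables[[design$outcome]]
  ty <- meta$types[[design$outcome]]
  outcome <- if (is.list(out)) list(time = out$time[idx], event = out$event[idx]) else out[idx]
  covs <- NULL
  if (length(design$covariates) > 0L) {
    covs <- do.call(cbind, lapply(design$covariates, function(nm) {
      v <- meta$variables[[nm]]
      if (is.list(v)) stopf("time-to-event variable '%s' cannot be a covariate", nm)
      if (is.factor(v)) {
        mm <- stats::model.matrix(~v)[, -1L, drop = FALSE]
        mm[idx, , drop = FALSE]
      } else {
        matrix(v[idx], ncol = 1L, dimnames = list(NULL, nm))
      }
    }))
  }
  list(outcome = outcome, type = ty, covariates = covs)
}

#' Per-feature moderated/unmoderated linear-model t statistics
#'
#' Fits, for every feature, a least-squares regression of the feature on the
#' outcome plus covariates and returns the t statistic of the outcome
#' coefficient. Categorical outcomes must have exactly two levels (dummy
#' coded); numeric outcomes enter as-is. With `moderate = TRUE`, residual
#' variances are shrunk toward a trimmed-mean prior with prior degrees of
#' freedom estimated by moment matching on the log residual variances
#' (empirical-Bayes variance moderation).
#'
#' @param d an [omics_dataset].
#' @param design an [npc_design] with a categorical (2-level) or numeric
#'   outcome.
#' @param moderate apply empirical-Bayes variance moderation.
#' @return named numeric vector of t statistics, one per feature.
#' @export
linear_model_t <- function(d, design, moderate = FALSE) {
  stopifnot(inherits(d, "omics_dataset"), inherits(design, "npc_design"))
  pieces <- design_pieces(design, d$sample_ids)
  lm_t_engine(d$values, pieces, moderate = moderate)
}

# Core worker, reused by the permutation scheme.
# X: features x samples; pieces from design_pieces().
lm_t_engine <- function(X, pieces, moderate = FALSE) {
  n <- ncol(X)
  z <- pieces$outcome
  if (pieces$type == "time_to_event") stopf("linear-model engine requires a categorical or numeric outcome")
  if (pieces$type == "categorical") {
    f <- droplevels(as.factor(z))
    if (nlevels(f) != 2L) stopf("categorical outcome must have exactly 2 levels (has %d)", nlevels(f))
    z <- as.numeric(f == levels(f)[2L])
  }
  z <- as.numeric(z)
  Zc <- cbind(`(Intercept)` = rep(1, n), pieces$covariates)
  if (n <= ncol(Zc) + 1L) stopf("too few samples (%d) for %d design columns", n, ncol(Zc) + 1L)
  qrZ <- qr(Zc)
  if (qrZ$rank < ncol(Zc)) {
    stopf("singular design: collinear columns {%s}", paste(colnames(Zc), collapse = ", "))
  }
  Q <- qr.Q(qrZ)
  zt <- z - Q %*% crossprod(Q, z)
  nz <- sum(zt^2)
  if (nz < 1e-12) stopf("outcome is collinear with the covariates")
  b <- drop(X %*% zt) / nz
  XQ <- X %*% Q
  rss <- rowSums(X^2) - rowSums(XQ^2) - b^2 * nz
  rss[rss < 0] <- 0
  df <- n - ncol(Zc) - 1L
  s2 <- rss / df
  if (moderate) s2 <- squeeze_var(s2, df)
  tstat <- b * sqrt(nz) / sqrt(s2)
  tstat[s2 == 0] <- sign(b[s2 == 0]) * Inf
  names(tstat) <- rownames(X)
  tstat
}

# Empirical-Bayes variance shrinkage: prior variance = 10%-trimmed mean of
# the observed residual variances; prior df by matching the excess variance
# of log(s2) over its sampling variance trigamma(df/2).
squeeze_var <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2L) return(s2)
  s0 <- mean(s2[ok], trim = 0.1)
  excess <- stats::var(log(s2[ok])) - trigamma(df / 2)
  if (is.na(excess) || excess <= 1e-8) return(rep(s0, length(s2)))  # d0 -> Inf
  d0 <- 2 * trigamma_inverse(excess)
  (d0 * s0 + df * s2) / (d0 + df)
}

#' Per-feature Cox Wald z statistics
#'
#' For every feature, fits a Cox proportional-hazards model of the
#' time-to-event outcome on the feature plus covariates (Breslow tie
#' handling, Newton iterations to gradient below 1e-8) and returns the Wald z
#' of the feature coefficient. Features whose fit does not converge yield
#' `NaN` with a warning; downstream permutation p-values treat them as 1.
#'
#' @param d an [omics_dataset].
#' @param design an [npc_design] with a time-to-event outcome; at least 5
#'   events are required.
#' @return named numeric vector of Wald z statistics, one per feature.
#' @export
cox_z <- function(d, design) {
  stopifnot(inherits(d, "omics_dataset"), inherits(design, "npc_design"))
  pieces <- design_pieces(design, d$sample_ids)
  cox_z_engine(d$values, pieces)
}

cox_z_engine <- function(X, pieces) {
  if (pieces$type != "time_to_event") stopf("Cox engine requires a time-to-event outcome")
  time <- pieces$outcome$time
  status <- pieces$outcome$event
  if (sum(status) == 0) stopf("no events; Cox model undefined")
  if (sum(status) < 5) stopf("fewer than 5 events; Cox statistics unreliable")
  covs <- pieces$covariates
  z <- vapply(seq_len(nrow(X)), function(i) {
    Z <- cbind(feature = X[i, ], covs)
    fit <- cox_fit(Z, time, status)
    if (!fit$converged || !is.finite(fit$z[1L])) NaN else fit$z[1L]
  }, numeric(1))
  if (anyNA(z)) warnf("%d feature(s) did not converge; statistic set to NaN (p treated as 1)", sum(is.nan(z)))
  names(z) <- rownames(X)
  z
}

# Resolve an engine spec ("lm", "lm_moderated", "cox", or a function) to a
# worker f(X, pieces) -> statistic vector.
resolve_engine <- function(engine) {
  if (is.function(engine)) return(engine)
  switch(engine,
    lm = function(X, pieces) lm_t_engine(X, pieces, moderate = FALSE),
    lm_moderated = function(X, pieces) lm_t_engine(X, pieces, moderate = TRUE),
    cox = cox_z_engine,
    stopf("unknown engine '%s' (use 'lm', 'lm_moderated', 'cox', or a function)", engine)
  )
}
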