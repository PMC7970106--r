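#' Combining functions for partial p-values
#'
#' Maps a vector of per-omic p-values for one feature tuple to a single
#' combined statistic; larger values mean stronger joint evidence for every
#' method. Fisher (`-2 * sum(log(p))`) behaves intermediately; Liptak
#' (`sum(qnorm(1 - p))`) rewards consensus across omics; Tippett
#' (`max(1 - p)`) rewards a single strong signal. `NA` entries (absent tuple
#' sides) are dropped; at least one p-value must remain.
#'
#' @param pvals numeric vector of p-values in (0, 1]; `NA` = absent.
#' @param method `"fisher"`, `"liptak"`, or `"tippett"`.
#' @return the combined statistic (a single number).
#' @export
combine_pvalues <- function(pvals, method = c("fisher", "liptak", "tippett")) {
  method <- match.arg(method)
  p <- pvals[!is.na(pvals)]
  if (length(p) == 0L) stopf("no p-values to combine")
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  switch(method,
    fisher = -2 * sum(log(p)),
    liptak = sum(stats::qnorm(1 - p)),
    tippett = max(1 - p)
  )
}

# Vectorised combined statistics for a tuples x k matrix of p-values
# (NA = absent side). Returns one statistic per row.
combine_matrix <- function(P, method) {
  switch(method,
    fisher = {
      L <- -2 * log(P); L[is.na(P)] <- 0
      rowSums(L)
    },
    liptak = {
      Q <- stats::qnorm(1 - P); Q[is.na(P)] <- 0
      rowSums(Q)
    },
    tippett = {
      M <- 1 - P; M[is.na(P)] <- -Inf
      do.call(pmax, as.data.frame(M))
    },
    stopf("unknown combining method '%s'", method)
  )
}

#' Parametric combination of independent p-values
#'
#' Closed-form alternative to the permutation-based global p-value, valid
#' when the partial p-values are uniform and independent under the null (an
#' assumption that cross-omic correlation violates — expect anti-conservative
#' behaviour there, which is why it is recommended only for fast preliminary
#' exploration). Fisher: upper tail of a chi-square with `2k` degrees of
#' freedom at the combined statistic; Liptak: upper tail of Normal(0, k);
#' Tippett: `1 - (1 - p_min)^k`.
#'
#' @param P matrix (tuples x k) or vector of p-values in (0, 1]; `NA` =
#'   absent side.
#' @param method combining method.
#' @return numeric vector of global p-values, one per row of `P`.
#' @export
parametric_combination <- function(P, method = c("fisher", "liptak", "tippett")) {
  method <- match.arg(method)
  if (!is.matrix(P)) P <- matrix(P, nrow = 1L)
  if (any(P <= 0 | P > 1, na.rm = TRUE)) stopf("p-values must lie in (0, 1]")
  k <- rowSums(!is.na(P))
  if (any(k == 0L)) stopf("row with no p-values to combine")
  Tc <- combine_matrix(P, method)
  switch(method,
    fisher = stats::pchisq(Tc, df = 2 * k, lower.tail = FALSE),
    liptak = stats::pnorm(Tc, mean = 0, sd = sqrt(k), lower.tail = FALSE),
    tippett = {
      pmin_row <- 1 - Tc  # Tc = max(1 - p) so 1 - Tc = min p
      1 - (1 - pmin_row)^k
    }
  )
}
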