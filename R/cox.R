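# Cox proportional-hazards machinery (Breslow tie handling).
#
# Hand-rolled Newton solver so that per-feature Wald statistics under
# permutation are cheap and free of per-fit formula overhead; the survival
# package serves as an independent oracle in the test suite.

# Sufficient statistics at coefficient vector beta.
# Z: n x d covariate matrix; time/status as usual.
# Returns loglik, gradient (d), information (d x d).
cox_stats <- function(Z, time, status, beta) {
  n <- nrow(Z); d <- ncol(Z)
  ord <- order(time)
  Z <- Z[ord, , drop = FALSE]; time <- time[ord]; status <- status[ord]
  eta <- drop(Z %*% beta)
  eta <- eta - mean(eta)  # numeric stabilisation; partial likelihood is shift-invariant
  w <- exp(eta)

  revcumsum <- function(x) rev(cumsum(rev(x)))
  S0 <- revcumsum(w)
  S1 <- apply(w * Z, 2L, revcumsum)
  if (d == 1L) S1 <- matrix(S1, ncol = 1L)
  # upper-triangular pair products for the information matrix
  pairs <- which(upper.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
  S2 <- apply(pairs, 1L, function(ix) revcumsum(w * Z[, ix[1L]] * Z[, ix[2L]]))
  if (nrow(pairs) == 1L) S2 <- matrix(S2, ncol = 1L)

  # Breslow: risk set at a death time includes all tied observations;
  # map each index to the first index sharing its time.
  first <- match(time, time)

  ev <- which(status == 1)
  f <- first[ev]
  ll <- sum(eta[ev]) - sum(log(S0[f]))
  mu <- S1[f, , drop = FALSE] / S0[f]        # E[Z | risk set], per event
  grad <- colSums(Z[ev, , drop = FALSE] - mu)
  info <- matrix(0, d, d)
  for (j in seq_len(nrow(pairs))) {
    a <- pairs[j, 1L]; bcol <- pairs[j, 2L]
    val <- sum(S2[f, j] / S0[f] - mu[, a] * mu[, bcol])
    info[a, bcol] <- info[bcol, a] <- val
  }
  list(loglik = ll, grad = grad, info = info)
}

# Newton fit; returns beta, se, z, converged.
cox_fit <- function(Z, time, status, max_iter = 25L, tol = 1e-8) {
  d <- ncol(Z)
  beta <- rep(0, d)
  st <- cox_stats(Z, time, status, beta)
  ll <- st$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(st$info, st$grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    new_beta <- beta + step
    new_st <- cox_stats(Z, time, status, new_beta)
    halvings <- 0L
    while ((!is.finite(new_st$loglik) || new_st$loglik < ll - 1e-10) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_st <- cox_stats(Z, time, status, new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta; st <- new_st; ll <- st$loglik
    if (max(abs(st$grad)) < tol) { converged <- TRUE; break }
  }
  se <- tryCatch(sqrt(diag(solve(st$info))), error = function(e) rep(NA_real_, d))
  list(beta = beta, se = se, z = beta / se, converged = converged, loglik = ll)
}

# Univariate score (log-rank-type) test of `x` at beta = 0.
# Returns chi-square statistic (1 df) and p-value.
cox_score_test <- function(x, time, status) {
  st <- cox_stats(matrix(x, ncol = 1L), time, status, 0)
  stat <- drop(st$grad)^2 / drop(st$info)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}
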