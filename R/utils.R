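# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing stochastic functions route their randomness through this so
# that a seed argument never clobbers the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# rank-from-the-top p-values: p_j = #{k: s_k >= s_j} / length(s)
top_rank_p <- function(s) {
  n <- length(s)
  (n + 1L - rank(s, ties.method = "min")) / n
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated SVD as a rank-k reconstruction plus factors; k = 0 gives zeros.
svd_trunc <- function(X, k) {
  if (k == 0L) {
    return(list(
      approx = matrix(0, nrow(X), ncol(X), dimnames = dimnames(X)),
      u = matrix(0, nrow(X), 0L), d = numeric(0), v = matrix(0, ncol(X), 0L)
    ))
  }
  s <- svd(X, nu = k, nv = k)
  d <- s$d[seq_len(k)]
  approx <- s$u %*% (d * t(s$v))
  dimnames(approx) <- dimnames(X)
  list(approx = approx, u = s$u, d = d, v = s$v)
}

# Inverse of trigamma by Newton on log-scale (monotone decreasing function).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}
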