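# Shared fixtures and small oracles used across the suite.

# deterministic toy block
toy_block <- function(p = 6, n = 4, seed = 99, name = "toy") {
  set.seed(seed)
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("f%02d", seq_len(p)), sprintf("s%02d", seq_len(n))))
  omics_dataset(x, name = name)
}

two_group_meta <- function(n, seed = 1) {
  set.seed(seed)
  sample_metadata(sprintf("s%03d", seq_len(n)),
                  list(group = rep(c("g1", "g2"), length.out = n),
                       age = rnorm(n, 50, 8)))
}

# adjusted Rand index (independent scoring oracle for clustering tests)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  si <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  expected <- sr * sc / choose(n, 2)
  maximum <- (sr + sc) / 2
  (si - expected) / (maximum - expected)
}

# brute-force hypergeometric upper tail by direct summation
hyper_tail_oracle <- function(overlap, set_size, universe_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(vapply(ks, function(k) {
    exp(lchoose(set_size, k) + lchoose(universe_size - set_size, query_size - k) -
          lchoose(universe_size, query_size))
  }, numeric(1)))
}
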