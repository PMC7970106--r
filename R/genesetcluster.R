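#' Right-tailed Fisher exact over-representation test
#'
#' Tests whether a query gene list overlaps a gene set more than expected by
#' chance over a finite gene universe: the right tail of the hypergeometric
#' distribution at the observed overlap, equivalent to a one-sided Fisher
#' exact test on the 2x2 (in-query x in-set) table.
#'
#' @param query character vector of query genes (must lie in `universe`).
#' @param gene_set character vector of gene-set members; genes outside the
#'   universe are ignored.
#' @param universe character vector defining the gene universe.
#' @return the enrichment p-value.
#' @export
ora_fisher <- function(query, gene_set, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0L) stopf("empty query gene list")
  if (length(universe) == 0L) stopf("empty gene universe")
  if (!all(query %in% universe)) {
    stopf("query gene '%s' is not in the universe", setdiff(query, universe)[1L])
  }
  gs <- unique(as.character(gene_set))
  gs <- gs[gs %in% universe]
  ov <- length(intersect(query, gs))
  stats::phyper(ov - 1L, m = length(gs), n = length(universe) - length(gs),
                k = length(query), lower.tail = FALSE)
}

#' Attach ORA p-values to every set of a collection
#'
#' @param collection a [gene_set_collection].
#' @param query query gene list.
#' @param universe gene universe (default: union of collection genes and the
#'   query).
#' @param source_analysis label recorded on the returned sets.
#' @return the collection with `p_value` filled in per set.
#' @export
ora_collection <- function(collection, query, universe = NULL, source_analysis = "") {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- universe %||% union(unlist(lapply(collection$sets, `[[`, "genes")), query)
  sets <- lapply(collection$sets, function(s) {
    s$p_value <- ora_fisher(query, s$genes, universe)
    if (nzchar(source_analysis)) s$source_analysis <- source_analysis
    s
  })
  gene_set_collection(sets)
}

#' Filter gene sets on significance and size
#'
#' Retains sets with `p_value < alpha` (strict) and at least `min_genes`
#' genes — the eligibility rule applied before similarity clustering.
#'
#' @param collection a [gene_set_collection] whose sets carry p-values.
#' @param alpha significance threshold (strict `<`).
#' @param min_genes minimum gene count.
#' @return the filtered [gene_set_collection]; empty results are an error
#'   (relax the thresholds instead).
#' @export
filter_gene_sets <- function(collection, alpha = 0.05, min_genes = 3L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  keep <- vapply(collection$sets, function(s) {
    !is.na(s$p_value) && s$p_value < alpha && length(s$genes) >= min_genes
  }, logical(1))
  if (!any(keep)) {
    stopf("no gene set passes p < %g with >= %d genes; relax the thresholds", alpha, min_genes)
  }
  gene_set_collection(collection$sets[keep])
}

#' Pairwise relative-risk similarity of gene sets
#'
#' For sets A, B over a universe of size N, `RR(A,B) = |A n B| * N /
#' (|A| * |B|)`: observed gene co-membership relative to its expectation
#' under independence. The matrix is symmetric and nonnegative; disjoint
#' pairs score 0 and the diagonal equals `N / |A|`. An asymmetric
#' epidemiological variant (odds of membership in B given A vs given not-A,
#' 0.5 continuity correction for zero cells) is available with
#' `variant = "epidemiological"`; the symmetric ratio is the default because
#' clustering requires a symmetric similarity.
#'
#' @param collection a [gene_set_collection] with >= 2 sets.
#' @param universe gene universe (default: union of all member genes). Every
#'   member gene must lie in it.
#' @param variant `"symmetric"` (default) or `"epidemiological"`.
#' @return an object of class `rr_matrix`: `set_ids`, `values` (symmetric
#'   matrix for the default variant), `universe_size`.
#' @export
rr_matrix <- function(collection, universe = NULL,
                      variant = c("symmetric", "epidemiological")) {
  variant <- match.arg(variant)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) < 2L) stopf("need >= 2 gene sets")
  genes <- lapply(collection$sets, `[[`, "genes")
  universe <- unique(as.character(universe %||% unlist(genes)))
  outside <- setdiff(unlist(genes), universe)
  if (length(outside) > 0L) stopf("gene '%s' lies outside the universe", outside[1L])
  N <- length(universe)
  k <- length(genes)
  # membership indicator matrix makes all pairwise overlaps one crossprod
  M <- vapply(genes, function(g) universe %in% g, logical(N)) * 1
  ov <- crossprod(M)                      # |A n B|
  sizes <- diag(ov)
  vals <- if (variant == "symmetric") {
    ov * N / outer(sizes, sizes)
  } else {
    # P(B | A) / P(B | not A), with 0.5 correction applied to zero overlaps
    a <- ov
    a[a == 0] <- 0.5
    b <- outer(rep(1, k), sizes) - a      # |B \ A|
    num <- a / outer(sizes, rep(1, k))
    den <- b / (N - outer(sizes, rep(1, k)))
    num / den
  }
  dimnames(vals) <- list(set_ids(collection), set_ids(collection))
  structure(list(set_ids = set_ids(collection), values = vals,
                 universe_size = N, variant = variant),
            class = "rr_matrix")
}

#' @export
print.rr_matrix <- function(x, ...) {
  cat(sprintf("<rr_matrix> %d sets over a universe of %d genes (%s variant)\n",
              length(x$set_ids), x$universe_size, x$variant))
  invisible(x)
}

#' Cluster gene sets on their relative-risk profiles
#'
#' Rows of the RR matrix are the feature vectors, with the diagonal zeroed
#' first: the self-similarity `N / |set|` carries no pairwise information and
#' its magnitude (an artifact of set size) would otherwise dominate every
#' between-row distance. k-means is run with `n_init` seeded restarts. When `k` is not given, the number of clusters is chosen
#' by the gap statistic: for each candidate k the log within-cluster
#' dispersion is compared with its expectation under `n_ref` uniform
#' reference draws over the observed per-feature ranges, and the smallest k
#' with `Gap(k) >= Gap(k+1) - SE(k+1)` is selected.
#'
#' @param rr an [rr_matrix].
#' @param k fixed cluster count (optional; selected by gap statistic when
#'   `NULL`).
#' @param k_max largest candidate k (clamped below the set count with a
#'   warning if needed).
#' @param n_ref number of reference draws for the gap statistic.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param n_init random k-means restarts.
#' @return an object of class `cluster_assignment`: `set_ids`,
#'   `cluster_labels` (1..k, relabelled in order of first appearance), `k`,
#'   and `gap_curve` (data frame k / gap / se, `NULL` when `k` was fixed).
#' @export
cluster_rr <- function(rr, k = NULL, k_max = 10L, n_ref = 50L, seed = NULL,
                       n_init = 25L) {
  stopifnot(inherits(rr, "rr_matrix"))
  X <- rr$values
  diag(X) <- 0  # self-similarity is size-driven and uninformative for grouping
  ns <- nrow(X)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L || k > ns) stopf("k = %d outside 1..%d", k, ns)
  }
  if (k_max >= ns) {
    warnf("k_max = %d >= number of sets (%d); clamped to %d", k_max, ns, ns - 1L)
    k_max <- ns - 1L
  }
  k_max <- max(k_max, 1L)

  km_w <- function(X, kk) {
    if (kk == 1L) {
      ctr <- colMeans(X)
      list(cluster = rep(1L, nrow(X)), withinss = sum(sweep(X, 2L, ctr)^2))
    } else {
      fit <- stats::kmeans(X, centers = kk, nstart = n_init, iter.max = 50L)
      list(cluster = fit$cluster, withinss = sum(fit$withinss))
    }
  }

  res <- with_seed(seed, {
    gap_curve <- NULL
    if (is.null(k)) {
      ks <- seq_len(k_max)
      logW <- vapply(ks, function(kk) log(max(km_w(X, kk)$withinss, 1e-12)), numeric(1))
      rng_lo <- apply(X, 2L, min)
      rng_hi <- apply(X, 2L, max)
      logW_ref <- matrix(NA_real_, n_ref, length(ks))
      for (r in seq_len(n_ref)) {
        Xr <- sapply(seq_len(ncol(X)), function(j) stats::runif(ns, rng_lo[j], rng_hi[j]))
        if (!is.matrix(Xr)) Xr <- matrix(Xr, nrow = ns)
        logW_ref[r, ] <- vapply(ks, function(kk) log(max(km_w(Xr, kk)$withinss, 1e-12)), numeric(1))
      }
      gap <- colMeans(logW_ref) - logW
      se <- apply(logW_ref, 2L, stats::sd) * sqrt(1 + 1 / n_ref)
      gap_curve <- data.frame(k = ks, gap = gap, se = se)
      pick <- NA_integer_
      for (kk in ks[-length(ks)]) {
        if (gap[kk] >= gap[kk + 1L] - se[kk + 1L]) { pick <- kk; break }
      }
      k <- if (is.na(pick)) k_max else pick
    }
    fit <- km_w(X, k)
    list(cluster = fit$cluster, k = k, gap_curve = gap_curve)
  })

  # canonical labels: clusters numbered by order of first appearance
  labels <- match(res$cluster, unique(res$cluster))
  structure(list(set_ids = rr$set_ids,
                 cluster_labels = stats::setNames(labels, rr$set_ids),
                 k = res$k, gap_curve = res$gap_curve),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d sets in %d cluster(s): sizes %s\n",
              length(x$set_ids), x$k,
              paste(tabulate(x$cluster_labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Cross-analysis membership matrix
#'
#' For several labelled gene-set collections (e.g. single-omic vs
#' combination-derived enrichment runs), records which sets appear in which
#' analysis — the yes/no annotation used to read off which clusters are
#' discovered only through integration.
#'
#' @param collections named list of [gene_set_collection]s; names are the
#'   analysis labels and must be unique.
#' @return logical matrix, union of set ids (rows, in order of first
#'   appearance) x analysis labels (columns).
#' @export
cross_analysis_membership <- function(collections) {
  if (!is.list(collections) || length(collections) < 2L) stopf("need >= 2 labelled collections")
  labels <- names(collections)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    stopf("collections must carry unique, non-empty analysis labels")
  }
  lapply(collections, function(x) stopifnot(inherits(x, "gene_set_collection")))
  all_ids <- unique(unlist(lapply(collections, set_ids)))
  out <- vapply(collections, function(x) all_ids %in% set_ids(x), logical(length(all_ids)))
  if (!is.matrix(out)) out <- matrix(out, nrow = length(all_ids), dimnames = list(NULL, labels))
  rownames(out) <- all_ids
  out
}
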