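# core data model and I/O

test_that("omics matrix TSV round-trips and rejects malformed input", {
  d <- toy_block(10, 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(d, path)
  d2 <- read_omics_matrix(path, name = "toy")
  expect_equal(d2$values, d$values)
  expect_identical(d2$feature_ids, d$feature_ids)
  expect_identical(d2$sample_ids, d$sample_ids)

  # small fixture shape
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"), p3)
  expect_equal(dim(read_omics_matrix(p3)), c(3L, 2L))

  # duplicate feature id named in the error
  pd <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), pd)
  expect_error(read_omics_matrix(pd), "g1")

  # non-numeric cell pinpointed
  pn <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "g1\t1\tx", "g2\t3\t4"), pn)
  expect_error(read_omics_matrix(pn), "row 1")

  # empty matrix
  pe <- withr::local_tempfile(fileext = ".tsv")
  writeLines("feature_id\ts1", pe)
  expect_error(read_omics_matrix(pe), "empty")
})

test_that("missing values are rejected unless drop policy requested", {
  x <- matrix(c(1, NA, 3, 4), 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(omics_dataset(x), "missing value")
  expect_message(d <- omics_dataset(x, na_action = "drop_features"), "dropped 1 of 2")
  expect_identical(d$feature_ids, "f1")  # f2 holds the NA
})

test_that("align_common_samples intersects in a's order, errors on < 2 shared", {
  a <- toy_block(4, 3, seed = 1); colnames(a$values) <- a$sample_ids <- c("s1", "s2", "s3")
  b <- toy_block(5, 3, seed = 2); colnames(b$values) <- b$sample_ids <- c("s2", "s3", "s4")
  al <- align_common_samples(a, b)
  expect_identical(al$a$sample_ids, c("s2", "s3"))
  expect_identical(al$b$sample_ids, c("s2", "s3"))
  expect_equal(al$b$values, b$values[, c("s2", "s3")])

  # identical sets returned unchanged
  al2 <- align_common_samples(a, a)
  expect_identical(al2$a$values, a$values)
  expect_identical(al2$b$values, a$values)

  # disjoint errors
  c1 <- toy_block(4, 2, seed = 3); colnames(c1$values) <- c1$sample_ids <- c("x1", "x2")
  expect_error(align_common_samples(a, c1), "share 0")

  # idempotence
  al3 <- align_common_samples(al$a, al$b)
  expect_identical(al3$a$values, al$a$values)
})

test_that("center_and_frobenius_scale meets its contract", {
  # hand-derived: [[1,-1],[2,-2]] is centred, sum sq = 10
  x <- matrix(c(1, -1, 2, -2), 2, 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  s <- center_and_frobenius_scale(omics_dataset(x))
  expect_equal(s$values, x / sqrt(10))

  # constant rows become zero, block sum of squares is 1
  y <- rbind(x, f3 = c(5, 5))
  s2 <- center_and_frobenius_scale(omics_dataset(y))
  expect_equal(unname(s2$values["f3", ]), c(0, 0))
  expect_equal(sum(s2$values^2), 1, tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(s2$values))), 1e-10)

  # idempotent up to re-normalisation
  s3 <- center_and_frobenius_scale(s2)
  expect_equal(s3$values, s2$values, tolerance = 1e-10)

  # per-feature variant: nonzero rows to unit SS, zero rows stay zero
  s4 <- center_and_frobenius_scale(omics_dataset(y), per_feature = TRUE)
  expect_equal(unname(rowSums(s4$values^2)), c(1, 1, 0))

  # all-constant block cannot be scaled
  z <- matrix(3, 2, 3, dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  expect_error(center_and_frobenius_scale(omics_dataset(z)), "constant")
})

test_that("combine_mappings builds the gene-referenced cross product", {
  map_a <- data.frame(feature = "m1", gene = "G")
  map_b <- data.frame(feature = c("r1", "r2"), gene = c("G", "G"))
  fm <- combine_mappings(map_a, map_b)
  expect_equal(nrow(fm$tuples), 2L)
  expect_setequal(fm$tuples$feature_b, c("r1", "r2"))
  expect_true(all(fm$tuples$feature_a == "m1"))

  # retained singletons under retain_all
  fm2 <- combine_mappings(data.frame(feature = "m1", gene = "G1"),
                          data.frame(feature = "r1", gene = "G2"),
                          retain_all = TRUE)
  expect_equal(nrow(fm2$tuples), 2L)
  expect_true(any(is.na(fm2$tuples$feature_a)) && any(is.na(fm2$tuples$feature_b)))

  # same genes, retain_all = FALSE: no complete pairs
  expect_error(combine_mappings(data.frame(feature = "m1", gene = "G1"),
                                data.frame(feature = "r1", gene = "G2"),
                                retain_all = FALSE), "no tuples")

  # retain_all = TRUE never yields fewer tuples, and covers all mapped features
  set.seed(5)
  ma <- data.frame(feature = paste0("a", 1:20), gene = sample(paste0("G", 1:8), 20, replace = TRUE))
  mb <- data.frame(feature = paste0("b", 1:15), gene = sample(paste0("G", 3:12), 15, replace = TRUE))
  full <- combine_mappings(ma, mb, retain_all = TRUE)
  strict <- combine_mappings(ma, mb, retain_all = FALSE)
  expect_gte(nrow(full$tuples), nrow(strict$tuples))
  expect_true(all(ma$feature %in% full$tuples$feature_a))
  expect_true(all(mb$feature %in% full$tuples$feature_b))

  # mapping TSV round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_mapping(fm2, path)
  fm3 <- read_feature_mapping(path)
  expect_equal(fm3$tuples, fm2$tuples)
})

test_that("read_gmt parses, deduplicates and validates", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tA", "S2\tdesc2\tC\tD\tE", "S3\t\tA\tC"), p)
  coll <- read_gmt(p)
  expect_length(coll, 3L)
  expect_setequal(coll$sets[["S1"]]$genes, c("A", "B"))

  pe <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), pe)
  expect_error(read_gmt(pe), "empty")

  pb <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA", "S2\tonlydesc"), pb)
  expect_error(read_gmt(pb), "line 2")

  # round-trip
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, p2)
  expect_equal(as_gene_set_table(read_gmt(p2))[, c("set_id", "genes")],
               as_gene_set_table(coll)[, c("set_id", "genes")])
})

test_that("sample metadata types, round-trip and subsetting", {
  meta <- sample_metadata(
    c("s1", "s2", "s3"),
    list(group = c("a", "b", "a"), age = c(60, 55, 70),
         surv = list(time = c(5, 3, 8), event = c(1, 0, 1)))
  )
  expect_identical(unname(meta$types), c("categorical", "numeric", "time_to_event"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(meta, path)
  meta2 <- read_sample_metadata(path)
  expect_identical(meta2$types, meta$types)
  expect_equal(meta2$variables$surv, meta$variables$surv)
  expect_equal(meta2$variables$age, meta$variables$age)

  sub <- subset_samples(meta, c("s3", "s1"))
  expect_identical(sub$sample_ids, c("s3", "s1"))
  expect_equal(sub$variables$surv$time, c(8, 5))

  expect_error(sample_metadata("s1", list(surv = list(time = 0.0, event = 1))), "positive")
  expect_error(sample_metadata("s1", list(surv = list(time = 1, event = 2))), "0/1")
  expect_error(sample_metadata(c("s1", "s1"), list(a = 1:2)), "duplicate")
})
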