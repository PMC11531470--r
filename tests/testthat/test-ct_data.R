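test_that("wide and long dialects parse to the same validated matrix", {
  wide <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t20.0\t21.0", "g2\t19.5\tNA"), wide)
  x <- read_ct_table(wide, "wide")
  expect_s3_class(x, "ct_matrix")
  expect_equal(sum(is.na(x$ct)), 1L)
  expect_equal(x$ct["g1", "s2"], 21.0)

  # same records, shuffled long form
  long <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tsample\tct", "g2\ts2\tNA", "g1\ts2\t21.0",
               "g2\ts1\t19.5", "g1\ts1\t20.0"), long)
  y <- read_ct_table(long, "long")
  expect_equal(y$ct[c("g1", "g2"), c("s1", "s2")],
               x$ct[c("g1", "g2"), c("s1", "s2")])
})

test_that("'Undetermined' is read as missing, like NA", {
  f1 <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t20.0\tUndetermined", "g2\t19.5\t22.1"), f1)
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t20.0\tNA", "g2\t19.5\t22.1"), f2)
  # record-by-record reference parse of f1
  rec <- read.table(f1, sep = "\t", header = TRUE, colClasses = "character")
  ref <- suppressWarnings(matrix(as.numeric(as.matrix(rec[, -1])), 2, 2,
                                 dimnames = list(rec$gene, c("s1", "s2"))))
  expect_equal(read_ct_table(f1, "wide")$ct, ref)
  expect_equal(read_ct_table(f1, "wide")$ct, read_ct_table(f2, "wide")$ct)
})

test_that("format violations are rejected with located errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t20.0\t21.0", "g1\t19.5\t20.5"), f)
  expect_error(read_ct_table(f, "wide"), "duplicate gene")
  writeLines(c("gene\ts1\ts2", "g1\t20.0\toops", "g2\t19.5\t20.5"), f)
  expect_error(read_ct_table(f, "wide"), "row 2.*s2")
  m <- matrix(60, 1, 1, dimnames = list("g", "s"))
  expect_error(ct_matrix(m), "\\[0, 50\\]")
  expect_error(ct_matrix(matrix(20, 1, 1, dimnames = list("g", "s")),
                         efficiency = 2.5), "\\(1, 2\\]")
})

test_that("read -> write -> read round-trips bit-identically", {
  set.seed(7)
  m <- matrix(round(runif(12, 15, 35), 7), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  m[2, 3] <- NA
  x <- ct_matrix(m)
  for (dialect in c("wide", "long")) {
    f <- tempfile(fileext = ".tsv")
    write_ct_table(x, f, dialect)
    y <- read_ct_table(f, dialect)
    expect_identical(y$ct[rownames(m), colnames(m)], m)
  }
})

test_that("qc_filter matches a brute-force row scan and reports reasons", {
  meta <- qc_meta_fixture()
  res <- qc_filter(meta)
  # brute-force scan of the same rules
  kept <- c()
  for (i in seq_len(nrow(meta))) {
    ok <- meta$viability_pct[i] > 25 &&
      (meta$cohort[i] != "pdx" || meta$cd19_pct[i] > 60) &&
      meta$rna_quality_ok[i]
    if (ok) kept <- c(kept, meta$sample_id[i])
  }
  expect_setequal(res$kept, kept)
  reason_of <- function(id) res$excluded$reason[res$excluded$sample_id == id]
  expect_equal(reason_of("s02"), "viability")   # viability 20, cd19 90
  expect_equal(reason_of("s03"), "cd19")        # viable but cd19 55
  expect_equal(reason_of("s04"), "rna_quality") # passes gates, bad RNA
  # boundary: strict inequality at the threshold
  expect_true("s06" %in% res$excluded$sample_id)  # viability 24
  # a viable, CD19-high, RNA-ok PDX sample is kept under default thresholds
  expect_true("s01" %in% res$kept)
})

test_that("qc_filter is monotone in its thresholds", {
  meta <- qc_meta_fixture()
  base <- qc_filter(meta, 25, 60)$kept
  for (v in c(30, 50, 90)) {
    expect_true(all(qc_filter(meta, v, 60)$kept %in% base))
    expect_true(all(qc_filter(meta, 25, min(v + 30, 100))$kept %in% base))
  }
  expect_error(qc_filter(transform(meta, viability_pct = NA)),
               "missing viability")
})

test_that("subset is order-preserving and group_split partitions samples", {
  x <- random_ct(4, 6, seed = 1)
  expect_identical(subset_ct(x)$ct, x$ct)
  sub <- subset_ct(x, genes = c("g3", "g1"), samples = c("s5", "s2"))
  expect_equal(rownames(sub$ct), c("g3", "g1"))
  expect_equal(colnames(sub$ct), c("s5", "s2"))
  expect_error(subset_ct(x, genes = "nope"), "unknown gene")

  meta <- qc_meta_fixture()[1:6, ]
  meta$sample_id <- colnames(x$ct)
  parts <- group_split_ct(x, meta, "compartment")
  expect_setequal(names(parts), c("spleen", "bm"))
  expect_equal(ncol(parts$spleen$ct), 3)
  # disjoint and exhaustive
  all_samples <- unlist(lapply(parts, function(p) colnames(p$ct)))
  expect_setequal(all_samples, colnames(x$ct))
  expect_equal(anyDuplicated(all_samples), 0L)
})
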