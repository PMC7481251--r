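ann3 <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                       gene_id = c("gA", "gA", "gB"),
                       length = c(1000, 2000, 500))

test_that("weighted counting applies the 1/n rule and conserves reads", {
  aln <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    transcripts = list("t1", c("t1", "t2"), c("t1", "t2", "t3"))
  )
  wc <- weighted_counts(aln)
  expect_equal(setNames(wc$count, wc$transcript_id),
               c(t1 = 11 / 6, t2 = 5 / 6, t3 = 1 / 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(wc$count), 3, tolerance = 1e-12)

  expect_equal(weighted_counts(tibble::tibble(read_id = "r1",
                                              transcripts = list("t1")))$count,
               1)

  # reads with empty candidate lists are dropped, not counted
  aln$transcripts[[2]] <- character(0)
  expect_warning(wc2 <- weighted_counts(aln), "1 read")
  expect_equal(sum(wc2$count), 2, tolerance = 1e-12)

  expect_error(weighted_counts(aln[1, ], ann3[2:3, ]), "unknown transcripts")
})

test_that("TPM divides by length and normalizes to one million", {
  out <- tpm(tibble::tibble(transcript_id = c("t1", "t2"), count = c(10, 20)),
             ann3)
  expect_equal(out$tpm, c(500000, 500000), tolerance = 1e-9)

  single <- tpm(tibble::tibble(transcript_id = "t1", count = 3), ann3)
  expect_equal(single$tpm, 1e6)

  m <- matrix(rpois(12, 40), 3, dimnames = list(ann3$transcript_id,
                                                paste0("s", 1:4)))
  res <- tpm(m, ann3)
  expect_equal(unname(colSums(res)), rep(1e6, 4), tolerance = 1e-6)

  m[, 2] <- 0
  expect_warning(res0 <- tpm(m, ann3), "all-zero")
  expect_equal(unname(res0[, 2]), rep(0, 3))
  expect_identical(attr(res0, "degenerate_samples"), "s2")

  expect_error(tpm(matrix(1, dimnames = list("tX", "s")), ann3),
               "without annotated length")
})

test_that("gene aggregation sums transcript values and preserves totals", {
  m <- matrix(c(300000, 700000, 0, 250000, 250000, 500000), 3,
              dimnames = list(ann3$transcript_id, c("s1", "s2")))
  g <- aggregate_to_genes(m, ann3)
  expect_equal(g["gA", "s1"], 1e6)
  expect_equal(unname(colSums(g)), unname(colSums(m)))

  one_per_gene <- m[c("t1", "t3"), ]
  expect_equal(unname(aggregate_to_genes(one_per_gene, ann3)),
               unname(one_per_gene))

  rownames(m)[1] <- "unknown"
  expect_error(aggregate_to_genes(m, ann3), "without gene mapping")
})

test_that("expression filter keeps genes reaching threshold in enough samples", {
  # groups of size 6, 6 and 5: the minimum group size is 5
  design <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:17),
    condition = rep(c("A", "B", "C"), c(6, 6, 5))
  )
  m <- matrix(0, 3, 17, dimnames = list(c("kept", "dropped", "zero"),
                                        design$sample_id))
  m["kept", 1:5] <- 2      # >= 1 in exactly 5 samples -> kept
  m["dropped", 1:4] <- 2   # only 4 samples -> dropped
  es <- expression_set(m, design, unit = "counts")
  filtered <- filter_expressed(es, threshold = 1)
  expect_identical(rownames(filtered$values), "kept")

  # idempotence and the trivial threshold
  expect_identical(filter_expressed(filtered, 1)$values, filtered$values)
  expect_identical(nrow(filter_expressed(es, 0)$values), 3L)
})

test_that("log transform applies log2(x + 1) and retags the unit", {
  m <- matrix(c(0, 1, 1023, 7), 2, dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2")))
  es <- expression_set(m, tibble::tibble(sample_id = c("s1", "s2"),
                                         condition = c("A", "B")),
                       unit = "counts")
  es$unit <- "TPM"  # bypass column-sum check for this tiny fixture
  lt <- log_transform(es)
  expect_equal(unname(lt$values), matrix(c(0, 1, 10, 3), 2))
  expect_identical(lt$unit, "logTPM")
  expect_error(log_transform(lt), "TPM or CPM")
})

test_that("log fold changes are antisymmetric and match direct evaluation", {
  design <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                           condition = c("A", "A", "B", "B"))
  m <- matrix(c(10, 3, 10, 5, 5, 1, 5, 3), 2,
              dimnames = list(c("g1", "g2"), design$sample_id))
  es <- expression_set(m, design, unit = "counts")
  es$unit <- "TPM"  # use values as-is, no CPM renormalization

  ab <- log_fold_changes(es, c("A", "B"))
  expect_equal(ab$logFC[1], log2(11 / 6), tolerance = 1e-12)

  ba <- log_fold_changes(es, c("B", "A"))
  expect_equal(ab$logFC, -ba$logFC, tolerance = 1e-12)

  aa <- log_fold_changes(es, c("A", "A"))
  expect_equal(aa$logFC, c(0, 0))

  expect_error(log_fold_changes(es, c("A", "X")), "not in design")
})
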