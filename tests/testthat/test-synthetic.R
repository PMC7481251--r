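test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_expression(design_multimuscle(n = 2), n_genes = 100, seed = 5,
                           signature = planted_signature(5, 5))
  b <- simulate_expression(design_multimuscle(n = 2), n_genes = 100, seed = 5,
                           signature = planted_signature(5, 5))
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$truth$genes, b$truth$genes)

  c <- simulate_expression(design_multimuscle(n = 2), n_genes = 100, seed = 6,
                           signature = planted_signature(5, 5))
  expect_false(identical(a$data$values, c$data$values))

  t1 <- simulate_toy(seed = 3)
  t2 <- simulate_toy(seed = 3)
  expect_identical(t1$data$values, t2$data$values)
})

test_that("simulated TPM columns sum to one million", {
  sim <- simulate_expression(design_multimuscle(), n_genes = 500, seed = 1)
  expect_equal(unname(colSums(sim$data$values)),
               rep(1e6, ncol(sim$data$values)), tolerance = 1e-9)
  expect_identical(sim$data$unit, "TPM")
})

test_that("simulation rejects invalid specifications", {
  expect_error(simulate_expression(design_multimuscle(n = 1), n_genes = 100),
               "n >= 2")
  expect_error(simulate_expression(design_multimuscle(), n_genes = 5),
               "n_genes")
  expect_error(simulate_expression(design_multimuscle(), n_genes = 100,
                                   noise_sd = 0), "noise_sd")
  expect_error(planted_signature(genes = tibble::tibble(
    gene_id = c("g1", "g1"), direction = c(1, -1))), "overlap")
  expect_error(design_multimuscle(reversal = 2), "\\[-1, 1\\]")
})

test_that("the toy reduces to a rank-1 matrix in the noiseless limit", {
  toy <- simulate_toy(noise_sd = 0)
  G <- double_center(toy$data)
  fit <- suppressWarnings(pc_decompose(G))  # null genes have zero-norm rows
  expect_equal(fit$lambda[1], 1, tolerance = 1e-12)
  # PC1 direction proportional to (-1, -1, 2): only sample 3 differs
  v1 <- fit$V[, 1]
  expect_equal(abs(v1 / v1[3]), c(0.5, 0.5, 1), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("toy defaults plant exactly the stated significance pattern", {
  toy <- simulate_toy()
  fit <- pc_decompose(toy$data)
  expect_gt(fit$lambda[1], max(fit$lambda[-1]))
  sets <- aligned_genes(fit, 1)
  truth <- toy$truth
  called <- union(sets$up, sets$down)
  expect_setequal(called, truth$gene_id[truth$label != "null"])
  # up and down calls carry opposite signs of the planted shift
  expect_length(sets$up, 3)
  expect_length(sets$down, 3)
  expect_true(all(table(truth$label[match(sets$up, truth$gene_id)]) == 3))
})

test_that("pseudoalignment records conserve reads and recover unique counts", {
  ann <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                        gene_id = c("gA", "gA", "gB"),
                        length = c(500, 1000, 1500))
  counts <- c(t1 = 10, t2 = 5, t3 = 7)

  aln <- simulate_pseudoalignments(ann, counts, multimap_rate = 0, seed = 1)
  expect_equal(nrow(aln), sum(counts), ignore_attr = TRUE)
  wc <- weighted_counts(aln, ann)
  expect_equal(setNames(wc$count, wc$transcript_id), counts,
               tolerance = 1e-12, ignore_attr = TRUE)

  aln2 <- simulate_pseudoalignments(ann, counts, multimap_rate = 0.6, seed = 2)
  expect_equal(nrow(aln2), sum(counts), ignore_attr = TRUE)
  expect_true(any(lengths(aln2$transcripts) > 1))
  wc2 <- weighted_counts(aln2, ann)
  expect_equal(sum(wc2$count), sum(counts), tolerance = 1e-9)

  expect_error(simulate_pseudoalignments(ann, c(t1 = -1), seed = 1),
               "negative")
  expect_error(simulate_pseudoalignments(ann, counts, multimap_rate = 1.2),
               "multimap_rate")
})

test_that("alignment sensitivity is non-decreasing in effect size", {
  sens <- vapply(c(0.25, 0.5, 1.0), function(e) {
    sim <- simulate_expression(
      design_multimuscle(reversal = -1), n_genes = 800,
      signature = planted_signature(25, 25, effect_size = e), seed = 11
    )
    alignment_sensitivity(sim, "30mCON", "10mCON")$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gte(sens[3], 0.9)
})

test_that("a resolved signature plants the same genes in different designs", {
  sig <- resolve_signature(planted_signature(5, 5),
                           sprintf("g%04d", 1:100), seed = 2)
  a <- simulate_expression(design_multimuscle(n = 2), n_genes = 100,
                           signature = sig, seed = 1)
  b <- simulate_expression(design_premature_aging(n = 3), n_genes = 100,
                           signature = sig, seed = 9)
  expect_identical(a$truth$genes, b$truth$genes)
})
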