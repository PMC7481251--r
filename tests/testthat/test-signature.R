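make_sets <- function(universe, up, down, label = "") {
  signed_gene_sets(universe[up], universe[down], universe, label)
}

test_that("overlap fold and p match hand arithmetic and the summation oracle", {
  u <- sprintf("g%03d", 1:100)
  a <- make_sets(u, 1:20, 61:80)
  b <- make_sets(u, c(1:12, 31:48), 81:100)
  res <- signed_overlap_enrichment(a, b)

  up <- dplyr::filter(res, category == "concordant-up")
  expect_equal(up$observed, 12L)
  expect_equal(up$expected, 20 * 30 / 100)
  expect_equal(up$fold, 2)
  expect_equal(up$p_value, oracle_overlap_p(12, 20, 30, 100),
               tolerance = 1e-12)

  down <- dplyr::filter(res, category == "concordant-down")
  expect_equal(down$observed, 0L)
  expect_equal(down$p_value, oracle_overlap_p(0, 20, 20, 100),
               tolerance = 1e-12)
})

test_that("hypergeometric p agrees with explicit summation on small universes", {
  for (N in c(10, 25, 40, 60)) {
    u <- sprintf("g%03d", seq_len(N))
    set.seed(N)
    for (i in 1:10) {
      na <- sample(1:(N %/% 2), 1)
      nb <- sample(1:(N %/% 2), 1)
      a <- make_sets(u, sample(N, na), integer(0))
      b <- make_sets(u, sample(N, nb), integer(0))
      res <- dplyr::filter(signed_overlap_enrichment(a, b),
                           category == "concordant-up")
      expect_equal(res$p_value, oracle_overlap_p(res$observed, na, nb, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("a signature against itself gives maximal overlap", {
  u <- sprintf("g%03d", 1:100)
  a <- make_sets(u, 1:20, 41:60)
  self <- signed_overlap_enrichment(a, a)
  expect_equal(dplyr::filter(self, category == "concordant-up")$observed, 20L)
  expect_equal(dplyr::filter(self, category == "concordant-up")$fold,
               20 / (20 * 20 / 100))
  other <- make_sets(u, 61:80, 21:40)
  cross <- signed_overlap_enrichment(a, other)
  expect_true(all(dplyr::filter(self, category != "discordant")$fold >=
                    dplyr::filter(cross, category != "discordant")$fold,
                  na.rm = TRUE))
})

test_that("independent random sets have mean fold near one", {
  u <- sprintf("g%03d", 1:200)
  set.seed(77)
  folds <- replicate(400, {
    a <- make_sets(u, sample(200, 40), integer(0))
    b <- make_sets(u, sample(200, 40), integer(0))
    dplyr::filter(signed_overlap_enrichment(a, b),
                  category == "concordant-up")$fold
  })
  expect_equal(mean(folds), 1, tolerance = 0.05)
})

test_that("empty sets are flagged degenerate instead of failing", {
  u <- sprintf("g%03d", 1:50)
  a <- make_sets(u, 1:10, integer(0))
  b <- make_sets(u, 11:20, integer(0))
  res <- signed_overlap_enrichment(a, b)
  down <- dplyr::filter(res, category == "concordant-down")
  expect_true(down$degenerate)
  expect_true(is.na(down$fold))
  expect_equal(down$p_value, 1)
})

test_that("clustering splits well-separated profiles perfectly", {
  profiles <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    a = rep(c(0, 5), each = 5),
    b = rep(c(0, -5), each = 5)
  )
  cl <- cluster_profiles(profiles, k = 2)
  expect_identical(cl$cluster[1:5], rep(cl$cluster[1], 5))
  expect_identical(cl$cluster[6:10], rep(cl$cluster[6], 5))
  expect_false(cl$cluster[1] == cl$cluster[6])
})

test_that("planted clusters are recovered exactly and labels order by size", {
  set.seed(3)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, byrow = TRUE)
  sizes <- c(12, 7, 4)
  truth <- rep(1:3, sizes)
  mat <- centers[truth, ] + matrix(rnorm(2 * sum(sizes), sd = 0.5),
                                   ncol = 2)
  profiles <- tibble::tibble(gene_id = sprintf("g%02d", seq_len(sum(sizes))),
                             x = mat[, 1], y = mat[, 2])
  cl <- cluster_profiles(profiles, k = 3)
  # perfect agreement with the planted partition
  expect_equal(length(unique(paste(truth, cl$cluster))), 3L)
  # labels decrease with cluster size
  expect_equal(unname(as.vector(table(cl$cluster))), sizes)
  expect_identical(cl$cluster[1], 1L)
})

test_that("clustering is invariant to input row order", {
  set.seed(9)
  profiles <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                             a = rnorm(20), b = rnorm(20))
  cl1 <- cluster_profiles(profiles, k = 4)
  cl2 <- cluster_profiles(profiles[sample(20), ], k = 4)
  expect_identical(dplyr::arrange(cl1, gene_id), dplyr::arrange(cl2, gene_id))
  expect_error(cluster_profiles(profiles[c(1, 1, 2), ], k = 2), "duplicate")
  expect_error(cluster_profiles(profiles[1:3, ], k = 5), "fewer profiles")
})
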