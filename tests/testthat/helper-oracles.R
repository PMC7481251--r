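# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the decomposition oracle goes through the
# covariance eigendecomposition, the overlap oracle sums binomial
# coefficients directly, and the enrichment-score oracle walks the full
# ranked list position by position.

withr_tempfile <- function() tempfile(fileext = ".tsv")

# eigendecomposition of the m x m covariance matrix C = G'G/(n-1):
# variance fractions, projections and alignment calls, written plainly.
oracle_decompose <- function(G, z_threshold = 1.96, r_threshold = 0.4) {
  C <- crossprod(G) / (nrow(G) - 1)
  e <- eigen(C, symmetric = TRUE)
  lambda <- e$values / sum(e$values)
  P <- G %*% e$vectors
  z <- P
  for (j in seq_len(ncol(P))) {
    z[, j] <- (P[, j] - mean(P[, j])) / sd(P[, j])
  }
  norms <- sqrt(rowSums(P^2))
  norms[norms == 0] <- 1
  cosine <- P / norms
  aligned <- abs(z) >= z_threshold & abs(cosine) >= r_threshold
  dimnames(P) <- dimnames(z) <- dimnames(cosine) <- dimnames(aligned) <- NULL
  list(lambda = lambda, P = P, z = z, cosine = cosine, aligned = aligned)
}

random_centered_matrix <- function(n, m) {
  x <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:m)))
  double_center(x)
}

# two-tailed hypergeometric probability by explicit summation of
# choose() terms: universe N, set sizes m and k, observed overlap obs.
oracle_overlap_p <- function(obs, m, k, N) {
  x <- 0:min(m, k)
  pmf <- choose(m, x) * choose(N - m, k - x) / choose(N, k)
  lower <- sum(pmf[x <= obs])
  upper <- sum(pmf[x >= obs])
  min(1, 2 * min(lower, upper))
}

# enrichment score by walking every position of the ranked list and
# recording the running sum before and after each step.
oracle_es <- function(stats_sorted, hit_logical, weight = 1) {
  N <- length(stats_sorted)
  w <- unname(abs(stats_sorted)^weight)
  W <- sum(w[hit_logical])
  d <- 1 / (N - sum(hit_logical))
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit_logical[i]) w[i] / W else -d
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# rank-based sensitivity of an alignment against planted truth, used by
# several simulation tests
alignment_sensitivity <- function(sim, condition_a, condition_b,
                                  threshold = 1) {
  fit <- sim$data |>
    filter_expressed(threshold) |>
    log_transform() |>
    pc_decompose()
  pc <- find_condition_pc(fit, condition_a, condition_b)
  sets <- aligned_genes(fit, pc)
  called <- union(sets$up, sets$down)
  planted <- sim$truth$genes$gene_id
  list(
    sensitivity = length(intersect(called, planted)) / length(planted),
    fpr = length(setdiff(called, planted)) /
      (length(sets$universe) - length(planted)),
    sets = sets, fit = fit, pc = pc
  )
}
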