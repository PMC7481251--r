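#' Double-center an expression matrix
#'
#' Subtracts row means and column means (adding back the grand mean), so
#' every row sum and every column sum of the result is zero. This removes
#' gene-specific baselines and sample-specific offsets, leaving the
#' gene-by-sample interaction structure that the principal components
#' describe. Sequential column-then-row (or row-then-column) mean
#' subtraction yields the identical matrix.
#'
#' @param x A numeric matrix (genes x samples) or an [expression_set()]
#'   (typically logTPM).
#' @return The centered numeric matrix `G`.
#' @examples
#' double_center(matrix(c(1, 3, 2, 4), 2))  # purely additive: all zero
#' @export
double_center <- function(x) {
  if (inherits(x, "expression_set")) x <- x$values
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("missing values in matrix", call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least a 2 x 2 matrix", call. = FALSE)
  x - rowMeans(x) - rep(colMeans(x), each = nrow(x)) + mean(x)
}

#' Singular value decomposition of a centered expression matrix
#'
#' Factorizes the double-centered matrix `G = U D V^T` and derives
#' everything the alignment analysis needs: the principal components (the
#' columns of `V`, directions in sample space ordered by decreasing
#' variance), the variance fractions `lambda_j = d_j^2 / sum(d_i^2)`, the
#' gene projections `P = U D` (equal to `G V`), the per-PC projection
#' z-scores (computed across genes, sample standard deviation), and the
#' cosine correlation of each gene vector with each PC,
#' `cos_kj = P_kj / ||g_k||`.
#'
#' The sign of each PC is fixed deterministically: the entry of `V` with
#' the largest absolute value is made positive (ties broken by the earliest
#' sample index), so results are stable across platforms.
#'
#' Genes whose centered row is all zero have no direction; their z-scores
#' enter as-is but their cosines are set to 0 with a warning.
#'
#' @param x A centered matrix (from [double_center()]), an uncentered
#'   matrix, or an [expression_set()]; anything not yet centered is
#'   double-centered first.
#' @return An object of class `pc_fit` with elements `G`, `U`, `d`, `V`,
#'   `lambda`, `P`, `z`, `cosine`, `gene_ids`, `sample_ids` and (when the
#'   input was an `expression_set`) `design`.
#' @seealso [aligned_genes()], [alignment_table()], [find_condition_pc()]
#' @examples
#' toy <- simulate_toy()
#' fit <- pc_decompose(toy$data)
#' fit$lambda
#' @export
pc_decompose <- function(x) {
  design <- NULL
  if (inherits(x, "expression_set")) {
    design <- x$design
    x <- x$values
  }
  stopifnot(is.matrix(x))
  if (!all(is.finite(x))) stop("non-finite entries in matrix", call. = FALSE)
  scale_ <- max(1, max(abs(x)))
  centered <- max(abs(rowSums(x)), abs(colSums(x))) <= 1e-10 * scale_ * ncol(x)
  G <- if (centered) x else double_center(x)

  s <- svd(G)  # thin: U is n x m, V is m x m
  U <- s$u
  d <- s$d
  V <- s$v
  # deterministic sign convention: largest-|entry| coordinate of each PC positive
  for (j in seq_along(d)) {
    i <- which.max(abs(V[, j]))  # ties -> earliest index
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  lambda <- d^2 / sum(d^2)
  P <- U %*% diag(d, length(d))

  gene_ids <- rownames(G) %||% sprintf("row%d", seq_len(nrow(G)))
  sample_ids <- colnames(G) %||% sprintf("col%d", seq_len(ncol(G)))
  dimnames(P) <- list(gene_ids, paste0("PC", seq_along(d)))
  dimnames(V) <- list(sample_ids, paste0("PC", seq_along(d)))

  z <- projection_zscores(P)
  cosine <- projection_cosines(P)

  structure(list(G = G, U = U, d = d, V = V, lambda = lambda, P = P,
                 z = z, cosine = cosine,
                 gene_ids = gene_ids, sample_ids = sample_ids,
                 design = design),
            class = "pc_fit")
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf("<pc_fit> %d genes x %d samples\n",
              nrow(x$P), length(x$d)))
  k <- min(6, length(x$lambda))
  cat("variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$lambda[seq_len(k)]),
            collapse = ", "),
      if (length(x$lambda) > k) "...", "\n")
  invisible(x)
}

#' Per-PC z-scores of gene projections
#'
#' For each principal component, standardizes the gene projections across
#' all genes: `z_kj = (P_kj - mean_k P_kj) / sd_k(P_kj)` with the sample
#' (n-1) standard deviation. If a PC's projections are all equal (zero sd)
#' its z-scores are undefined and reported as 0 with a warning.
#'
#' @param P Projection matrix (genes x PCs), e.g. `pc_fit$P`.
#' @return Matrix of z-scores, same shape as `P`.
#' @export
projection_zscores <- function(P) {
  stopifnot(is.matrix(P), nrow(P) >= 2)
  mu <- colMeans(P)
  sd_ <- apply(P, 2, stats::sd)
  zero <- sd_ == 0
  if (any(zero)) {
    warning("zero projection spread on component(s) ",
            paste(which(zero), collapse = ", "), "; z set to 0", call. = FALSE)
    sd_[zero] <- 1
    P[, zero] <- mu[zero][col(P[, zero, drop = FALSE])]
  }
  sweep(sweep(P, 2, mu, "-"), 2, sd_, "/")
}

#' Cosine correlation of gene vectors with principal components
#'
#' `cos_kj = P_kj / ||g_k||` where `||g_k|| = sqrt(sum_l P_kl^2)` is the
#' norm of gene `k`'s centered expression vector. Because the PCs form an
#' orthonormal basis of the row space, `sum_j cos_kj^2 = 1` for every
#' nonzero gene. Zero-norm genes get cosine 0 with a warning.
#'
#' @param P Projection matrix (genes x PCs).
#' @return Matrix of cosines in `[-1, 1]`, same shape as `P`.
#' @export
projection_cosines <- function(P) {
  stopifnot(is.matrix(P))
  norm <- sqrt(rowSums(P^2))
  zero <- norm == 0
  if (any(zero)) {
    warning(sum(zero), " zero-norm gene row(s); cosine set to 0", call. = FALSE)
    norm[zero] <- 1
  }
  P / norm
}

#' Alignment table: gene-by-PC projections, z-scores and cosines
#'
#' @param fit A [pc_decompose()] fit.
#' @param z_threshold,r_threshold Alignment thresholds on `|z|` and
#'   `|cosine|` (defaults 1.96 and 0.4).
#' @return A tibble with one row per (gene, PC): `gene_id`, `pc`,
#'   `projection`, `z`, `cosine`, `aligned` (both thresholds met) and
#'   `sign` (+1/-1, the sign of the projection).
#' @export
alignment_table <- function(fit, z_threshold = 1.96, r_threshold = 0.4) {
  stopifnot(inherits(fit, "pc_fit"), z_threshold > 0, r_threshold > 0)
  m <- length(fit$d)
  tibble::tibble(
    gene_id = rep(fit$gene_ids, times = m),
    pc = rep(seq_len(m), each = length(fit$gene_ids)),
    projection = as.vector(fit$P),
    z = as.vector(fit$z),
    cosine = as.vector(fit$cosine)
  ) |>
    dplyr::mutate(
      aligned = abs(.data$z) >= z_threshold & abs(.data$cosine) >= r_threshold,
      sign = ifelse(.data$projection >= 0, 1, -1)
    )
}

#' Signed gene sets
#'
#' A pair of disjoint up/down gene-id sets with the universe they were
#' drawn from, used for overlap enrichment between signatures.
#'
#' @param up,down Character vectors of gene ids (disjoint).
#' @param universe Character vector containing all of `up` and `down`.
#' @param label Provenance label.
#' @return Object of class `signed_gene_sets`.
#' @export
signed_gene_sets <- function(up, down, universe, label = "") {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  universe <- unique(as.character(universe))
  if (length(intersect(up, down))) {
    stop("up and down sets overlap", call. = FALSE)
  }
  if (!all(c(up, down) %in% universe)) {
    stop("up/down sets are not contained in the universe", call. = FALSE)
  }
  structure(list(up = up, down = down, universe = universe, label = label),
            class = "signed_gene_sets")
}

#' @export
print.signed_gene_sets <- function(x, ...) {
  cat(sprintf("<signed_gene_sets>%s %d up / %d down of %d genes\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$up), length(x$down), length(x$universe)))
  invisible(x)
}

#' Genes aligned with a principal component
#'
#' Applies the two-threshold alignment rule on one PC: a gene joins the
#' up-set if `z >= z_threshold` and `cosine >= r_threshold`, and the
#' down-set if `z <= -z_threshold` and `cosine <= -r_threshold`. The
#' universe is every gene in the decomposition.
#'
#' @inheritParams alignment_table
#' @param pc Index of the principal component.
#' @param label Provenance label for the resulting sets.
#' @return A [signed_gene_sets()] object.
#' @export
aligned_genes <- function(fit, pc, z_threshold = 1.96, r_threshold = 0.4,
                          label = paste0("PC", pc)) {
  stopifnot(inherits(fit, "pc_fit"), z_threshold > 0, r_threshold > 0)
  if (pc < 1 || pc > length(fit$d)) {
    stop("`pc` out of range 1..", length(fit$d), call. = FALSE)
  }
  z <- fit$z[, pc]
  r <- fit$cosine[, pc]
  up <- fit$gene_ids[z >= z_threshold & r >= r_threshold]
  down <- fit$gene_ids[z <= -z_threshold & r <= -r_threshold]
  signed_gene_sets(up, down, fit$gene_ids, label = label)
}

#' Find the PC that separates two conditions
#'
#' Scans the PC sample coordinates (`V`) and returns the component along
#' which two condition groups are most strongly separated, measured by the
#' absolute two-sample t-statistic of the coordinates. In a multi-tissue
#' design, tissue identity dominates the leading PCs while a shared
#' condition (e.g. aging) axis appears further down; this helper locates it.
#'
#' @param fit A [pc_decompose()] fit carrying a design (decompose an
#'   [expression_set()] to keep it), or pass `design` explicitly.
#' @param condition_a,condition_b Condition labels to separate.
#' @param design Optional design tibble overriding the one stored in `fit`.
#' @return Integer PC index.
#' @export
find_condition_pc <- function(fit, condition_a, condition_b, design = NULL) {
  stopifnot(inherits(fit, "pc_fit"))
  design <- design %||% fit$design
  if (is.null(design)) stop("no design available", call. = FALSE)
  idx <- match(fit$sample_ids, design$sample_id)
  cond <- design$condition[idx]
  a <- cond == condition_a
  b <- cond == condition_b
  if (!any(a) || !any(b)) stop("conditions not found in design", call. = FALSE)
  tstat <- apply(fit$V, 2, function(v) {
    va <- v[a]; vb <- v[b]
    pooled <- sqrt(stats::var(va) / length(va) + stats::var(vb) / length(vb))
    if (pooled == 0) 0 else (mean(va) - mean(vb)) / pooled
  })
  unname(which.max(abs(tstat)))
}
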