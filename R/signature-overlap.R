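#' Signed overlap enrichment between two gene signatures
#'
#' Compares two [signed_gene_sets()] over their shared universe and reports
#' three categories: concordant-up (`A$up` vs `B$up`), concordant-down
#' (`A$down` vs `B$down`) and discordant (the pooled `A$up` vs `B$down` and
#' `A$down` vs `B$up` overlaps). Fold enrichment is observed over expected,
#' with `expected = |A| * |B| / |universe|`; the p-value is the two-tailed
#' hypergeometric probability (doubled smaller tail, capped at 1). The
#' discordant category pools two overlaps, whose null distribution is
#' computed as the convolution of the two hypergeometrics (treating them as
#' independent draws from the shared universe).
#'
#' Sets are restricted to the shared universe first. If either side of a
#' category is empty the fold is undefined; the row is returned with
#' `fold = NA`, `p_value = 1` and `degenerate = TRUE`.
#'
#' @param a,b [signed_gene_sets()] objects.
#' @return A tibble with columns `category`, `observed`, `expected`,
#'   `fold`, `p_value`, `degenerate`.
#' @examples
#' u <- sprintf("g%03d", 1:100)
#' a <- signed_gene_sets(u[1:20], u[51:70], u)
#' b <- signed_gene_sets(u[c(1:12, 31:48)], u[71:90], u)
#' signed_overlap_enrichment(a, b)
#' @export
signed_overlap_enrichment <- function(a, b) {
  stopifnot(inherits(a, "signed_gene_sets"), inherits(b, "signed_gene_sets"))
  universe <- intersect(a$universe, b$universe)
  if (!length(universe)) stop("shared universe is empty", call. = FALSE)
  restrict <- function(s) lapply(s[c("up", "down")], intersect, universe)
  a <- restrict(a)
  b <- restrict(b)
  N <- length(universe)

  row_for <- function(category, pairs) {
    obs <- sum(vapply(pairs, function(p) length(intersect(p[[1]], p[[2]])), 1L))
    sizes <- vapply(pairs, function(p) c(length(p[[1]]), length(p[[2]])),
                    numeric(2))
    expected <- sum(sizes[1, ] * sizes[2, ]) / N
    degenerate <- expected == 0
    if (degenerate) {
      return(tibble::tibble(category = category, observed = obs,
                            expected = expected, fold = NA_real_,
                            p_value = 1, degenerate = TRUE))
    }
    pmf <- overlap_null_pmf(sizes, N)
    lower <- sum(pmf[seq_len(obs + 1)])
    upper <- sum(pmf[(obs + 1):length(pmf)])
    p <- min(1, 2 * min(lower, upper))
    tibble::tibble(category = category, observed = obs, expected = expected,
                   fold = obs / expected, p_value = p, degenerate = FALSE)
  }

  dplyr::bind_rows(
    row_for("concordant-up", list(list(a$up, b$up))),
    row_for("concordant-down", list(list(a$down, b$down))),
    row_for("discordant", list(list(a$up, b$down), list(a$down, b$up)))
  )
}

# pmf of the (sum of) hypergeometric overlap(s); sizes is a 2 x k matrix of
# set sizes, N the universe size. k = 1 gives the plain hypergeometric.
overlap_null_pmf <- function(sizes, N) {
  pmf <- 1
  for (j in seq_len(ncol(sizes))) {
    m <- sizes[1, j]
    k <- sizes[2, j]
    x <- 0:min(m, k)
    pj <- stats::dhyper(x, m, N - m, k)
    out <- numeric(length(pmf) + length(pj) - 1)
    for (i in seq_along(pmf)) {
      idx <- i:(i + length(pj) - 1)
      out[idx] <- out[idx] + pmf[i] * pj
    }
    pmf <- out
  }
  pmf
}

#' Hierarchical clustering of fold-change profiles
#'
#' Groups genes by the Euclidean distance between their fold-change
#' profiles using agglomerative clustering (average linkage by default) and
#' cuts the tree into exactly `k` clusters. Rows are ordered by gene id
#' before clustering and clusters are relabeled by decreasing size (ties
#' broken by the lexicographically smallest member gene id), so the output
#' is deterministic and invariant to input order.
#'
#' @param profiles Tibble with a `gene_id` column and one numeric column
#'   per contrast (e.g. the output of [log_fold_changes()] with `by`).
#' @param k Number of clusters (>= 2).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A tibble `gene_id`, `cluster` (integer, 1 = largest cluster).
#' @export
cluster_profiles <- function(profiles, k = 10, linkage = "average") {
  profiles <- tibble::as_tibble(profiles)
  stopifnot("gene_id" %in% names(profiles), k >= 2)
  if (anyDuplicated(profiles$gene_id)) {
    stop("duplicate gene ids in profiles", call. = FALSE)
  }
  if (nrow(profiles) < k) stop("fewer profiles than clusters", call. = FALSE)
  profiles <- dplyr::arrange(profiles, .data$gene_id)
  mat <- as.matrix(profiles[setdiff(names(profiles), "gene_id")])
  if (!is.numeric(mat) || anyNA(mat)) {
    stop("profiles must be complete and numeric", call. = FALSE)
  }
  rownames(mat) <- profiles$gene_id
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"), method = linkage)
  raw <- stats::cutree(hc, k = k)
  # relabel by decreasing size, ties by smallest member id (rows are sorted)
  first_member <- match(seq_len(k), raw)
  ord <- order(-tabulate(raw, k), first_member)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  tibble::tibble(gene_id = profiles$gene_id, cluster = relabel[raw])
}
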