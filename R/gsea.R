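#' Pre-ranked gene set enrichment analysis
#'
#' The weighted Kolmogorov-Smirnov-like running-sum statistic: genes are
#' sorted by the ranking statistic in decreasing order (ties broken by gene
#' id); walking down the list, the running sum increases by
#' `|stat|^weight_exponent / sum_hits |stat|^weight_exponent` at gene-set
#' members and decreases by `1 / (N - N_hits)` elsewhere. The enrichment
#' score ES is the signed maximum deviation from zero. The null is built by
#' gene-label permutation: `n_permutations` random sets of the same size.
#' NES is ES divided by the mean `|ES|` of same-sign null scores, the
#' permutation p-value is the same-sign null exceedance fraction, and FDR
#' follows the standard positive/negative-null NES ratio (pooled across the
#' supplied sets). The leading edge counts members ranked at or before the
#' ES extremum for positive ES, and at or after it for negative ES.
#'
#' @param ranked Named numeric vector (gene id -> ranking statistic,
#'   typically a log fold change) or a tibble with columns `gene_id` and a
#'   single statistic column.
#' @param gene_sets A character vector of gene ids (one set) or a named
#'   list of such vectors. Members absent from `ranked` are ignored.
#' @param weight_exponent Exponent on `|stat|` in the hit increments;
#'   1 (default) is the classic weighted statistic, 0 gives the unweighted
#'   KS statistic (invariant to monotone transforms of the ranking).
#' @param n_permutations Number of gene-label permutations (>= 100).
#' @param seed Integer seed; required, so results are reproducible.
#' @return An object of class `gsea_result`; its `table` element (also
#'   returned by `tidy()`) has one row per set with `set`, `size`, `ES`,
#'   `NES`, `p_value`, `FDR`, `leading_edge_count`.
#' @examples
#' ranked <- c(g1 = 3, g2 = 2, g3 = 1, g4 = 0.5)
#' res <- preranked_gsea(ranked, list(top = c("g1", "g3")),
#'                       n_permutations = 100, seed = 1)
#' tidy(res)
#' @export
preranked_gsea <- function(ranked, gene_sets, weight_exponent = 1,
                           n_permutations = 1000, seed) {
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  if (is.data.frame(ranked)) {
    stopifnot("gene_id" %in% names(ranked), ncol(ranked) == 2)
    statcol <- setdiff(names(ranked), "gene_id")
    ranked <- stats::setNames(ranked[[statcol]], ranked$gene_id)
  }
  stopifnot(is.numeric(ranked), !is.null(names(ranked)))
  if (n_permutations < 100) stop("need n_permutations >= 100", call. = FALSE)
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  }

  # sort decreasing, ties by gene id for platform-stable output
  ord <- order(-ranked, names(ranked))
  stat <- ranked[ord]
  genes <- names(stat)
  N <- length(stat)
  absw <- abs(stat)^weight_exponent

  obs <- lapply(gene_sets, function(s) {
    hits <- sort(match(intersect(unique(s), genes), genes))
    if (!length(hits)) stop("gene set has no genes in the ranking", call. = FALSE)
    es <- running_es(hits, absw, N)
    c(list(hits = hits), es)
  })

  withr_seed(seed, {
    null_es <- lapply(obs, function(o) {
      h <- length(o$hits)
      vapply(seq_len(n_permutations), function(i) {
        running_es(sort(sample.int(N, h)), absw, N)$es
      }, numeric(1))
    })
  })

  rows <- purrr::map2(obs, null_es, function(o, nes_null) {
    same <- nes_null[sign(nes_null) == sign(o$es)]
    mean_same <- if (length(same)) mean(abs(same)) else NA_real_
    nes <- if (is.na(mean_same) || mean_same == 0) NA_real_ else o$es / mean_same
    p <- (1 + sum(abs(same) >= abs(o$es))) / (1 + length(same))
    tibble::tibble(size = length(o$hits), ES = o$es, NES = nes, p_value = p,
                   leading_edge_count = o$le_count)
  })
  table <- dplyr::bind_rows(rows, .id = "set")

  # pooled-null FDR on the NES scale (Subramanian et al. style)
  null_nes <- purrr::map2(null_es, table$NES, function(nes_null, obs_nes) {
    pos <- nes_null[nes_null > 0]
    neg <- nes_null[nes_null < 0]
    c(if (length(pos)) pos / mean(pos) else numeric(0),
      if (length(neg)) -neg / mean(-neg) * -1 else numeric(0))
  })
  pool <- unlist(null_nes, use.names = FALSE)
  table$FDR <- vapply(table$NES, function(nes) {
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num_null <- mean(pool >= nes & pool > 0)
      den_null <- mean(pool > 0)
      num_obs <- sum(table$NES >= nes, na.rm = TRUE)
      den_obs <- sum(table$NES > 0, na.rm = TRUE)
    } else {
      num_null <- mean(pool <= nes & pool < 0)
      den_null <- mean(pool < 0)
      num_obs <- sum(table$NES <= nes, na.rm = TRUE)
      den_obs <- sum(table$NES < 0, na.rm = TRUE)
    }
    if (den_null == 0 || den_obs == 0) return(0)
    min(1, (num_null / den_null) / (num_obs / den_obs))
  }, numeric(1))

  structure(list(table = table, ranked = stat,
                 hits = lapply(obs, `[[`, "hits"),
                 params = list(weight_exponent = weight_exponent,
                               n_permutations = n_permutations, seed = seed)),
            class = "gsea_result")
}

# running-sum enrichment score from sorted hit positions.
# absw: |stat|^alpha for ALL positions (length N); hits index into it.
running_es <- function(hits, absw, N) {
  h <- length(hits)
  if (h >= N) stop("gene set covers the whole ranking", call. = FALSE)
  w <- absw[hits]
  W <- sum(w)
  if (W == 0) stop("all ranking statistics in the set are zero", call. = FALSE)
  d <- 1 / (N - h)
  cw <- cumsum(w) / W
  at_hit <- cw - (hits - seq_len(h)) * d          # just after each hit
  before_hit <- c(0, cw[-h]) - (hits - seq_len(h)) * d  # just before each hit
  max_pos <- max(at_hit)
  min_neg <- min(before_hit, 0)
  if (max_pos >= -min_neg) {
    j <- unname(which.max(at_hit))
    list(es = unname(max_pos), le_count = j)
  } else {
    j <- unname(which.min(before_hit))
    list(es = unname(min_neg), le_count = h - j + 1L)
  }
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> %d set(s), %d permutations, seed %d\n",
              nrow(x$table), x$params$n_permutations, x$params$seed))
  print(x$table)
  invisible(x)
}

#' Screen signature clusters against a contrast ranking
#'
#' Runs [preranked_gsea()] for each cluster's gene set against a ranking
#' (typically the drug-vs-aged log fold changes) and flags clusters with
#' `FDR < fdr_threshold`. A cluster of aging-induced genes that is
#' significantly *negatively* enriched in the drug contrast indicates the
#' drug reverses that part of the signature.
#'
#' @param clusters Tibble `gene_id`, `cluster` (from [cluster_profiles()])
#'   or a named list of gene-id vectors.
#' @param ranked Ranking as in [preranked_gsea()].
#' @param fdr_threshold Significance threshold on the permutation FDR
#'   (default 0.01).
#' @inheritParams preranked_gsea
#' @return A `gsea_result` whose table has an extra logical `flagged`
#'   column.
#' @export
reversal_screen <- function(clusters, ranked, fdr_threshold = 0.01,
                            weight_exponent = 1, n_permutations = 1000, seed) {
  if (is.data.frame(clusters)) {
    stopifnot(all(c("gene_id", "cluster") %in% names(clusters)))
    clusters <- split(clusters$gene_id, paste0("cluster", clusters$cluster))
  }
  res <- preranked_gsea(ranked, clusters, weight_exponent = weight_exponent,
                        n_permutations = n_permutations, seed = seed)
  res$table$flagged <- !is.na(res$table$FDR) & res$table$FDR < fdr_threshold
  res
}
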