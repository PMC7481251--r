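#' Tidy a PC decomposition into the gene-by-PC alignment table
#'
#' @param x A [pc_decompose()] fit.
#' @param z_threshold,r_threshold Alignment thresholds used for the
#'   `aligned` column.
#' @param ... Unused.
#' @return The [alignment_table()] tibble.
#' @export
tidy.pc_fit <- function(x, z_threshold = 1.96, r_threshold = 0.4, ...) {
  alignment_table(x, z_threshold = z_threshold, r_threshold = r_threshold)
}

#' One-row summary of a PC decomposition
#'
#' @param x A [pc_decompose()] fit.
#' @param ... Unused.
#' @return A one-row tibble: gene and sample counts and the leading
#'   variance fractions.
#' @export
glance.pc_fit <- function(x, ...) {
  lam <- x$lambda
  out <- tibble::tibble(n_genes = nrow(x$P), n_samples = length(x$d))
  for (j in seq_len(min(5, length(lam)))) {
    out[[paste0("lambda", j)]] <- lam[j]
  }
  out
}

#' Tidy a GSEA result
#'
#' @param x A [preranked_gsea()] result.
#' @param ... Unused.
#' @return The per-set result tibble (`set`, `size`, `ES`, `NES`,
#'   `p_value`, `FDR`, `leading_edge_count`, and `flagged` when produced by
#'   [reversal_screen()]).
#' @export
tidy.gsea_result <- function(x, ...) x$table

#' @rdname tidy.gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(n_sets = nrow(x$table),
                 n_genes_ranked = length(x$ranked),
                 weight_exponent = x$params$weight_exponent,
                 n_permutations = x$params$n_permutations,
                 seed = x$params$seed)
}

#' Tidy a total-least-squares fit
#'
#' @param x A [tls_fit()] object.
#' @param ... Unused.
#' @return `tidy()`: a tibble of terms (slope, intercept); `glance()`: a
#'   one-row tibble with slope, intercept, Pearson r, the OLS slope for
#'   comparison, and n.
#' @export
tidy.tls_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @rdname tidy.tls_fit
#' @export
glance.tls_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 slope_ols = x$slope_ols, n = x$n, vertical = x$vertical)
}
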