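#' Plot sample coordinates of principal components
#'
#' Scatter of the PC sample coordinates (columns of `V`), one point per
#' sample, colored by condition when the fit carries a design — the
#' standard view for spotting which component separates conditions versus
#' tissues.
#'
#' @param object A [pc_decompose()] fit.
#' @param pcs Length-2 integer vector: which PCs to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_fit <- function(object, pcs = c(1, 2), ...) {
  stopifnot(length(pcs) == 2, all(pcs >= 1), all(pcs <= length(object$d)))
  df <- tibble::tibble(
    sample_id = object$sample_ids,
    x = object$V[, pcs[1]],
    y = object$V[, pcs[2]]
  )
  lab <- function(j) {
    sprintf("PC%d (%.1f%%)", j, 100 * object$lambda[j])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(object$design)) {
    df <- dplyr::left_join(df, object$design, by = "sample_id")
    aes_args <- list(colour = if ("condition" %in% names(df)) rlang::sym("condition"),
                     shape = if ("muscle" %in% names(df)) rlang::sym("muscle"))
    aes_args <- aes_args[!vapply(aes_args, is.null, TRUE)]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          !!!aes_args))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(pcs[1]), y = lab(pcs[2])) +
    ggplot2::theme_minimal()
}

#' Plot gene-PC alignment for one component
#'
#' Projection z-score against cosine correlation for every gene on one PC,
#' with the alignment thresholds drawn and aligned genes highlighted.
#'
#' @param fit A [pc_decompose()] fit.
#' @param pc PC index.
#' @param z_threshold,r_threshold Alignment thresholds.
#' @return A ggplot object.
#' @export
plot_alignment <- function(fit, pc, z_threshold = 1.96, r_threshold = 0.4) {
  stopifnot(inherits(fit, "pc_fit"))
  df <- tibble::tibble(
    gene_id = fit$gene_ids,
    z = fit$z[, pc],
    cosine = fit$cosine[, pc]
  ) |>
    dplyr::mutate(aligned = abs(.data$z) >= z_threshold &
                    abs(.data$cosine) >= r_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cosine, y = .data$z,
                                   colour = .data$aligned)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * z_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * r_threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = sprintf("cosine with PC%d", pc),
                  y = "projection z-score") +
    ggplot2::theme_minimal()
}

#' Enrichment plot for a GSEA result
#'
#' The classic running-sum curve with a rug of gene-set hit positions.
#'
#' @param object A [preranked_gsea()] result.
#' @param set Name of the set to draw (default: the first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsea_result <- function(object, set = NULL, ...) {
  set <- set %||% object$table$set[1]
  hits <- object$hits[[set]]
  N <- length(object$ranked)
  absw <- abs(object$ranked)^object$params$weight_exponent
  w <- absw[hits]
  W <- sum(w)
  d <- 1 / (N - length(hits))
  run <- numeric(N)
  run[hits] <- w / W + d
  run <- cumsum(run - d)
  df <- tibble::tibble(rank = seq_len(N), running_sum = run)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running_sum)) +
    ggplot2::geom_line(colour = "forestgreen") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_rug(data = tibble::tibble(rank = hits),
                      ggplot2::aes(x = .data$rank), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::labs(title = set, x = "rank in ordered list",
                  y = "running enrichment score") +
    ggplot2::theme_minimal()
}

#' Density-grid plot of a pairwise fold-change comparison
#'
#' Binned 2-D density of the paired fold changes with the
#' total-least-squares line (direction of highest variance) overlaid.
#'
#' @param object A [tls_fit()] object.
#' @param bins Bins per axis for [density_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tls_fit <- function(object, bins = 50, ...) {
  grid <- density_grid(object$x, object$y, bins = bins) |>
    dplyr::filter(.data$count > 0)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x_mid, y = .data$y_mid,
                                          fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey90", high = "black") +
    ggplot2::labs(x = "x log-fold change", y = "y log-fold change",
                  subtitle = sprintf("s = %.2f, i = %.2f, r = %.2f",
                                     object$slope, object$intercept,
                                     object$r)) +
    ggplot2::theme_minimal()
  if (!object$vertical) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  linetype = 2)
  }
  p
}
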