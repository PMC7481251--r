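#' Total-least-squares fit of paired fold-change vectors
#'
#' Fits the line along the direction of highest variance of the 2-D point
#' cloud: the slope is taken from the leading eigenvector of the 2x2
#' covariance matrix of `(x, y)` (orthogonal regression), and the line
#' passes through the centroid. Unlike ordinary least squares, swapping
#' `x` and `y` maps the slope to its reciprocal. The ordinary
#' least-squares slope is reported alongside for comparison, and the
#' Pearson correlation summarizes the association strength.
#'
#' If the leading eigenvector is vertical the slope is infinite and the
#' fit is flagged (`vertical = TRUE`).
#'
#' @param x,y Paired numeric vectors (same genes, same order), length >= 3,
#'   finite. Alternatively `x` may be a data frame whose first two numeric
#'   columns (after an optional `gene_id`) are used.
#' @return An object of class `tls_fit` with `slope`, `intercept`, `r`,
#'   `n`, `slope_ols`, `vertical`, and the data for plotting.
#' @examples
#' f <- tls_fit(c(0, 1, 2, 3), c(0.1, 2.1, 3.9, 6.1))
#' glance(f)
#' @export
tls_fit <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    num <- x[vapply(x, is.numeric, TRUE)]
    stopifnot(ncol(num) >= 2)
    y <- num[[2]]
    x <- num[[1]]
  }
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired points", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  C <- stats::cov(cbind(x, y))
  if (all(C == 0)) stop("zero variance in both coordinates", call. = FALSE)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  vertical <- v[1] == 0
  slope <- if (vertical) Inf else v[2] / v[1]
  intercept <- if (vertical) NA_real_ else mean(y) - slope * mean(x)
  r <- if (C[1, 1] == 0 || C[2, 2] == 0) 0 else stats::cor(x, y)
  slope_ols <- if (C[1, 1] == 0) NA_real_ else C[1, 2] / C[1, 1]
  structure(list(slope = slope, intercept = intercept, r = r,
                 n = length(x), slope_ols = slope_ols, vertical = vertical,
                 x = x, y = y),
            class = "tls_fit")
}

#' @export
print.tls_fit <- function(x, ...) {
  cat(sprintf("<tls_fit> s = %.4g, i = %.4g, r = %.3f, n = %d%s\n",
              x$slope, x$intercept, x$r, x$n,
              if (x$vertical) " (vertical)" else ""))
  invisible(x)
}

#' 2-D histogram of paired fold changes
#'
#' Counts points on an equal-width grid spanning the data range, the
#' binned representation used to draw pairwise fold-change density panels.
#' The counts always sum to the number of points.
#'
#' @param x,y Paired numeric vectors.
#' @param bins Number of bins per axis (>= 2).
#' @return A tibble with one row per grid cell: bin indices, cell
#'   midpoints and `count` (zero-count cells included).
#' @export
density_grid <- function(x, y, bins = 50) {
  stopifnot(length(x) == length(y), bins >= 2)
  edges <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  }
  ex <- edges(x)
  ey <- edges(y)
  ix <- pmin(findInterval(x, ex, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(y, ey, rightmost.closed = TRUE), bins)
  counts <- table(factor(ix, levels = seq_len(bins)),
                  factor(iy, levels = seq_len(bins)))
  tidyr::expand_grid(x_bin = seq_len(bins), y_bin = seq_len(bins)) |>
    dplyr::mutate(
      x_mid = (ex[.data$x_bin] + ex[.data$x_bin + 1]) / 2,
      y_mid = (ey[.data$y_bin] + ey[.data$y_bin + 1]) / 2,
      count = as.vector(counts[cbind(.data$x_bin, .data$y_bin)])
    )
}
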