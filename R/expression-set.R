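#' Expression set: a unit-tagged expression matrix with a sample design
#'
#' The basic data container of the package: a numeric feature-by-sample
#' matrix together with a design table mapping each sample to its group
#' (typically a muscle and a condition), and a unit tag recording the
#' normalization state of the values.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). No missing values allowed.
#' @param design A data frame with one row per sample. Must contain a
#'   `sample_id` column matching `colnames(values)`; typically also `muscle`
#'   and `condition` columns defining the experimental groups.
#' @param unit One of `"counts"`, `"CPM"`, `"TPM"`, `"logTPM"`. For `"TPM"`
#'   and `"CPM"` every column is expected to sum to 1e6 (checked with a
#'   relative tolerance of 1e-6; all-zero columns are tolerated but flagged
#'   as degenerate elsewhere).
#'
#' @return An object of class `expression_set`: a list with elements
#'   `values`, `design` (a tibble) and `unit`.
#' @examples
#' m <- matrix(c(5, 0, 995000, 999995, 1000000, 5000), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' es <- expression_set(m, data.frame(sample_id = c("s1", "s2"),
#'                                    condition = c("A", "B")), unit = "TPM")
#' es
#' @export
expression_set <- function(values, design, unit = c("counts", "CPM", "TPM", "logTPM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature rownames and sample colnames", call. = FALSE)
  }
  if (anyNA(values)) stop("`values` contains missing values", call. = FALSE)
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate feature ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  design <- tibble::as_tibble(design)
  if (!"sample_id" %in% names(design)) {
    stop("`design` must have a `sample_id` column", call. = FALSE)
  }
  if (!setequal(design$sample_id, colnames(values)) ||
      anyDuplicated(design$sample_id)) {
    stop("`design$sample_id` must match the matrix columns one-to-one", call. = FALSE)
  }
  design <- design[match(colnames(values), design$sample_id), ]
  if (unit %in% c("TPM", "CPM")) {
    cs <- colSums(values)
    bad <- cs > 0 & abs(cs - 1e6) > 1e-6 * 1e6
    if (any(bad)) {
      stop("columns tagged ", unit, " must sum to 1e6: ",
           paste(utils::head(colnames(values)[bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(values = values, design = design, unit = unit),
            class = "expression_set")
}

# internal constructor for derived sets (e.g. after gene filtering), where
# the unit tag records provenance but column sums need not be exact anymore
new_expression_set <- function(values, design, unit) {
  structure(list(values = values, design = design, unit = unit),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  grp <- setdiff(names(x$design), "sample_id")
  if (length(grp)) {
    tab <- do.call(paste, c(x$design[grp], sep = ":"))
    cat("groups:", paste(sprintf("%s (n=%d)", names(table(tab)), table(tab)),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Convert an expression set to a long tibble
#'
#' @param x An `expression_set`.
#' @param ... Unused.
#' @return A tibble with one row per (feature, sample) pair, the expression
#'   value, the unit and the design columns joined in.
#' @export
as_tibble.expression_set <- function(x, ...) {
  long <- tibble::tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id  = rep(colnames(x$values), each = nrow(x$values)),
    value      = as.vector(x$values),
    unit       = x$unit
  )
  dplyr::left_join(long, x$design, by = "sample_id")
}

# group key used for filtering / group means: all design columns except sample_id
design_groups <- function(es) {
  grp <- setdiff(names(es$design), c("sample_id", "signal"))
  if (!length(grp)) stop("design has no grouping columns", call. = FALSE)
  do.call(paste, c(es$design[grp], sep = ":"))
}
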