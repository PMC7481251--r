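#' Weighted read-to-transcript counting
#'
#' Assigns mapped reads to transcripts in a weighted manner: a uniquely
#' mapped read adds 1 to its transcript's count; a read compatible with
#' `n` transcripts adds `1/n` to each. The total of all counts therefore
#' equals the number of (valid) reads exactly. Reads with an empty
#' candidate list are dropped with a warning reporting how many.
#'
#' @param alignments Tibble with columns `read_id` and `transcripts`
#'   (a list column of candidate transcript ids, as produced by
#'   [simulate_pseudoalignments()] or [read_pseudoalignments_tsv()]).
#' @param annotation Optional annotation tibble; when given, every candidate
#'   transcript must be present in it.
#' @return A tibble with columns `transcript_id` and `count` (fractional
#'   counts allowed), sorted by transcript id.
#' @examples
#' aln <- tibble::tibble(read_id = c("r1", "r2", "r3"),
#'                       transcripts = list("t1", c("t1", "t2"),
#'                                          c("t1", "t2", "t3")))
#' weighted_counts(aln)  # t1 = 11/6, t2 = 5/6, t3 = 1/3
#' @export
weighted_counts <- function(alignments, annotation = NULL) {
  stopifnot(is.data.frame(alignments),
            all(c("read_id", "transcripts") %in% names(alignments)))
  k <- lengths(alignments$transcripts)
  if (any(k == 0)) {
    warning(sum(k == 0), " read(s) with empty transcript list dropped",
            call. = FALSE)
    alignments <- alignments[k > 0, ]
    k <- k[k > 0]
  }
  tx <- unlist(alignments$transcripts, use.names = FALSE)
  if (!is.null(annotation)) {
    annotation <- check_annotation(annotation)
    missing <- setdiff(unique(tx), annotation$transcript_id)
    if (length(missing)) {
      stop("alignments reference unknown transcripts: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  w <- rep(1 / k, times = k)
  out <- rowsum(w, tx)
  tibble::tibble(transcript_id = rownames(out), count = unname(out[, 1])) |>
    dplyr::arrange(.data$transcript_id)
}

check_annotation <- function(annotation) {
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("transcript_id", "gene_id", "length") %in% names(annotation)))
  if (anyDuplicated(annotation$transcript_id)) {
    stop("duplicate transcript ids in annotation", call. = FALSE)
  }
  if (any(annotation$length <= 0)) {
    stop("transcript lengths must be positive", call. = FALSE)
  }
  annotation
}

#' Transcripts-per-million from length-normalized counts
#'
#' Computes `t_i = (c_i / l_i) / sum_j(c_j / l_j) * 1e6` per sample: each
#' transcript's count is divided by its length and the column is normalized
#' to one million. Columns with no reads at all yield all-zero TPM and are
#' flagged as degenerate with a warning.
#'
#' @param counts Either a tibble with columns `transcript_id` and `count`
#'   (one sample) or a numeric matrix of counts, transcripts in rows and
#'   samples in columns.
#' @param annotation Annotation tibble with `transcript_id`, `gene_id`,
#'   `length` covering every counted transcript.
#' @return A tibble (`transcript_id`, `tpm`) for vector input, or a matrix of
#'   the same shape for matrix input. Every non-degenerate column sums to 1e6.
#' @examples
#' ann <- tibble::tibble(transcript_id = c("t1", "t2"), gene_id = c("gA", "gB"),
#'                       length = c(1000, 2000))
#' tpm(tibble::tibble(transcript_id = c("t1", "t2"), count = c(10, 20)), ann)
#' @export
tpm <- function(counts, annotation) {
  annotation <- check_annotation(annotation)
  if (is.data.frame(counts)) {
    stopifnot(all(c("transcript_id", "count") %in% names(counts)))
    mat <- matrix(counts$count, ncol = 1,
                  dimnames = list(counts$transcript_id, "sample"))
    res <- tpm(mat, annotation)
    return(tibble::tibble(transcript_id = rownames(res), tpm = unname(res[, 1])))
  }
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  len <- annotation$length[match(rownames(counts), annotation$transcript_id)]
  if (anyNA(len)) {
    stop("counted transcripts without annotated length: ",
         paste(utils::head(rownames(counts)[is.na(len)], 5), collapse = ", "),
         call. = FALSE)
  }
  rate <- counts / len
  tot <- colSums(rate)
  degenerate <- tot == 0
  if (any(degenerate)) {
    warning("all-zero sample(s): ",
            paste(colnames(counts)[degenerate], collapse = ", "), call. = FALSE)
    tot[degenerate] <- 1 # keeps the column zero
  }
  out <- sweep(rate, 2, tot, "/") * 1e6
  attr(out, "degenerate_samples") <- colnames(counts)[degenerate]
  out
}

#' Counts-per-million normalization
#'
#' @param counts Numeric matrix of (possibly fractional) counts.
#' @return Matrix of the same shape with every non-zero column scaled to sum
#'   to 1e6.
#' @export
cpm <- function(counts) {
  stopifnot(is.matrix(counts))
  tot <- colSums(counts)
  degenerate <- tot == 0
  if (any(degenerate)) {
    warning("all-zero sample(s): ",
            paste(colnames(counts)[degenerate], collapse = ", "), call. = FALSE)
    tot[degenerate] <- 1
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Aggregate transcript-level values to gene level
#'
#' Sums, within each sample, the values of all transcripts belonging to the
#' same gene. Valid for both TPM (normalized expression is additive over a
#' gene's transcripts) and raw counts.
#'
#' @param x Numeric matrix with transcript rownames, or an
#'   [expression_set()] at transcript level.
#' @param annotation Annotation tibble mapping every transcript to exactly
#'   one gene.
#' @return Object of the same kind as `x`, with gene rows.
#' @export
aggregate_to_genes <- function(x, annotation) {
  annotation <- check_annotation(annotation)
  if (inherits(x, "expression_set")) {
    out <- aggregate_to_genes(x$values, annotation)
    return(expression_set(out, x$design, unit = x$unit))
  }
  stopifnot(is.matrix(x))
  gene <- annotation$gene_id[match(rownames(x), annotation$transcript_id)]
  if (anyNA(gene)) {
    stop("transcripts without gene mapping: ",
         paste(utils::head(rownames(x)[is.na(gene)], 5), collapse = ", "),
         call. = FALSE)
  }
  rowsum(x, gene)
}

#' Filter genes by minimum expression in enough samples
#'
#' Keeps a gene if it reaches `threshold` (in the matrix's own unit,
#' typically 1 CPM or 1 TPM) in at least as many samples -- counted across
#' the whole matrix -- as the size of the smallest group in the design.
#' The filter is idempotent.
#'
#' @param es An [expression_set()].
#' @param threshold Expression threshold (default 1 unit).
#' @return The filtered `expression_set`.
#' @export
filter_expressed <- function(es, threshold = 1) {
  stopifnot(inherits(es, "expression_set"))
  groups <- design_groups(es)
  min_n <- min(table(groups))
  keep <- rowSums(es$values >= threshold) >= min_n
  new_expression_set(es$values[keep, , drop = FALSE], es$design,
                     unit = es$unit)
}

#' Log-transform a TPM matrix
#'
#' Applies `log2(TPM + 1)` and retags the unit as `logTPM`. The pseudocount
#' keeps zeros finite (the expression filter only guarantees non-zero
#' values in the smallest group's worth of samples).
#'
#' @param es An [expression_set()] in TPM (or CPM) units.
#' @return The transformed `expression_set` with unit `"logTPM"`.
#' @export
log_transform <- function(es) {
  stopifnot(inherits(es, "expression_set"))
  if (!es$unit %in% c("TPM", "CPM")) {
    stop("log transform expects TPM or CPM input, got ", es$unit, call. = FALSE)
  }
  if (any(es$values < 0)) stop("negative expression values", call. = FALSE)
  expression_set(log2(es$values + 1), es$design, unit = "logTPM")
}

#' Per-gene log fold changes between two conditions
#'
#' A simplified normalized-mean estimator:
#' `logFC = log2((mean_A + pseudocount) / (mean_B + pseudocount))` on
#' library-normalized values (counts are CPM-normalized first; TPM and CPM
#' are used as-is). Swapping the contrast negates every logFC.
#'
#' @param es An [expression_set()].
#' @param contrast Character vector `c(A, B)` of two condition labels; the
#'   result is A relative to B.
#' @param by Optional design column (e.g. `"muscle"`): compute the contrast
#'   separately within each level, returning one logFC column per level.
#' @param pseudocount Positive stabilizing constant (default 1).
#' @return A tibble with `gene_id` and either `logFC`, or one
#'   `logFC_<level>` column per `by` level.
#' @export
log_fold_changes <- function(es, contrast, by = NULL, pseudocount = 1) {
  stopifnot(inherits(es, "expression_set"), length(contrast) == 2,
            pseudocount > 0)
  if (!"condition" %in% names(es$design)) {
    stop("design lacks a `condition` column", call. = FALSE)
  }
  missing <- setdiff(contrast, es$design$condition)
  if (length(missing)) {
    stop("condition(s) not in design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- if (es$unit == "counts") cpm(es$values) else es$values

  one_contrast <- function(cols_a, cols_b) {
    ma <- rowMeans(vals[, cols_a, drop = FALSE])
    mb <- rowMeans(vals[, cols_b, drop = FALSE])
    unname(log2((ma + pseudocount) / (mb + pseudocount)))
  }

  if (is.null(by)) {
    lfc <- one_contrast(es$design$condition == contrast[1],
                        es$design$condition == contrast[2])
    return(tibble::tibble(gene_id = rownames(vals), logFC = lfc))
  }
  stopifnot(by %in% names(es$design))
  levels <- unique(es$design[[by]])
  out <- tibble::tibble(gene_id = rownames(vals))
  for (lv in levels) {
    in_lv <- es$design[[by]] == lv
    out[[paste0("logFC_", lv)]] <- one_contrast(
      in_lv & es$design$condition == contrast[1],
      in_lv & es$design$condition == contrast[2]
    )
  }
  out
}
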