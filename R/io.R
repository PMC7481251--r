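#' Read and write expression matrices as TSV
#'
#' The interchange format is plain TSV: the first column holds feature ids
#' (header `feature_id`), the remaining columns are samples. Values are
#' written with 17 significant digits, so a write/read round trip is
#' lossless to within double precision.
#'
#' @param path File path.
#' @param design Optional design table (or path to a design TSV) to attach,
#'   producing an [expression_set()]; without it a plain matrix is
#'   returned.
#' @param unit Unit tag for the resulting `expression_set`.
#' @return `read_expression_tsv()`: a numeric matrix, or an
#'   `expression_set` when a design is supplied. `write_expression_tsv()`:
#'   the input, invisibly.
#' @export
read_expression_tsv <- function(path, design = NULL,
                                unit = c("counts", "CPM", "TPM", "logTPM")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    stop("ragged row at line ", which(widths != widths[1])[1], " of ", path,
         call. = FALSE)
  }
  header <- cells[[1]]
  body <- cells[-1]
  ids <- vapply(body, `[[`, "", 1)
  if (anyDuplicated(ids)) {
    line <- which(duplicated(ids))[1] + 1
    stop("duplicate feature id '", ids[duplicated(ids)][1], "' at line ",
         line, call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(widths[1] - 1))
  )
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1] + 1
    stop("non-numeric cell at line ", bad, " of ", path, call. = FALSE)
  }
  mat <- t(matrix(vals, nrow = widths[1] - 1,
                  dimnames = list(header[-1], ids)))
  if (is.null(design)) return(mat)
  if (is.character(design)) design <- read_design_tsv(design)
  expression_set(mat, design, unit = unit)
}

#' @rdname read_expression_tsv
#' @param x A numeric matrix or an [expression_set()].
#' @export
write_expression_tsv <- function(x, path) {
  mat <- if (inherits(x, "expression_set")) x$values else x
  stopifnot(is.matrix(mat))
  header <- paste(c("feature_id", colnames(mat)), collapse = "\t")
  rows <- paste(rownames(mat),
                apply(mat, 1, function(r) {
                  paste(sprintf("%.17g", r), collapse = "\t")
                }),
                sep = "\t")
  write_atomic(c(header, rows), path)
  invisible(x)
}

#' Read and write sample design tables
#'
#' A design TSV has a header and one row per sample; the first column must
#' be `sample_id`, further columns (e.g. `muscle`, `condition`) define the
#' groups.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_design_tsv
#' @param design Design data frame.
#' @export
write_design_tsv <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(design)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#' Lines with fewer than three fields or empty member lists are rejected
#' with the offending line number; duplicated members within a line are
#' deduplicated with a warning.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors, with set
#'   descriptions in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) < 3)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], ": need name, description, members",
         call. = FALSE)
  }
  sets <- lapply(seq_along(cells), function(i) {
    members <- cells[[i]][-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop("empty member list at GMT line ", i, call. = FALSE)
    }
    if (anyDuplicated(members)) {
      warning("duplicated members in set '", cells[[i]][1],
              "' deduplicated", call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- vapply(cells, `[[`, "", 1)
  attr(sets, "descriptions") <- vapply(cells, `[[`, "", 2)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  write_atomic(lines, path)
  invisible(sets)
}

#' Read and write pseudoalignment records
#'
#' TSV with two columns and no header: a read id, and the comma-separated
#' ids of the transcripts the read is compatible with.
#'
#' @param path File path.
#' @return A tibble with `read_id` and a `transcripts` list column.
#' @export
read_pseudoalignments_tsv <- function(path) {
  lines <- readLines(path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != 2)
  if (length(bad)) {
    stop("malformed alignment record at line ", bad[1], call. = FALSE)
  }
  tibble::tibble(
    read_id = vapply(cells, `[[`, "", 1),
    transcripts = lapply(cells, function(r) {
      tx <- strsplit(r[2], ",", fixed = TRUE)[[1]]
      tx[nzchar(tx)]
    })
  )
}

#' @rdname read_pseudoalignments_tsv
#' @param alignments Tibble with `read_id` and `transcripts` list column.
#' @export
write_pseudoalignments_tsv <- function(alignments, path) {
  lines <- paste(alignments$read_id,
                 vapply(alignments$transcripts, paste, "", collapse = ","),
                 sep = "\t")
  write_atomic(lines, path)
  invisible(alignments)
}

# write lines to path atomically (tmp file + rename)
write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
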