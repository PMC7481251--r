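#' Design builders for the synthetic multi-muscle study
#'
#' These helpers build the design tibbles consumed by [simulate_expression()].
#' Each row is one experimental group with columns `muscle`, `condition`,
#' `n` (samples per group) and `signal`, the multiplier applied to the
#' planted signature's effect size in that group.
#'
#' `design_multimuscle()` emulates a multi-muscle aging/drug study: four
#' muscles (TA, TRI, GAS, SOL) by three conditions (adult controls `10mCON`,
#' aged controls `30mCON`, aged drug-treated `30mRM`) with six animals per
#' group. The aged condition carries the full aging signal scaled per muscle;
#' the treated condition carries `(1 + reversal) * scaling`, so
#' `reversal = -1` means the drug fully reverses the aging signature in that
#' muscle and positive values mean exacerbation. The defaults mirror the
#' biology the generator is meant to emulate: reversal in the drug-protected
#' fore/anterior muscles (TA, TRI) and mild exacerbation in the unprotected
#' posterior muscles (GAS, SOL).
#'
#' `design_premature_aging()` emulates a single-muscle (EDL) genetic model:
#' two genotypes by two ages with five animals per group, where only the
#' aged knockout carries the signature (wild types stay flat).
#'
#' `design_nmj()` emulates paired synaptic (NMJ) vs extra-synaptic (xNMJ)
#' regions at two ages, with the aging signal stronger in the synaptic
#' compartment.
#'
#' @param n Samples per group.
#' @param muscles Character vector of muscle labels.
#' @param reversal Named numeric in `[-1, 1]`, one entry per muscle: drug
#'   coefficient (negative = reversal, positive = exacerbation). A single
#'   unnamed value is recycled to all muscles.
#' @param scaling Named numeric, per-muscle multiplier of the aging effect.
#'   A single unnamed value is recycled.
#' @return A tibble with columns `muscle`, `condition`, `n`, `signal`.
#' @seealso [simulate_expression()], [planted_signature()]
#' @export
design_multimuscle <- function(n = 6,
                               muscles = c("TA", "TRI", "GAS", "SOL"),
                               reversal = c(TA = -1, TRI = -1, GAS = 0.5, SOL = 0.5),
                               scaling = 1) {
  reversal <- recycle_by_muscle(reversal, muscles, "reversal")
  scaling <- recycle_by_muscle(scaling, muscles, "scaling")
  if (any(reversal < -1 | reversal > 1)) {
    stop("`reversal` coefficients must lie in [-1, 1]", call. = FALSE)
  }
  tidyr::expand_grid(muscle = muscles,
                     condition = c("10mCON", "30mCON", "30mRM")) |>
    dplyr::mutate(
      n = n,
      signal = dplyr::case_when(
        .data$condition == "10mCON" ~ 0,
        .data$condition == "30mCON" ~ scaling[.data$muscle],
        .data$condition == "30mRM" ~ scaling[.data$muscle] *
          (1 + reversal[.data$muscle])
      )
    )
}

#' @rdname design_multimuscle
#' @export
design_premature_aging <- function(n = 5) {
  tibble::tibble(
    muscle = "EDL",
    condition = c("3mCON", "9mCON", "3mKO", "9mKO"),
    n = n,
    signal = c(0, 0, 0, 1)
  )
}

#' @rdname design_multimuscle
#' @param nmj_scaling Multiplier of the aging signal in the synaptic
#'   compartment relative to the extra-synaptic one.
#' @export
design_nmj <- function(n = 8, nmj_scaling = 2) {
  tidyr::expand_grid(muscle = c("NMJ", "xNMJ"),
                     condition = c("10m", "30m")) |>
    dplyr::mutate(
      n = n,
      signal = ifelse(.data$condition == "30m",
                      ifelse(.data$muscle == "NMJ", nmj_scaling, 1), 0)
    )
}

recycle_by_muscle <- function(x, muscles, what) {
  if (is.null(names(x))) {
    if (length(x) == 1) x <- stats::setNames(rep(x, length(muscles)), muscles)
    else if (length(x) == length(muscles)) names(x) <- muscles
    else stop("`", what, "` must be named by muscle or length 1", call. = FALSE)
  }
  if (!all(muscles %in% names(x))) {
    stop("`", what, "` misses muscles: ",
         paste(setdiff(muscles, names(x)), collapse = ", "), call. = FALSE)
  }
  x[muscles]
}

#' Planted differential-expression signature
#'
#' Describes the genes the simulator displaces along the latent aging axis:
#' `n_up` genes move up and `n_down` move down by `effect_size` (log2 units)
#' times the per-group `signal` multiplier of the design. Gene identities are
#' either chosen by the simulator (reproducibly, from its seed) or fixed
#' explicitly via `genes`, which allows the same signature to be planted in
#' several simulated datasets.
#'
#' @param n_up,n_down Number of up-/down-regulated planted genes.
#' @param effect_size Log2-scale displacement per unit of design `signal`;
#'   must be non-negative (0 yields a null dataset).
#' @param genes Optional tibble with columns `gene_id` and `direction`
#'   (+1/-1) pinning the planted genes explicitly.
#' @return An object of class `planted_signature`.
#' @export
planted_signature <- function(n_up = 50, n_down = 50, effect_size = 1,
                              genes = NULL) {
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  if (!is.null(genes)) {
    genes <- tibble::as_tibble(genes)
    stopifnot(all(c("gene_id", "direction") %in% names(genes)),
              all(genes$direction %in% c(-1, 1)))
    if (anyDuplicated(genes$gene_id)) {
      stop("planted up/down sets overlap: duplicated gene ids", call. = FALSE)
    }
  }
  structure(list(n_up = n_up, n_down = n_down, effect_size = effect_size,
                 genes = genes),
            class = "planted_signature")
}

#' Pin a signature's planted genes to a concrete gene universe
#'
#' Resolves a [planted_signature()] whose genes were left unspecified by
#' drawing its member genes from `gene_ids` under `seed`. Use this to plant
#' one and the same signature into several simulated datasets.
#'
#' @param signature A `planted_signature`.
#' @param gene_ids Character vector of available gene ids.
#' @param seed Integer seed for the draw.
#' @return The signature with an explicit `genes` tibble.
#' @export
resolve_signature <- function(signature, gene_ids, seed = 1) {
  stopifnot(inherits(signature, "planted_signature"))
  if (!is.null(signature$genes)) return(signature)
  k <- signature$n_up + signature$n_down
  if (k > length(gene_ids)) {
    stop("more planted genes than genes in the universe", call. = FALSE)
  }
  withr_seed(seed, {
    picked <- sample(gene_ids, k)
  })
  signature$genes <- tibble::tibble(
    gene_id = picked,
    direction = rep(c(1, -1), c(signature$n_up, signature$n_down))
  )
  signature
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a multi-group expression matrix with a planted signature
#'
#' Generates log2-scale expression as
#' `gene baseline + per-(gene, muscle) identity offset +
#' direction * effect_size * signal + Gaussian noise`, exponentiates and
#' rescales each sample to one million, so the returned matrix is in TPM
#' units. The per-group `signal` column of the design carries the latent
#' aging axis (and its modulation by a drug); see [design_multimuscle()].
#'
#' @param design Design tibble with columns `muscle`, `condition`, `n`,
#'   `signal` (see the design builders).
#' @param n_genes Number of genes.
#' @param signature A [planted_signature()]. Unresolved signatures are pinned
#'   to genes using `seed`.
#' @param noise_sd Standard deviation of the i.i.d. log2-scale noise (> 0).
#' @param baseline_log_mean,baseline_log_sd Location/spread of gene baseline
#'   log2 expression.
#' @param muscle_sd Standard deviation of the per-(gene, muscle) identity
#'   offsets; this is what makes muscle identity dominate the first principal
#'   components, as in real multi-muscle data.
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return A list with `data` (an [expression_set()] in TPM units, design
#'   columns `sample_id`, `muscle`, `condition`) and `truth` (planted gene
#'   table, the design with its signal column, effect size, noise, seed).
#' @examples
#' sim <- simulate_expression(design_multimuscle(n = 2), n_genes = 100,
#'                            signature = planted_signature(5, 5), seed = 1)
#' sim$data
#' head(sim$truth$genes)
#' @export
simulate_expression <- function(design, n_genes = 2000,
                                signature = planted_signature(),
                                noise_sd = 0.3,
                                baseline_log_mean = 5, baseline_log_sd = 2,
                                muscle_sd = 0.5, seed = 1) {
  design <- tibble::as_tibble(design)
  stopifnot(all(c("muscle", "condition", "n", "signal") %in% names(design)))
  if (any(design$n < 2)) stop("need n >= 2 samples per group", call. = FALSE)
  if (n_genes < 10) stop("need n_genes >= 10", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  key <- paste(design$muscle, design$condition)
  if (anyDuplicated(key)) stop("duplicate (muscle, condition) groups", call. = FALSE)

  gene_ids <- sprintf("g%0*d", max(4, nchar(n_genes)), seq_len(n_genes))
  signature <- resolve_signature(signature, gene_ids, seed)
  if (!all(signature$genes$gene_id %in% gene_ids)) {
    stop("planted gene ids are not a subset of the simulated genes", call. = FALSE)
  }

  samples <- design |>
    dplyr::rowwise() |>
    dplyr::reframe(muscle = .data$muscle, condition = .data$condition,
                   signal = .data$signal, rep = seq_len(.data$n)) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_%d", .data$muscle,
                                      .data$condition, .data$rep))
  m <- nrow(samples)
  muscles <- unique(design$muscle)

  withr_seed(seed, {
    baseline <- stats::rnorm(n_genes, baseline_log_mean, baseline_log_sd)
    offsets <- matrix(stats::rnorm(n_genes * length(muscles), 0, muscle_sd),
                      n_genes, length(muscles),
                      dimnames = list(gene_ids, muscles))
    noise <- matrix(stats::rnorm(n_genes * m, 0, noise_sd), n_genes, m)
  })

  logx <- baseline + offsets[, samples$muscle, drop = FALSE] + noise
  idx <- match(signature$genes$gene_id, gene_ids)
  shift <- signature$genes$direction * signature$effect_size
  logx[idx, ] <- logx[idx, ] +
    outer(shift, samples$signal)
  dimnames(logx) <- list(gene_ids, samples$sample_id)

  tpm <- 2^logx
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6

  data <- expression_set(
    tpm,
    samples[, c("sample_id", "muscle", "condition")],
    unit = "TPM"
  )
  truth <- list(genes = signature$genes, design = design,
                effect_size = signature$effect_size,
                noise_sd = noise_sd, seed = seed)
  list(data = data, truth = truth)
}

#' Simulate the 26-gene, 3-sample toy illustration
#'
#' A small fixture illustrating the gene-PC alignment geometry: `n_null`
#' genes share a common expected level across all samples, while `n_up`
#' (`n_down`) genes are shifted up (down) by `effect_size` in the last
#' sample only. On the double-centered matrix, the displaced genes line up
#' with the first principal component, whose sample coordinates are
#' proportional to `(-1, -1, 2)`.
#'
#' With 6 signal genes among 26, the planted genes dominate the projection
#' spread themselves, capping their attainable projection z-score at
#' `5/sqrt(6) ~ 2.04` -- barely above the 1.96 alignment threshold. The
#' default noise is therefore kept small so the planted significance pattern
#' holds by construction; see the methods vignette.
#'
#' @param n_null,n_up,n_down Gene counts per class (defaults 20/3/3).
#' @param n_samples Number of samples (the last one carries the shift).
#' @param effect_size Shift applied in the last sample (log2 units).
#' @param noise_sd Per-cell Gaussian noise; 0 gives the exact rank-1 limit.
#' @param seed Integer seed.
#' @return List with `data` (an [expression_set()], log-scale) and `truth`
#'   (tibble of gene labels: `"null"`, `"up"` or `"down"`).
#' @export
simulate_toy <- function(n_null = 20, n_up = 3, n_down = 3, n_samples = 3,
                         effect_size = 2, noise_sd = 0.02, seed = 7) {
  stopifnot(n_null >= 0, n_up >= 0, n_down >= 0, n_samples >= 2,
            effect_size >= 0, noise_sd >= 0)
  n_genes <- n_null + n_up + n_down
  gene_ids <- sprintf("gene%02d", seq_len(n_genes))
  label <- rep(c("null", "up", "down"), c(n_null, n_up, n_down))
  sample_ids <- sprintf("S%d", seq_len(n_samples))

  withr_seed(seed, {
    mu <- stats::rnorm(n_genes, 5, 1)
    noise <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                    n_genes, n_samples)
  })
  x <- mu + noise
  shift <- ifelse(label == "up", effect_size,
                  ifelse(label == "down", -effect_size, 0))
  x[, n_samples] <- x[, n_samples] + shift
  dimnames(x) <- list(gene_ids, sample_ids)

  data <- expression_set(
    x,
    tibble::tibble(sample_id = sample_ids, condition = sample_ids),
    unit = "logTPM"
  )
  list(data = data, truth = tibble::tibble(gene_id = gene_ids, label = label))
}

#' Simulate pseudoalignment records with controllable multi-mapping
#'
#' Emits one record per read. With probability `multimap_rate` a read lists
#' two or three candidate transcripts (its true transcript plus decoys drawn
#' from the annotation); otherwise it maps uniquely. Used to exercise the
#' weighted read-to-transcript assignment rule.
#'
#' @param annotation Tibble with columns `transcript_id`, `gene_id`,
#'   `length`.
#' @param true_counts Named integer vector (or tibble with `transcript_id`,
#'   `count`) of reads truly originating from each transcript.
#' @param multimap_rate Probability in `[0, 1]` that a read multi-maps.
#' @param seed Integer seed.
#' @return A tibble with columns `read_id` and `transcripts` (list column of
#'   candidate transcript ids); `nrow` equals `sum(true_counts)`.
#' @export
simulate_pseudoalignments <- function(annotation, true_counts,
                                      multimap_rate = 0.2, seed = 1) {
  annotation <- check_annotation(annotation)
  if (is.data.frame(true_counts)) {
    true_counts <- stats::setNames(true_counts$count, true_counts$transcript_id)
  }
  if (any(true_counts < 0)) stop("negative read counts", call. = FALSE)
  if (multimap_rate < 0 || multimap_rate > 1) {
    stop("`multimap_rate` must be in [0, 1]", call. = FALSE)
  }
  if (!all(names(true_counts) %in% annotation$transcript_id)) {
    stop("counts refer to transcripts absent from the annotation", call. = FALSE)
  }
  true_counts <- true_counts[true_counts > 0]
  origin <- rep(names(true_counts), times = true_counts)
  n_reads <- length(origin)
  all_tx <- annotation$transcript_id

  withr_seed(seed, {
    multi <- stats::runif(n_reads) < multimap_rate
    candidates <- lapply(seq_len(n_reads), function(i) {
      if (!multi[i] || length(all_tx) < 2) return(origin[i])
      n_extra <- sample(1:2, 1)
      decoys <- sample(setdiff(all_tx, origin[i]),
                       min(n_extra, length(all_tx) - 1))
      sort(c(origin[i], decoys))
    })
  })

  tibble::tibble(
    read_id = sprintf("r%0*d", max(6, nchar(n_reads)), seq_len(n_reads)),
    transcripts = candidates
  )
}
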