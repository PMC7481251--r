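#' Default configuration for the synthetic end-to-end analysis
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param n_genes,n_per_group,effect_size,noise_sd Simulation parameters
#'   (see [simulate_expression()] and [planted_signature()]).
#' @param reversal Per-muscle drug coefficient passed to
#'   [design_multimuscle()].
#' @param z_threshold,r_threshold Alignment thresholds.
#' @param cluster_k,linkage Clustering parameters.
#' @param gsea_permutations Permutations for the GSEA stages.
#' @param filter_threshold,filter_unit Expression filter settings.
#' @param out_dir Optional output directory; when set, stage outputs are
#'   written as TSV.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1, n_genes = 2000, n_per_group = 6,
                            effect_size = 1, noise_sd = 0.3,
                            reversal = c(TA = -1, TRI = -1, GAS = 0.5, SOL = 0.5),
                            z_threshold = 1.96, r_threshold = 0.4,
                            cluster_k = 10, linkage = "average",
                            gsea_permutations = 1000,
                            filter_threshold = 1, filter_unit = "TPM",
                            out_dir = NULL) {
  as.list(environment())
}

validate_config <- function(config) {
  required <- c("seed", "n_genes", "n_per_group", "effect_size", "noise_sd",
                "reversal", "z_threshold", "r_threshold", "cluster_k",
                "linkage", "gsea_permutations", "filter_threshold",
                "filter_unit")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$seed)) stop("a seed is required", call. = FALSE)
  stopifnot(config$z_threshold > 0, config$r_threshold > 0,
            config$cluster_k >= 2, config$gsea_permutations >= 100)
  invisible(config)
}

#' Run the full synthetic signature analysis
#'
#' Executes the pipeline end to end on simulated data: (1) simulate a
#' multi-muscle aging/drug dataset and a single-muscle premature-aging
#' dataset sharing one planted signature; (2) filter, log-transform,
#' double-center and decompose both; (3) locate the aging PC in each and
#' call aligned genes, scoring sensitivity and false-positive rate against
#' the planted truth; (4) signed overlap enrichment between the two aligned
#' signatures; (5) hierarchical clustering of the aligned genes'
#' fold-change profiles; (6) GSEA of the clusters against the drug-contrast
#' ranking (reversal screen); (7) total-least-squares fits of pairwise
#' per-muscle aging fold changes.
#'
#' @param config A list from [pipeline_config()], or a path to a YAML file
#'   with the same fields.
#' @return A list with `results` (per-stage objects and summary numbers)
#'   and `manifest` (a tibble of stage output hashes plus the config hash,
#'   package version and timestamp). Re-running with an identical config
#'   reproduces identical hashes.
#' @examples
#' \donttest{
#' out <- run_pipeline(pipeline_config(seed = 1, n_genes = 500,
#'                                     gsea_permutations = 100))
#' out$results$recovery
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is needed to read YAML configs", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
    config$reversal <- unlist(config$reversal)
  }
  validate_config(config)
  n_warn <- 0L
  withCallingHandlers({
    out <- run_pipeline_impl(config)
  }, warning = function(w) {
    n_warn <<- n_warn + 1L
    invokeRestart("muffleWarning")
  })
  out$manifest$warnings <- n_warn
  out
}

run_pipeline_impl <- function(config) {
  stages <- list()
  note <- function(name, obj) stages[[name]] <<- rlang::hash(obj)

  # --- stage 1: simulation, one signature planted in both datasets --------
  signature <- resolve_signature(
    planted_signature(effect_size = config$effect_size),
    sprintf("g%0*d", max(4, nchar(config$n_genes)), seq_len(config$n_genes)),
    seed = config$seed
  )
  sim_mm <- simulate_expression(
    design_multimuscle(n = config$n_per_group, reversal = config$reversal),
    n_genes = config$n_genes, signature = signature,
    noise_sd = config$noise_sd, seed = config$seed
  )
  sim_pa <- simulate_expression(
    design_premature_aging(),
    n_genes = config$n_genes, signature = signature,
    noise_sd = config$noise_sd, seed = config$seed + 1L
  )
  note("simulate", list(sim_mm$data$values, sim_pa$data$values))

  # --- stage 2: filter, log, decompose ------------------------------------
  prep <- function(sim) {
    sim$data |>
      filter_expressed(threshold = config$filter_threshold) |>
      log_transform() |>
      pc_decompose()
  }
  fit_mm <- prep(sim_mm)
  fit_pa <- prep(sim_pa)
  note("decompose", list(fit_mm$lambda, fit_pa$lambda))

  # --- stage 3: aging-PC alignment and recovery vs truth ------------------
  pc_mm <- find_condition_pc(fit_mm, "30mCON", "10mCON")
  pc_pa <- find_condition_pc(fit_pa, "9mKO", "3mKO")
  sets_mm <- aligned_genes(fit_mm, pc_mm, config$z_threshold,
                           config$r_threshold, label = "natural aging")
  sets_pa <- aligned_genes(fit_pa, pc_pa, config$z_threshold,
                           config$r_threshold, label = "premature aging")
  recovery <- score_recovery(sets_mm, sim_mm$truth$genes)
  note("align", list(sets_mm$up, sets_mm$down, sets_pa$up, sets_pa$down))

  # --- stage 4: cross-dataset signed overlap ------------------------------
  overlap <- signed_overlap_enrichment(sets_mm, sets_pa)
  note("overlap", overlap)

  # --- stage 5: fold-change profiles and clustering -----------------------
  filtered <- filter_expressed(sim_mm$data, config$filter_threshold) |>
    log_transform()
  profiles <- dplyr::inner_join(
    log_fold_changes(filtered, c("30mCON", "10mCON"), by = "muscle"),
    log_fold_changes(filtered, c("30mRM", "30mCON"), by = "muscle"),
    by = "gene_id", suffix = c(".aging", ".drug")
  )
  aligned_all <- union(sets_mm$up, sets_mm$down)
  clusters <- cluster_profiles(
    dplyr::filter(profiles, .data$gene_id %in% aligned_all),
    k = min(config$cluster_k, length(aligned_all) - 1),
    linkage = config$linkage
  )
  note("cluster", clusters)

  # --- stage 6: reversal screen (GSEA of clusters vs drug ranking) --------
  drug_lfc <- log_fold_changes(filtered, c("30mRM", "30mCON"))
  ranking <- stats::setNames(drug_lfc$logFC, drug_lfc$gene_id)
  gsea <- reversal_screen(clusters, ranking,
                          n_permutations = config$gsea_permutations,
                          seed = config$seed)
  note("gsea", gsea$table)

  # --- stage 7: pairwise TLS fits between muscle aging responses ----------
  aging_cols <- grep("^logFC_.*aging$", names(profiles), value = TRUE)
  pairs <- utils::combn(aging_cols, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    f <- tls_fit(profiles[[p[1]]], profiles[[p[2]]])
    tibble::tibble(x = p[1], y = p[2], slope = f$slope,
                   intercept = f$intercept, r = f$r, n = f$n)
  })
  note("pairwise", pairwise)

  results <- list(
    sim_multimuscle = sim_mm, sim_premature = sim_pa,
    fit_multimuscle = fit_mm, fit_premature = fit_pa,
    aging_pc = c(multimuscle = pc_mm, premature = pc_pa),
    aligned_multimuscle = sets_mm, aligned_premature = sets_pa,
    recovery = recovery, overlap = overlap, profiles = profiles,
    clusters = clusters, gsea = gsea, pairwise = pairwise
  )

  if (!is.null(config$out_dir)) write_pipeline_outputs(results, config)

  manifest <- tibble::tibble(
    stage = names(stages),
    hash = unlist(stages)
  )
  manifest <- tibble::add_column(
    manifest,
    config_hash = rlang::hash(config[sort(names(config))]),
    version = as.character(utils::packageVersion("pcalign")),
    timestamp = format(Sys.time(), tz = "UTC"),
    .before = 1
  )
  list(results = results, manifest = manifest)
}

# sensitivity / false-positive rate of an aligned signature vs planted truth
score_recovery <- function(sets, truth_genes) {
  called <- union(sets$up, sets$down)
  planted <- truth_genes$gene_id
  nulls <- setdiff(sets$universe, planted)
  correct_sign <- c(
    intersect(sets$up, truth_genes$gene_id[truth_genes$direction == 1]),
    intersect(sets$down, truth_genes$gene_id[truth_genes$direction == -1])
  )
  # the PC's overall sign is arbitrary relative to "aging up"; score the
  # orientation that recovers the planted directions
  flipped <- c(
    intersect(sets$down, truth_genes$gene_id[truth_genes$direction == 1]),
    intersect(sets$up, truth_genes$gene_id[truth_genes$direction == -1])
  )
  hits <- max(length(correct_sign), length(flipped))
  tibble::tibble(
    sensitivity = hits / length(planted),
    fpr = length(intersect(called, nulls)) / length(nulls),
    n_called = length(called),
    n_planted = length(planted)
  )
}

write_pipeline_outputs <- function(results, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_expression_tsv(results$sim_multimuscle$data, p("multimuscle_tpm.tsv"))
  write_design_tsv(results$sim_multimuscle$data$design, p("multimuscle_design.tsv"))
  readr::write_tsv(alignment_table(results$fit_multimuscle,
                                   config$z_threshold, config$r_threshold),
                   p("alignment_table.tsv"), progress = FALSE)
  readr::write_tsv(results$overlap, p("overlap_enrichment.tsv"), progress = FALSE)
  readr::write_tsv(results$clusters, p("clusters.tsv"), progress = FALSE)
  readr::write_tsv(results$gsea$table, p("gsea.tsv"), progress = FALSE)
  readr::write_tsv(results$pairwise, p("pairwise_fits.tsv"), progress = FALSE)
  readr::write_tsv(results$recovery, p("recovery.tsv"), progress = FALSE)
  invisible(NULL)
}
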