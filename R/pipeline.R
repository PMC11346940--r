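#' Default run configuration
#'
#' All tunable thresholds with their standard values: quasi H-score cutoff
#' 150 (strict >), Wilcoxon alpha 0.05, |log2 FC| gate 1, mutation
#' prevalence gate 5%, response threshold 50%, GI50 windows at 1 nM and
#' 10 nM, cluster counts 5 / 10 / 10, the 13 critical tissues, the nine
#' NCI60 panels and their tumor-type mapping, and the six clinically tested
#' payload names.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    quasi_h_threshold = 150,
    consistency_policy = "within_one",
    min_evidence_score = 1,
    alpha = 0.05,
    min_abs_log2fc = 1,
    min_prevalence = 0.05,
    min_group = 3,
    threshold_pct = 50,
    k_picomolar = 5,
    k_low_nanomolar = 10,
    k_overlap = 10,
    critical_tissues = critical_tissues(),
    panels = nci60_panels(),
    payloads = adc_payload_names(),
    panel_mapping = default_panel_mapping(),
    seed = 1L
  )
}

# modifyList would recurse into the panel-mapping data frame; splice it in
# whole instead
.merge_config <- function(base, override) {
  pm <- override$panel_mapping
  override$panel_mapping <- NULL
  out <- utils::modifyList(base, override)
  if (!is.null(pm)) out$panel_mapping <- pm
  out
}

.validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg,
                                         call. = FALSE)
  chk(cfg$quasi_h_threshold >= 0 && cfg$quasi_h_threshold <= 300,
      "quasi_h_threshold must lie in [0, 300]")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  chk(cfg$min_abs_log2fc >= 0, "min_abs_log2fc must be non-negative")
  chk(cfg$min_prevalence >= 0 && cfg$min_prevalence <= 1,
      "min_prevalence must lie in [0, 1]")
  chk(cfg$threshold_pct >= 0 && cfg$threshold_pct <= 100,
      "threshold_pct must lie in [0, 100]")
  chk(all(c(cfg$k_picomolar, cfg$k_low_nanomolar, cfg$k_overlap) >= 1),
      "cluster counts must be at least 1")
  chk(length(cfg$panels) >= 1, "panel vocabulary is empty")
  invisible(cfg)
}

#' Read a YAML run configuration
#'
#' Missing fields fall back to [default_config()]; the `panel_mapping`
#' field, if present, must be a list of (panel, tumor_type) records.
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$panel_mapping)) {
    raw$panel_mapping <- dplyr::bind_rows(lapply(raw$panel_mapping,
                                                 tibble::as_tibble))
  }
  .validate_config(.merge_config(default_config(), raw))
}

#' Run the full discovery pipeline end to end
#'
#' Generates (or consumes) the input bundles, runs the target cascade, the
#' mutation screen, the payload workflow and the combination join, and
#' writes all result tables plus a JSON manifest with stage counts. With
#' `synthetic = TRUE` (the default) inputs are generated by the synthetic
#' cohort module at the configured seed; otherwise supply the bundles
#' directly.
#'
#' @param config Configuration list (see [default_config()]) or a path to a
#'   YAML file.
#' @param out_dir Output directory for result tables and the manifest.
#' @param synthetic Generate synthetic inputs (default TRUE).
#' @param target_bundle,mutation_bundle,gi50_bundle Pre-built input bundles
#'   used when `synthetic = FALSE` (same shapes as the `synth_*` outputs).
#' @param queries Query gene symbols for the mutation screen (synthetic mode
#'   derives them from the planted associations).
#' @return List with `cascade`, `associations`, `payloads`, `combinations`
#'   and `manifest`, invisibly.
#' @export
run_all <- function(config = default_config(), out_dir = tempfile("adcmine"),
                    synthetic = TRUE, target_bundle = NULL,
                    mutation_bundle = NULL, gi50_bundle = NULL,
                    queries = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- .validate_config(.merge_config(default_config(), config))
  seed <- cfg$seed

  if (synthetic) {
    target_bundle <- synth_target_bundle(seed = seed)
    gi50_bundle <- synth_gi50_bundle(seed = seed + 1L,
                                     payload_names = cfg$payloads)
  }
  cascade <- run_cascade(target_bundle,
                         config = cfg[c("quasi_h_threshold",
                                        "critical_tissues",
                                        "consistency_policy",
                                        "min_evidence_score")])

  if (synthetic && is.null(mutation_bundle)) {
    targets <- utils::head(cascade$targets, 5)
    cohorts <- utils::head(unique(cascade$indications$cancer_type), 4)
    if (length(targets) > 0 && length(cohorts) > 0) {
      planted <- tidyr::expand_grid(target = targets,
                                    cohort = cohorts) |>
        dplyr::mutate(query = paste0("Q", match(.data$cohort,
                                                unique(.data$cohort))),
                      log2_fc = 2, fraction = 0.2)
      mutation_bundle <- synth_mutation_bundle(
        cohorts, n_per_cohort = 100, planted = planted, seed = seed + 2L,
        background_queries = c("QBG1", "QBG2"))
    }
  }
  associations <- if (!is.null(mutation_bundle)) {
    screen_associations(
      mutation_bundle$expr, mutation_bundle$muts,
      targets = intersect(cascade$targets,
                          rownames(mutation_bundle$expr$values)),
      queries = if (is.null(queries)) unique(mutation_bundle$muts$gene)
                else queries,
      alpha = cfg$alpha, min_abs_log2fc = cfg$min_abs_log2fc,
      min_prevalence = cfg$min_prevalence, min_group = cfg$min_group)
  } else {
    NULL
  }

  payloads <- run_payload_pipeline(
    gi50_bundle$measurements,
    config = cfg[c("threshold_pct", "k_picomolar", "k_low_nanomolar",
                   "k_overlap", "panels")])

  panel_sets <- suppressWarnings(payload_indications(
    payloads$profiles$low_nanomolar, cfg$payloads, panels = cfg$panels))
  combos <- match_combinations(cascade$indications, panel_sets,
                               associations, mapping = cfg$panel_mapping)

  trace <- cascade$trace
  for (i in seq_len(nrow(payloads$trace$stages))) {
    trace <- trace_record(trace,
                          paste0("payload_", payloads$trace$stages$stage[i]),
                          payloads$trace$stages$n[i])
  }
  records <- list(
    prioritized_targets = tibble::tibble(gene = cascade$targets),
    target_indications = cascade$indications,
    quasi_h_scores = cascade$quasi_h,
    evidence_scores = cascade$evidence_scores,
    associations = if (is.null(associations)) {
      tibble::tibble(target = character())
    } else associations,
    association_summary = if (is.null(associations)) {
      tibble::tibble(query_gene = character())
    } else summarize_by_query(associations),
    payload_groups = payloads$groups,
    payload_clusters = payloads$clusters,
    combinations = flatten_combinations(combos)
  )
  cfg_echo <- cfg
  cfg_echo$panel_mapping <- NULL
  manifest <- write_outputs(trace, records, out_dir, config = cfg_echo,
                            seed = seed)
  invisible(list(cascade = cascade, associations = associations,
                 payloads = payloads, combinations = combos,
                 manifest = manifest))
}
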