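#' IHC-derived quasi H-scores from a pathology table
#'
#' Applies the quasi H-score formula (1 x %low + 2 x %medium + 3 x %high)
#' to every (gene, cancer type) row of a pathology record table.
#'
#' @param pathology Tibble with columns gene, cancer_type, frac_low,
#'   frac_medium, frac_high (percentages of patients at each staining level).
#' @return Tibble with columns gene, context (cancer type), score, source
#'   ("ihc").
#' @export
quasi_h_from_fractions <- function(pathology) {
  tibble::tibble(
    gene = pathology$gene,
    context = pathology$cancer_type,
    score = quasi_h_score(pathology$frac_low, pathology$frac_medium,
                          pathology$frac_high),
    source = "ihc"
  )
}

.filter_result <- function(kept, dropped) {
  list(kept = kept, dropped = dropped)
}

#' Keep membrane-annotated genes
#'
#' Stage 1 of the target cascade: genes lacking any membrane annotation are
#' removed. Intracellular annotations on individual isoforms do not exclude
#' a gene as long as a membrane annotation is present.
#'
#' @param annotations Gene annotation tibble (gene, is_membrane,
#'   has_protein_evidence, is_surfaceome).
#' @param genes Optional gene subset to filter; defaults to all annotated
#'   genes.
#' @return List with `kept` (character) and `dropped` (tibble item, reason).
#' @export
filter_membrane <- function(annotations, genes = annotations$gene) {
  ann <- annotations[match(genes, annotations$gene), ]
  keep <- !is.na(ann$is_membrane) & ann$is_membrane
  .filter_result(
    genes[keep],
    tibble::tibble(item = genes[!keep], reason = "no membrane annotation")
  )
}

#' Keep genes with evidence at protein level
#'
#' Stage 2 of the target cascade.
#'
#' @inheritParams filter_membrane
#' @return List with `kept` and `dropped`.
#' @export
filter_protein_evidence <- function(annotations, genes = annotations$gene) {
  ann <- annotations[match(genes, annotations$gene), ]
  keep <- !is.na(ann$has_protein_evidence) & ann$has_protein_evidence
  .filter_result(
    genes[keep],
    tibble::tibble(item = genes[!keep], reason = "no protein evidence")
  )
}

#' Combined membrane + protein-evidence filter
#'
#' Convenience wrapper applying stages 1 and 2 together.
#'
#' @inheritParams filter_membrane
#' @return List with `kept` and `dropped`.
#' @export
filter_membrane_evidence <- function(annotations, genes = annotations$gene) {
  s1 <- filter_membrane(annotations, genes)
  s2 <- filter_protein_evidence(annotations, s1$kept)
  .filter_result(s2$kept, dplyr::bind_rows(s1$dropped, s2$dropped))
}

#' Remove genes with high IHC expression in critical normal tissues
#'
#' A gene is dropped iff any normal-tissue IHC record for it, in any critical
#' tissue and any cell type, is at level high. Genes without records in
#' critical tissues are kept.
#'
#' @param normal Normal-tissue IHC tibble (gene, tissue, cell_type, level).
#' @param genes Gene set to filter.
#' @param tissues Critical tissue list; defaults to the 13-tissue standard
#'   list. Every listed tissue must appear in the table's tissue vocabulary.
#' @return List with `kept` and `dropped`.
#' @export
filter_critical_normal <- function(normal, genes,
                                   tissues = critical_tissues()) {
  if (length(tissues) == 0) {
    stop("critical tissue list is empty", call. = FALSE)
  }
  unknown <- setdiff(tissues, unique(normal$tissue))
  if (length(unknown) > 0) {
    stop("critical tissue(s) absent from normal-tissue data: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hits <- normal[normal$gene %in% genes &
                   normal$tissue %in% tissues &
                   as.character(normal$level) == "high", ]
  bad <- unique(hits$gene)
  first_tissue <- hits$tissue[!duplicated(hits$gene)]
  .filter_result(
    setdiff(genes, bad),
    tibble::tibble(
      item = bad,
      reason = paste0("high IHC level in critical tissue: ", first_tissue)
    )
  )
}

#' Keep genes with a high quasi H-score in at least one tumor type
#'
#' Computes IHC-derived quasi H-scores per (gene, cancer type) and keeps
#' genes scoring strictly above the threshold in at least one cancer type.
#' For (gene, cancer) pairs without IHC pathology data, mRNA-derived scores
#' can be supplied as a fallback.
#'
#' @param pathology Pathology tibble (gene, cancer_type, frac_*).
#' @param genes Gene set to filter.
#' @param threshold Quasi H-score cutoff (strict >), default 150.
#' @param mrna_scores Optional tibble (gene, context, score, source) of
#'   mRNA-derived scores used where IHC is missing.
#' @return List with `kept`, `dropped`, and `indications`: a tibble
#'   (gene, cancer_type, score, source) of all passing pairs.
#' @export
filter_tumor_quasi_h <- function(pathology, genes, threshold = 150,
                                 mrna_scores = NULL) {
  stopifnot(threshold >= 0, threshold <= 300)
  ihc <- quasi_h_from_fractions(pathology[pathology$gene %in% genes, ])
  scores <- ihc
  if (!is.null(mrna_scores)) {
    fallback <- mrna_scores[mrna_scores$gene %in% genes, ]
    have <- paste(ihc$gene, ihc$context, sep = "\r")
    fallback <- fallback[!(paste(fallback$gene, fallback$context,
                                 sep = "\r") %in% have), ]
    scores <- dplyr::bind_rows(ihc, fallback)
  }
  passing <- scores[scores$score > threshold, ]
  kept <- intersect(genes, unique(passing$gene))
  no_data <- setdiff(genes, unique(scores$gene))
  low <- setdiff(genes, c(kept, no_data))
  .filter_result(kept,
    dplyr::bind_rows(
      tibble::tibble(item = low,
                     reason = sprintf("no tumor type above quasi H-score %g",
                                      threshold)),
      tibble::tibble(item = no_data, reason = "no tumor data")
    )
  ) |>
    c(list(indications = tibble::tibble(
      gene = passing$gene, cancer_type = passing$context,
      score = passing$score, source = passing$source
    )))
}

#' Keep genes annotated as surfaceome members
#'
#' @inheritParams filter_membrane
#' @return List with `kept` and `dropped`.
#' @export
filter_surfaceome <- function(annotations, genes = annotations$gene) {
  ann <- annotations[match(genes, annotations$gene), ]
  keep <- !is.na(ann$is_surfaceome) & ann$is_surfaceome
  .filter_result(
    genes[keep],
    tibble::tibble(item = genes[!keep], reason = "not in surfaceome")
  )
}

#' Per-tissue IHC consensus levels
#'
#' Collapses cell-type-level IHC records to one level per (gene, tissue): the
#' maximum level over cell types (a tissue is as exposed as its most strongly
#' staining cell type).
#'
#' @param normal Normal-tissue IHC tibble.
#' @return Tibble (gene, tissue, level).
#' @export
ihc_tissue_levels <- function(normal) {
  normal |>
    dplyr::group_by(.data$gene, .data$tissue) |>
    dplyr::summarise(level = max(.data$level), .groups = "drop")
}

#' Per-tissue mRNA categories from a normal-tissue expression matrix
#'
#' Categorizes each gene's abundance across tissues into the four-level
#' vocabulary using the gene's own quartiles over all tissues (zeros ->
#' not detected).
#'
#' @param normal_expr An [expr_matrix()] whose samples are tissues.
#' @return Tibble (gene, tissue, level).
#' @export
mrna_tissue_levels <- function(normal_expr) {
  stopifnot(is_expr_matrix(normal_expr))
  v <- normal_expr$values
  purrr::map_dfr(rownames(v), function(g) {
    tibble::tibble(
      gene = g,
      tissue = colnames(v),
      level = categorize_quartiles(v[g, ], "four_level")
    )
  })
}

#' Consistency check between mRNA-derived and IHC expression categories
#'
#' Stage 6a of the cascade: for each gene, every tissue present in both
#' category maps must agree. Under the default `within_one` policy agreement
#' means an ordinal distance of at most one level; under `exact` the levels
#' must be identical. Tissues present in only one map are ignored; a gene
#' with no overlapping tissue fails.
#'
#' @param mrna_levels Tibble (gene, tissue, level) from mRNA categorization.
#' @param ihc_levels Tibble (gene, tissue, level) from IHC.
#' @param policy "within_one" (default) or "exact".
#' @return Tibble (gene, pass, reason) covering every gene present in either
#'   map.
#' @export
check_consistency_6a <- function(mrna_levels, ihc_levels,
                                 policy = c("within_one", "exact")) {
  policy <- match.arg(policy)
  tol <- if (policy == "within_one") 1L else 0L
  joined <- dplyr::inner_join(
    dplyr::rename(mrna_levels, mrna = "level"),
    dplyr::rename(ihc_levels, ihc = "level"),
    by = c("gene", "tissue")
  )
  joined$dist <- level_distance(joined$mrna, joined$ihc)
  verdict <- joined |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(pass = all(.data$dist <= tol), .groups = "drop")
  all_genes <- union(unique(mrna_levels$gene), unique(ihc_levels$gene))
  out <- tibble::tibble(gene = all_genes) |>
    dplyr::left_join(verdict, by = "gene")
  out$reason <- dplyr::case_when(
    is.na(out$pass) ~ "no overlapping evidence",
    out$pass ~ NA_character_,
    TRUE ~ sprintf("mRNA/IHC categories diverge beyond policy '%s'", policy)
  )
  out$pass[is.na(out$pass)] <- FALSE
  out
}

#' mRNA-derived quasi H-score for one gene in one cohort
#'
#' Categorizes the cohort's samples for the gene into low / medium / high by
#' the three-level quartile scheme and applies the quasi H-score formula to
#' the resulting sample percentages. By default quartiles come from the
#' cohort's own values; with `reference = "pangene"` they are computed from
#' the gene's values across all samples of the matrix, so that cohorts where
#' the gene runs hot relative to its pan-cohort distribution score high.
#'
#' @param expr An [expr_matrix()] with tumor cohorts.
#' @param cohort Cohort (tumor-type) code; needs at least 4 samples.
#' @param gene Gene symbol; must be present in the matrix.
#' @param reference "cohort" or "pangene" quartile reference.
#' @return Tibble (gene, context, score, source = "mrna") with one row.
#' @export
quasi_h_from_expression <- function(expr, cohort, gene,
                                    reference = c("cohort", "pangene")) {
  reference <- match.arg(reference)
  stopifnot(is_expr_matrix(expr))
  if (!gene %in% rownames(expr$values)) {
    stop("gene absent from expression matrix: ", gene, call. = FALSE)
  }
  samples <- cohort_samples(expr, cohort)
  if (length(samples) < 4) {
    stop("cohort '", cohort, "' has fewer than 4 samples", call. = FALSE)
  }
  vals <- expr$values[gene, samples]
  quart <- if (reference == "pangene") {
    stats::quantile(expr$values[gene, ], c(0.25, 0.75), names = FALSE,
                    type = 7)
  } else {
    NULL
  }
  cats <- categorize_quartiles(vals, "three_level", quartiles = quart)
  pct <- 100 * tabulate(as.integer(cats), nbins = 4) / length(cats)
  tibble::tibble(
    gene = gene, context = cohort,
    score = quasi_h_score(pct[2], pct[3], pct[4]),
    source = "mrna"
  )
}

#' mRNA quasi H-scores for many genes across all cohorts
#'
#' @param expr An [expr_matrix()].
#' @param genes Gene symbols (silently restricted to those present).
#' @param reference Quartile reference, see [quasi_h_from_expression()].
#' @return Tibble (gene, context, score, source).
#' @export
cohort_quasi_h <- function(expr, genes, reference = "pangene") {
  genes <- intersect(genes, rownames(expr$values))
  cohorts <- unique(expr$cohort)
  cohorts <- cohorts[vapply(cohorts,
                            function(cc) length(cohort_samples(expr, cc)) >= 4,
                            logical(1))]
  purrr::map_dfr(genes, function(g) {
    purrr::map_dfr(cohorts, function(cc) {
      quasi_h_from_expression(expr, cc, g, reference = reference)
    })
  })
}

#' Remove genes highly expressed on hematopoietic stem/progenitor cells
#'
#' Quartiles are computed over the ENTIRE hematopoietic expression matrix
#' (all genes x all samples). Each gene's HSC/MPP level is the three-level
#' category of the mean of its HSC/MPP-sample values against those global
#' quartiles; genes at high are dropped, genes absent from the matrix are
#' dropped with their own reason.
#'
#' @param hema An [expr_matrix()] of hematopoietic expression.
#' @param genes Gene set to filter.
#' @param hsc_samples Sample ids of the HSC/MPP populations (non-empty,
#'   subset of the matrix samples).
#' @return List with `kept`, `dropped`, and `levels`: tibble (gene, level)
#'   for retained genes.
#' @export
filter_hsc_mpp <- function(hema, genes, hsc_samples) {
  stopifnot(is_expr_matrix(hema))
  if (length(hsc_samples) == 0) {
    stop("no HSC/MPP samples designated", call. = FALSE)
  }
  if (!all(hsc_samples %in% colnames(hema$values))) {
    stop("HSC/MPP sample(s) absent from hematopoietic matrix: ",
         paste(setdiff(hsc_samples, colnames(hema$values)), collapse = ", "),
         call. = FALSE)
  }
  global_q <- stats::quantile(hema$values, c(0.25, 0.75), names = FALSE,
                              type = 7)
  present <- intersect(genes, rownames(hema$values))
  absent <- setdiff(genes, present)
  means <- rowMeans(hema$values[present, hsc_samples, drop = FALSE])
  lev <- categorize_quartiles(means, "three_level", quartiles = global_q)
  high <- present[as.character(lev) == "high"]
  kept <- setdiff(present, high)
  .filter_result(kept,
    dplyr::bind_rows(
      tibble::tibble(item = high,
                     reason = "high expression on HSC/MPP populations"),
      tibble::tibble(item = absent,
                     reason = "absent from hematopoietic study")
    )
  ) |>
    c(list(levels = tibble::tibble(
      gene = present, level = as.character(lev)
    )[present %in% kept, ]))
}

#' Evidence-based prioritization score
#'
#' Counts how many of the five evidence criteria (literature, antibody,
#' protein family, preclinical, clinical) are met, giving a 0-5 score; genes
#' scoring 0 are dropped from the prioritized list.
#'
#' @param evidence Tibble with gene plus the five logical criterion columns.
#' @return Tibble (gene, score).
#' @export
evidence_score <- function(evidence) {
  crit <- c("literature", "antibody", "protein_family", "preclinical",
            "clinical")
  stopifnot(all(crit %in% names(evidence)))
  flags <- as.matrix(evidence[crit])
  mode(flags) <- "logical"
  flags[is.na(flags)] <- FALSE
  tibble::tibble(gene = evidence$gene, score = as.integer(rowSums(flags)))
}

#' Run the nine-stage ADC target identification cascade
#'
#' Applies, in order: membrane annotation, protein-level evidence, critical
#' normal tissue exclusion, tumor quasi H-score, surfaceome membership,
#' mRNA/IHC consistency (6a), dual IHC+mRNA quasi H-score (6b), HSC/MPP
#' exclusion, and evidence-criteria scoring. Stage 6b requires the IHC- and
#' mRNA-derived scores to exceed the threshold in the same tumor type, with
#' mRNA scores computed against each gene's pan-cohort quartiles.
#'
#' @param inputs Named list with elements: `annotation` (gene_annotation
#'   tibble), `evidence` (evidence tibble), `normal_ihc` (normal-tissue IHC
#'   tibble), `normal_mrna` ([expr_matrix()] over tissues), `pathology`
#'   (pathology tibble), `tumor_expr` ([expr_matrix()] over tumor cohorts),
#'   `hema_expr` ([expr_matrix()]), `hsc_samples` (character).
#' @param config List of tunables: `quasi_h_threshold` (default 150),
#'   `critical_tissues`, `consistency_policy` ("within_one"/"exact"),
#'   `min_evidence_score` (default 1).
#' @return List with `targets` (prioritized genes), `indications` (tibble
#'   gene, cancer_type, score, source for the surviving genes),
#'   `quasi_h` (full IHC + mRNA score table), `evidence_scores`,
#'   `hsc_levels`, and `trace` (a `cascade_trace` of nine stages).
#' @export
run_cascade <- function(inputs, config = list()) {
  cfg <- utils::modifyList(
    list(quasi_h_threshold = 150, critical_tissues = critical_tissues(),
         consistency_policy = "within_one", min_evidence_score = 1),
    config
  )
  if (cfg$quasi_h_threshold < 0 || cfg$quasi_h_threshold > 300) {
    stop("quasi_h_threshold must lie in [0, 300]", call. = FALSE)
  }
  ann <- inputs$annotation
  trace <- new_trace()
  universe <- ann$gene

  if (length(universe) == 0) {
    empty <- tibble::tibble(gene = character(), cancer_type = character(),
                            score = numeric(), source = character())
    for (st in c("membrane", "protein_evidence", "critical_normal",
                 "tumor_quasi_h", "surfaceome", "consistency_6a",
                 "dual_score_6b", "hsc_mpp", "evidence")) {
      trace <- trace_record(trace, st, character())
    }
    return(list(targets = character(), indications = empty,
                quasi_h = empty, evidence_scores = evidence_score(
                  inputs$evidence[0, , drop = FALSE]),
                hsc_levels = tibble::tibble(gene = character(),
                                            level = character()),
                trace = trace))
  }

  s1 <- filter_membrane(ann, universe)
  trace <- trace_record(trace, "membrane", s1$kept, s1$dropped)
  s2 <- filter_protein_evidence(ann, s1$kept)
  trace <- trace_record(trace, "protein_evidence", s2$kept, s2$dropped)
  s3 <- filter_critical_normal(inputs$normal_ihc, s2$kept,
                               tissues = cfg$critical_tissues)
  trace <- trace_record(trace, "critical_normal", s3$kept, s3$dropped)

  mrna_scores <- cohort_quasi_h(inputs$tumor_expr, s3$kept,
                                reference = "pangene")
  s4 <- filter_tumor_quasi_h(inputs$pathology, s3$kept,
                             threshold = cfg$quasi_h_threshold,
                             mrna_scores = mrna_scores)
  trace <- trace_record(trace, "tumor_quasi_h", s4$kept, s4$dropped)

  s5 <- filter_surfaceome(ann, s4$kept)
  trace <- trace_record(trace, "surfaceome", s5$kept, s5$dropped)

  mrna_norm <- mrna_tissue_levels(inputs$normal_mrna)
  ihc_norm <- ihc_tissue_levels(inputs$normal_ihc)
  verdict <- check_consistency_6a(
    mrna_norm[mrna_norm$gene %in% s5$kept, ],
    ihc_norm[ihc_norm$gene %in% s5$kept, ],
    policy = cfg$consistency_policy
  )
  verdict <- verdict[match(s5$kept, verdict$gene), ]
  verdict$pass[is.na(verdict$pass)] <- FALSE
  verdict$reason[is.na(verdict$pass) | !verdict$pass] <-
    dplyr::coalesce(verdict$reason[is.na(verdict$pass) | !verdict$pass],
                    "no overlapping evidence")
  s6a_kept <- s5$kept[verdict$pass]
  trace <- trace_record(trace, "consistency_6a", s6a_kept,
                        tibble::tibble(item = s5$kept[!verdict$pass],
                                       reason = verdict$reason[!verdict$pass]))

  # 6b: a tumor type must clear the threshold in BOTH the IHC- and the
  # mRNA-derived score for the gene to survive.
  ihc_pass <- s4$indications
  mrna_pass <- mrna_scores[mrna_scores$score > cfg$quasi_h_threshold, ]
  both <- dplyr::inner_join(
    ihc_pass[ihc_pass$gene %in% s6a_kept,
             c("gene", "cancer_type", "score")],
    tibble::tibble(gene = mrna_pass$gene, cancer_type = mrna_pass$context),
    by = c("gene", "cancer_type")
  )
  s6b_kept <- intersect(s6a_kept, unique(both$gene))
  trace <- trace_record(trace, "dual_score_6b", s6b_kept,
                        tibble::tibble(
                          item = setdiff(s6a_kept, s6b_kept),
                          reason = "mRNA quasi H-score below threshold in all IHC-passing tumor types"))

  s8 <- filter_hsc_mpp(inputs$hema_expr, s6b_kept, inputs$hsc_samples)
  trace <- trace_record(trace, "hsc_mpp", s8$kept, s8$dropped)

  ev <- evidence_score(inputs$evidence)
  ev_sub <- ev[match(s8$kept, ev$gene), ]
  ev_sub$score[is.na(ev_sub$score)] <- 0L
  keep <- ev_sub$score >= cfg$min_evidence_score
  final <- s8$kept[keep]
  trace <- trace_record(trace, "evidence", final,
                        tibble::tibble(item = s8$kept[!keep],
                                       reason = "no evidence criterion met"))

  all_scores <- dplyr::bind_rows(
    quasi_h_from_fractions(inputs$pathology) |>
      dplyr::rename(cancer_type = "context"),
    mrna_scores |> dplyr::rename(cancer_type = "context")
  )
  list(
    targets = final,
    indications = s4$indications[s4$indications$gene %in% final, ],
    quasi_h = all_scores,
    evidence_scores = ev_sub[keep, ],
    hsc_levels = s8$levels,
    trace = trace
  )
}
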