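#' Default clinically tested ADC payload names
#' @return Character vector of six payload names.
#' @export
adc_payload_names <- function() {
  c("Dxd", "exatecan mesylate", "maytansine", "monomethyl auristatin E",
    "maytansine deriv", "eribulin mesylate")
}

#' Default NCI60 panel to tumor-type mapping
#'
#' Aligns the nine NCI60 indication panels with TCGA-style tumor-type codes.
#' One-to-many mappings are allowed (CNS covers both glioblastoma and
#' low-grade glioma). Overridable via configuration.
#'
#' @return Tibble (panel, tumor_type).
#' @export
default_panel_mapping <- function() {
  tibble::tribble(
    ~panel, ~tumor_type,
    "Renal Cancer", "KIRC",
    "Breast Cancer", "BRCA",
    "Ovarian Cancer", "OV",
    "Prostate Cancer", "PRAD",
    "Colon Cancer", "COAD",
    "Melanoma", "SKCM",
    "CNS Cancer", "GBM",
    "CNS Cancer", "LGG",
    "Non-Small Cell Lung Cancer", "LUAD",
    "Non-Small Cell Lung Cancer", "LUSC",
    "Leukemia", "LAML"
  )
}

#' Fully responsive panels per payload
#'
#' For each named payload, the NCI60 panels in which every measured cell
#' line is responsive (100% response) in the supplied profile table
#' (conventionally the low-nanomolar, <= 10 nM window). Payload names are
#' matched after trimming and case-folding; unresolvable names produce a
#' warning and are excluded.
#'
#' @param profiles Response profile tibble from [response_profiles()].
#' @param payload_names Payload names to resolve (default
#'   [adc_payload_names()]).
#' @param panels Panel vocabulary.
#' @return Named list, payload name -> character vector of panels at 100%.
#' @export
payload_indications <- function(profiles, payload_names = adc_payload_names(),
                                panels = nci60_panels()) {
  norm_prof <- .norm_name(profiles$name)
  out <- list()
  for (p in payload_names) {
    hit <- which(norm_prof == .norm_name(p))
    if (length(hit) == 0) {
      warning("payload not found in profiles: ", p, call. = FALSE)
      next
    }
    pct <- as.numeric(profiles[hit[1], paste0("pct_", panels)])
    out[[p]] <- panels[!is.na(pct) & pct >= 100 - 1e-9]
  }
  out
}

#' Map an NCI60 panel to tumor-type codes
#'
#' @param panel Panel name.
#' @param mapping Mapping tibble (panel, tumor_type); default
#'   [default_panel_mapping()].
#' @return Character vector of tumor-type codes (empty, with a warning, for
#'   an unmapped panel).
#' @export
map_indication <- function(panel, mapping = default_panel_mapping()) {
  if (!all(c("panel", "tumor_type") %in% names(mapping))) {
    stop("panel mapping needs columns 'panel' and 'tumor_type'",
         call. = FALSE)
  }
  codes <- mapping$tumor_type[mapping$panel == panel]
  if (length(codes) == 0) {
    warning("no tumor-type mapping for panel: ", panel, call. = FALSE)
  }
  codes
}

#' Join targets, indications and payloads into combination records
#'
#' Emits one record per (target, tumor type, payload) where the tumor type
#' is mapped from an NCI60 panel in which the payload shows 100% response,
#' and the (target, tumor type) pair passed the quasi H-score gate. All
#' screened mutation associations for the (target, tumor type) pair are
#' attached as context.
#'
#' @param target_indications Tibble (gene, cancer_type, score) of passing
#'   target-indication pairs.
#' @param payload_panels Named list from [payload_indications()].
#' @param associations Screened association tibble (may be empty).
#' @param mapping Panel mapping tibble.
#' @return Tibble with columns target, tumor_type, nci60_panel, payload,
#'   target_score and a `mutation_context` list-column of per-row tibbles
#'   (query_gene, log2_fc, p_value, direction).
#' @export
match_combinations <- function(target_indications, payload_panels,
                               associations = NULL,
                               mapping = default_panel_mapping()) {
  rows <- list()
  for (payload in names(payload_panels)) {
    for (panel in payload_panels[[payload]]) {
      codes <- suppressWarnings(map_indication(panel, mapping))
      for (code in codes) {
        hit <- target_indications[target_indications$cancer_type == code, ]
        if (nrow(hit) == 0) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          target = hit$gene, tumor_type = code, nci60_panel = panel,
          payload = payload, target_score = hit$score
        )
      }
    }
  }
  empty_ctx <- tibble::tibble(query_gene = character(), log2_fc = numeric(),
                              p_value = numeric(), direction = character())
  if (length(rows) == 0) {
    out <- tibble::tibble(target = character(), tumor_type = character(),
                          nci60_panel = character(), payload = character(),
                          target_score = numeric())
    out$mutation_context <- list()
    return(out)
  }
  out <- dplyr::bind_rows(rows)
  out$mutation_context <- purrr::map2(out$target, out$tumor_type,
    function(tg, tt) {
      if (is.null(associations) || nrow(associations) == 0) return(empty_ctx)
      sub <- associations[associations$target == tg &
                            associations$cohort == tt, ]
      tibble::tibble(query_gene = sub$query_gene, log2_fc = sub$log2_fc,
                     p_value = sub$p_value, direction = sub$direction)
    })
  out
}

#' Flatten combination records for TSV export
#'
#' One row per combination x mutation association (combinations without any
#' association keep a single row with NA context columns).
#'
#' @param combos Tibble from [match_combinations()].
#' @return Flat tibble without list-columns.
#' @export
flatten_combinations <- function(combos) {
  if (nrow(combos) == 0) {
    return(tibble::tibble(target = character(), tumor_type = character(),
                          nci60_panel = character(), payload = character(),
                          target_score = numeric(), query_gene = character(),
                          log2_fc = numeric(), p_value = numeric(),
                          direction = character()))
  }
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    ctx <- combos$mutation_context[[i]]
    base <- combos[i, setdiff(names(combos), "mutation_context")]
    if (nrow(ctx) == 0) {
      return(dplyr::mutate(base, query_gene = NA_character_,
                           log2_fc = NA_real_, p_value = NA_real_,
                           direction = NA_character_))
    }
    dplyr::bind_cols(base[rep(1, nrow(ctx)), ], ctx)
  })
}
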