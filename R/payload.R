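GI50_PICO_MAX <- -9   # log10 molar; GI50 <= 1 nM
GI50_NANO_MAX <- -8   # log10 molar; GI50 <= 10 nM

.norm_name <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out[is.na(x) | out == ""] <- NA_character_
  out
}

#' Merge compounds sharing a name under one NSC id
#'
#' NCI-DTP snapshots contain distinct NSC accessions mapping to the same
#' compound name. Compounds whose normalized names (trimmed, case-folded)
#' coincide are merged under the smallest NSC id involved; unnamed compounds
#' are keyed by NSC id alone and never merged. Measurements are re-labelled,
#' the failed-screen flag is the OR over merged accessions, and the most
#' advanced clinical status is retained.
#'
#' @param measurements GI50 measurement tibble (nsc_id, name, cell_line,
#'   panel, log_gi50, failed_screen, status).
#' @return Measurement tibble with merged compound identities.
#' @export
dedupe_compounds <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  key <- .norm_name(m$name)
  key[is.na(key)] <- paste0("\rnsc:", m$nsc_id[is.na(key)])
  canon <- stats::aggregate(m$nsc_id, by = list(key = key), FUN = min)
  canon_id <- stats::setNames(canon$x, canon$key)
  orig_id <- m$nsc_id
  m$nsc_id <- as.integer(canon_id[key])
  status_rank <- c(none = 0L, clinical = 1L, fda_approved = 2L)
  m$.orig <- orig_id
  m <- m |>
    dplyr::group_by(.data$nsc_id) |>
    dplyr::mutate(
      # the surviving accession keeps its own name spelling
      name = .data$name[match(.data$nsc_id[1], .data$.orig)],
      failed_screen = any(.data$failed_screen),
      status = names(status_rank)[max(status_rank[.data$status]) + 1L]
    ) |>
    dplyr::ungroup()
  m$.orig <- NULL
  m
}

#' Classify a GI50 value into a potency window
#'
#' Picomolar: GI50 at most 1 nM (log10 molar <= -9); low nanomolar: above
#' 1 nM up to 10 nM (-9 < log10 <= -8); anything weaker is "none". Both
#' boundaries are inclusive on the potent side.
#'
#' @param log_gi50 Numeric vector of log10 molar GI50 values; non-finite
#'   entries are returned as NA with a warning.
#' @return Character vector in {"picomolar", "low_nanomolar", "none"}.
#' @export
classify_sensitivity <- function(log_gi50) {
  out <- ifelse(log_gi50 <= GI50_PICO_MAX, "picomolar",
           ifelse(log_gi50 <= GI50_NANO_MAX, "low_nanomolar", "none"))
  if (any(!is.finite(log_gi50))) {
    warning("non-finite log_gi50 value(s) skipped", call. = FALSE)
    out[!is.finite(log_gi50)] <- NA_character_
  }
  out
}

#' Aggregate replicate measurements per compound and cell line
#'
#' Replicates are averaged on the log10 scale (geometric-mean GI50
#' convention) before any response computation.
#'
#' @param measurements GI50 measurement tibble.
#' @return One row per (nsc_id, cell_line) with the aggregated log_gi50.
#' @export
aggregate_replicates <- function(measurements) {
  measurements |>
    dplyr::group_by(.data$nsc_id, .data$name, .data$panel, .data$cell_line,
                    .data$failed_screen, .data$status) |>
    dplyr::summarise(log_gi50 = mean(.data$log_gi50), .groups = "drop")
}

#' Per-panel response profiles for one sensitivity class
#'
#' For each compound and NCI60 panel, the percentage of measured cell lines
#' responsive in the class window (picomolar: GI50 <= 1 nM; low nanomolar:
#' GI50 <= 10 nM -- a line killed at picomolar dose is still responsive at
#' 10 nM). A compound qualifies if any panel reaches `threshold_pct`.
#' Panels with no measured line are NA (missing), not 0.
#'
#' @param measurements Deduped GI50 measurement tibble (replicates are
#'   aggregated internally).
#' @param sens_class "picomolar" or "low_nanomolar".
#' @param threshold_pct Qualification threshold (default 50, inclusive >=).
#' @param panels Panel vocabulary defining the profile columns.
#' @return Tibble: nsc_id, name, sens_class, one `pct_<panel>` column per
#'   panel, `qualifies`.
#' @export
response_profiles <- function(measurements,
                              sens_class = c("picomolar", "low_nanomolar"),
                              threshold_pct = 50, panels = nci60_panels()) {
  sens_class <- match.arg(sens_class)
  cutoff <- if (sens_class == "picomolar") GI50_PICO_MAX else GI50_NANO_MAX
  agg <- aggregate_replicates(measurements)
  if (nrow(agg) == 0) {
    out <- tibble::tibble(nsc_id = integer(), name = character(),
                          sens_class = character())
    for (p in panels) out[[paste0("pct_", p)]] <- numeric()
    out$qualifies <- logical()
    return(out)
  }
  per_panel <- agg |>
    dplyr::group_by(.data$nsc_id, .data$name, .data$panel) |>
    dplyr::summarise(
      pct = 100 * mean(.data$log_gi50 <= cutoff),
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(per_panel, names_from = "panel",
                             values_from = "pct", names_prefix = "pct_")
  for (p in paste0("pct_", panels)) if (!p %in% names(wide)) wide[[p]] <- NA_real_
  wide <- wide[c("nsc_id", "name", paste0("pct_", panels))]
  pctm <- as.matrix(wide[paste0("pct_", panels)])
  wide$sens_class <- sens_class
  wide$qualifies <- apply(pctm, 1, function(v) any(v >= threshold_pct,
                                                   na.rm = TRUE))
  wide[c("nsc_id", "name", "sens_class", paste0("pct_", panels),
         "qualifies")]
}

#' Remove compounds flagged as failed NCI60 screens
#'
#' Applied after the response screen, matching the workflow order.
#'
#' @param profiles Response profile tibble.
#' @param measurements Measurement tibble carrying the per-compound
#'   `failed_screen` flag.
#' @return Profiles with failed compounds removed.
#' @export
drop_failed <- function(profiles, measurements) {
  failed <- unique(measurements$nsc_id[measurements$failed_screen])
  profiles[!profiles$nsc_id %in% failed, ]
}

#' Partition final compounds into the three sensitivity groups
#'
#' @param pico_qualifiers,nano_qualifiers NSC ids qualifying in each class
#'   (post failed-screen removal).
#' @return Tibble (nsc_id, group) over the union, with group in
#'   picomolar_only / low_nanomolar_only / overlap.
#' @export
partition_groups <- function(pico_qualifiers, nano_qualifiers) {
  overlap <- intersect(pico_qualifiers, nano_qualifiers)
  tibble::tibble(
    nsc_id = c(setdiff(pico_qualifiers, overlap),
               setdiff(nano_qualifiers, overlap), overlap),
    group = rep(c("picomolar_only", "low_nanomolar_only", "overlap"),
                c(length(setdiff(pico_qualifiers, overlap)),
                  length(setdiff(nano_qualifiers, overlap)),
                  length(overlap)))
  ) |>
    dplyr::arrange(.data$nsc_id)
}

#' Cluster compound response profiles
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances) of the 9-dimensional per-panel response-percentage vectors,
#' cut at exactly `k` clusters. Profiles are sorted by compound id first, so
#' the partition (and its labels) is invariant to input row order; missing
#' panels are imputed as 0% for the distance computation only.
#'
#' @param profiles Response profile tibble (from [response_profiles()]).
#' @param k Number of clusters (at most the number of profiles).
#' @param panels Panel vocabulary.
#' @return Tibble (nsc_id, cluster) sorted by nsc_id.
#' @export
cluster_profiles <- function(profiles, k, panels = nci60_panels()) {
  if (nrow(profiles) < k) {
    stop("fewer profiles (", nrow(profiles), ") than clusters (", k, ")",
         call. = FALSE)
  }
  profiles <- dplyr::arrange(profiles, .data$nsc_id)
  m <- as.matrix(profiles[paste0("pct_", panels)])
  m[is.na(m)] <- 0
  labels <- if (k == nrow(profiles)) {
    seq_len(nrow(profiles))
  } else {
    stats::cutree(stats::hclust(stats::dist(m), method = "ward.D2"), k = k)
  }
  tibble::tibble(nsc_id = profiles$nsc_id, cluster = as.integer(labels))
}

#' Run the payload mining workflow
#'
#' Workflow order: merge duplicate-name compounds; assign each compound to
#' sensitivity categories from its measured line-level GI50s (picomolar
#' category: any line at most 1 nM; low-nanomolar category: any line in the
#' 1-10 nM band); screen each category for at least `threshold_pct` percent
#' responsive lines in at least one of the nine indications (windows:
#' <= 1 nM and <= 10 nM respectively); remove failed-screen compounds;
#' partition qualifiers into picomolar-only / low-nanomolar-only / overlap;
#' cluster each group's profiles (low-nanomolar window profiles for the
#' overlap group).
#'
#' @param measurements GI50 measurement tibble.
#' @param config List of tunables: `threshold_pct` (50), `k_picomolar` (5),
#'   `k_low_nanomolar` (10), `k_overlap` (10), `panels`. Cluster counts are
#'   capped at the group size.
#' @return List with `groups` (nsc_id, name, group, status), `profiles`
#'   (per-class response profiles), `clusters` (nsc_id, group, cluster),
#'   and `trace`.
#' @export
run_payload_pipeline <- function(measurements, config = list()) {
  cfg <- utils::modifyList(
    list(threshold_pct = 50, k_picomolar = 5, k_low_nanomolar = 10,
         k_overlap = 10, panels = nci60_panels()),
    config
  )
  trace <- new_trace()
  trace <- trace_record(trace, "input", length(unique(measurements$nsc_id)))
  dd <- dedupe_compounds(measurements)
  trace <- trace_record(trace, "dedupe", length(unique(dd$nsc_id)))
  agg <- aggregate_replicates(dd)
  cls <- classify_sensitivity(agg$log_gi50)
  pico_members <- unique(agg$nsc_id[cls == "picomolar"])
  nano_members <- unique(agg$nsc_id[cls == "low_nanomolar"])

  prof_pico <- response_profiles(dd[dd$nsc_id %in% pico_members, ],
                                 "picomolar", cfg$threshold_pct, cfg$panels)
  prof_nano <- response_profiles(dd[dd$nsc_id %in% nano_members, ],
                                 "low_nanomolar", cfg$threshold_pct,
                                 cfg$panels)
  trace <- trace_record(trace, "picomolar_category", length(pico_members))
  q_pico <- prof_pico[prof_pico$qualifies, ]
  trace <- trace_record(trace, "picomolar_qualified", nrow(q_pico))
  q_pico <- drop_failed(q_pico, dd)
  trace <- trace_record(trace, "picomolar_after_failed", nrow(q_pico))
  trace <- trace_record(trace, "low_nanomolar_category", length(nano_members))
  q_nano <- prof_nano[prof_nano$qualifies, ]
  trace <- trace_record(trace, "low_nanomolar_qualified", nrow(q_nano))
  q_nano <- drop_failed(q_nano, dd)
  trace <- trace_record(trace, "low_nanomolar_after_failed", nrow(q_nano))

  groups <- partition_groups(q_pico$nsc_id, q_nano$nsc_id)
  trace <- trace_record(trace, "final", nrow(groups))
  meta <- dplyr::distinct(dd[c("nsc_id", "name", "status")])
  groups <- dplyr::left_join(groups, meta, by = "nsc_id")

  cluster_one <- function(ids, prof, k) {
    sub <- prof[prof$nsc_id %in% ids, ]
    if (nrow(sub) == 0) {
      return(tibble::tibble(nsc_id = integer(), cluster = integer()))
    }
    cluster_profiles(sub, min(k, nrow(sub)), panels = cfg$panels)
  }
  clusters <- dplyr::bind_rows(
    picomolar_only = cluster_one(
      groups$nsc_id[groups$group == "picomolar_only"], prof_pico,
      cfg$k_picomolar),
    low_nanomolar_only = cluster_one(
      groups$nsc_id[groups$group == "low_nanomolar_only"], prof_nano,
      cfg$k_low_nanomolar),
    overlap = cluster_one(
      groups$nsc_id[groups$group == "overlap"], prof_nano, cfg$k_overlap),
    .id = "group"
  )
  list(groups = groups,
       profiles = list(picomolar = prof_pico, low_nanomolar = prof_nano),
       clusters = clusters,
       trace = trace)
}
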