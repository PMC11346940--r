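.noncritical_tissue_pool <- function() {
  c("cerebellum", "cerebral cortex", "pancreas", "thyroid gland",
    "adrenal gland", "testis", "spleen", "lymph node", "breast", "prostate",
    "ovary", "urinary bladder")
}

.cascade_stage_names <- function() {
  c("membrane", "protein_evidence", "critical_normal", "tumor_quasi_h",
    "surfaceome", "consistency_6a", "dual_score_6b", "hsc_mpp", "evidence")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate the target-arm input bundle with planted ground truth
#'
#' Builds all tables the nine-stage target cascade consumes -- gene
#' annotations, five-criteria evidence flags, normal-tissue IHC levels, a
#' normal-tissue mRNA matrix, per-cancer pathology patient fractions, a
#' tumor expression matrix with cohort labels, and a hematopoietic
#' expression matrix -- around planted structure: a set of "ideal targets"
#' constructed to survive every cascade stage, and one decoy family per
#' stage, each violating exactly that stage's criterion while satisfying all
#' others.
#'
#' Background genes get Dirichlet-sampled patient fractions and log-normal
#' expression (meanlog 1, sdlog 1, zeros injected at `zero_rate` so the
#' not-detected category is exercised); ideal targets carry high patient
#' fractions (quasi H-score 245) in two tumor types, concordant mRNA, no
#' high level in any critical tissue, and sub-quartile hematopoietic
#' expression. Normal-tissue IHC levels are derived from the normal mRNA
#' matrix (per-gene four-level quartile categories), so mRNA and IHC are
#' concordant by construction except for the consistency-stage decoys.
#'
#' @param n_genes Total gene count (>= planted count; 0 gives empty tables).
#' @param n_cancer_types Number of tumor-type codes (2-20).
#' @param n_tissues Number of normal tissues (16 to 25; always includes the
#'   13 critical tissues).
#' @param seed Mandatory integer seed; identical (arguments, seed) give
#'   identical bundles.
#' @param n_ideal Number of planted ideal targets.
#' @param n_decoy_per_stage Decoy family size per cascade stage.
#' @param n_tumor_per_cohort Tumor samples per cohort.
#' @param zero_rate Zero-injection rate for background expression.
#' @return List with `annotation`, `evidence`, `normal_ihc`, `normal_mrna`,
#'   `pathology`, `tumor_expr`, `hema_expr`, `hsc_samples`, and `truth`
#'   (ideal_targets, decoys, target_cancers, counts).
#' @export
synth_target_bundle <- function(n_genes = 500, n_cancer_types = 20,
                                n_tissues = 20, seed,
                                n_ideal = 8, n_decoy_per_stage = 3,
                                n_tumor_per_cohort = 20, zero_rate = 0.05) {
  stopifnot(!missing(seed))
  stages <- .cascade_stage_names()
  n_planted <- n_ideal + length(stages) * n_decoy_per_stage
  if (n_genes == 0) {
    empty_truth <- list(ideal_targets = character(),
                        decoys = tibble::tibble(gene = character(),
                                                stage = character()),
                        target_cancers = tibble::tibble(
                          gene = character(), cancer_type = character()),
                        counts = list(membrane_evidence = 0L))
    return(list(
      annotation = tibble::tibble(gene = character(), is_membrane = logical(),
                                  has_protein_evidence = logical(),
                                  is_surfaceome = logical()),
      evidence = tibble::tibble(gene = character(), literature = logical(),
                                antibody = logical(),
                                protein_family = logical(),
                                preclinical = logical(),
                                clinical = logical()),
      normal_ihc = tibble::tibble(gene = character(), tissue = character(),
                                  cell_type = character(),
                                  level = parse_expression_level(character())),
      normal_mrna = NULL, pathology = tibble::tibble(
        gene = character(), cancer_type = character(), frac_low = numeric(),
        frac_medium = numeric(), frac_high = numeric()),
      tumor_expr = NULL, hema_expr = NULL, hsc_samples = character(),
      truth = empty_truth))
  }
  if (n_genes < n_planted) {
    stop("n_genes (", n_genes, ") smaller than planted gene count (",
         n_planted, ")", call. = FALSE)
  }
  if (n_cancer_types < 2 || n_cancer_types > length(tumor_type_codes())) {
    stop("n_cancer_types must lie in [2, 20]", call. = FALSE)
  }
  crit <- critical_tissues()
  pool <- .noncritical_tissue_pool()
  # per-gene quartile categorization marks the top quarter of a gene's
  # tissues "high", so planted genes need enough non-critical slots to soak
  # up every high category
  if (n_tissues < length(crit) + 5 || n_tissues > length(crit) + length(pool)) {
    stop("n_tissues must lie in [", length(crit) + 5, ", ",
         length(crit) + length(pool), "]", call. = FALSE)
  }
  if (n_tissues - floor((n_tissues - 1) * 0.75 + 1) > n_tissues - length(crit)) {
    stop("not enough non-critical tissues for the planted high categories",
         call. = FALSE)
  }

  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    ideal <- genes[seq_len(n_ideal)]
    decoys <- tibble::tibble(
      gene = genes[n_ideal + seq_len(length(stages) * n_decoy_per_stage)],
      stage = rep(stages, each = n_decoy_per_stage)
    )
    planted <- c(ideal, decoys$gene)
    background <- setdiff(genes, planted)
    cancers <- tumor_type_codes()[seq_len(n_cancer_types)]
    tissues <- c(crit, pool[seq_len(n_tissues - length(crit))])
    noncrit <- setdiff(tissues, crit)

    decoy_of <- function(stage) decoys$gene[decoys$stage == stage]

    ## --- annotations -------------------------------------------------
    ann <- tibble::tibble(
      gene = genes,
      is_membrane = TRUE,
      has_protein_evidence = TRUE,
      is_surfaceome = TRUE
    )
    bg_idx <- match(background, genes)
    ann$is_membrane[bg_idx] <- stats::runif(length(bg_idx)) < 0.5
    ann$has_protein_evidence[bg_idx] <- stats::runif(length(bg_idx)) < 0.8
    ann$is_surfaceome[bg_idx] <- stats::runif(length(bg_idx)) < 0.4
    ann$is_membrane[ann$gene %in% decoy_of("membrane")] <- FALSE
    ann$has_protein_evidence[ann$gene %in% decoy_of("protein_evidence")] <- FALSE
    ann$is_surfaceome[ann$gene %in% decoy_of("surfaceome")] <- FALSE

    ev <- tibble::tibble(
      gene = genes,
      literature = stats::runif(n_genes) < 0.3,
      antibody = stats::runif(n_genes) < 0.3,
      protein_family = stats::runif(n_genes) < 0.3,
      preclinical = stats::runif(n_genes) < 0.3,
      clinical = stats::runif(n_genes) < 0.3
    )
    ev$literature[ev$gene %in% planted] <- TRUE   # guarantees score >= 1
    for (cl in c("literature", "antibody", "protein_family", "preclinical",
                 "clinical")) {
      ev[[cl]][ev$gene %in% decoy_of("evidence")] <- FALSE
    }

    ## --- normal tissue mRNA + IHC ------------------------------------
    nm <- matrix(0, nrow = n_genes, ncol = length(tissues),
                 dimnames = list(genes, tissues))
    nm[bg_idx, ] <- stats::rlnorm(length(bg_idx) * length(tissues), 1, 1)
    zero_mask <- matrix(stats::runif(length(bg_idx) * length(tissues)) <
                          zero_rate,
                        nrow = length(bg_idx))
    nm[bg_idx, ][zero_mask] <- 0
    # a gene with well-separated high tissues gets exactly n - floor(h)
    # tissues above its type-7 Q3 (h = (n-1) * 0.75 + 1); plant that many
    # highs so no stray tissue is pushed into the high category
    n_high <- n_tissues - floor((n_tissues - 1) * 0.75 + 1)
    high_tissue <- list()
    for (g in planted) {
      ht <- sample(noncrit, n_high)
      if (g %in% decoy_of("critical_normal")) {
        ht <- c(ht[seq_len(n_high - 1)], "liver")
      }
      high_tissue[[g]] <- ht
      v <- stats::setNames(stats::rlnorm(length(tissues), 0.3, 0.3), tissues)
      v[ht] <- 30 * stats::rlnorm(length(ht), 0, 0.1)
      nm[g, ] <- v[tissues]
    }
    normal_mrna <- expr_matrix(nm, stats::setNames(tissues, tissues),
                               unit = "TPM")

    ihc <- mrna_tissue_levels(normal_mrna)
    # consistency decoys: report not-detected by IHC where mRNA is high
    for (g in decoy_of("consistency_6a")) {
      hit <- ihc$gene == g & ihc$tissue %in% high_tissue[[g]]
      ihc$level[hit] <- factor("not_detected", levels = expression_levels(),
                               ordered = TRUE)
    }
    normal_ihc <- ihc |>
      dplyr::mutate(cell_type = paste0(.data$tissue, " cells")) |>
      dplyr::select("gene", "tissue", "cell_type", "level")

    ## --- pathology fractions -----------------------------------------
    target_cancers <- lapply(stats::setNames(planted, planted),
                             function(g) sample(cancers, 2))
    path_rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      g <- genes[i]
      if (g %in% background) {
        fr <- t(vapply(seq_along(cancers),
                       function(j) .rdirichlet1(c(6, 3, 2, 1)),
                       numeric(4))) * 100
      } else if (g %in% decoy_of("tumor_quasi_h")) {
        fr <- matrix(rep(c(40, 30, 20, 10), each = length(cancers)),
                     ncol = 4)
      } else if (g %in% decoy_of("dual_score_6b")) {
        # deterministic sub-threshold fractions outside the target cancers,
        # so the gene's only IHC-passing cancers are the mRNA-cold ones
        fr <- matrix(rep(c(40, 30, 20, 10), each = length(cancers)),
                     ncol = 4)
        hit <- cancers %in% target_cancers[[g]]
        fr[hit, ] <- matrix(rep(c(5, 10, 20, 65), each = sum(hit)), ncol = 4)
      } else {
        fr <- t(vapply(seq_along(cancers),
                       function(j) .rdirichlet1(c(8, 4, 2, 0.5)),
                       numeric(4))) * 100
        hit <- cancers %in% target_cancers[[g]]
        fr[hit, ] <- matrix(rep(c(5, 10, 20, 65), each = sum(hit)), ncol = 4)
      }
      path_rows[[i]] <- tibble::tibble(
        gene = g, cancer_type = cancers,
        frac_low = fr[, 2], frac_medium = fr[, 3], frac_high = fr[, 4]
      )
    }
    pathology <- dplyr::bind_rows(path_rows)

    ## --- tumor expression --------------------------------------------
    samples <- as.vector(vapply(cancers, function(cc) {
      sprintf("S_%s_%03d", cc, seq_len(n_tumor_per_cohort))
    }, character(n_tumor_per_cohort)))
    cohort <- stats::setNames(rep(cancers, each = n_tumor_per_cohort),
                              samples)
    tm <- matrix(stats::rlnorm(n_genes * length(samples), 1, 1),
                 nrow = n_genes, dimnames = list(genes, samples))
    for (g in planted) {
      # a cohort scores < 150 against the gene's pan-cohort quartiles only
      # when most of its samples sit below the pooled Q1, so the 6b decoys
      # run COLD in their IHC-high cancers and hot everywhere else
      hot <- if (g %in% decoy_of("dual_score_6b")) {
        setdiff(cancers, target_cancers[[g]])
      } else {
        target_cancers[[g]]
      }
      base <- stats::rlnorm(length(samples), 1, 0.5)
      hot_samples <- cohort %in% hot
      base[hot_samples] <- stats::rlnorm(sum(hot_samples), 4, 0.5)
      tm[g, ] <- base
    }
    tumor_expr <- expr_matrix(tm, cohort, unit = "FPKM")

    ## --- hematopoietic expression ------------------------------------
    pops <- c("HSC", "MPP", "CMP", "GMP", "MEP", "Monocyte", "Erythroid")
    hema_samples <- as.vector(vapply(pops, function(p) {
      sprintf("%s_%d", p, 1:3)
    }, character(3)))
    hsc_samples <- hema_samples[startsWith(hema_samples, "HSC") |
                                  startsWith(hema_samples, "MPP")]
    hm <- matrix(stats::rlnorm(n_genes * length(hema_samples), 1, 1),
                 nrow = n_genes, dimnames = list(genes, hema_samples))
    for (g in setdiff(planted, decoy_of("hsc_mpp"))) {
      hm[g, ] <- stats::rlnorm(length(hema_samples),
                               if (match(g, planted) %% 2 == 0) 0 else 0.8,
                               0.3)
    }
    for (g in decoy_of("hsc_mpp")) {
      hm[g, ] <- stats::rlnorm(length(hema_samples), 0, 0.3)
      hm[g, hsc_samples] <- stats::rlnorm(length(hsc_samples), 3.5, 0.3)
    }
    absent_gene <- decoy_of("hsc_mpp")[n_decoy_per_stage]
    hm <- hm[setdiff(genes, absent_gene), , drop = FALSE]
    hema_expr <- expr_matrix(
      hm, stats::setNames(sub("_[0-9]+$", "", hema_samples), hema_samples),
      unit = "AU")

    truth <- list(
      ideal_targets = ideal,
      decoys = decoys,
      target_cancers = dplyr::bind_rows(lapply(ideal, function(g) {
        tibble::tibble(gene = g, cancer_type = target_cancers[[g]])
      })),
      counts = list(
        membrane = sum(ann$is_membrane),
        membrane_evidence = sum(ann$is_membrane & ann$has_protein_evidence)
      )
    )
    list(annotation = ann, evidence = ev, normal_ihc = normal_ihc,
         normal_mrna = normal_mrna, pathology = pathology,
         tumor_expr = tumor_expr, hema_expr = hema_expr,
         hsc_samples = hsc_samples, truth = truth)
  })
}

#' Generate mutation-screen inputs with planted associations
#'
#' Wild-type expression is log-normal (meanlog 3, sdlog 0.5 by default on a
#' TPM-like scale, keeping the pseudocount in the fold-change estimator
#' negligible); samples mutated in a planted (target, query, cohort) spec
#' have the target's expression scaled by `2^log2_fc`; mutation calls are
#' Bernoulli at the spec's mutated fraction. Background query genes receive
#' effect-free Bernoulli calls.
#'
#' @param cohorts Cohort (tumor-type) labels.
#' @param n_per_cohort Samples per cohort (>= 2).
#' @param planted Tibble with columns target, query, cohort, log2_fc,
#'   fraction (fraction in (0,1), finite effect). The same (query, cohort)
#'   pair must not appear with two different fractions.
#' @param seed Mandatory integer seed.
#' @param meanlog,sdlog Wild-type log-normal parameters.
#' @param background_queries Extra query genes with calls but no effect.
#' @param background_rate Mutation rate for background queries.
#' @return List with `expr` ([expr_matrix()]), `muts` (sample, gene) and
#'   `truth` (the planted tibble).
#' @export
synth_mutation_bundle <- function(cohorts, n_per_cohort, planted, seed,
                                  meanlog = 3, sdlog = 0.5,
                                  background_queries = character(),
                                  background_rate = 0.1) {
  stopifnot(!missing(seed))
  if (n_per_cohort < 2) {
    stop("cohorts need at least 2 samples", call. = FALSE)
  }
  planted <- tibble::as_tibble(planted)
  stopifnot(all(c("target", "query", "cohort", "log2_fc", "fraction") %in%
                  names(planted)))
  if (any(planted$fraction <= 0 | planted$fraction >= 1) ||
      any(!is.finite(planted$log2_fc))) {
    stop("planted specs need fraction in (0,1) and finite log2_fc",
         call. = FALSE)
  }
  qc <- dplyr::distinct(planted[c("query", "cohort", "fraction")])
  if (anyDuplicated(qc[c("query", "cohort")])) {
    stop("conflicting fractions for one (query, cohort) pair", call. = FALSE)
  }
  withr::with_seed(seed, {
    samples <- as.vector(vapply(cohorts, function(cc) {
      sprintf("S_%s_%03d", cc, seq_len(n_per_cohort))
    }, character(n_per_cohort)))
    cohort <- stats::setNames(rep(cohorts, each = n_per_cohort), samples)
    targets <- unique(planted$target)
    m <- matrix(stats::rlnorm(length(targets) * length(samples), meanlog,
                              sdlog),
                nrow = length(targets), dimnames = list(targets, samples))
    mut_rows <- list()
    for (i in seq_len(nrow(qc))) {
      cs <- samples[cohort == qc$cohort[i]]
      hit <- cs[stats::runif(length(cs)) < qc$fraction[i]]
      if (length(hit) > 0) {
        mut_rows[[length(mut_rows) + 1]] <-
          tibble::tibble(sample = hit, gene = qc$query[i])
      }
    }
    for (q in background_queries) {
      hit <- samples[stats::runif(length(samples)) < background_rate]
      if (length(hit) > 0) {
        mut_rows[[length(mut_rows) + 1]] <-
          tibble::tibble(sample = hit, gene = q)
      }
    }
    muts <- if (length(mut_rows) > 0) {
      dplyr::distinct(dplyr::bind_rows(mut_rows))
    } else {
      tibble::tibble(sample = character(), gene = character())
    }
    for (i in seq_len(nrow(planted))) {
      cs <- samples[cohort == planted$cohort[i]]
      hit <- intersect(cs, muts$sample[muts$gene == planted$query[i]])
      m[planted$target[i], hit] <- m[planted$target[i], hit] *
        2^planted$log2_fc[i]
    }
    list(expr = expr_matrix(m, cohort, unit = "TPM"), muts = muts,
         truth = planted)
  })
}

.reflect_above <- function(x, floor) ifelse(x < floor, 2 * floor - x, x)

#' Generate a GI50 measurement bundle with planted payload groups
#'
#' Plants compounds realizing the three final sensitivity groups of the
#' payload workflow: picomolar-only compounds (all lines of one responsive
#' panel at GI50 <= 1 nM, everything else inactive and never inside the
#' 1-10 nM band), low-nanomolar-only compounds (responsive panel inside the
#' band), and overlap compounds (one panel at picomolar, another in the
#' band). Responsive panels cycle through the nine indications so each group
#' carries distinct per-panel sensitivity patterns. Background compounds are
#' inactive: Normal(-6, 1) on the log10 molar scale, reflected above -7.8 so
#' no background line leaks into the potency windows. A configurable subset
#' of extra nano-like compounds is flagged as failed screens, duplicate-name
#' twin accessions exercise compound merging, and some background compounds
#' are unnamed.
#'
#' @param seed Mandatory integer seed.
#' @param planted_sizes Named integer vector: picomolar_only,
#'   low_nanomolar_only, overlap.
#' @param n_background Inactive background compounds.
#' @param n_failed Failed-screen compounds (nano-like, removed by the
#'   workflow).
#' @param n_dupe_pairs Duplicate-name twin accessions (merged on dedupe).
#' @param n_unnamed Unnamed background compounds.
#' @param lines_per_panel Named integer vector of cell lines per panel (all
#'   positive).
#' @param partial_every Every k-th planted compound responds in only ~60% of
#'   its panel's lines (still above the 50% qualifier).
#' @param payload_names Optional compound names assigned to the first
#'   low-nanomolar planted compounds (for combination matching).
#' @return List with `measurements` (gi50 tibble) and `truth` (group
#'   memberships, responsive panels, failed ids, dupe pairs).
#' @export
synth_gi50_bundle <- function(seed,
                              planted_sizes = c(picomolar_only = 33,
                                                low_nanomolar_only = 631,
                                                overlap = 65),
                              n_background = 300, n_failed = 20,
                              n_dupe_pairs = 5, n_unnamed = 10,
                              lines_per_panel = nci60_lines_per_panel(),
                              partial_every = 5,
                              payload_names = NULL) {
  stopifnot(!missing(seed))
  panels <- names(lines_per_panel)
  if (any(lines_per_panel <= 0)) {
    stop("every panel needs at least one cell line", call. = FALSE)
  }
  lines <- dplyr::bind_rows(lapply(panels, function(p) {
    tibble::tibble(panel = p,
                   cell_line = sprintf("%s_line%02d", gsub("[^A-Za-z]", "",
                                                           p),
                                       seq_len(lines_per_panel[[p]])))
  }))
  n_pico <- planted_sizes[["picomolar_only"]]
  n_nano <- planted_sizes[["low_nanomolar_only"]]
  n_over <- planted_sizes[["overlap"]]

  withr::with_seed(seed, {
    inactive <- function(n) .reflect_above(stats::rnorm(n, -6, 1), -7.8)
    pico_vals <- function(n) pmin(stats::rnorm(n, -9.6, 0.15), -9.05)
    band_vals <- function(n) pmin(pmax(stats::rnorm(n, -8.5, 0.12), -8.95),
                                  -8.05)

    next_nsc <- 1000L
    rows <- list()
    truth_panel <- list()
    add_compound <- function(kind, idx, name, failed = FALSE,
                             status = "none", full = FALSE) {
      nsc <- next_nsc
      next_nsc <<- next_nsc + 1L
      vals <- inactive(nrow(lines))
      frac <- if (!full && idx %% partial_every == 0) 0.6 else 1
      resp <- panels[(idx - 1) %% length(panels) + 1]
      in_panel <- which(lines$panel == resp)
      n_resp <- ceiling(frac * length(in_panel))
      resp_lines <- in_panel[seq_len(n_resp)]
      if (kind == "pico") {
        vals[resp_lines] <- pico_vals(n_resp)
      } else if (kind == "nano") {
        vals[resp_lines] <- band_vals(n_resp)
      } else if (kind == "overlap") {
        vals[resp_lines] <- pico_vals(n_resp)
        second <- panels[idx %% length(panels) + 1]
        in2 <- which(lines$panel == second)
        vals[in2] <- band_vals(length(in2))
      }
      rows[[length(rows) + 1]] <<- tibble::tibble(
        nsc_id = nsc, name = name, cell_line = lines$cell_line,
        panel = lines$panel, log_gi50 = vals, failed_screen = failed,
        status = status
      )
      truth_panel[[length(truth_panel) + 1]] <<-
        tibble::tibble(nsc_id = nsc, kind = kind,
                       panel = if (kind == "background") NA_character_
                               else resp)
      nsc
    }

    status_for <- function(i, kind) {
      if (kind == "pico" && i == 1) "fda_approved"
      else if (kind == "pico" && i == 2) "clinical"
      else if (kind == "nano" && i <= 5) "fda_approved"
      else if (kind == "nano" && i <= 10) "clinical"
      else if (kind == "overlap" && i <= 2) "fda_approved"
      else "none"
    }

    pico_ids <- vapply(seq_len(n_pico), function(i) {
      add_compound("pico", i, sprintf("CPD-P%04d", i),
                   status = status_for(i, "pico"))
    }, integer(1))
    nano_names <- sprintf("CPD-N%04d", seq_len(n_nano))
    if (!is.null(payload_names)) {
      stopifnot(length(payload_names) <= n_nano)
      nano_names[seq_along(payload_names)] <- payload_names
    }
    nano_ids <- vapply(seq_len(n_nano), function(i) {
      # payload-named compounds keep a fully (100%) responsive panel so
      # they can anchor target-indication-payload combinations
      add_compound("nano", i, nano_names[i], status = status_for(i, "nano"),
                   full = !is.null(payload_names) &&
                     i <= length(payload_names))
    }, integer(1))
    over_ids <- vapply(seq_len(n_over), function(i) {
      add_compound("overlap", i, sprintf("CPD-O%04d", i),
                   status = status_for(i, "overlap"))
    }, integer(1))
    failed_ids <- vapply(seq_len(n_failed), function(i) {
      add_compound("nano", i, sprintf("CPD-F%04d", i), failed = TRUE)
    }, integer(1))
    bg_ids <- vapply(seq_len(n_background), function(i) {
      nm <- if (i <= n_unnamed) NA_character_ else sprintf("CPD-B%04d", i)
      add_compound("background", i, nm)
    }, integer(1))

    # duplicate-name twins of the first nano compounds (distinct NSC ids,
    # case/whitespace name variants); merged back on dedupe
    stopifnot(n_dupe_pairs <= n_nano)
    dupe_pairs <- tibble::tibble(kept = integer(), merged = integer())
    for (i in seq_len(n_dupe_pairs)) {
      twin_name <- paste0(toupper(nano_names[i]), " ")
      orig <- rows[[which(vapply(rows, function(r) r$nsc_id[1] == nano_ids[i],
                                 logical(1)))]]
      nsc <- next_nsc
      next_nsc <- next_nsc + 1L
      jig <- orig
      jig$nsc_id <- nsc
      jig$name <- twin_name
      in_band <- jig$log_gi50 <= -8.05 & jig$log_gi50 > -8.95
      jig$log_gi50[!in_band] <- inactive(sum(!in_band))
      jig$log_gi50[in_band] <- band_vals(sum(in_band))
      rows[[length(rows) + 1]] <- jig
      dupe_pairs <- dplyr::bind_rows(dupe_pairs,
                                     tibble::tibble(kept = nano_ids[i],
                                                    merged = nsc))
    }

    measurements <- dplyr::bind_rows(rows)
    # replicate a few (compound, line) pairs to exercise aggregation
    reps <- measurements[seq(1, nrow(measurements), by = 997), ]
    reps$log_gi50 <- reps$log_gi50 + stats::rnorm(nrow(reps), 0, 0.01)
    measurements <- dplyr::bind_rows(measurements, reps)

    truth <- list(
      groups = list(picomolar_only = pico_ids,
                    low_nanomolar_only = nano_ids,
                    overlap = over_ids),
      responsive_panels = dplyr::bind_rows(truth_panel),
      failed = failed_ids,
      dupe_pairs = dupe_pairs
    )
    list(measurements = measurements, truth = truth)
  })
}
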