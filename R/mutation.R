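#' Exact two-sided Wilcoxon rank-sum p-value by permutation enumeration
#'
#' Enumerates every assignment of the pooled observations to the two groups
#' (using midranks, so ties are handled exactly) and returns the two-sided
#' tail probability of the observed rank sum around its permutation mean.
#' Intended for small groups; the combined size must not exceed
#' `max_n` (the C(20,10) = 184,756 enumeration is the practical ceiling).
#'
#' @param x,y Numeric vectors of the two groups' values.
#' @param max_n Largest combined size accepted.
#' @return Two-sided p-value in (0, 1].
#' @export
ranksum_exact_p <- function(x, y, max_n = 20) {
  n1 <- length(x)
  n <- n1 + length(y)
  if (n > max_n) stop("combined size too large for exact enumeration",
                      call. = FALSE)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  sums <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
}

.ranksum_p <- function(x, y, exact_max_n = 20) {
  if (length(unique(c(x, y))) == 1) return(1)
  if (length(x) + length(y) <= exact_max_n) {
    ranksum_exact_p(x, y)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Mutant-versus-wild-type expression association for one triple
#'
#' Splits a tumor cohort into samples carrying a somatic mutation in the
#' query gene and wild-type samples, then compares the target gene's
#' expression between the groups: a two-sided Wilcoxon rank-sum p-value
#' (exact tie-aware enumeration for combined n of at most 20, normal
#' approximation with tie and continuity correction above) and a fold change
#' `log2((mean_mut + 1) / (mean_wt + 1))` on the abundance scale.
#'
#' @param expr Tumor [expr_matrix()].
#' @param muts Mutation call tibble (sample, gene).
#' @param cohort Cohort (tumor-type) code.
#' @param target Target gene symbol (expression readout).
#' @param query_gene Mutated query gene symbol (grouping).
#' @param min_group Minimum group size for testability (default 3); smaller
#'   groups yield `testable = FALSE` with NA statistics rather than an error.
#' @param covered_samples Optional sample ids with mutation data in this
#'   cohort; samples outside it are excluded from both groups. When NULL,
#'   every cohort sample without a call is treated as wild-type.
#' @return One-row tibble: target, query_gene, cohort, log2_fc, p_value,
#'   prevalence, direction ("up"/"down"/"none"), n_mut, n_wt, testable.
#' @export
association_test <- function(expr, muts, cohort, target, query_gene,
                             min_group = 3, covered_samples = NULL) {
  stopifnot(is_expr_matrix(expr))
  if (!target %in% rownames(expr$values)) {
    stop("target gene absent from expression matrix: ", target,
         call. = FALSE)
  }
  samples <- cohort_samples(expr, cohort)
  if (!is.null(covered_samples)) samples <- intersect(samples, covered_samples)
  mut_samples <- unique(muts$sample[muts$gene == query_gene])
  grp_mut <- intersect(samples, mut_samples)
  grp_wt <- setdiff(samples, grp_mut)
  n_mut <- length(grp_mut)
  n_wt <- length(grp_wt)
  base <- tibble::tibble(
    target = target, query_gene = query_gene, cohort = cohort,
    log2_fc = NA_real_, p_value = NA_real_,
    prevalence = if (n_mut + n_wt > 0) n_mut / (n_mut + n_wt) else NA_real_,
    direction = NA_character_, n_mut = n_mut, n_wt = n_wt, testable = FALSE
  )
  if (n_mut < min_group || n_wt < min_group) return(base)
  vx <- expr$values[target, grp_mut]
  vy <- expr$values[target, grp_wt]
  lfc <- log2((mean(vx) + 1) / (mean(vy) + 1))
  base$log2_fc <- lfc
  base$p_value <- .ranksum_p(vx, vy)
  base$direction <- if (lfc > 0) "up" else if (lfc < 0) "down" else "none"
  base$testable <- TRUE
  base
}

#' Screen all target x query x cohort triples for mutation-linked expression
#'
#' Runs [association_test()] over every combination and retains records
#' passing all three gates: p-value below `alpha`, absolute log2 fold change
#' of at least `min_abs_log2fc`, and mutation prevalence of at least
#' `min_prevalence`. Both up- and down-regulated associations are retained.
#' No multiple-testing correction is applied by default (raw p-values); set
#' `adjust = "BH"` for Benjamini-Hochberg across the screened triples.
#'
#' @param expr Tumor [expr_matrix()].
#' @param muts Mutation call tibble (sample, gene).
#' @param targets Target gene symbols.
#' @param queries Query (mutated) gene symbols.
#' @param alpha Significance gate on the p-value (default 0.05, strict <).
#' @param min_abs_log2fc Fold-change gate on |log2 FC| (default 1, >=).
#' @param min_prevalence Prevalence gate (default 0.05, >=).
#' @param min_group Minimum per-group size (default 3).
#' @param covered_samples Optional named list, cohort -> sample ids with
#'   mutation coverage (see [association_test()]).
#' @param adjust "none" (default) or "BH".
#' @return Tibble of passing association records.
#' @export
screen_associations <- function(expr, muts, targets, queries,
                                alpha = 0.05, min_abs_log2fc = 1,
                                min_prevalence = 0.05, min_group = 3,
                                covered_samples = NULL, adjust = "none") {
  if (length(targets) == 0 || length(queries) == 0) {
    return(association_test(
      expr, muts, unique(expr$cohort)[1],
      rownames(expr$values)[1], "none")[0, ])
  }
  cohorts <- unique(expr$cohort)
  grid <- tidyr::expand_grid(cohort = cohorts, target = targets,
                             query_gene = queries)
  recs <- purrr::pmap_dfr(grid, function(cohort, target, query_gene) {
    association_test(expr, muts, cohort, target, query_gene,
                     min_group = min_group,
                     covered_samples = covered_samples[[cohort]])
  })
  recs <- recs[recs$testable, ]
  if (nrow(recs) == 0) return(recs)
  if (adjust == "BH") recs$p_value <- stats::p.adjust(recs$p_value, "BH")
  recs[recs$p_value < alpha &
         abs(recs$log2_fc) >= min_abs_log2fc &
         recs$prevalence >= min_prevalence, ]
}

#' Summarize screened associations per query gene
#'
#' @param records Association tibble from [screen_associations()].
#' @return Tibble (query_gene, n_targets, n_cohorts, n_up, n_down) with
#'   distinct-target and distinct-cohort counts.
#' @export
summarize_by_query <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(query_gene = character(), n_targets = integer(),
                          n_cohorts = integer(), n_up = integer(),
                          n_down = integer()))
  }
  records |>
    dplyr::group_by(.data$query_gene) |>
    dplyr::summarise(
      n_targets = dplyr::n_distinct(.data$target),
      n_cohorts = dplyr::n_distinct(.data$cohort),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop"
    )
}

#' Cohort x query fold-change table for one target
#'
#' The tabular backing of a per-target "radar" view: one row per cohort, one
#' column per query gene, cells holding log2 fold changes of the screened
#' associations (NA where no association passed).
#'
#' @param records Association tibble.
#' @param target Target gene symbol.
#' @return Wide tibble, first column `cohort`.
#' @export
radar_table <- function(records, target) {
  sub <- records[records$target == target, ]
  tidyr::pivot_wider(sub[c("cohort", "query_gene", "log2_fc")],
                     names_from = "query_gene", values_from = "log2_fc")
}
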