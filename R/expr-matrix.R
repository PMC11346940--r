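#' Gene-by-sample expression matrix with cohort labels
#'
#' A light container for normalized abundance values (FPKM/TPM) across
#' samples, each sample carrying a cohort label (a tumor-type code, a tissue
#' name, or a cell-type label depending on the study).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). No negative values.
#' @param cohort Character vector of cohort labels, one per sample; either
#'   named by sample id or in column order.
#' @param unit Abundance unit, recorded for provenance ("TPM", "FPKM", "AU").
#' @return Object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, cohort, unit = "AU") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  if (is.null(names(cohort))) {
    if (length(cohort) != ncol(values)) {
      stop("cohort labels must cover every sample", call. = FALSE)
    }
    names(cohort) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(cohort))
  if (length(missing) > 0) {
    stop("samples without a cohort label: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  structure(
    list(values = values,
         cohort = as.character(cohort[colnames(values)]) |>
           stats::setNames(colnames(values)),
         unit = unit),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", x$unit, "); cohorts: ",
      paste(utils::head(unique(x$cohort), 8), collapse = ", "),
      if (length(unique(x$cohort)) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname expr_matrix
#' @param x Object to test.
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

#' Sample ids of a cohort
#' @param expr An `expr_matrix`.
#' @param cohort Cohort label.
#' @return Character vector of sample ids.
#' @export
cohort_samples <- function(expr, cohort) {
  names(expr$cohort)[expr$cohort == cohort]
}

#' Genes present in the matrix
#' @param expr An `expr_matrix`.
#' @return Character vector of gene symbols.
#' @export
expr_genes <- function(expr) rownames(expr$values)

#' Convert an expression matrix to long tidy form
#'
#' @param expr An `expr_matrix`.
#' @return Tibble with columns `gene`, `sample`, `cohort`, `value`.
#' @export
expr_to_long <- function(expr) {
  stopifnot(is_expr_matrix(expr))
  tibble::tibble(
    gene = rep(rownames(expr$values), times = ncol(expr$values)),
    sample = rep(colnames(expr$values), each = nrow(expr$values)),
    cohort = rep(unname(expr$cohort), each = nrow(expr$values)),
    value = as.numeric(expr$values)
  )
}

#' Build an expression matrix from long tidy form
#'
#' @param df Data frame with columns `gene`, `sample`, `cohort`, `value`.
#' @param unit Abundance unit.
#' @return An `expr_matrix`.
#' @export
expr_from_long <- function(df, unit = "AU") {
  stopifnot(all(c("gene", "sample", "cohort", "value") %in% names(df)))
  genes <- unique(df$gene)
  samples <- unique(df$sample)
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(df$gene, genes), match(df$sample, samples))] <- df$value
  if (anyNA(m)) {
    stop("long expression table does not cover every gene x sample cell",
         call. = FALSE)
  }
  cohort <- df$cohort[!duplicated(df$sample)]
  names(cohort) <- df$sample[!duplicated(df$sample)]
  conflict <- tapply(df$cohort, df$sample, function(v) length(unique(v)) > 1)
  if (any(conflict)) {
    stop("conflicting cohort labels for sample(s): ",
         paste(names(conflict)[conflict], collapse = ", "), call. = FALSE)
  }
  expr_matrix(m, cohort, unit = unit)
}
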