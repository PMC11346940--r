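#' Expression level vocabulary
#'
#' The four ordinal staining/expression levels used throughout the pipeline,
#' in increasing order: not detected < low < medium < high. Serialized table
#' forms ("Not detected", "Low", "Medium", "High") map onto these
#' case-insensitively.
#'
#' @return Character vector of the four level names in increasing order.
#' @export
expression_levels <- function() {
  c("not_detected", "low", "medium", "high")
}

#' Parse serialized expression-level strings
#'
#' @param x Character vector of level strings ("Not detected", "low", ...).
#'   Matching is case-insensitive; spaces and hyphens are treated as
#'   underscores.
#' @return Ordered factor over [expression_levels()].
#' @export
parse_expression_level <- function(x) {
  norm <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  bad <- !is.na(x) & !(norm %in% expression_levels())
  if (any(bad)) {
    stop(
      "unknown expression level(s): ",
      paste(unique(x[bad]), collapse = ", "),
      "; accepted values are: Not detected, Low, Medium, High",
      call. = FALSE
    )
  }
  factor(norm, levels = expression_levels(), ordered = TRUE)
}

#' Ordinal distance between two expression levels
#'
#' @param a,b Ordered factors (or strings) over the four-level vocabulary.
#' @return Integer vector of absolute rank differences (0-3).
#' @export
level_distance <- function(a, b) {
  if (!is.factor(a)) a <- parse_expression_level(a)
  if (!is.factor(b)) b <- parse_expression_level(b)
  abs(as.integer(a) - as.integer(b))
}

#' Categorize expression values by quartiles
#'
#' Bins non-negative abundance values (FPKM/TPM-like) into ordinal expression
#' categories using the first and third quartiles of the supplied values
#' (computed over all values, zeros included, by linear interpolation between
#' order statistics -- sample-quantile type 7).
#'
#' Two schemes are available:
#' \describe{
#'   \item{four_level}{0 -> not_detected; (0, Q1] -> low; (Q1, Q3] -> medium;
#'     > Q3 -> high. Used to align mRNA abundance with four-level IHC
#'     annotation.}
#'   \item{three_level}{< Q1 -> low; [Q1, Q3] -> medium; > Q3 -> high. Used
#'     for mRNA-derived quasi H-scores and the hematopoietic screen, where no
#'     not-detected class exists.}
#' }
#'
#' @param values Numeric vector of non-negative values (at least 4).
#' @param scheme "four_level" or "three_level".
#' @param quartiles Optional numeric c(Q1, Q3) to categorize against reference
#'   quartiles computed elsewhere (e.g. a global or pan-cohort reference)
#'   instead of quartiles of `values` itself.
#' @return Ordered factor over [expression_levels()], same length as `values`.
#' @export
categorize_quartiles <- function(values,
                                 scheme = c("four_level", "three_level"),
                                 quartiles = NULL) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  if (is.null(quartiles)) {
    if (length(values) < 4) {
      stop("insufficient samples for quartile categorization (need >= 4)",
           call. = FALSE)
    }
    quartiles <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  }
  q1 <- quartiles[[1]]
  q3 <- quartiles[[2]]
  out <- if (scheme == "four_level") {
    ifelse(values == 0, "not_detected",
      ifelse(values <= q1, "low",
        ifelse(values <= q3, "medium", "high")))
  } else {
    ifelse(values < q1, "low",
      ifelse(values <= q3, "medium", "high"))
  }
  factor(out, levels = expression_levels(), ordered = TRUE)
}

#' Quasi H-score from staining-level fractions
#'
#' The quasi H-score summarizes the distribution of patients (or samples)
#' across staining levels as
#' `1 * %low + 2 * %medium + 3 * %high`, ranging from 0 (all patients
#' not-detected) to 300 (all patients high).
#'
#' @param frac_low,frac_medium,frac_high Percentages of patients (0-100) at
#'   each level. Vectors are recycled by the usual rules. The remainder to
#'   100 is the not-detected fraction and contributes nothing.
#' @return Numeric score(s) in [0, 300].
#' @export
quasi_h_score <- function(frac_low, frac_medium, frac_high) {
  fr <- cbind(frac_low, frac_medium, frac_high)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 100)) {
    stop("staining fractions must be percentages in [0, 100]", call. = FALSE)
  }
  tot <- rowSums(fr)
  if (any(tot > 100 + 1e-9)) {
    stop("staining fractions sum above 100% (rows: ",
         paste(which(tot > 100 + 1e-9), collapse = ", "), ")", call. = FALSE)
  }
  as.numeric(fr %*% c(1, 2, 3))
}
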