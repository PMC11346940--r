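#' Default NCI60 indication panel vocabulary
#'
#' The nine tumor-type panels of the NCI 60-cell-line screen.
#'
#' @return Character vector of nine panel names.
#' @export
nci60_panels <- function() {
  c("Leukemia", "Non-Small Cell Lung Cancer", "Colon Cancer", "CNS Cancer",
    "Melanoma", "Ovarian Cancer", "Renal Cancer", "Prostate Cancer",
    "Breast Cancer")
}

#' Default number of screened cell lines per NCI60 panel
#' @return Named integer vector over [nci60_panels()] (sums to 60).
#' @export
nci60_lines_per_panel <- function() {
  stats::setNames(c(6L, 9L, 7L, 6L, 9L, 7L, 8L, 2L, 6L), nci60_panels())
}

#' The thirteen critical normal tissues
#'
#' Tissues in which high target expression disqualifies an ADC antigen
#' (on-target off-tumor toxicity risk).
#'
#' @return Character vector of 13 tissue names.
#' @export
critical_tissues <- function() {
  c("lung", "oral mucosa", "esophagus", "stomach", "duodenum",
    "small intestine", "colon", "rectum", "liver", "kidney",
    "heart muscle", "skin", "bone marrow")
}

#' Default tumor-type codes
#'
#' Twenty TCGA-style tumor-type codes used as the default cancer vocabulary
#' for pathology scoring and cohort labels.
#'
#' @return Character vector of 20 codes.
#' @export
tumor_type_codes <- function() {
  c("BRCA", "OV", "PRAD", "COAD", "SKCM", "GBM", "LGG", "LUAD", "LUSC",
    "LAML", "KIRC", "PAAD", "THCA", "UCEC", "CESC", "STAD", "LIHC",
    "BLCA", "HNSC", "ESCA")
}

.schemas <- function() {
  list(
    normal_tissue = list(cols = c("gene", "tissue", "cell_type", "level")),
    pathology = list(cols = c("gene", "cancer_type")),
    gene_annotation = list(cols = c("gene", "is_membrane",
                                    "has_protein_evidence", "is_surfaceome")),
    evidence = list(cols = c("gene", "literature", "antibody",
                             "protein_family", "preclinical", "clinical")),
    expression_matrix = list(cols = c("gene", "sample", "cohort", "value")),
    mutation = list(cols = c("sample", "gene")),
    gi50 = list(cols = c("nsc_id", "name", "cell_line", "panel", "log_gi50",
                         "failed_screen", "status"))
  )
}

.parse_flag <- function(x, col, rows) {
  norm <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[norm %in% c("true", "t", "1", "yes")] <- TRUE
  out[norm %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(is.na(out) & !is.na(x) & norm != "na" & norm != "")
  if (length(bad) > 0) {
    stop("column '", col, "': unparseable logical at file line(s) ",
         paste(utils::head(rows[bad], 5), collapse = ", "), call. = FALSE)
  }
  out
}

.parse_num <- function(x, col, rows) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "" & toupper(trimws(x)) != "NA")
  if (length(bad) > 0) {
    stop("column '", col, "': unparseable numeric '",
         x[bad[1]], "' at file line ", rows[bad[1]], call. = FALSE)
  }
  out
}

#' Read and validate a pipeline input table
#'
#' Reads a UTF-8 TSV with a mandatory header row ("NA" or empty cell =
#' missing), validates it against one of the pipeline schemas, normalizes
#' category strings, and returns a typed record collection. Error messages
#' carry file line numbers (header = line 1).
#'
#' Schemas:
#' \describe{
#'   \item{normal_tissue}{gene, tissue, cell_type, level (four-level IHC
#'     vocabulary); (gene, tissue, cell_type) unique.}
#'   \item{pathology}{gene, cancer_type plus either percentage columns
#'     `frac_low`, `frac_medium`, `frac_high` (each 0-100, summing to at most
#'     100; remainder = not-detected patients) or patient-count columns
#'     `n_not_detected`, `n_low`, `n_medium`, `n_high`, which are converted
#'     to percentages.}
#'   \item{gene_annotation}{gene plus logical flags is_membrane,
#'     has_protein_evidence, is_surfaceome.}
#'   \item{evidence}{gene plus the five logical prioritization criteria:
#'     literature, antibody, protein_family, preclinical, clinical.}
#'   \item{expression_matrix}{long form gene, sample, cohort, value;
#'     returned as an [expr_matrix()].}
#'   \item{mutation}{sample, gene somatic calls; duplicated pairs are
#'     collapsed.}
#'   \item{gi50}{nsc_id, name, cell_line, panel, log_gi50 (log10 molar),
#'     failed_screen, status in none/clinical/fda_approved; panel must come
#'     from `panels`.}
#' }
#'
#' @param path Path to the TSV file.
#' @param schema One of the schema names above.
#' @param panels Accepted panel vocabulary for the gi50 schema.
#' @param unit Abundance unit recorded for the expression_matrix schema.
#' @return A tibble of typed records, or an [expr_matrix()] for the
#'   expression_matrix schema. The tibble carries the originating file line
#'   number in the `.row` column.
#' @export
read_adc_table <- function(path, schema, panels = nci60_panels(),
                           unit = "AU") {
  schemas <- .schemas()
  if (!schema %in% names(schemas)) {
    stop("unknown schema '", schema, "'; expected one of: ",
         paste(names(schemas), collapse = ", "), call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"), progress = FALSE)
  need <- schemas[[schema]]$cols
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("schema '", schema, "': missing mandatory column(s) ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  rows <- seq_len(nrow(df)) + 1L  # file line numbers; header is line 1
  df$.row <- rows

  switch(schema,
    normal_tissue = {
      df$level <- parse_expression_level(df$level)
      key <- paste(df$gene, df$tissue, df$cell_type, sep = "\r")
      if (anyDuplicated(key)) {
        stop("duplicate (gene, tissue, cell_type) at file line ",
             rows[which(duplicated(key))[1]], call. = FALSE)
      }
      df[c("gene", "tissue", "cell_type", "level", ".row")]
    },
    pathology = {
      has_frac <- all(c("frac_low", "frac_medium", "frac_high") %in% names(df))
      has_counts <- all(c("n_not_detected", "n_low", "n_medium", "n_high") %in%
                          names(df))
      if (!has_frac && !has_counts) {
        stop("schema 'pathology': need frac_low/frac_medium/frac_high or ",
             "n_not_detected/n_low/n_medium/n_high columns", call. = FALSE)
      }
      if (has_frac) {
        for (cl in c("frac_low", "frac_medium", "frac_high")) {
          df[[cl]] <- .parse_num(df[[cl]], cl, rows)
        }
      } else {
        cnt <- sapply(c("n_not_detected", "n_low", "n_medium", "n_high"),
                      function(cl) .parse_num(df[[cl]], cl, rows))
        cnt <- matrix(cnt, nrow = nrow(df))
        tot <- rowSums(cnt)
        if (any(tot <= 0)) {
          stop("pathology counts sum to zero at file line ",
               rows[which(tot <= 0)[1]], call. = FALSE)
        }
        df$frac_low <- 100 * cnt[, 2] / tot
        df$frac_medium <- 100 * cnt[, 3] / tot
        df$frac_high <- 100 * cnt[, 4] / tot
      }
      fr <- cbind(df$frac_low, df$frac_medium, df$frac_high)
      bad <- which(apply(fr, 1, function(v) any(v < 0 | v > 100)) |
                     rowSums(fr) > 100 + 1e-9)
      if (length(bad) > 0) {
        stop("pathology fractions out of range or summing above 100% at ",
             "file line ", rows[bad[1]], call. = FALSE)
      }
      df[c("gene", "cancer_type", "frac_low", "frac_medium", "frac_high",
           ".row")]
    },
    gene_annotation = ,
    evidence = {
      flags <- setdiff(need, "gene")
      for (cl in flags) df[[cl]] <- .parse_flag(df[[cl]], cl, rows)
      if (any(is.na(df$gene) | trimws(df$gene) == "")) {
        stop("empty gene symbol at file line ",
             rows[which(is.na(df$gene) | trimws(df$gene) == "")[1]],
             call. = FALSE)
      }
      if (anyDuplicated(df$gene)) {
        stop("duplicate gene symbol '",
             df$gene[which(duplicated(df$gene))[1]], "' at file line ",
             rows[which(duplicated(df$gene))[1]], call. = FALSE)
      }
      df[c(need, ".row")]
    },
    expression_matrix = {
      df$value <- .parse_num(df$value, "value", rows)
      if (any(df$value < 0, na.rm = TRUE)) {
        stop("negative expression value at file line ",
             rows[which(df$value < 0)[1]], call. = FALSE)
      }
      expr_from_long(df, unit = unit)
    },
    mutation = {
      dplyr::distinct(df[c("sample", "gene")], .keep_all = FALSE) |>
        dplyr::mutate(.row = NA_integer_)
    },
    gi50 = {
      df$nsc_id <- .parse_num(df$nsc_id, "nsc_id", rows)
      df$log_gi50 <- .parse_num(df$log_gi50, "log_gi50", rows)
      bad <- which(!is.finite(df$log_gi50))
      if (length(bad) > 0) {
        stop("non-finite log_gi50 at file line ", rows[bad[1]], call. = FALSE)
      }
      df$failed_screen <- .parse_flag(df$failed_screen, "failed_screen", rows)
      df$failed_screen[is.na(df$failed_screen)] <- FALSE
      df$status[is.na(df$status)] <- "none"
      bad <- which(!df$status %in% c("none", "clinical", "fda_approved"))
      if (length(bad) > 0) {
        stop("unknown status '", df$status[bad[1]], "' at file line ",
             rows[bad[1]], "; accepted: none, clinical, fda_approved",
             call. = FALSE)
      }
      bad <- which(!df$panel %in% panels)
      if (length(bad) > 0) {
        stop("unknown panel '", df$panel[bad[1]], "' at file line ",
             rows[bad[1]], "; accepted panels: ",
             paste(panels, collapse = ", "), call. = FALSE)
      }
      df$nsc_id <- as.integer(df$nsc_id)
      df[c("nsc_id", "name", "cell_line", "panel", "log_gi50",
           "failed_screen", "status", ".row")]
    }
  )
}

.write_one <- function(x, path) {
  if (is_expr_matrix(x)) x <- expr_to_long(x)
  x <- tibble::as_tibble(x)
  x$.row <- NULL
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  path
}

#' Write pipeline result tables and a run manifest
#'
#' Emits every supplied record collection as a TSV (expression matrices in
#' long form), plus a JSON run manifest recording stage counts, configuration
#' echo and seed. Empty collections are written as header-only tables.
#' Writing then re-reading a table through [read_adc_table()] reproduces the
#' records.
#'
#' @param trace A `cascade_trace` (or NULL).
#' @param records Named list of tibbles / `expr_matrix` objects to write,
#'   one TSV per element.
#' @param out_dir Output directory (created if absent).
#' @param config Configuration list echoed into the manifest.
#' @param seed Seed echoed into the manifest.
#' @param inputs Named character vector of input paths echoed into the
#'   manifest.
#' @return The manifest as a list, invisibly; written to
#'   `out_dir/manifest.json`.
#' @export
write_outputs <- function(trace, records, out_dir, config = list(),
                          seed = NULL, inputs = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  stopifnot(is.list(records))
  if (length(records) > 0 && is.null(names(records))) {
    stop("records must be a named list", call. = FALSE)
  }
  files <- character()
  for (nm in names(records)) {
    files[nm] <- .write_one(records[[nm]], file.path(out_dir,
                                                     paste0(nm, ".tsv")))
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = as.list(inputs),
    config = config,
    stages = if (is.null(trace)) list() else
      stats::setNames(as.list(trace$stages$n), trace$stages$stage),
    files = as.list(basename(files)),
    counts = lapply(records, function(x) {
      if (is_expr_matrix(x)) nrow(x$values) else nrow(x)
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  if (!is.null(trace)) {
    .write_one(trace$stages, file.path(out_dir, "trace_stages.tsv"))
    .write_one(trace_drops(trace), file.path(out_dir, "trace_drops.tsv"))
  }
  invisible(manifest)
}
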