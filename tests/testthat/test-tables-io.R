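write_tmp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, na = "NA")
  path
}

test_that("normal-tissue rows parse with normalized levels", {
  p <- write_tmp_tsv(tibble::tibble(
    gene = "EGFR", tissue = "liver", cell_type = "hepatocytes",
    level = "High"))
  rec <- read_adc_table(p, "normal_tissue")
  expect_equal(nrow(rec), 1)
  expect_equal(as.character(rec$level), "high")
  expect_equal(rec$.row, 2L)
})

test_that("schema violations carry column names and file line numbers", {
  p <- write_tmp_tsv(tibble::tibble(gene = "A", tissue = "liver"))
  expect_error(read_adc_table(p, "normal_tissue"), "cell_type")
  p2 <- write_tmp_tsv(tibble::tibble(
    gene = "A", cancer_type = "BRCA", frac_low = 60, frac_medium = 50,
    frac_high = 20))
  expect_error(read_adc_table(p2, "pathology"), "above 100.*line 2")
  p3 <- write_tmp_tsv(tibble::tibble(
    gene = c("A", "B"), cancer_type = "BRCA", frac_low = c("10", "x"),
    frac_medium = 0, frac_high = 0))
  expect_error(read_adc_table(p3, "pathology"), "frac_low.*'x'.*line 3")
  p4 <- write_tmp_tsv(tibble::tibble(
    gene = "A", tissue = "liver", cell_type = "h", level = "strong"))
  expect_error(read_adc_table(p4, "normal_tissue"), "accepted values")
})

test_that("gi50 panel vocabulary is enforced with the accepted list", {
  row <- tibble::tibble(nsc_id = 1, name = "x", cell_line = "L1",
                        panel = "Renal", log_gi50 = -8, failed_screen = FALSE,
                        status = "none")
  p <- write_tmp_tsv(row)
  expect_error(read_adc_table(p, "gi50"), "Renal Cancer")
  row$panel <- "Renal Cancer"
  p2 <- write_tmp_tsv(row)
  expect_equal(read_adc_table(p2, "gi50")$panel, "Renal Cancer")
})

test_that("pathology patient counts are converted to percentages", {
  p <- write_tmp_tsv(tibble::tibble(
    gene = "A", cancer_type = "BRCA", n_not_detected = 1, n_low = 1,
    n_medium = 1, n_high = 1))
  rec <- read_adc_table(p, "pathology")
  expect_equal(c(rec$frac_low, rec$frac_medium, rec$frac_high),
               rep(25, 3))
})

test_that("write-then-read round-trips every schema", {
  dir <- withr::local_tempdir()
  path <- fixture_target_bundle()$pathology
  gi <- fixture_gi50_bundle()$measurements[1:500, ]
  em <- tiny_expr(C1 = c(1.25, 2.5, 0, 7.125), C2 = c(3, 4, 5, 6))
  write_outputs(NULL, list(pathology = path, gi50 = gi, expr = em), dir)

  back <- read_adc_table(file.path(dir, "pathology.tsv"), "pathology")
  expect_equal(back$frac_high, path$frac_high, tolerance = 1e-6)
  expect_equal(back$gene, path$gene)

  gi_back <- read_adc_table(file.path(dir, "gi50.tsv"), "gi50")
  expect_equal(gi_back$log_gi50, gi$log_gi50, tolerance = 1e-6)
  expect_equal(gi_back$failed_screen, gi$failed_screen)

  em_back <- read_adc_table(file.path(dir, "expr.tsv"), "expression_matrix")
  expect_equal(em_back$values, em$values, tolerance = 1e-6)
  expect_equal(em_back$cohort, em$cohort)
})

test_that("manifest records stage counts in order and empty tables write", {
  dir <- withr::local_tempdir()
  tr <- new_trace()
  tr <- trace_record(tr, "membrane", 10)
  tr <- trace_record(tr, "evidence", 8)
  empty <- tibble::tibble(gene = character(), score = numeric())
  man <- write_outputs(tr, list(survivors = empty), dir, seed = 3)
  expect_equal(man$stages, list(membrane = 10L, evidence = 8L))
  expect_equal(man$counts$survivors, 0L)
  on_disk <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(names(on_disk$stages), c("membrane", "evidence"))
  back <- readr::read_tsv(file.path(dir, "survivors.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), 0)
  expect_equal(names(back), c("gene", "score"))
})

test_that("trace invariants hold: monotone counts, one reason per drop", {
  tr <- new_trace()
  tr <- trace_record(tr, "a", c("g1", "g2"),
                     tibble::tibble(item = "g3", reason = "x"))
  expect_error(
    trace_record(tr, "b", 1,
                 tibble::tibble(item = c("g1", "g1"), reason = c("x", "y"))),
    "multiple drop reasons")
  tr <- trace_record(tr, "b", "g1",
                     tibble::tibble(item = "g2", reason = "y"))
  expect_silent(trace_check_monotone(tr))
  tr_bad <- trace_record(tr, "c", 5)
  expect_error(trace_check_monotone(tr_bad), "increase")
  expect_equal(trace_drops(tr)$item, c("g3", "g2"))
})

test_that("mutation schema deduplicates (sample, gene) pairs", {
  p <- write_tmp_tsv(tibble::tibble(sample = c("s1", "s1", "s2"),
                                    gene = c("KRAS", "KRAS", "KRAS")))
  expect_equal(nrow(read_adc_table(p, "mutation")), 2)
})
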