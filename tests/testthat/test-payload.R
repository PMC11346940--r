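gi_row <- function(nsc, name, line, panel, lg, failed = FALSE,
                   status = "none") {
  tibble::tibble(nsc_id = as.integer(nsc), name = name, cell_line = line,
                 panel = panel, log_gi50 = lg, failed_screen = failed,
                 status = status)
}

test_that("duplicate names merge under the smallest NSC id", {
  m <- dplyr::bind_rows(
    gi_row(2, "taxol ", "L1", "Leukemia", -8.5),
    gi_row(1, "Taxol", "L2", "Leukemia", -8.6),
    gi_row(3, NA, "L1", "Leukemia", -6),
    gi_row(4, NA, "L1", "Leukemia", -6))
  dd <- dedupe_compounds(m)
  expect_equal(sort(unique(dd$nsc_id)), c(1L, 3L, 4L))
  expect_equal(unique(dd$name[dd$nsc_id == 1]), "Taxol")
  # injected duplicate pairs in the synthetic bundle collapse exactly
  g <- fixture_gi50_bundle()
  dd2 <- dedupe_compounds(g$measurements)
  expect_equal(length(unique(dd2$nsc_id)),
               length(unique(g$measurements$nsc_id)) -
                 nrow(g$truth$dupe_pairs))
  expect_false(any(g$truth$dupe_pairs$merged %in% dd2$nsc_id))
})

test_that("sensitivity windows are inclusive at -9 and -8 and exhaustive", {
  expect_equal(classify_sensitivity(c(-9, -8, -7.3, -9.4, -8.2)),
               c("picomolar", "low_nanomolar", "none", "picomolar",
                 "low_nanomolar"))
  expect_warning(out <- classify_sensitivity(c(-9, Inf)), "non-finite")
  expect_true(is.na(out[2]))
  # every value at or below -8 maps to exactly one of the two classes
  set.seed(61)
  v <- stats::runif(500, -12, -8)
  cl <- classify_sensitivity(v)
  expect_true(all(cl %in% c("picomolar", "low_nanomolar")))
  expect_equal(cl == "picomolar", v <= -9)
})

test_that("response percentages follow measured-line arithmetic", {
  m <- dplyr::bind_rows(
    gi_row(1, "a", sprintf("R%d", 1:6), "Renal Cancer",
           c(rep(-8.5, 4), -6, -6)),
    gi_row(1, "a", sprintf("P%d", 1:2), "Prostate Cancer", c(-8.2, -6)),
    gi_row(2, "b", sprintf("R%d", 1:3), "Renal Cancer", rep(-5, 3)))
  prof <- response_profiles(m, "low_nanomolar")
  a <- prof[prof$nsc_id == 1, ]
  expect_equal(a[["pct_Renal Cancer"]], 100 * 4 / 6, tolerance = 1e-9)
  expect_equal(a[["pct_Prostate Cancer"]], 50)
  expect_true(a$qualifies)           # 50% in 1/9 panels is enough
  expect_true(is.na(a[["pct_Breast Cancer"]]))  # unmeasured, not 0
  b <- prof[prof$nsc_id == 2, ]
  expect_equal(b[["pct_Renal Cancer"]], 0)
  expect_false(b$qualifies)
})

test_that("replicate aggregation makes profiles duplication invariant", {
  m <- dplyr::bind_rows(
    gi_row(1, "a", sprintf("R%d", 1:4), "Renal Cancer",
           c(-8.5, -8.4, -6, -6)))
  doubled <- dplyr::bind_rows(m, m)
  expect_equal(response_profiles(m, "low_nanomolar"),
               response_profiles(doubled, "low_nanomolar"))
  # a line killed at picomolar dose still counts as responsive at 10 nM
  deep <- gi_row(1, "a", sprintf("R%d", 1:2), "Renal Cancer", c(-9.5, -8.5))
  expect_equal(
    response_profiles(deep, "low_nanomolar")[["pct_Renal Cancer"]], 100)
})

test_that("failed-screen removal and partition conservation", {
  prof <- tibble::tibble(nsc_id = 1:3, qualifies = TRUE)
  m <- gi_row(2, "x", "L1", "Leukemia", -8.5, failed = TRUE)
  expect_equal(drop_failed(prof, m)$nsc_id, c(1L, 3L))
  part <- partition_groups(c(1, 2, 5), c(2, 3, 4))
  expect_equal(part$group[part$nsc_id == 2], "overlap")
  expect_equal(part$group[part$nsc_id == 1], "picomolar_only")
  expect_equal(part$group[part$nsc_id == 3], "low_nanomolar_only")
  expect_equal(nrow(part), 5)
  expect_false(anyDuplicated(part$nsc_id) > 0)
})

test_that("clustering is deterministic, order invariant, and separates", {
  set.seed(62)
  panels <- nci60_panels()
  mk_prof <- function(ids, hot) {
    out <- tibble::tibble(nsc_id = ids, name = as.character(ids),
                          sens_class = "low_nanomolar")
    for (p in panels) {
      out[[paste0("pct_", p)]] <- ifelse(rep(p == hot, length(ids)),
                                         stats::runif(length(ids), 90, 100),
                                         stats::runif(length(ids), 0, 10))
    }
    out$qualifies <- TRUE
    out
  }
  prof <- dplyr::bind_rows(mk_prof(1:6, "Leukemia"),
                           mk_prof(7:12, "Renal Cancer"))
  cl <- cluster_profiles(prof, 2)
  expect_equal(length(unique(cl$cluster[cl$nsc_id <= 6])), 1)
  expect_equal(length(unique(cl$cluster[cl$nsc_id > 6])), 1)
  expect_false(cl$cluster[1] == cl$cluster[12])
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(cluster_profiles(shuffled, 2), cl)
  singleton <- cluster_profiles(prof, nrow(prof))
  expect_equal(sort(singleton$cluster), 1:12)
  expect_error(cluster_profiles(prof, 13), "fewer profiles")
})

test_that("payload pipeline recovers the planted group sizes exactly", {
  g <- fixture_gi50_bundle()
  res <- fixture_payload_run()
  sizes <- table(res$groups$group)
  expect_equal(as.integer(sizes[c("picomolar_only", "low_nanomolar_only",
                                  "overlap")]),
               c(33L, 631L, 65L))
  for (grp in names(g$truth$groups)) {
    expect_setequal(res$groups$nsc_id[res$groups$group == grp],
                    g$truth$groups[[grp]])
  }
  expect_false(any(g$truth$failed %in% res$groups$nsc_id))
  # per-branch trace counts are monotone
  st <- res$trace$stages
  branch <- function(names) trace_check_monotone(res$trace, names)
  expect_silent(branch(c("input", "dedupe")))
  expect_silent(branch(c("picomolar_category", "picomolar_qualified",
                         "picomolar_after_failed")))
  expect_silent(branch(c("low_nanomolar_category",
                         "low_nanomolar_qualified",
                         "low_nanomolar_after_failed")))
  # clusters cover the final compounds at the configured counts
  pico_cl <- res$clusters[res$clusters$group == "picomolar_only", ]
  expect_equal(nrow(pico_cl), 33)
  expect_equal(length(unique(pico_cl$cluster)), 5)
  nano_cl <- res$clusters[res$clusters$group == "low_nanomolar_only", ]
  expect_equal(length(unique(nano_cl$cluster)), 10)
})

test_that("a fully failed compound set yields empty groups", {
  m <- dplyr::bind_rows(
    gi_row(1, "a", "L1", "Leukemia", -8.5, failed = TRUE),
    gi_row(2, "b", "L1", "Leukemia", -9.5, failed = TRUE))
  res <- run_payload_pipeline(m)
  expect_equal(nrow(res$groups), 0)
})
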