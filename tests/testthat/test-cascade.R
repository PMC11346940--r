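test_that("membrane and protein-evidence filters keep and drop correctly", {
  ann <- tibble::tibble(
    gene = c("A", "B", "C"),
    is_membrane = c(TRUE, TRUE, FALSE),
    has_protein_evidence = c(TRUE, FALSE, TRUE),
    is_surfaceome = TRUE)
  res <- filter_membrane_evidence(ann)
  expect_equal(res$kept, "A")
  expect_equal(res$dropped$reason[res$dropped$item == "B"],
               "no protein evidence")
  expect_equal(res$dropped$reason[res$dropped$item == "C"],
               "no membrane annotation")
})

test_that("critical-tissue filter drops on any high in any cell type", {
  normal <- tibble::tibble(
    gene = c("A", "A", "B", "C", "D"),
    tissue = c("liver", "cerebellum", "liver", "cerebellum", "liver"),
    cell_type = c("hepatocytes", "purkinje", "hepatocytes", "purkinje",
                  "bile duct"),
    level = parse_expression_level(c("High", "Low", "Medium", "High",
                                     "Medium")))
  res <- filter_critical_normal(normal, c("A", "B", "C", "D", "E"),
                                tissues = c("liver"))
  # A: high in liver -> out; C: high only in cerebellum (non-critical) ->
  # kept; E: no records at all -> kept
  expect_equal(sort(res$kept), c("B", "C", "D", "E"))
  expect_match(res$dropped$reason, "liver")
  expect_error(
    filter_critical_normal(normal, "A", tissues = c("liver", "spleen")),
    "spleen")
})

test_that("tumor quasi H-score gate is strict and falls back to mRNA", {
  path <- tibble::tibble(
    gene = c("A", "A", "B", "C"),
    cancer_type = c("BRCA", "OV", "BRCA", "BRCA"),
    frac_low = c(20, 1, 0, 0), frac_medium = c(30, 0, 0, 75),
    frac_high = c(20, 50, 50, 0))
  # A: 140 and 151 -> kept with one passing pair; B: exactly 150 -> out;
  # C: 150 -> out
  res <- filter_tumor_quasi_h(path, c("A", "B", "C", "D"))
  expect_equal(res$kept, "A")
  expect_equal(nrow(res$indications[res$indications$gene == "A", ]), 1)
  expect_equal(res$indications$cancer_type[res$indications$gene == "A"],
               "OV")
  expect_equal(res$dropped$reason[res$dropped$item == "D"], "no tumor data")
  # mRNA fallback rescues a gene with no IHC rows
  mrna <- tibble::tibble(gene = "D", context = "BRCA", score = 200,
                         source = "mrna")
  res2 <- filter_tumor_quasi_h(path, c("B", "D"), mrna_scores = mrna)
  expect_equal(res2$kept, "D")
  expect_equal(res2$indications$source[res2$indications$gene == "D"], "mrna")
})

test_that("six-a consistency policies behave per ordinal distance", {
  mk <- function(lv) tibble::tibble(gene = "A", tissue = c("t1", "t2"),
                                    level = parse_expression_level(lv))
  same <- check_consistency_6a(mk(c("low", "high")), mk(c("low", "high")))
  expect_true(same$pass)
  far <- check_consistency_6a(mk(c("high", "low")),
                              mk(c("not_detected", "low")))
  expect_false(far$pass)
  near_m <- mk(c("medium", "low"))
  near_i <- mk(c("high", "low"))
  expect_true(check_consistency_6a(near_m, near_i, "within_one")$pass)
  expect_false(check_consistency_6a(near_m, near_i, "exact")$pass)
  # disjoint tissue sets -> no overlapping evidence
  none <- check_consistency_6a(
    tibble::tibble(gene = "A", tissue = "t1",
                   level = parse_expression_level("low")),
    tibble::tibble(gene = "A", tissue = "t2",
                   level = parse_expression_level("low")))
  expect_false(none$pass)
  expect_equal(none$reason, "no overlapping evidence")
})

test_that("mRNA quasi H-score matches the quantile arithmetic", {
  em <- tiny_expr(C1 = c(1, 2, 3, 100))
  rec <- quasi_h_from_expression(em, "C1", "G1")
  # Q1 = 1.75, Q3 = 27.25 -> (low, med, med, high) -> 25 + 100 + 75
  expect_equal(rec$score, 200)
  expect_equal(rec$source, "mrna")
  uni <- tiny_expr(C1 = rep(5, 6))
  expect_equal(quasi_h_from_expression(uni, "C1", "G1")$score, 200)
  expect_error(quasi_h_from_expression(em, "C1", "G9"), "G9")
  expect_error(quasi_h_from_expression(tiny_expr(C1 = 1:3), "C1", "G1"),
               "fewer than 4")
  # three-level scores live in [100, 300]
  set.seed(7)
  for (i in 1:25) {
    em2 <- tiny_expr(C1 = stats::rlnorm(sample(4:30, 1), 1, 1))
    s <- quasi_h_from_expression(em2, "C1", "G1")$score
    expect_gte(s, 100)
    expect_lte(s, 300)
  }
})

test_that("HSC/MPP filter uses global quartiles and drops absentees", {
  genes <- sprintf("H%02d", 1:20)
  set.seed(8)
  m <- matrix(stats::rlnorm(20 * 6, 1, 1), nrow = 20,
              dimnames = list(genes, sprintf("s%d", 1:6)))
  m["H01", ] <- max(m) * 2          # far above global Q3
  m["H02", ] <- min(m) / 2          # below global Q1
  hema <- expr_matrix(m, stats::setNames(rep("HSC", 6), colnames(m)))
  res <- filter_hsc_mpp(hema, c("H01", "H02", "H03", "ZZZ"),
                        hsc_samples = colnames(m))
  expect_false("H01" %in% res$kept)
  expect_true("H02" %in% res$kept)
  expect_equal(res$levels$level[res$levels$gene == "H02"], "low")
  expect_equal(res$dropped$reason[res$dropped$item == "ZZZ"],
               "absent from hematopoietic study")
  expect_error(filter_hsc_mpp(hema, "H01", character()), "no HSC/MPP")
})

test_that("evidence score counts set flags over all 32 combinations", {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(combos) <- c("literature", "antibody", "protein_family",
                     "preclinical", "clinical")
  ev <- tibble::as_tibble(cbind(gene = sprintf("g%02d", 1:32), combos))
  sc <- evidence_score(ev)
  expect_equal(sc$score, rowSums(combos))
  expect_equal(max(sc$score), 5L)
})

test_that("cascade recovers planted structure and filters are idempotent", {
  b <- fixture_target_bundle()
  res <- fixture_cascade()
  expect_true(all(b$truth$ideal_targets %in% res$targets))
  drops <- trace_drops(res$trace)
  hit <- dplyr::left_join(b$truth$decoys, drops, by = c(gene = "item"))
  expect_equal(hit$stage.y, hit$stage.x)
  # survivors at each stage nest in the previous stage's survivors
  expect_true(all(diff(res$trace$stages$n) <= 0))
  # stage-2 survivor count equals the annotation tabulation in the truth
  expect_equal(res$trace$stages$n[2], b$truth$counts$membrane_evidence)
  # idempotence: re-filtering survivors changes nothing
  again <- filter_membrane_evidence(b$annotation, res$targets)
  expect_equal(again$kept, res$targets)
  crit <- filter_critical_normal(b$normal_ihc, res$targets)
  expect_equal(crit$kept, res$targets)
  surf <- filter_surfaceome(b$annotation, res$targets)
  expect_equal(surf$kept, res$targets)
})

test_that("an empty gene universe yields nine zero-count stages", {
  b <- synth_target_bundle(n_genes = 0, seed = 1)
  res <- run_cascade(b)
  expect_equal(res$targets, character())
  expect_equal(res$trace$stages$n, rep(0L, 9))
})
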