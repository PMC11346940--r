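mut_fixture <- function(mut_vals, wt_vals, target = "T1", query = "Q1",
                        cohort = "C1") {
  n <- length(mut_vals) + length(wt_vals)
  samples <- sprintf("s%03d", seq_len(n))
  em <- expr_matrix(
    matrix(c(mut_vals, wt_vals), nrow = 1,
           dimnames = list(target, samples)),
    stats::setNames(rep(cohort, n), samples))
  muts <- tibble::tibble(sample = samples[seq_along(mut_vals)], gene = query)
  list(expr = em, muts = muts)
}

test_that("association test reproduces the hand-worked example", {
  fx <- mut_fixture(c(8, 8, 8), c(1, 1, 1))
  rec <- association_test(fx$expr, fx$muts, "C1", "T1", "Q1")
  expect_equal(rec$log2_fc, log2(9 / 2), tolerance = 1e-9)
  expect_equal(rec$p_value, 0.1, tolerance = 1e-9)   # 2 of C(6,3) orderings
  expect_equal(rec$direction, "up")
  expect_equal(rec$prevalence, 0.5)
  expect_true(rec$testable)
})

test_that("identical groups give zero fold change and no direction", {
  fx <- mut_fixture(c(5, 5, 5), c(5, 5, 5))
  rec <- association_test(fx$expr, fx$muts, "C1", "T1", "Q1")
  expect_equal(rec$log2_fc, 0)
  expect_equal(rec$direction, "none")
  expect_equal(rec$p_value, 1)
})

test_that("groups below the minimum size are untestable, not errors", {
  fx <- mut_fixture(c(8, 8), c(1, 1, 1, 1))
  rec <- association_test(fx$expr, fx$muts, "C1", "T1", "Q1")
  expect_false(rec$testable)
  expect_true(is.na(rec$p_value))
  expect_equal(rec$n_mut, 2)
})

test_that("exact rank-sum p matches enumeration for all sizes up to 6+6", {
  set.seed(51)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      x <- stats::rlnorm(n1, 2, 1)
      y <- stats::rlnorm(n2, 1, 1)
      expect_equal(ranksum_exact_p(x, y), ranksum_oracle(x, y),
                   tolerance = 1e-9)
      # tied pools exercise the midrank path
      xt <- sample(1:3, n1, replace = TRUE)
      yt <- sample(1:3, n2, replace = TRUE)
      expect_equal(ranksum_exact_p(xt, yt), ranksum_oracle(xt, yt),
                   tolerance = 1e-9)
    }
  }
  # tie-free case agrees with the classical exact distribution
  x <- c(1.2, 3.4, 9.1, 0.4)
  y <- c(2.2, 5.5, 7.1, 8.8, 0.1)
  expect_equal(ranksum_exact_p(x, y),
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("swapping group labels negates log2 FC and preserves p", {
  set.seed(52)
  for (i in 1:20) {
    a <- stats::rlnorm(sample(3:8, 1), 2, 0.5)
    b <- stats::rlnorm(sample(3:8, 1), 1, 0.5)
    f1 <- mut_fixture(a, b)
    f2 <- mut_fixture(b, a)
    r1 <- association_test(f1$expr, f1$muts, "C1", "T1", "Q1")
    r2 <- association_test(f2$expr, f2$muts, "C1", "T1", "Q1")
    expect_equal(r1$log2_fc, -r2$log2_fc, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  }
})

test_that("screen gates behave: prevalence, monotonicity, directions", {
  set.seed(53)
  cohorts <- c("C1", "C2")
  planted <- tibble::tibble(
    target = c("T1", "T2"), query = c("Q1", "Q2"), cohort = c("C1", "C2"),
    log2_fc = c(2, -2), fraction = c(0.3, 0.3))
  mb <- synth_mutation_bundle(cohorts, 150, planted, seed = 9)
  recs <- screen_associations(mb$expr, mb$muts, c("T1", "T2"),
                              c("Q1", "Q2"))
  expect_true(any(recs$target == "T1" & recs$query_gene == "Q1" &
                    recs$direction == "up"))
  expect_true(any(recs$target == "T2" & recs$query_gene == "Q2" &
                    recs$direction == "down"))
  # sub-prevalence planting never passes the 5% gate
  lowprev <- synth_mutation_bundle("C1", 200, tibble::tibble(
    target = "T1", query = "Q1", cohort = "C1", log2_fc = 3,
    fraction = 0.015), seed = 10)
  got <- screen_associations(lowprev$expr, lowprev$muts, "T1", "Q1")
  expect_equal(nrow(got), 0)
  # raising any threshold never adds records
  tight <- screen_associations(mb$expr, mb$muts, c("T1", "T2"),
                               c("Q1", "Q2"), alpha = 0.01,
                               min_abs_log2fc = 1.5, min_prevalence = 0.2)
  key <- function(d) paste(d$target, d$query_gene, d$cohort)
  expect_true(all(key(tight) %in% key(recs)))
  # empty target set -> empty result
  expect_equal(nrow(screen_associations(mb$expr, mb$muts, character(),
                                        "Q1")), 0)
})

test_that("per-query summary counts distinct targets and cohorts", {
  expect_equal(nrow(summarize_by_query(
    screen_associations(mut_fixture(1, 1)$expr,
                        tibble::tibble(sample = character(),
                                       gene = character()),
                        character(), character()))), 0)
  recs <- tibble::tibble(
    target = c("T1", "T2", "T2"), query_gene = "Q",
    cohort = c("A", "A", "B"), log2_fc = c(2, 1.5, -2),
    p_value = 0.01, prevalence = 0.2,
    direction = c("up", "up", "down"), n_mut = 10, n_wt = 90,
    testable = TRUE)
  s <- summarize_by_query(recs)
  expect_equal(s$n_targets, 2L)
  expect_equal(s$n_cohorts, 2L)
  expect_equal(s$n_up, 2L)
  expect_equal(s$n_down, 1L)
  rt <- radar_table(recs, "T2")
  expect_equal(names(rt), c("cohort", "Q"))
  expect_equal(nrow(rt), 2)
})
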