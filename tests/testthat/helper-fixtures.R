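# Shared fixtures, computed once per test run. The target bundle at seed 7
# and the GI50 bundle at seed 7 are the reference synthetic worlds used by
# the recovery tests and the acceptance suite.

fixture_target_bundle <- function() {
  if (is.null(.fixture_env$target_bundle)) {
    .fixture_env$target_bundle <- synth_target_bundle(seed = 7)
  }
  .fixture_env$target_bundle
}

fixture_cascade <- function() {
  if (is.null(.fixture_env$cascade)) {
    .fixture_env$cascade <- run_cascade(fixture_target_bundle())
  }
  .fixture_env$cascade
}

fixture_gi50_bundle <- function() {
  if (is.null(.fixture_env$gi50)) {
    .fixture_env$gi50 <- synth_gi50_bundle(seed = 7)
  }
  .fixture_env$gi50
}

fixture_payload_run <- function() {
  if (is.null(.fixture_env$payload)) {
    .fixture_env$payload <- run_payload_pipeline(
      fixture_gi50_bundle()$measurements)
  }
  .fixture_env$payload
}

fixture_run_all <- function() {
  if (is.null(.fixture_env$run_all)) {
    .fixture_env$run_all_dir <- file.path(tempdir(), "adcmine-fixture-run")
    .fixture_env$run_all <- run_all(out_dir = .fixture_env$run_all_dir)
  }
  .fixture_env$run_all
}

.fixture_env <- new.env(parent = emptyenv())

# Independent linear-interpolation sample-quantile oracle (type 7), written
# from the order-statistic definition rather than stats::quantile.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Independent exact rank-sum oracle: enumerate every assignment of the
# pooled midranks to group 1 via index combinations.
ranksum_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  sum(abs(sums - mu) >= abs(w - mu) - 1e-9) / ncol(idx)
}

# Tiny expression matrix helper: one cohort per value set.
tiny_expr <- function(..., gene = "G1", unit = "AU") {
  sets <- list(...)
  vals <- unlist(sets)
  samples <- sprintf("s%02d", seq_along(vals))
  cohort <- stats::setNames(rep(names(sets), lengths(sets)), samples)
  expr_matrix(matrix(vals, nrow = 1, dimnames = list(gene, samples)),
              cohort, unit = unit)
}
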