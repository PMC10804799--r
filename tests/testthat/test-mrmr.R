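# oracle_mi / oracle_mrmr come from helper-oracles.R

test_that("greedy ranking matches the brute-force oracle on small cases", {
  set.seed(42)
  for (case in 1:8) {
    n <- 120L
    k <- sample(4:8, 1)
    x <- matrix(sample(0:3, n * k, replace = TRUE), n, k)
    # discrete label with few levels: neither route needs to discretize,
    # so the oracle stays fully independent of the implementation
    y <- x[, 1] + sample(0:2, n, replace = TRUE)
    for (m in c(2L, 3L, k)) {
      got <- mrmr_rank(x, y, m = m, bins = 10L)
      expect_equal(got$column, oracle_mrmr(x, y, m),
                   info = sprintf("case %d m %d", case, m))
    }
  }
})

test_that("a redundant exact copy loses to an independent feature", {
  # f1 drives the label, f2 is a copy of f1 (its redundancy with f1
  # cancels its relevance under MID), f3 is independently informative
  set.seed(7)
  n <- 400L
  f1 <- sample(0:4, n, replace = TRUE)
  f2 <- f1
  f3 <- sample(0:4, n, replace = TRUE)
  y <- as.numeric(f1) + 0.3 * (f3 >= 3)
  got <- mrmr_rank(cbind(f1, f2, f3), y, m = 3L, bins = 10L)
  expect_equal(got$column[1:2], c(1L, 3L))
  expect_equal(got$column[3], 2L)   # the copy ranks last
  expect_equal(got$relevance[1], max(got$relevance))
})

test_that("identical features tie-break to the lowest column index", {
  set.seed(8)
  n <- 200L
  f <- sample(0:3, n, replace = TRUE)
  x <- cbind(f, f, f, f)
  y <- as.numeric(f) + rnorm(n, sd = 0.2)
  got <- mrmr_rank(x, y, m = 2L)
  expect_equal(got$column[1], 1L)
})

test_that("constant features are never ranked before informative ones", {
  set.seed(9)
  n <- 200L
  f1 <- sample(0:3, n, replace = TRUE)
  cst <- rep(1L, n)
  y <- as.numeric(f1) + rnorm(n, sd = 0.5)
  got <- mrmr_rank(cbind(cst, f1, f1), y, m = 3L)
  expect_equal(got$column[1], 2L)
  expect_equal(got$relevance[got$column == 1L], 0)
  expect_equal(got$column[3], 1L)  # constant comes last
})

test_that("m larger than the candidate pool is an error", {
  x <- matrix(sample(0:2, 50, replace = TRUE), 10, 5)
  expect_error(mrmr_rank(x, rnorm(10), m = 6L), "exceeds")
})

test_that("shuffling candidate column order permutes only labels, not picks", {
  set.seed(10)
  n <- 300L
  x <- matrix(sample(0:4, n * 6, replace = TRUE), n, 6)
  y <- x[, 2] + 0.5 * x[, 5] + rnorm(n)
  perm <- c(4L, 2L, 6L, 1L, 5L, 3L)
  r1 <- mrmr_rank(x, y, m = 4L)
  r2 <- mrmr_rank(x[, perm], y, m = 4L)
  expect_equal(perm[r2$column], r1$column)
})

test_that("budget rule stops at the first sub-threshold improvement", {
  expect_equal(choose_feature_budget(
    data.frame(m = c(50, 100, 150), validation_mse = c(1.00, 0.80, 0.77))),
    100L)  # next improvement 3.75% < 5%
  expect_equal(choose_feature_budget(
    data.frame(m = c(50, 100), validation_mse = c(1.0, 1.0))), 50L)
  expect_warning(
    m <- choose_feature_budget(
      data.frame(m = c(50, 100, 150), validation_mse = c(1.0, 0.9, 0.81))),
    "largest")
  expect_equal(m, 150L)
  expect_error(choose_feature_budget(
    data.frame(m = c(100, 50), validation_mse = c(1, 2))), "increasing")
  expect_error(choose_feature_budget(
    data.frame(m = 50, validation_mse = 1)))
})

test_that("selection keeps the protected blocks and reports m + F", {
  ds <- small_synth()
  fm <- assemble_synth(ds)
  ranking <- mrmr_rank(fm, m = 10L)
  red <- apply_selection(fm, ranking, m = 10L)
  F <- fm$blocks[["fingerprint"]]

  expect_equal(attr(red, "selected_count"), 10L + F)
  expect_equal(red$blocks[["fingerprint"]], F)
  expect_equal(red$blocks[["mode_flag"]], 1L)
  expect_equal(ncol(red$x), 10L + F + 1L)
  # provenance re-indexed to the reduced matrix, partitions all columns
  expect_equal(red$provenance$column, seq_len(ncol(red$x)))
  expect_equal(sum(red$blocks), ncol(red$x))

  # m = 0: fingerprint + mode flag only
  none <- apply_selection(fm, ranking, m = 0L)
  expect_equal(ncol(none$x), F + 1L)
  expect_setequal(unique(none$provenance$block), c("fingerprint", "mode_flag"))
})

test_that("the reference accounting yields 1224 retained features at m = 200", {
  # 1,024-bit protected fingerprint block + 200 mRMR-ranked features;
  # the always-kept mode flag is appended but not counted
  rec <- make_records(list(R = list(agonist = 30L)))
  set.seed(1)
  codes <- matrix(sample(0:4, 300, replace = TRUE), 1, 300,
                  dimnames = list("R", NULL))
  fp <- matrix(rbinom(30 * 1024, 1, 0.1), 30, 1024,
               dimnames = list(rec$ligand_id, NULL))
  fm <- assemble_features(rec, codes, fp)
  ranking <- mrmr_rank(fm, m = 200L)
  red <- apply_selection(fm, ranking, m = 200L)
  expect_equal(unname(attr(red, "selected_count")), 1224L)
})

test_that("no protected column ever appears in the ranked list", {
  ds <- small_synth()
  fm <- assemble_synth(ds)
  ranking <- mrmr_rank(fm, m = 15L)
  protected <- c(block_columns(fm, "fingerprint"),
                 block_columns(fm, "mode_flag"))
  expect_length(intersect(ranking$column, protected), 0L)
})
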