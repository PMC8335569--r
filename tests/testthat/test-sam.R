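# SAM statistic, fudge-factor estimation, and the permutation test.

test_that("sam_statistic reproduces hand values and its limits", {
  # class0 = 1,2,3; class1 = 4,5,6: diff = 3, pooled scatter sqrt(2/3)
  d <- sam_statistic(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1), s0 = 0)
  expect_equal(d, 3 / sqrt(2 / 3), tolerance = 1e-12)

  # equal class means -> 0 for any s0
  expect_equal(sam_statistic(c(1, 3, 2, 2, 1, 3), c(0, 0, 0, 1, 1, 1), 0.5), 0)

  # |d| decreases monotonically to 0 as s0 grows
  ds <- vapply(c(0, 1, 10, 100, 1e4),
               function(s0) abs(sam_statistic(c(1, 2, 3, 4, 5, 6),
                                              c(0, 0, 0, 1, 1, 1), s0)), 0)
  expect_true(all(diff(ds) < 0))
  expect_lt(ds[5], 1e-3)
})

test_that("sam_statistic agrees with the direct per-class formula and is antisymmetric", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(12)
    lab <- sample(rep(c(0, 1), 6))
    parts <- oracle_sam_parts(x, lab)
    s0 <- runif(1, 0, 0.5)
    expect_equal(sam_statistic(x, lab, s0), parts$diff / (parts$s + s0),
                 tolerance = 1e-12)
    expect_equal(sam_statistic(x, 1 - lab, s0), -sam_statistic(x, lab, s0),
                 tolerance = 1e-12)
  }
  expect_error(sam_statistic(1:5, c(1, 0, 0, 0, 0), 0), "class size")
})

test_that("estimate_s0 minimises the windowed-MAD CV over the candidate grid", {
  set.seed(21)
  ab <- random_matrix(50, 40, seed = 21)
  ab <- ab * rexp(50)  # heterogeneous row scales so s varies
  lab <- rep(c(0, 1), 20)
  s0 <- estimate_s0(ab, lab)

  parts <- vapply(seq_len(nrow(ab)),
                  function(i) unlist(oracle_sam_parts(ab[i, ], lab)), numeric(2))
  diffs <- parts[1, ]; s <- parts[2, ]
  cand <- sort(unique(c(0, unname(quantile(s, seq(0, 1, by = 0.05))))))
  n_windows <- max(2, min(10, floor(length(s) / 5)))
  cvs <- vapply(cand, function(c0) oracle_s0_cv(diffs, s, c0, n_windows), 0)
  nearest <- which.min(abs(cand - s0))
  expect_lt(abs(cand[nearest] - s0), 1e-8)
  expect_lte(cvs[nearest], min(cvs, na.rm = TRUE) + 1e-8)
})

test_that("estimate_s0 handles degenerate inputs deterministically", {
  # all rows identical scatter -> that value
  ab <- matrix(rep(c(1, 2, 3, 4), 6), nrow = 6, byrow = TRUE,
               dimnames = list(paste0("r", 1:6), paste0("c", 1:4)))
  lab <- c(0, 0, 1, 1)
  s_common <- oracle_sam_parts(ab[1, ], lab)$s
  expect_equal(estimate_s0(ab, lab), s_common)

  # single row -> median(s) fallback with a warning
  one <- ab[1, , drop = FALSE]
  s0 <- suppressWarnings(estimate_s0(one, lab))
  expect_warning(expect_warning(estimate_s0(one, lab), "single feature"),
                 "fewer than 5")
  expect_equal(s0, s_common)
})

test_that("sam_test recovers a planted shift with direction +1 and is reproducible", {
  set.seed(77)
  ab <- random_matrix(10, 60, seed = 77)
  lab <- rep(c(1, 0), c(18, 42))
  ab[4, lab == 1] <- ab[4, lab == 1] + 3
  res <- sam_test(ab, lab, n_perm = 200, seed = 5)
  expect_s3_class(res, "sam_result")
  expect_true(res$significant["r04"])
  expect_equal(unname(res$direction["r04"]), 1)
  expect_true(all(res$q >= 0 & res$q <= 1))

  res2 <- sam_test(ab, lab, n_perm = 200, seed = 5)
  expect_identical(res, res2)    # bit-exact for a fixed seed

  # identical permutation of samples in both inputs leaves the result invariant
  set.seed(1); perm <- sample(ncol(ab))
  res3 <- sam_test(ab[, perm], lab[perm], n_perm = 200, seed = 5)
  expect_equal(res3$d, res$d, tolerance = 1e-12)
  expect_equal(res3$p, res$p)
})

test_that("permutation p-values are super-uniform under the null", {
  # null data: fraction of cells with p < t should not exceed t materially
  set.seed(42)
  ps <- unlist(lapply(1:8, function(i) {
    ab <- random_matrix(25, 40, seed = 1000 + i)
    lab <- rep(c(1, 0), 20)
    sam_test(ab, lab, n_perm = 1000, seed = i)$p
  }))
  for (t in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps < t), t + 2 * sqrt(t * (1 - t) / length(ps)) + 0.02)
  # pseudo-count guarantees p > 0
  expect_true(all(ps > 0))
})

test_that("sam_test rejects undersized classes and missing seeds", {
  ab <- random_matrix(5, 30, seed = 1)
  expect_error(sam_test(ab, c(1, rep(0, 29)), n_perm = 100, seed = 1), "few")
  expect_error(sam_test(ab, rep(c(1, 0), 15), n_perm = 10, seed = 1), "n_perm")
  expect_error(sam_test(ab, rep(c(1, 0), 15), n_perm = 100), "seed")
})
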