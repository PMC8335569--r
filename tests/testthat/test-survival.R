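# Cox coefficients, risk scores, median split, log-rank, and the assembled
# risk signature.

make_surv_cohort <- function(n, beta, seed, censor = 0.25) {
  truth <- cohort_truth(mut_freq = 0.3, surv_beta = beta, censor_rate = censor)
  generate_cohort(n, length(beta), 2, truth, seed = seed)
}

test_that("risk scores are the exact linear combination of Eq-style sums", {
  ab <- rbind(c1 = c(2, 1, 0), c2 = c(3, -1, 2))
  colnames(ab) <- paste0("s", 1:3)
  beta <- c(c1 = 1, c2 = -1)
  expect_equal(unname(risk_scores(beta, ab)), c(-1, 2, -2))
  expect_equal(risk_scores(c(c1 = 0, c2 = 0), ab), rep(0, 3), ignore_attr = TRUE)
  # linearity in the abundances
  expect_equal(risk_scores(beta, ab * 3), 3 * risk_scores(beta, ab))
  expect_error(risk_scores(c(zz = 1), ab), "match")
})

test_that("median split sends ties to low risk and ignores shifts", {
  s <- c(a = 1, b = 2, c = 3, d = 4)
  g <- median_split(s)
  expect_equal(as.character(g), c("low", "low", "high", "high"))

  s2 <- c(a = 1, b = 2, c = 2, d = 3)   # median 2: ties at the median go low
  g2 <- median_split(s2)
  expect_equal(as.character(g2), c("low", "low", "low", "high"))

  expect_identical(median_split(s + 100), g)
  expect_error(median_split(rep(1, 6)), "degenerate")
})

test_that("log-rank matches the at-risk-table oracle on a 6-patient example", {
  sv <- data.frame(sample = paste0("p", 1:6),
                   time = c(1, 3, 5, 2, 4, 6),
                   event = c(1, 1, 0, 1, 1, 1))
  groups <- setNames(factor(rep(c("low", "high"), each = 3)), sv$sample)
  got <- log_rank(groups, sv)
  want <- oracle_logrank_chisq(sv$time, sv$event, rep(c("low", "high"), each = 3))
  expect_equal(got$chi_square, want, tolerance = 1e-10)
  expect_equal(got$p, pchisq(want, 1, lower.tail = FALSE))

  # swapping group labels leaves the statistic unchanged
  swapped <- setNames(factor(rep(c("high", "low"), each = 3)), sv$sample)
  expect_equal(log_rank(swapped, sv)$chi_square, got$chi_square, tolerance = 1e-10)

  # two identical groups -> statistic 0, p = 1
  sv2 <- data.frame(sample = paste0("q", 1:8),
                    time = rep(c(1, 2, 3, 4), 2), event = rep(1, 8))
  g2 <- setNames(factor(rep(c("A", "B"), each = 4)), sv2$sample)
  lr2 <- log_rank(g2, sv2)
  expect_equal(lr2$chi_square, 0, tolerance = 1e-10)
  expect_equal(lr2$p, 1, tolerance = 1e-10)
})

test_that("Cox fit recovers planted coefficients and a null cell stays near 0", {
  co <- make_surv_cohort(400, c(cell01 = 1, cell02 = -1, cell03 = 0), seed = 55)
  beta <- fit_cox(co$abundance, co$survival)
  expect_equal(unname(beta["cell01"]), 1, tolerance = 0.25)
  expect_equal(unname(beta["cell02"]), -1, tolerance = 0.25)
  se <- sqrt(diag(vcov(attr(beta, "fit"))))
  expect_lt(abs(beta["cell03"]), 1.96 * se[3] + 0.15)

  # duplicating every sample leaves the partial-likelihood maximiser unchanged
  ab2 <- cbind(co$abundance, co$abundance)
  colnames(ab2) <- c(colnames(co$abundance), paste0(colnames(co$abundance), "b"))
  sv2 <- rbind(co$survival,
               transform(co$survival, sample = paste0(sample, "b")))
  beta2 <- fit_cox(ab2, sv2)
  expect_equal(as.numeric(beta2), as.numeric(beta), tolerance = 1e-6)
})

test_that("Cox fit drops zero-variance and collinear cells with warnings", {
  co <- make_surv_cohort(120, c(cell01 = 0.8, cell02 = 0), seed = 7)
  ab <- rbind(co$abundance, flat = 1)
  expect_warning(beta <- fit_cox(ab, co$survival), "zero-variance")
  expect_false("flat" %in% names(beta))

  ab3 <- rbind(co$abundance, dup = co$abundance["cell01", ])
  expect_warning(beta3 <- fit_cox(ab3, co$survival), "collinear")
  expect_equal(names(beta3), c("cell01", "cell02"))
})

test_that("the assembled risk model stratifies survival for prognostic cells", {
  co <- make_surv_cohort(300, c(cell01 = 1.2, cell02 = -1, cell03 = 0), seed = 99)
  rm_fit <- cell_risk_model(co$abundance, c("cell01", "cell02"), co$survival,
                            gene = "G001")
  expect_s3_class(rm_fit, "cell_risk")
  expect_equal(sort(unique(as.character(rm_fit$groups))), c("high", "low"))
  expect_lte(abs(sum(rm_fit$groups == "high") - sum(rm_fit$groups == "low")), 1)
  expect_lt(rm_fit$log_rank$p, 0.01)   # strong planted effect separates groups
  expect_equal(predict(rm_fit, co$abundance), rm_fit$risk_scores,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(names(coef(rm_fit)), c("cell01", "cell02"))
  expect_output(print(rm_fit), "log-rank")

  # KM estimator sanity: starts at 1, nonincreasing within strata
  sf <- rm_fit$survfit
  for (i in seq_along(sf$strata)) {
    idx <- rep(seq_along(sf$strata), sf$strata) == i
    expect_true(all(diff(sf$surv[idx]) <= 1e-12))
    expect_lte(sf$surv[idx][1], 1)
  }
})
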