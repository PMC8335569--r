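# z-scoring, binarization, Fisher exact test, BH, the per-gene driven-cell
# orchestration, and pairwise co-occurrence / mutual exclusivity.

test_that("zscore_rows standardises rows and flags constant rows", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(7, 7, 7, 7, 7))
  colnames(m) <- paste0("s", 1:5)
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]),
               c(-1.2649, -0.6325, 0, 0.6325, 1.2649), tolerance = 1e-4)
  expect_equal(unname(z["b", ]), rep(0, 5))
  expect_equal(attr(z, "constant_rows"), "b")

  set.seed(1)
  r <- matrix(rnorm(40), 4, dimnames = list(paste0("r", 1:4), paste0("c", 1:10)))
  zr <- zscore_rows(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(zr, 1, sd)), rep(1, 4), tolerance = 1e-12)
})

test_that("binarization uses strict > for up, <= for down, disjointly", {
  x <- matrix(c(rep(0, 9), 10), nrow = 1,
              dimnames = list("r", paste0("s", 1:10)))
  z <- zscore_rows(x)
  expect_equal(unname(z[1, 10]), 9 / sqrt(10), tolerance = 1e-12)  # approx 2.846
  b <- binarize(z)
  expect_equal(unname(b$up[1, ]), c(rep(0, 9), 1))
  expect_equal(sum(b$down), 0)

  # boundary: z exactly at the threshold
  zb <- matrix(c(2, -2, 0, 1), nrow = 1, dimnames = list("r", paste0("s", 1:4)))
  bb <- binarize(zb, 2)
  expect_equal(unname(bb$up[1, ]), c(0, 0, 0, 0))    # strict >
  expect_equal(unname(bb$down[1, ]), c(0, 1, 0, 0))  # inclusive <=

  # negating a z row swaps up and down (away from the exact boundary, where
  # the strict/inclusive asymmetry applies)
  zc <- matrix(c(2.5, -2.5, 0, 1), nrow = 1,
               dimnames = list("r", paste0("s", 1:4)))
  bc <- binarize(zc, 2)
  bn <- binarize(-zc, 2)
  expect_identical(bn$up, bc$down)
  expect_identical(bn$down, bc$up)
  expect_true(all(bb$up + bb$down <= 1))
})

test_that("fisher_exact_2x2 matches enumeration and degenerate conventions", {
  ft <- fisher_exact_2x2(matrix(c(8, 2, 1, 9), 2, byrow = TRUE))
  expect_equal(ft$p, oracle_fisher_p(8, 2, 1, 9), tolerance = 1e-12)
  expect_equal(ft$p, 0.005477495, tolerance = 1e-7)  # frozen from the oracle
  expect_equal(ft$odds_ratio, 36)

  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$odds_ratio, 1)

  deg <- fisher_exact_2x2(matrix(c(0, 10, 0, 10), 2, byrow = TRUE))
  expect_equal(deg$p, 1)
  expect_true(is.na(deg$odds_ratio))

  inf <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_identical(inf$odds_ratio, Inf)
})

test_that("bh_adjust reproduces hand step-up values and its invariances", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))

  set.seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm])     # permutation equivariance
  expect_gte(q[which.max(p)], max(p))           # largest p never shrinks
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("find_driven_cells recovers a planted association and is equivariant", {
  truth <- cohort_truth(planted = data.frame(gene = 1, cell = 5, direction = 1,
                                             effect = 3),
                        mut_freq = 0.3)
  co <- generate_cohort(200, 12, 4, truth, seed = 31)
  res <- find_driven_cells(co$abundance, co$mutations, n_perm = 200, seed = 9)
  pairs <- driven_pairs(res)
  expect_true(any(pairs$gene == "G001" & pairs$cell == "cell05" &
                    pairs$direction == "up"))
  # result tables carry valid BH output and the driven calls respect the cut
  r <- res$genes[["G001"]]
  expect_equal(r$fdr, bh_adjust(r$p), tolerance = 1e-12)
  expect_true(all(r$fdr[r$driven] < 0.05))

  # relabeling samples identically in both inputs changes nothing
  set.seed(2); perm <- sample(ncol(co$abundance))
  res2 <- find_driven_cells(co$abundance[, perm], co$mutations[, perm],
                            n_perm = 200, seed = 9)
  expect_equal(driven_pairs(res2), pairs)
  expect_equal(res2$summary, res$summary)
})

test_that("genes without SAM-significant cells give empty results, not errors", {
  co <- generate_cohort(60, 6, 3, cohort_truth(mut_freq = 0.4), seed = 4)
  res <- find_driven_cells(co$abundance, co$mutations, n_perm = 100, seed = 1)
  expect_equal(length(res$genes), 3L)
  expect_true(all(vapply(res$genes, is.data.frame, TRUE)))
  expect_equal(nrow(res$summary), 3L)

  # disjoint samples are an error
  ab2 <- co$abundance; colnames(ab2) <- paste0("X", colnames(ab2))
  expect_error(find_driven_cells(ab2, co$mutations, n_perm = 100, seed = 1),
               "shared")
})

test_that("co-occurrence and exclusivity labels follow odds-ratio direction", {
  set.seed(12)
  n <- 100
  a <- rbinom(n, 1, 0.4)
  m <- rbind(A = a, B = a,                       # exact copy: co-occurring
             C = 1 - a,                          # complement: exclusive
             D = rbinom(n, 1, 0.3))
  colnames(m) <- sprintf("S%03d", 1:n)
  res <- cooc_mutex(m)
  ab <- res[res$gene_a == "A" & res$gene_b == "B", ]
  expect_identical(ab$odds_ratio, Inf)
  expect_equal(ab$label, "co-occurring")
  ac <- res[res$gene_a == "A" & res$gene_b == "C", ]
  expect_equal(ac$odds_ratio, 0)
  expect_equal(ac$label, "mutually exclusive")
  expect_equal(nrow(res), choose(4, 2))
  expect_error(cooc_mutex(m, genes = "A"), "2 genes")
})

test_that("independent mutation vectors are rarely labelled", {
  set.seed(33)
  frac <- replicate(20, {
    m <- matrix(rbinom(8 * 80, 1, 0.3), nrow = 8,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:80)))
    res <- cooc_mutex(m, alpha = 0.05)
    mean(res$label != "none")
  })
  # Fisher is conservative at these counts; allow Monte-Carlo slack
  expect_lte(mean(frac), 0.05 + 2 * sd(frac) / sqrt(length(frac)))
})
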