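test_that("the lnROR matrix is assembled in events-x-drugs orientation", {
  rs <- toy_report_set()
  sig <- pairwise_signals(rs, drugs = c("D", "X"), events = c("E", "F"))
  m <- assemble_matrix(sig)
  expect_equal(dim(m), c(2, 2))
  expect_equal(rownames(m), c("E", "F"))
  expect_equal(colnames(m), c("D", "X"))
  # entry checked against the directly computed pair statistic
  s_de <- signal_stats(build_contingency(rs, "D", "E"))
  expect_equal(m["E", "D"], s_de$ln_ror)
  expect_true(all(is.finite(m)))
  expect_error(assemble_matrix(sig, drugs = c("D", "D")), "duplicate")
  expect_error(assemble_matrix(sig[sig$drug != "D" | sig$event != "E", ]),
               "missing signal")
})

test_that("correlation PCA matches the closed-form 2x2 solution and its invariants", {
  # two identical columns: all variance on PC1
  x <- cbind(a = c(1, 5, 3, 4), b = c(2, 10, 6, 8))
  p <- pca_correlation(x, n_retain = 2)
  expect_equal(p$eigenvalues[1], 2, tolerance = 1e-12)
  expect_equal(p$pct_variance[1], 100, tolerance = 1e-9)
  # closed form: eigenvalues of a 2x2 correlation matrix are 1 +/- r
  y <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5))
  r <- cor(y)[1, 2]
  p2 <- pca_correlation(y, n_retain = 2)
  expect_equal(p2$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-12)
  expect_equal(p2$pct_variance[1], 100 * (1 + r) / 2, tolerance = 1e-9)
  # loadings are correlations between components and columns
  expect_equal(unname(p2$loadings[, 1]),
               unname(cor(y, p2$scores[, 1])[, 1]), tolerance = 1e-12)
  expect_true(all(abs(p2$loadings) <= 1 + 1e-9))
  # scores are standardized
  expect_equal(unname(apply(p2$scores, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(pca_correlation(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance")
  expect_error(pca_correlation(y[1:2, ]), "at least 3")
})

test_that("PCA percent variance sums to 100 and is invariant to column scaling", {
  set.seed(11)
  x <- matrix(rnorm(21 * 31), 21, 31,
              dimnames = list(sprintf("e%02d", 1:21), sprintf("d%02d", 1:31)))
  p <- pca_correlation(x)
  expect_equal(sum(p$pct_variance), 100, tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # with more variables than observations, trace is still the variable count
  expect_equal(sum(p$eigenvalues), 31, tolerance = 1e-9)
  # scaling a column changes nothing (correlation PCA), incl. fixed signs
  x2 <- x; x2[, 4] <- x2[, 4] * 37.5
  p2 <- pca_correlation(x2)
  expect_equal(p2$eigenvalues, p$eigenvalues, tolerance = 1e-9)
  expect_equal(p2$loadings, p$loadings, tolerance = 1e-8)
  expect_equal(p2$scores, p$scores, tolerance = 1e-8)
  # byte-for-byte determinism on identical input
  expect_identical(pca_correlation(x), p)
})

test_that("the site t-test matches its hand-computed pooled-variance example", {
  out <- pc_site_ttest(c(1, 2, 3, 4, 5, 6),
                       c(rep("upper", 3), rep("lower", 3)))
  expect_equal(abs(out$t), 3.674235, tolerance = 1e-6)
  expect_equal(out$df, 4)
  expect_equal(out$p_value, 0.0213, tolerance = 1e-3)
  # identical groups: t = 0, p = 1
  same <- pc_site_ttest(rep(c(1, 2), 4), rep(c("upper", "lower"), each = 4))
  expect_equal(same$p_value, 1)
  # not_classified events are excluded; small groups are an error
  expect_error(pc_site_ttest(1:4, c("upper", "upper", "upper", "lower")),
               "at least 2")
  # strongly site-differentiated synthetic signals separate on some component
  cfg <- scenario_planted_clusters(seed = 6)
  rs <- generate_reports(cfg)
  sig <- pairwise_signals(rs)
  pca <- pca_correlation(assemble_matrix(sig))
  sites <- cfg$truth_sites[rownames(pca$scores)]
  pmin_ <- min(vapply(seq_len(pca$n_retain), function(j)
    pc_site_ttest(pca$scores[, j], sites)$p_value, numeric(1)))
  expect_lt(pmin_, 0.05)
})

test_that("Ward clustering orders merges by height and recovers planted 1-D structure", {
  # identical points: all merge heights 0
  x0 <- matrix(1, 4, 2, dimnames = list(letters[1:4], NULL))
  hc0 <- ward_cluster(x0)
  expect_equal(hc0$height, rep(0, 3))
  # {0, 0.1} and {10, 10.1}: two tiny merges, one dominant merge
  x1 <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
               dimnames = list(c("p1", "p2", "p3", "p4"), NULL))
  hc1 <- ward_cluster(x1)
  expect_true(all(diff(hc1$height) >= 0))
  expect_lt(hc1$height[2], 0.2)
  expect_gt(hc1$height[3], 5)
  cl <- assign_clusters(hc1, 2)
  expect_equal(unname(cl[c("p1", "p2")]), rep(cl[["p1"]], 2))
  expect_equal(unname(cl[c("p3", "p4")]), rep(cl[["p3"]], 2))
  expect_true(cl[["p1"]] != cl[["p3"]])
  expect_error(ward_cluster(x1[1, , drop = FALSE]), "at least 2")
})

test_that("the elbow rule finds the largest relative height jump", {
  # single dominant final merge -> k = 2
  expect_equal(elbow_select_k(c(0.1, 0.12, 0.15, 8)), 2L)
  # three planted 1-D triples -> k = 3
  x <- matrix(c(0, 0.1, 10, 10.1, 20, 20.1), ncol = 1,
              dimnames = list(sprintf("p%d", 1:6), NULL))
  expect_equal(elbow_select_k(ward_cluster(x)), 3L)
  # all-equal heights: degenerate, k = 1 with warning
  expect_warning(k <- elbow_select_k(c(1, 1, 1)), "no elbow")
  expect_equal(k, 1L)
  expect_error(elbow_select_k(0.5), "at least 2")
})

test_that("cluster assignment partitions, renumbers by size, and handles edge k", {
  set.seed(5)
  x <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(6, 8), 3, 2))
  rownames(x) <- sprintf("d%d", 1:8)
  hc <- ward_cluster(x)
  cl <- assign_clusters(hc, 2)
  expect_equal(sort(unique(cl)), 1:2)
  expect_equal(sum(cl == 1), 5)  # largest cluster gets label 1
  expect_equal(unique(assign_clusters(hc, 1)), 1L)
  expect_equal(sort(unique(assign_clusters(hc, 8))), 1:8)  # singletons
  expect_error(assign_clusters(hc, 9), "k must be")
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(9)
  for (i in 1:20) {
    a <- sample(1:3, 25, TRUE); b <- sample(1:4, 25, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})
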