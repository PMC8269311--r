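test_that("PCA handles degenerate and rank-1 inputs", {
  # identical samples: nothing to explain, all scores zero
  same <- make_rma(matrix(c(1, 2, 3, 1, 2, 3), 3), group = c("flight",
                                                             "ground"))
  p <- run_pca(same)
  expect_true(all(p$scores == 0))
  expect_true(all(p$explained_variance_fraction == 0))

  # one planted axis of variation, no noise: PC1 carries everything
  base <- c(1, 2, 3)
  shift <- c(0, 1, 2, 3)
  vals <- outer(base, shift) + 5
  r1 <- make_rma(vals, group = c("flight", "flight", "ground", "ground"))
  p1 <- run_pca(r1)
  expect_equal(p1$explained_variance_fraction[1L], 1, tolerance = 1e-12)

  expect_error(run_pca(make_rma(matrix(1:3, 3, 1), group = "flight")),
               "2 samples")
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(101)
  for (rep in 1:5) {
    vals <- matrix(rnorm(100), 10, 10,
                   dimnames = list(sprintf("M%02d", 1:10), NULL))
    tab <- make_rma(vals, group = rep(c("flight", "ground"), each = 5))
    p <- run_pca(tab)
    ev <- eigen(cov(t(vals)), symmetric = TRUE)$values
    expect_equal(p$explained_variance_fraction, ev / sum(ev),
                 tolerance = 1e-9)
    # loadings orthonormal, scores = centered data projected on loadings
    expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    centered <- t(vals) - colMeans(t(vals))[col(t(vals))]
    centered <- scale(t(vals), center = TRUE, scale = FALSE)
    expect_equal(unname(centered %*% p$loadings), unname(p$scores),
                 tolerance = 1e-9)
  }
})

test_that("PCA separates planted groups on PC1", {
  set.seed(7)
  vals <- matrix(rnorm(40 * 8, 100, 1), 40, 8)
  vals[, 1:4] <- vals[, 1:4] + 50  # large between-group shift
  tab <- make_rma(vals, group = rep(c("flight", "ground"), each = 4))
  p <- run_pca(tab)
  s1 <- p$scores[1:4, 1L]
  s2 <- p$scores[5:8, 1L]
  expect_true(all(sign(s1) == sign(s1[1])))
  expect_true(all(sign(s2) == -sign(s1[1])))
})

test_that("heatmap matrix is standardised, bounded and scale-free", {
  vals <- matrix(c(1, 5, 2, 7, 3, 6), 2,
                 dimnames = list(c("A", "B"), NULL))
  tab <- make_rma(vals, group = c("flight", "flight", "ground"))
  hm <- heatmap_matrix(tab)
  z <- (vals - rowMeans(vals)) / apply(vals, 1, sd)  # hand z-score
  expect_equal(unname(hm$values), unname(z / max(abs(z))),
               tolerance = 1e-12)
  expect_true(all(abs(hm$values) <= 1))
  expect_equal(max(abs(hm$values)), 1)

  # invariant under positive rescaling of the input
  hm2 <- heatmap_matrix(make_rma(vals * 37, group = c("flight", "flight",
                                                      "ground")))
  expect_equal(hm2$values, hm$values, tolerance = 1e-12)

  # constant metabolite row maps to zero with a warning
  vals3 <- rbind(vals, C = c(4, 4, 4))
  expect_warning(hm3 <- heatmap_matrix(
    make_rma(vals3, group = c("flight", "flight", "ground"))), "zero-var")
  expect_true(all(hm3$values["C", ] == 0))
})

test_that("ground merging averages the listed samples", {
  vals <- matrix(c(1, 10, 3, 30, 5, 50), 2,
                 dimnames = list(c("A", "B"), c("f1", "g1", "g2")))
  tab <- make_rma(vals, group = c("flight", "ground", "ground"))
  out <- merge_ground(tab, c("g1", "g2"))
  expect_equal(ncol(out$values), 2L)
  expect_equal(unname(out$values[, "ground_mean"]), c(4, 40))

  # single id: identity rename
  out1 <- merge_ground(tab, "g1", merged_id = "gm")
  expect_equal(unname(out1$values[, "gm"]), c(3, 30))
  expect_equal(ncol(out1$values), 3L)

  expect_error(merge_ground(tab, c("f1", "g1")), "ground")
  expect_error(merge_ground(tab, "nope"), "unknown")
})

test_that("outlier flagging scores max-share and splits ties", {
  set.seed(33)
  vals <- matrix(rlnorm(50 * 6, log(100), 0.2), 50, 6)
  vals[, 3] <- vals[, 3] * 3  # leakage-like global inflation
  tab <- make_rma(vals, group = rep(c("flight", "ground"), each = 3))
  fl <- flag_outlier_samples(tab)
  expect_equal(fl$sample_id[1L], "S03")
  expect_gt(fl$score[1L], 0.95)
  expect_identical(fl$flagged, c(TRUE, rep(FALSE, 5)))

  # exchangeable noise-only columns: scores near 1/n, nothing flagged
  vals0 <- matrix(rlnorm(200 * 6, log(100), 0.2), 200, 6)
  fl0 <- flag_outlier_samples(make_rma(vals0,
                                       group = rep(c("flight", "ground"),
                                                   each = 3)))
  expect_false(any(fl0$flagged))
  expect_lt(max(fl0$score), 0.5)

  # two tied maximum columns split the score, so neither is flagged
  tie <- matrix(c(5, 5, 1), 10, 3, byrow = TRUE)
  flt <- flag_outlier_samples(make_rma(tie, group = c("flight", "flight",
                                                      "ground")))
  expect_equal(sort(flt$score), c(0, 0.5, 0.5))
  expect_false(any(flt$flagged))

  expect_error(flag_outlier_samples(make_rma(matrix(1:4, 2),
                                             group = c("flight", "ground"))),
               "3 samples")
})

test_that("the planted leakage sample is flagged in the default world", {
  pair <- generate_pair(seed = 9)
  pre <- preprocess_platform(pair$cellbox)
  fl <- flag_outlier_samples(pre$rma)
  expect_identical(fl$sample_id[fl$flagged], "FM_02")
})
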