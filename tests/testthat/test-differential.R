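test_that("signed fold change keeps inversion semantics", {
  expect_equal(fold_change(10, 5), 2)
  expect_equal(fold_change(10, 10), 1)
  # consumption at 1 g turning into production in flight is negative
  expect_equal(fold_change(60, -1), -60)
  expect_warning(fc0 <- fold_change(5, 0), "undefined")
  expect_true(is.na(fc0))
})

test_that("two-sample test matches a Welch oracle and its conventions", {
  expect_equal(test_two_sample(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(test_two_sample(c(2, 2, 2), c(1, 1, 1)), 0)
  set.seed(5)
  x <- rlnorm(5, log(100), 0.4)
  y <- rlnorm(3, log(150), 0.3)
  expect_equal(test_two_sample(x, y), welch_oracle(x, y),
               tolerance = 1e-12)
  # near-complete separation
  expect_lt(test_two_sample(c(100, 100.1, 99.9, 100), c(0, 0.1, -0.1)),
            1e-6)
  expect_error(test_two_sample(1, c(1, 2)), ">= 2")
})

test_that("single-sample test matches the hand t computation", {
  expect_equal(test_single_sample(c(11, 11, 11), 11), 1)
  expect_equal(test_single_sample(c(10, 11, 12), 11), 1)  # t = 0
  x <- c(10, 12, 14)
  t <- mean(x) / (sd(x) / sqrt(3))
  expect_equal(test_single_sample(x, 0), 2 * pt(-abs(t), df = 2),
               tolerance = 1e-12)
  expect_error(test_single_sample(10, 0), ">= 2")
})

test_that("FDR estimation is Benjamini-Hochberg", {
  expect_equal(estimate_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(estimate_fdr(0.2), 0.2)
  expect_equal(estimate_fdr(rep(1, 4)), rep(1, 4))
  set.seed(8)
  p <- runif(6)
  perms <- matrix(unlist(combinat_perms(6)), ncol = 6, byrow = TRUE)
  for (k in sample(nrow(perms), 50)) {
    pp <- p[perms[k, ]]
    expect_equal(estimate_fdr(pp), bh_oracle(pp), tolerance = 1e-12)
  }
  # order-preserving: monotone in the raw p-values
  q <- estimate_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("band assignment uses the two FDR tiers inclusively", {
  expect_equal(assign_band(c(0.10, 0.42, 0.70)), c("pp", "p", "ns"))
  # boundary conventions: 0.35 falls into "+", 0.50 still "+"
  expect_equal(assign_band(c(0.35, 0.50, 0.5000001)), c("p", "p", "ns"))
  expect_equal(assign_band(0.3499999), "pp")
})

test_that("effect regions follow the volcano-plot geometry", {
  expect_equal(classify_effect(3.7, "pp"), "strong_increase")
  expect_equal(classify_effect(-60, "p"), "strong_inversion")
  expect_equal(classify_effect(0.3, "ns"), "unclassified")
  expect_equal(classify_effect(0.3, "p"), "weak_or_inverted_decrease")
  expect_equal(classify_effect(-0.2, "pp"), "weak_or_inverted_decrease")
  # all region boundaries are open
  expect_equal(classify_effect(c(2, 0.5, -0.5, -1), rep("pp", 4)),
               rep("unclassified", 4))
  expect_equal(classify_effect(NA_real_, "pp"), "unclassified")
})

test_that("direction of change is the sign of the mean difference", {
  expect_equal(direction_of_change(50, 20), 1L)
  expect_equal(direction_of_change(-40, -10), -1L)
  expect_equal(direction_of_change(7, 7), 0L)
})

test_that("two-sample records carry consistent fields", {
  set.seed(3)
  vals <- rbind(Up = c(rnorm(4, 60, 2), rnorm(3, 20, 2)),
                Flat = c(rnorm(4, 30, 2), rnorm(3, 30, 2)),
                Invert = c(rnorm(4, 40, 2), rnorm(3, -10, 2)))
  colnames(vals) <- sprintf("s%d", 1:7)
  tab <- make_rma(vals, group = rep(c("flight", "ground"), c(4, 3)))
  rec <- differential_two_sample(tab)
  expect_equal(rec$metabolite_id, rownames(vals))
  expect_equal(rec$fc, rec$flight_mean / rec$ground_mean)
  expect_equal(rec$fdr, estimate_fdr(rec$raw_p))
  expect_equal(rec$band, assign_band(rec$fdr))
  # negative fc if and only if the means have opposite signs
  expect_equal(rec$fc < 0,
               sign(rec$flight_mean) != sign(rec$ground_mean))
  expect_lt(rec$raw_p[1L], 0.01)
  expect_gt(rec$raw_p[2L], 0.1)
  expect_equal(rec$direction, c(1L, direction_of_change(
    rec$flight_mean[2L], rec$ground_mean[2L]), 1L))
})

test_that("single-sample records test replicates against the ground mean", {
  pair <- generate_pair(seed = 13, noise_cv = 0, missing_below_lod_prob = 0)
  pre <- preprocess_platform(pair$texus)
  rec <- differential_single_sample(pre, pre$rma, "ug")
  tr <- pair$truth
  i <- match("Ornithine", rec$metabolite_id)
  expect_equal(rec$fc[i], tr$effects$Ornithine[["ug"]])
  # zero noise: replicates equal the sample value; equal-to-ground means p=1
  stable <- match("L-Leucine", rec$metabolite_id)
  expect_equal(rec$raw_p[stable], 1)
  expect_error(differential_single_sample(pre, pre$rma, "longterm"),
               "condition")
})

test_that("bar export filters by FDR and reports sample sd", {
  vals <- rbind(A = c(10, 20, 5, 8, 6), B = c(1, 2, 1.2, 0.8, 1.1))
  colnames(vals) <- sprintf("s%d", 1:5)
  tab <- make_rma(vals, group = rep(c("flight", "ground"), c(2, 3)))
  rec <- differential_two_sample(tab)
  rec$fdr <- c(0.2, 0.6)
  rec$band <- assign_band(rec$fdr)
  out <- bar_export(tab, rec, fdr_cutoff = 0.5)
  expect_setequal(out$metabolite_id, "A")
  g <- out[out$group == "ground", ]
  expect_equal(g$mean, mean(c(5, 8, 6)))
  expect_equal(g$sd, sd(c(5, 8, 6)))
  expect_equal(unique(out$band), "++")
  # ground sd over two values is the n-1 sample sd: sd(10,20) = 7.07
  expect_equal(sd(c(10, 20)), 7.0710678, tolerance = 1e-6)
  # empty selection yields an empty, well-formed frame
  none <- bar_export(tab, rec, fdr_cutoff = 0.1)
  expect_equal(nrow(none), 0L)
  expect_named(none, c("metabolite_id", "group", "mean", "sd", "band"))
})
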