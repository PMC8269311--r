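test_that("technical-pair imputation follows the LOD rule", {
  # partner below the detection limit: censoring, impute 1/5 of minimum
  expect_equal(impute_technical_pair(45, NA, dataset_min = 30), c(45, 6))
  expect_equal(impute_technical_pair(NA, 45, dataset_min = 30), c(6, 45))
  # partner clearly detected: carry the successful measurement over
  expect_equal(impute_technical_pair(120, NA, dataset_min = 30), c(120, 120))
  # boundary: exactly at the LOD counts as detected
  expect_equal(impute_technical_pair(50, NA, dataset_min = 30), c(50, 50))
  # nothing missing: untouched
  expect_equal(impute_technical_pair(80, 90, dataset_min = 30), c(80, 90))
  # both missing: left for the group-level filter
  expect_equal(impute_technical_pair(NA_real_, NA_real_, 30),
               c(NA_real_, NA_real_))
})

test_that("replicate collapsing and volume weighting are correct", {
  meta <- make_meta(c("s1a", "s1b", "s2a", "s2b", "s2c"),
                    bio = c("s1", "s1", "s2", "s2", "s2"),
                    rep = c(1L, 2L, 1L, 2L, 3L))
  tab <- raw_table(matrix(c(10, 20, 10, 10, 10), 1), metabolite_meta("M1"),
                   meta)
  out <- collapse_technical(tab)
  expect_equal(unname(out$values[1, ]), c(15, 10))

  # single replicate is the identity
  tab1 <- raw_table(matrix(c(7, 9), 1), metabolite_meta("M1"),
                    make_meta(c("a", "b"), bio = c("a", "b")))
  expect_equal(unname(collapse_technical(tab1)$values[1, ]), c(7, 9))

  # volume-weighted compartment combination: (10*3 + 20*1) / 4 = 12.5
  metac <- make_meta(c("x1", "x2", "y1"), bio = c("x", "x", "y"),
                     comp = c("C1", "C2", "C1"), vol = c(3, 1, 2))
  tabc <- raw_table(matrix(c(10, 20, 5), 1), metabolite_meta("M1"), metac)
  out <- combine_compartments(tabc)
  expect_equal(unname(out$values[1, ]), c(12.5, 5))

  # equal volumes reduce to the plain mean
  metac$recovered_volume <- c(1, 1, 2)
  tabe <- raw_table(matrix(c(10, 20, 5), 1), metabolite_meta("M1"), metac)
  expect_equal(unname(combine_compartments(tabe)$values[1, 1]), 15)
})

test_that("missingness filter applies both rules with the LOD clause", {
  M <- NA_real_
  # rule A: two missing flight values, all observed flight above 50
  f1 <- filter_missingness(raw_5v3(c(M, M, 80, 90, 70), c(60, 70, 80)))
  expect_equal(nrow(f1$values), 0L)
  expect_equal(attr(f1, "removed")$rule, "A")
  # an observed flight value at or below 50 blocks rule A
  f2 <- filter_missingness(raw_5v3(c(M, M, 40, 90, 70), c(60, 70, 80)))
  expect_equal(nrow(f2$values), 1L)
  # rule B: more than half missing in both groups, regardless of values
  f3 <- filter_missingness(raw_5v3(c(M, M, M, 40, 45), c(M, M, 44)))
  expect_equal(attr(f3, "removed")$rule, "B")
  # one missing ground value with large observed ground values: rule A
  f4 <- filter_missingness(raw_5v3(c(80, 90, 70, 60, 75), c(M, 70, 80)))
  expect_equal(attr(f4, "removed")$rule, "A")
  # complete data survive
  f5 <- filter_missingness(raw_5v3(c(80, 90, 70, 60, 75), c(60, 70, 80)))
  expect_equal(nrow(f5$values), 1L)
})

test_that("missingness filter matches the brute-force rule oracle", {
  # literal restatement of the stated rules, enumerated over every
  # missingness pattern of 5 flight + 3 ground samples with observed
  # values drawn from {40, 80}
  oracle <- function(fl, gr) {
    mf <- sum(is.na(fl)); mg <- sum(is.na(gr))
    a <- (mf >= 2 && all(fl[!is.na(fl)] > 50)) ||
      (mg >= 1 && all(gr[!is.na(gr)] > 50))
    b <- mf > 5 / 2 && mg > 3 / 2
    a || b
  }
  vals <- c(40, 80)
  mism <- 0L
  for (code in 0:(3^8 - 1)) {
    digits <- (code %/% 3^(0:7)) %% 3  # 0 = missing, 1 = 40, 2 = 80
    x <- c(NA, vals)[digits + 1]
    fl <- x[1:5]; gr <- x[6:8]
    if (all(is.na(x))) next
    got <- nrow(filter_missingness(raw_5v3(fl, gr))$values) == 0L
    if (got != oracle(fl, gr)) mism <- mism + 1L
  }
  expect_equal(mism, 0L)
})

test_that("residual mean imputation is within-group", {
  vals <- matrix(c(10, NA, 20, 100, 200, 300), 1)
  tab <- raw_table(vals, metabolite_meta("M1"),
                   make_meta(sprintf("s%d", 1:6),
                             group = rep(c("flight", "ground"), each = 3),
                             condition = rep(c("longterm", "control"),
                                             each = 3)))
  out <- impute_residual_mean(tab)
  expect_equal(unname(out$values[1, 2]), 15)  # mean(10, 20), not grand mean
  expect_equal(attr(out, "imputed_mean"), 1L)

  # two gaps in one group are both replaced by the observed mean
  vals2 <- matrix(c(10, NA, NA, 30, 1, 2, 3, 4), 1)
  tab2 <- raw_table(vals2, metabolite_meta("M1"),
                    make_meta(sprintf("s%d", 1:8),
                              group = rep(c("flight", "ground"), each = 4),
                              condition = rep(c("longterm", "control"),
                                              each = 4)))
  out2 <- impute_residual_mean(tab2)
  expect_equal(unname(out2$values[1, 2:3]), c(20, 20))

  # a fully missing surviving group is an internal error
  vals3 <- matrix(c(NA, NA, NA, 1, 2, 3), 1)
  tab3 <- raw_table(vals3, metabolite_meta("M1"),
                    make_meta(sprintf("s%d", 1:6),
                              group = rep(c("flight", "ground"), each = 3),
                              condition = rep(c("longterm", "control"),
                                              each = 3)))
  expect_error(impute_residual_mean(tab3), "fully missing")
})

test_that("blank preparation averages, imputes and falls back", {
  mk_blank <- function(x) raw_table(matrix(x, 1), metabolite_meta("M1"),
                                    make_meta(sprintf("b%d", seq_along(x)),
                                              role = "blank", group = "none",
                                              condition = "none",
                                              bio = "BLANK",
                                              rep = seq_along(x)))
  expect_equal(unname(prepare_blank(mk_blank(c(100, 110, 120)), 30)), 110)
  expect_equal(unname(prepare_blank(mk_blank(c(100, NA, 120)), 30)), 110)
  expect_equal(unname(prepare_blank(mk_blank(c(NA, NA, NA)), 30)), 6)
})

test_that("blank subtraction yields signed net fluxes", {
  tab <- raw_table(matrix(c(150, 60, 100), 1), metabolite_meta("M1"),
                   make_meta(c("s1", "s2", "s3"),
                             group = c("flight", "flight", "ground"),
                             condition = c("longterm", "longterm",
                                           "control")))
  out <- subtract_blank(tab, c(M1 = 100))
  expect_equal(unname(out$values[1, ]), c(50, -40, 0))
  expect_true(out$blank_subtracted)
  expect_error(subtract_blank(tab, c(OTHER = 100)), "panel")
})

test_that("problematic metabolites are removed per platform", {
  vals <- matrix(1:6, 3, dimnames = list(c("Sucrose", "Nonadecane",
                                           "Alanine"), NULL))
  cb <- make_rma(vals, group = c("flight", "ground"))
  out_cb <- remove_problematic(cb)
  expect_setequal(rownames(out_cb$values), "Alanine")
  expect_equal(attr(out_cb, "removed_problematic")$reason[
    attr(out_cb, "removed_problematic")$metabolite_id == "Sucrose"],
    "fixative_component")

  # Sucrose is only a fixative component on the long-term platform
  tx <- make_rma(vals, group = c("flight", "ground"), platform = "TEXUS54",
                 condition = c("ug", "control"))
  out_tx <- remove_problematic(tx)
  expect_setequal(rownames(out_tx$values), c("Alanine", "Sucrose"))

  expect_identical(remove_problematic(cb, exclusions = NULL)$values,
                   cb$values)
})

test_that("reference scaling matches means and is degenerate-safe", {
  target <- make_rma(matrix(c(10, 30, 20, 20), 2), group = c("flight",
                                                             "ground"))
  ref <- make_rma(matrix(c(5, 15, 10, 10), 2), group = c("flight",
                                                         "ground"))
  out <- scale_to_reference(target, ref)
  expect_equal(out$scaled_by, 2)
  expect_equal(mean(out$values), mean(ref$values), tolerance = 1e-12)
  expect_equal(out$values, target$values / 2)

  same <- scale_to_reference(ref, ref)
  expect_equal(same$scaled_by, 1)
  expect_equal(same$values, ref$values)

  zero <- make_rma(matrix(0, 2, 2), group = c("flight", "ground"))
  expect_error(scale_to_reference(zero, ref), "degenerate")
})

test_that("the ladder is idempotent on an already-processed table", {
  pair <- generate_pair(seed = 21, noise_cv = 0,
                        missing_below_lod_prob = 0)
  pre <- preprocess_platform(pair$cellbox)
  # re-feed the collapsed complete sample-level values as a raw-style table
  # (shift into positive territory since raw tables are non-negative)
  shift <- abs(min(pre$rma$values)) + 1
  tab <- raw_table(pre$rma$values + shift,
                   metabolite_meta(rownames(pre$rma$values)),
                   pre$rma$samples)
  # column ids are rewritten by the collapse steps; the values must not be
  expect_equal(unname(collapse_technical(tab)$values), unname(tab$values))
  expect_equal(unname(combine_compartments(tab)$values), unname(tab$values))
  expect_identical(filter_missingness(tab)$values, tab$values)
  expect_identical(impute_residual_mean(tab)$values, tab$values)
})

test_that("dataset minimum spans samples and blanks", {
  pair <- generate_pair(seed = 2)
  expect_equal(dataset_min(pair$cellbox),
               min(pair$cellbox$values, na.rm = TRUE))
})

test_that("unannotated compounds never survive preprocessing", {
  pair <- generate_pair(seed = 3)
  pre <- preprocess_platform(pair$texus)
  expect_false(any(grepl("^Unknown_", rownames(pre$rma$values))))
  expect_equal(pre$report$removed_unannotated, 4L)
  # all-annotated input is untouched by the annotation step
  ann <- drop_unannotated(pair$texus)
  expect_identical(drop_unannotated(ann)$values, ann$values)
  # none annotated: empty with a warning
  none <- raw_table(matrix(1:2, 1), metabolite_meta("M1", annotated = FALSE),
                    make_meta(c("a", "b"), bio = c("a", "b")))
  expect_warning(out <- drop_unannotated(none), "no annotated")
  expect_equal(nrow(out$values), 0L)
})
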