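#' Signed fold change of net fluxes
#'
#' The ratio of flight to ground mean net flux. Because net fluxes are
#' blank-subtracted they can be negative, so the fold change is signed:
#' a negative value means the metabolite inverted between net production
#' and net consumption across conditions. The magnitude of a net flux
#' (its absolute value) is referred to as the effect size.
#'
#' @param flight_mean,ground_mean Signed mean net fluxes.
#' @return `flight_mean / ground_mean`; `NA` with a warning where
#'   `ground_mean` is zero (undefined fold change).
#' @examples
#' fold_change(10, 5)    # 2
#' fold_change(60, -1)   # -60: consumption at 1 g, production in flight
#' @export
fold_change <- function(flight_mean, ground_mean) {
  undef <- ground_mean == 0
  if (any(undef, na.rm = TRUE))
    warning("undefined fold change for zero ground mean")
  out <- flight_mean / ground_mean
  out[undef] <- NA_real_
  out
}

#' Welch two-sample t-test p-value
#'
#' Two-sided two-sample t-test with unequal variances for the difference
#' of mean net flux between the flight and ground groups. If both groups
#' are constant, the p-value is 1 for equal means and 0 otherwise by
#' convention.
#'
#' @param flight_values,ground_values Numeric vectors (>= 2 values each).
#' @return The raw p-value.
#' @export
test_two_sample <- function(flight_values, ground_values) {
  if (length(flight_values) < 2L || length(ground_values) < 2L)
    stop("two-sample test needs >= 2 values per group", call. = FALSE)
  if (sd(flight_values) == 0 && sd(ground_values) == 0)
    return(if (mean(flight_values) == mean(ground_values)) 1 else 0)
  t.test(flight_values, ground_values, var.equal = FALSE)$p.value
}

#' One-sample t-test p-value against the ground mean
#'
#' For designs with a single flight sample per condition, the flight
#' condition's technical replicates are tested (two-sided) against the
#' pooled ground mean as the null value.
#'
#' @param flight_values Technical replicates of the flight condition.
#' @param ground_mean Null value (pooled ground mean net flux).
#' @return The raw p-value.
#' @export
test_single_sample <- function(flight_values, ground_mean) {
  if (length(flight_values) < 2L)
    stop("single-sample test needs >= 2 replicates", call. = FALSE)
  if (sd(flight_values) == 0)
    return(if (mean(flight_values) == ground_mean) 1 else 0)
  t.test(flight_values, mu = ground_mean)$p.value
}

#' Benjamini-Hochberg FDR estimates
#'
#' Step-up adjusted p-values: on sorted raw p-values,
#' `q(i) = min over j >= i of m * p(j) / j`, capped at 1 and mapped back
#' to the input order.
#'
#' @param raw_p Vector of raw p-values.
#' @return Adjusted values in the input order.
#' @export
estimate_fdr <- function(raw_p) {
  stopifnot(all(raw_p >= 0 & raw_p <= 1, na.rm = TRUE))
  p.adjust(raw_p, method = "BH")
}

#' Assign the two-tier significance band
#'
#' `"pp"` ("++") below the upper FDR threshold, `"p"` ("+") from there
#' up to and including the lower threshold, `"ns"` beyond.
#'
#' @param fdr FDR estimates.
#' @param constants [grav_constants()].
#' @return Character vector in `c("pp", "p", "ns")`.
#' @export
assign_band <- function(fdr, constants = grav_constants()) {
  ifelse(fdr < constants$fdr_upper, "pp",
         ifelse(fdr <= constants$fdr_lower, "p", "ns"))
}

#' Classify the fold-change effect region
#'
#' Significant metabolites fall into three regions of the signed
#' fold-change axis: `strong_increase` (more than double),
#' `weak_or_inverted_decrease` (less than half in magnitude, inverted if
#' below zero), and `strong_inversion` (inverted with equal or larger
#' effect strength, fc below -1). Region boundaries are open intervals;
#' non-significant records and undefined fold changes are
#' `unclassified`.
#'
#' @param fc Signed fold changes.
#' @param band Significance bands ([assign_band()]).
#' @param constants [grav_constants()].
#' @return Character vector of effect regions.
#' @export
classify_effect <- function(fc, band, constants = grav_constants()) {
  out <- rep("unclassified", length(fc))
  sig <- band != "ns" & !is.na(fc)
  out[sig & fc > constants$fc_increase] <- "strong_increase"
  out[sig & fc > constants$fc_weak_lo & fc < constants$fc_weak_hi] <-
    "weak_or_inverted_decrease"
  out[sig & fc < constants$fc_invert] <- "strong_inversion"
  out
}

#' Direction of change between flight and ground
#'
#' The sign of `flight_mean - ground_mean`: +1 means more generation (or
#' less consumption) in flight, -1 less generation (or stronger
#' consumption).
#'
#' @param flight_mean,ground_mean Mean net fluxes.
#' @return Integer vector in `{-1, 0, +1}`.
#' @export
direction_of_change <- function(flight_mean, ground_mean) {
  as.integer(sign(flight_mean - ground_mean))
}

build_records <- function(ids, contrast, flight_mean, ground_mean,
                          ground_sd, raw_p, constants) {
  fdr <- estimate_fdr(raw_p)
  fc <- suppressWarnings(fold_change(flight_mean, ground_mean))
  band <- assign_band(fdr, constants)
  data.frame(metabolite_id = ids,
             contrast = contrast,
             flight_mean = unname(flight_mean),
             ground_mean = unname(ground_mean),
             ground_sd = unname(ground_sd),
             row.names = NULL,
             fc = fc,
             raw_p = raw_p,
             fdr = fdr,
             band = band,
             effect_region = classify_effect(fc, band, constants),
             direction = direction_of_change(flight_mean, ground_mean),
             stringsAsFactors = FALSE)
}

#' Two-sample differential analysis (flight vs ground)
#'
#' Per metabolite: Welch t-test of flight against ground sample net
#' fluxes, BH-FDR over the panel, signed fold change of the group means,
#' significance band and effect-region classification.
#'
#' @param table A blank-subtracted [rma_table()] (outliers already
#'   removed if applicable).
#' @param constants [grav_constants()].
#' @return A data.frame of differential records, one row per metabolite.
#' @export
differential_two_sample <- function(table, constants = grav_constants()) {
  assert_net(table, "differential analysis")
  grp <- table$samples$group
  fl <- which(grp == "flight")
  gr <- which(grp == "ground")
  v <- table$values
  raw_p <- vapply(seq_len(nrow(v)), function(i)
    test_two_sample(v[i, fl], v[i, gr]), 0)
  build_records(rownames(v), "flight_vs_ground",
                rowMeans(v[, fl, drop = FALSE]),
                rowMeans(v[, gr, drop = FALSE]),
                apply(v[, gr, drop = FALSE], 1L, sd),
                raw_p, constants)
}

#' Single-sample differential analysis (one flight sample vs ground)
#'
#' For the short-term design, each flight condition has a single
#' biological sample; its technical replicates (blank-subtracted) are
#' tested against the pooled ground mean with a one-sample t-test. Means
#' and fold changes use the collapsed per-sample table.
#'
#' @param pre A `grav_preprocess` result (provides the replicate-level
#'   net values) or a list with `values` and `measurements` like its
#'   `tech_net` element.
#' @param table The collapsed blank-subtracted [rma_table()] of the same
#'   platform.
#' @param condition Flight condition to contrast (`"hypg"` or `"ug"`).
#' @param constants [grav_constants()].
#' @return A data.frame of differential records.
#' @export
differential_single_sample <- function(pre, table, condition,
                                       constants = grav_constants()) {
  tech <- if (inherits(pre, "grav_preprocess")) pre$tech_net else pre
  assert_net(table, "differential analysis")
  meta <- tech$measurements
  fl_reps <- which(meta$condition == condition)
  if (length(fl_reps) < 2L)
    stop("no replicated flight measurements for condition ", condition,
         call. = FALSE)
  gr <- which(table$samples$group == "ground")
  fl <- which(table$samples$condition == condition)
  if (length(fl) != 1L)
    stop("expected exactly one flight sample for condition ", condition,
         call. = FALSE)
  v <- table$values
  ids <- rownames(v)
  ground_mean <- rowMeans(v[, gr, drop = FALSE])
  raw_p <- vapply(seq_along(ids), function(i)
    test_single_sample(tech$values[ids[i], fl_reps], ground_mean[i]), 0)
  build_records(ids, paste0(condition, "_vs_ground"),
                v[, fl], ground_mean,
                apply(v[, gr, drop = FALSE], 1L, sd),
                raw_p, constants)
}

#' Export bar-plot data for significant metabolites
#'
#' Rows of (metabolite, group, mean, sd, band mark) restricted to
#' records at or below the FDR cutoff — the data behind per-metabolite
#' abundance bar charts with mean +/- standard deviation. Groups with a
#' single sample get `NA` standard deviation.
#'
#' @param table The [rma_table()] the records were computed from.
#' @param records Differential records for one contrast.
#' @param fdr_cutoff Include records with `fdr <= fdr_cutoff`.
#' @return A data.frame with `metabolite_id`, `group`, `mean`, `sd`,
#'   `band`.
#' @export
bar_export <- function(table, records, fdr_cutoff = 0.5) {
  sel <- records[records$fdr <= fdr_cutoff, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(metabolite_id = character(), group = character(),
                      mean = numeric(), sd = numeric(), band = character(),
                      stringsAsFactors = FALSE))
  cond <- sub("_vs_ground$", "", sel$contrast[1L])
  fl <- if (cond == "flight") which(table$samples$group == "flight")
  else which(table$samples$condition == cond)
  gr <- which(table$samples$group == "ground")
  v <- table$values[sel$metabolite_id, , drop = FALSE]
  sd_or_na <- function(x) if (length(x) > 1L) sd(x) else NA_real_
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    data.frame(metabolite_id = sel$metabolite_id[i],
               group = c(cond, "ground"),
               mean = c(mean(v[i, fl]), mean(v[i, gr])),
               sd = c(sd_or_na(v[i, fl]), sd_or_na(v[i, gr])),
               band = unname(c(pp = "++", p = "+", ns = "")[sel$band[i]]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
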