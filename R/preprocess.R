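#' Minimum observed raw signal of a dataset
#'
#' The lowest non-missing raw value over the whole platform dataset,
#' blanks included; the reference point for detection-limit imputation
#' (a fixed fraction of it replaces values censored near the LOD).
#'
#' @param table A [raw_table()].
#' @return A scalar.
#' @export
dataset_min <- function(table) {
  v <- table$values
  if (all(is.na(v))) stop("no observed values in dataset", call. = FALSE)
  min(v, na.rm = TRUE)
}

#' Drop unannotated compounds
#'
#' Compounds whose spectra could not be matched to a reference metabolite
#' carry no interpretable identity and are removed first.
#'
#' @param table A [raw_table()].
#' @return The table restricted to annotated metabolites.
#' @export
drop_unannotated <- function(table) {
  keep <- table$metabolites$annotated
  if (!any(keep)) warning("no annotated metabolites remain")
  raw_table(table$values[keep, , drop = FALSE],
            table$metabolites[keep, , drop = FALSE],
            table$measurements)
}

#' Impute a technical-replicate pair with one missing value
#'
#' If one of two technical replicates is missing and the observed one
#' lies below the detection limit, the missing slot is replaced by
#' `impute_fraction` (1/5) of the lowest signal observed in the whole
#' dataset — the partner is itself barely detectable, so the failed
#' injection is read as censoring. If the observed replicate is at or
#' above the limit, the measurement is taken to have simply failed and
#' the observed value is carried over. Pairs without missingness pass
#' through unchanged; pairs with both values missing are left to the
#' group-level missingness filter.
#'
#' @param v1,v2 Replicate values (`NA` = missing).
#' @param dataset_min Minimum observed signal of the whole dataset.
#' @param constants [grav_constants()].
#' @return Numeric vector `c(v1, v2)` after imputation.
#' @examples
#' impute_technical_pair(45, NA, dataset_min = 30)   # -> c(45, 6)
#' impute_technical_pair(120, NA, dataset_min = 30)  # -> c(120, 120)
#' @export
impute_technical_pair <- function(v1, v2, dataset_min,
                                  constants = grav_constants()) {
  pair <- c(v1, v2)
  miss <- is.na(pair)
  if (sum(miss) != 1L) return(pair)
  obs <- pair[!miss]
  pair[miss] <- if (obs < constants$lod)
    dataset_min * constants$impute_fraction
  else obs
  pair
}

#' Collapse technical replicates
#'
#' Averages technical replicates into one column per (biological sample,
#' compartment). Replicate pairs with a single missing value are first
#' imputed with [impute_technical_pair()]; for larger replicate groups
#' the mean of the observed values is taken; fully missing groups stay
#' missing.
#'
#' @param table A [raw_table()].
#' @param constants [grav_constants()].
#' @param min_value Minimum observed signal of the dataset; computed from
#'   `table` when not supplied (supply the pre-split value when blanks
#'   are processed separately).
#' @return A [raw_table()] with `tech_rep_index = 0` columns.
#' @export
collapse_technical <- function(table, constants = grav_constants(),
                               min_value = NULL) {
  if (is.null(min_value)) min_value <- dataset_min(table)
  meta <- table$measurements
  key <- paste(meta$biological_sample_id, meta$compartment_id, sep = "\r")
  groups <- split(seq_len(nrow(meta)), factor(key, unique(key)))
  vals <- sapply(groups, function(idx) {
    v <- table$values[, idx, drop = FALSE]
    apply(v, 1L, function(x) {
      if (length(x) == 2L) x <- impute_technical_pair(x[1L], x[2L],
                                                      min_value, constants)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    })
  })
  if (nrow(table$values) == 1L) vals <- matrix(vals, nrow = 1L)
  first <- vapply(groups, `[`, 0L, 1L)
  meta2 <- meta[first, , drop = FALSE]
  meta2$tech_rep_index <- 0L
  meta2$measurement_id <- paste(meta2$biological_sample_id,
                                meta2$compartment_id, sep = ".")
  rownames(meta2) <- NULL
  raw_table(vals, table$metabolites, meta2)
}

#' Combine hardware compartments by recovered volume
#'
#' Joins the compartments of each biological sample into a single signal
#' by the volume-weighted mean `sum(v_i * x_i) / sum(v_i)`, the in-silico
#' equivalent of pooling the recovered fluids. Compartments with missing
#' values are dropped from the weighted mean; a sample missing in all
#' compartments stays missing.
#'
#' @param table A [raw_table()] with technical replicates collapsed.
#' @param constants [grav_constants()].
#' @return A [raw_table()] with one column per biological sample.
#' @export
combine_compartments <- function(table, constants = grav_constants()) {
  meta <- table$measurements
  groups <- split(seq_len(nrow(meta)),
                  factor(meta$biological_sample_id,
                         unique(meta$biological_sample_id)))
  vals <- sapply(groups, function(idx) {
    w <- meta$recovered_volume[idx]
    if (all(w <= 0)) stop("all-zero recovered volumes", call. = FALSE)
    v <- table$values[, idx, drop = FALSE]
    apply(v, 1L, function(x) {
      ok <- !is.na(x)
      if (!any(ok)) return(NA_real_)
      sum(x[ok] * w[ok]) / sum(w[ok])
    })
  })
  if (nrow(table$values) == 1L) vals <- matrix(vals, nrow = 1L)
  first <- vapply(groups, `[`, 0L, 1L)
  meta2 <- meta[first, , drop = FALSE]
  meta2$compartment_id <- "combined"
  meta2$recovered_volume <- vapply(groups, function(idx)
    sum(meta$recovered_volume[idx]), 0)
  meta2$measurement_id <- meta2$biological_sample_id
  rownames(meta2) <- NULL
  raw_table(vals, table$metabolites, meta2)
}

#' Filter metabolites by group-level missingness
#'
#' Applies two removal rules to the sample-level table:
#'
#' * Rule A: a metabolite is removed when its missing count reaches
#'   `ceiling(2/5 * n_flight)` in the flight group or
#'   `ceiling(1/3 * n_ground)` in the ground group, but only if every
#'   observed value of that metabolite in the triggering group lies
#'   above the detection limit — observed near-LOD signals make the
#'   missingness plausibly censoring rather than absence, and block
#'   removal.
#' * Rule B (independent of A): removed when strictly more than half the
#'   values are missing in the flight group and strictly more than half
#'   in the ground group.
#'
#' @param table A [raw_table()] collapsed to biological samples (no
#'   blanks).
#' @param constants [grav_constants()].
#' @return The filtered table, with attribute `"removed"` — a data.frame
#'   of removed metabolite ids and the rule that fired.
#' @export
filter_missingness <- function(table, constants = grav_constants()) {
  grp <- table$measurements$group
  fl <- which(grp == "flight")
  gr <- which(grp == "ground")
  thr_fl <- ceiling(2 / 5 * length(fl))
  thr_gr <- ceiling(1 / 3 * length(gr))
  rule <- character(nrow(table$values))
  for (i in seq_len(nrow(table$values))) {
    x_fl <- table$values[i, fl]
    x_gr <- table$values[i, gr]
    m_fl <- sum(is.na(x_fl))
    m_gr <- sum(is.na(x_gr))
    a_fl <- m_fl >= thr_fl && m_fl > 0L &&
      all(x_fl[!is.na(x_fl)] > constants$lod)
    a_gr <- m_gr >= thr_gr && m_gr > 0L &&
      all(x_gr[!is.na(x_gr)] > constants$lod)
    b <- m_fl > length(fl) / 2 && m_gr > length(gr) / 2
    rule[i] <- if (b) "B" else if (a_fl || a_gr) "A" else ""
  }
  removed <- data.frame(metabolite_id = rownames(table$values)[rule != ""],
                        rule = rule[rule != ""], stringsAsFactors = FALSE)
  keep <- rule == ""
  out <- raw_table(table$values[keep, , drop = FALSE],
                   table$metabolites[keep, , drop = FALSE],
                   table$measurements)
  attr(out, "removed") <- removed
  out
}

#' Impute residual missing values with the within-group mean
#'
#' After filtering, isolated missing values are replaced by the mean of
#' the metabolite's observed values within the same (flight or ground)
#' group; the grand mean is avoided so imputation cannot leak the
#' between-group contrast into imputed cells.
#'
#' @param table A sample-level [raw_table()].
#' @return The table with no missing values, plus attribute
#'   `"imputed_mean"` (count of imputed cells).
#' @export
impute_residual_mean <- function(table) {
  grp <- table$measurements$group
  v <- table$values
  n_imp <- 0L
  for (g in unique(grp)) {
    cols <- which(grp == g)
    for (i in seq_len(nrow(v))) {
      x <- v[i, cols]
      if (anyNA(x)) {
        if (all(is.na(x)))
          stop("metabolite ", rownames(v)[i], " fully missing in group ", g,
               " survived filtering", call. = FALSE)
        n_imp <- n_imp + sum(is.na(x))
        x[is.na(x)] <- mean(x, na.rm = TRUE)
        v[i, cols] <- x
      }
    }
  }
  out <- raw_table(v, table$metabolites, table$measurements)
  attr(out, "imputed_mean") <- n_imp
  out
}

#' Collapse blank replicates into a per-metabolite blank value
#'
#' Blank replicates are averaged without prior filtering; partial gaps
#' are effectively mean-imputed (the mean of the observed replicates is
#' taken), and a metabolite missing in every blank replicate falls back
#' to `impute_fraction` of the minimum observed signal of the whole
#' dataset.
#'
#' @param blank_table A [raw_table()] containing only blank columns.
#' @param min_value Minimum observed signal of the whole dataset
#'   (samples and blanks).
#' @param constants [grav_constants()].
#' @return A named per-metabolite vector of blank values.
#' @export
prepare_blank <- function(blank_table, min_value,
                          constants = grav_constants()) {
  v <- blank_table$values
  out <- apply(v, 1L, function(x) {
    if (all(is.na(x))) min_value * constants$impute_fraction
    else mean(x, na.rm = TRUE)
  })
  setNames(out, rownames(v))
}

#' Subtract the medium blank
#'
#' Converts supernatant abundances into net flux profiles: positive
#' entries are net production (secretion into the medium), negative
#' entries net consumption (uptake from the medium).
#'
#' @param table A sample-level [raw_table()] without missing values.
#' @param blank Named per-metabolite blank vector ([prepare_blank()]).
#' @return A blank-subtracted [rma_table()].
#' @export
subtract_blank <- function(table, blank) {
  ids <- rownames(table$values)
  if (!all(ids %in% names(blank)))
    stop("blank vector does not cover the metabolite panel", call. = FALSE)
  rma_table(table$values - blank[ids], table$measurements,
            blank_subtracted = TRUE)
}

#' Remove problematic metabolites
#'
#' Drops metabolites that carry no interpretable biological signal
#' (fixative components, reference-mixture compounds, ubiquitous
#' metabolites, compounds not documented in humans). Entries whose
#' `platform` is not `"all"` apply only to that platform.
#'
#' @param table An [rma_table()].
#' @param exclusions Data.frame with columns `name`, `reason`,
#'   `platform` ([default_exclusions()]).
#' @param platform Platform of `table`.
#' @return The filtered table with attribute `"removed_problematic"`.
#' @export
remove_problematic <- function(table, exclusions = default_exclusions(),
                               platform = NULL) {
  if (is.null(platform)) platform <- table$samples$platform[1L]
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    attr(table, "removed_problematic") <-
      data.frame(metabolite_id = character(), reason = character())
    return(table)
  }
  applies <- exclusions$platform == "all" | exclusions$platform == platform
  excl <- exclusions[applies, , drop = FALSE]
  hit <- rownames(table$values) %in% excl$name
  removed <- data.frame(
    metabolite_id = rownames(table$values)[hit],
    reason = excl$reason[match(rownames(table$values)[hit], excl$name)],
    stringsAsFactors = FALSE)
  out <- rma_table(table$values[!hit, , drop = FALSE], table$samples,
                   blank_subtracted = table$blank_subtracted,
                   scaled_by = table$scaled_by)
  attr(out, "removed_problematic") <- removed
  out
}

#' Scale a dataset to the mean of a reference dataset
#'
#' The relative abundance scales of the two platforms are not
#' comparable; the target table is divided by the scalar
#' `k = mean(target) / mean(reference)` so both share the same grand
#' mean. Fold changes and correlations downstream are invariant under
#' this positive global rescaling.
#'
#' @param target,reference Blank-subtracted [rma_table()]s.
#' @return The rescaled target with `scaled_by = k`.
#' @export
scale_to_reference <- function(target, reference) {
  assert_net(target, "scale_to_reference")
  assert_net(reference, "scale_to_reference")
  mt <- mean(target$values)
  mr <- mean(reference$values)
  if (mt == 0) stop("degenerate scaling: target mean is zero", call. = FALSE)
  k <- mt / mr
  if (!is.finite(k) || k <= 0)
    stop("degenerate scaling: non-positive scale factor", call. = FALSE)
  out <- rma_table(target$values / k, target$samples,
                   blank_subtracted = TRUE, scaled_by = k)
  stopifnot(abs(mean(out$values) - mr) <= 1e-9 * max(1, abs(mr)))
  out
}

#' Run the full preprocessing ladder on one platform
#'
#' Applies, in order: annotation filtering, technical-replicate
#' imputation and averaging, volume-weighted compartment combination,
#' group-level missingness filtering, residual within-group mean
#' imputation, blank preparation and subtraction, optional scaling to a
#' reference dataset, and problematic-metabolite removal. The blank is
#' subtracted after the missingness filter so the detection-limit
#' clauses of the filter act on raw signals, where the LOD is defined.
#'
#' @param raw A [raw_table()] (samples and blanks together).
#' @param constants [grav_constants()].
#' @param exclusions Problematic-metabolite list ([default_exclusions()]).
#' @param reference Optional blank-subtracted reference [rma_table()]
#'   (triggers mean scaling, applied before the exclusion step).
#' @return A list of class `grav_preprocess`:
#' \describe{
#'   \item{rma}{final blank-subtracted (possibly scaled) [rma_table()]}
#'   \item{rma_unscaled_means}{the table before scaling/exclusions, for
#'     use as a scaling reference for the other platform}
#'   \item{blank}{per-metabolite blank vector (final panel)}
#'   \item{tech_net}{blank-subtracted technical-replicate-level values of
#'     the sample measurements (matrix) and their metadata, for
#'     single-sample testing}
#'   \item{report}{audit trail of every rule fired}
#' }
#' @export
preprocess_platform <- function(raw, constants = grav_constants(),
                                exclusions = default_exclusions(),
                                reference = NULL) {
  report <- list()
  ann <- drop_unannotated(raw)
  report$removed_unannotated <- nrow(raw$values) - nrow(ann$values)

  min_value <- dataset_min(ann)
  is_blank <- ann$measurements$role == "blank"
  samples <- raw_table(ann$values[, !is_blank, drop = FALSE],
                       ann$metabolites,
                       ann$measurements[!is_blank, , drop = FALSE])
  blanks <- raw_table(ann$values[, is_blank, drop = FALSE],
                      ann$metabolites,
                      ann$measurements[is_blank, , drop = FALSE])

  n_missing_before <- sum(is.na(samples$values))
  coll <- collapse_technical(samples, constants, min_value)
  comb <- combine_compartments(coll, constants)
  filt <- filter_missingness(comb, constants)
  report$filtered_missingness <- attr(filt, "removed")
  imp <- impute_residual_mean(filt)
  report$imputed_mean <- attr(imp, "imputed_mean")
  report$missing_in_samples <- n_missing_before

  blank_vec <- prepare_blank(blanks, min_value, constants)
  net <- subtract_blank(imp, blank_vec)

  rma_prescale <- net
  if (!is.null(reference)) net <- scale_to_reference(net, reference)
  report$scale_factor <- net$scaled_by

  final <- remove_problematic(net, exclusions)
  report$removed_problematic <- attr(final, "removed_problematic")
  report$dataset_min <- min_value
  report$n_metabolites_final <- nrow(final$values)

  keep <- rownames(samples$values) %in% rownames(final$values)
  tech_vals <- samples$values[keep, , drop = FALSE] -
    blank_vec[rownames(samples$values)[keep]]
  if (net$scaled_by != 1) tech_vals <- tech_vals / net$scaled_by

  structure(list(rma = final,
                 rma_unscaled_means = rma_prescale,
                 blank = blank_vec,
                 tech_net = list(values = tech_vals,
                                 measurements = samples$measurements),
                 report = report),
            class = "grav_preprocess")
}

#' @export
print.grav_preprocess <- function(x, ...) {
  r <- x$report
  cat("preprocessing report:\n")
  cat(sprintf("  unannotated removed:        %d\n", r$removed_unannotated))
  cat(sprintf("  missing sample cells (raw): %d\n", r$missing_in_samples))
  cat(sprintf("  missingness-filtered:       %d\n",
              nrow(r$filtered_missingness)))
  cat(sprintf("  residual mean-imputed:      %d\n", r$imputed_mean))
  cat(sprintf("  problematic removed:        %d\n",
              nrow(r$removed_problematic)))
  cat(sprintf("  scale factor:               %.6g\n", r$scale_factor))
  cat(sprintf("  final panel:                %d metabolites\n",
              r$n_metabolites_final))
  invisible(x)
}

#' Drop samples from an RMA table
#'
#' @param table An [rma_table()].
#' @param sample_ids Biological sample ids to drop.
#' @return The table without those columns.
#' @export
drop_samples <- function(table, sample_ids) {
  keep <- !(table$samples$biological_sample_id %in% sample_ids)
  rma_table(table$values[, keep, drop = FALSE],
            table$samples[keep, , drop = FALSE],
            blank_subtracted = table$blank_subtracted,
            scaled_by = table$scaled_by)
}
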