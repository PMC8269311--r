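PLATFORMS <- c("TEXUS54", "CELLBOX")
ROLES <- c("sample", "blank")
GROUPS <- c("flight", "ground", "none")
CONDITIONS <- c("hypg", "ug", "longterm", "control", "none")

#' Construct a metabolite metadata table
#'
#' @param metabolite_id Character vector of unique metabolite ids.
#' @param name Display names (default: the ids).
#' @param annotated Logical: matched to a reference spectrum. Compounds
#'   without annotation never survive preprocessing.
#' @param excluded_reason Optional exclusion reason, `"none"` by default.
#' @return A validated data.frame of metabolite metadata.
#' @export
metabolite_meta <- function(metabolite_id,
                            name = metabolite_id,
                            annotated = TRUE,
                            excluded_reason = "none") {
  df <- data.frame(metabolite_id = as.character(metabolite_id),
                   name = as.character(name),
                   annotated = rep_len(as.logical(annotated),
                                       length(metabolite_id)),
                   excluded_reason = rep_len(as.character(excluded_reason),
                                             length(metabolite_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$metabolite_id))
    stop("duplicate metabolite ids", call. = FALSE)
  df
}

#' Construct a measurement metadata table
#'
#' One row per measured column of a raw abundance table: which platform,
#' whether the column is a biological sample or a medium blank, its
#' flight/ground group and gravity condition, the biological sample and
#' hardware compartment it came from, the volume recovered from that
#' compartment (used for in-silico volume-weighted signal combination),
#' and the technical replicate index.
#'
#' @param measurement_id Unique column ids.
#' @param platform `"TEXUS54"` or `"CELLBOX"`.
#' @param role `"sample"` or `"blank"`.
#' @param group `"flight"`, `"ground"` or `"none"` (blanks).
#' @param condition `"hypg"`, `"ug"`, `"longterm"`, `"control"` or `"none"`.
#' @param biological_sample_id Biological sample id.
#' @param compartment_id Hardware compartment id within the sample.
#' @param recovered_volume Recovered volume (mL), positive.
#' @param tech_rep_index Technical replicate index (non-negative integer).
#' @return A validated data.frame of measurement metadata.
#' @export
measurement_meta <- function(measurement_id, platform, role, group,
                             condition, biological_sample_id,
                             compartment_id = "C1",
                             recovered_volume = 1,
                             tech_rep_index = 1L) {
  n <- length(measurement_id)
  df <- data.frame(measurement_id = as.character(measurement_id),
                   platform = rep_len(as.character(platform), n),
                   role = rep_len(as.character(role), n),
                   group = rep_len(as.character(group), n),
                   condition = rep_len(as.character(condition), n),
                   biological_sample_id =
                     rep_len(as.character(biological_sample_id), n),
                   compartment_id = rep_len(as.character(compartment_id), n),
                   recovered_volume = rep_len(as.numeric(recovered_volume), n),
                   tech_rep_index = rep_len(as.integer(tech_rep_index), n),
                   stringsAsFactors = FALSE)
  validate_measurements(df)
  df
}

validate_measurements <- function(df) {
  if (anyDuplicated(df$measurement_id))
    stop("duplicate measurement ids", call. = FALSE)
  if (!all(df$platform %in% PLATFORMS))
    stop("unknown platform", call. = FALSE)
  if (!all(df$role %in% ROLES)) stop("unknown role", call. = FALSE)
  if (!all(df$group %in% GROUPS)) stop("unknown group", call. = FALSE)
  if (!all(df$condition %in% CONDITIONS))
    stop("unknown condition", call. = FALSE)
  bl <- df$role == "blank"
  if (any(df$group[bl] != "none") || any(df$condition[bl] != "none"))
    stop("blank measurements must have group = 'none' and condition = 'none'",
         call. = FALSE)
  if (any(!is.finite(df$recovered_volume) | df$recovered_volume <= 0))
    stop("recovered_volume must be positive", call. = FALSE)
  if (any(df$tech_rep_index < 0L))
    stop("tech_rep_index must be non-negative", call. = FALSE)
  key <- paste(df$biological_sample_id, df$compartment_id,
               df$tech_rep_index, sep = "\r")
  if (anyDuplicated(key))
    stop("(biological_sample_id, compartment_id, tech_rep_index) not unique",
         call. = FALSE)
  invisible(df)
}

#' Construct a raw abundance table
#'
#' A metabolite x measurement matrix of non-negative relative metabolite
#' abundances (RMA; internal-standard normalised, dimensionless) with
#' `NA` for missing entries, together with metabolite and measurement
#' metadata. Zero is a genuine measurement; missingness is always `NA`.
#'
#' @param values Numeric matrix, metabolites in rows, measurements in
#'   columns; entries `>= 0` or `NA`.
#' @param metabolites Metabolite metadata ([metabolite_meta()]).
#' @param measurements Measurement metadata ([measurement_meta()]).
#' @return An object of class `grav_raw`.
#' @export
raw_table <- function(values, metabolites, measurements) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(metabolites))
    stop("row count does not match metabolite metadata", call. = FALSE)
  if (ncol(values) != nrow(measurements))
    stop("column count does not match measurement metadata", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("raw abundance values must be non-negative", call. = FALSE)
  validate_measurements(measurements)
  rownames(values) <- metabolites$metabolite_id
  colnames(values) <- measurements$measurement_id
  structure(list(values = values,
                 metabolites = metabolites,
                 measurements = measurements),
            class = "grav_raw")
}

#' @export
print.grav_raw <- function(x, ...) {
  cat(sprintf("raw abundance table: %d metabolites x %d measurements\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  platform(s): %s\n",
              paste(unique(x$measurements$platform), collapse = ", ")))
  cat(sprintf("  samples: %d, blanks: %d, missing entries: %d\n",
              sum(x$measurements$role == "sample"),
              sum(x$measurements$role == "blank"),
              sum(is.na(x$values))))
  invisible(x)
}

#' Construct a net-abundance (RMA) table
#'
#' A metabolite x biological-sample matrix. After blank subtraction,
#' entries are signed net fluxes: positive means net production
#' (secretion into the medium), negative means net consumption (uptake).
#'
#' @param values Numeric matrix, metabolites x biological samples.
#' @param samples Per-sample metadata (one row per column; technical
#'   replicate and compartment structure collapsed).
#' @param blank_subtracted Logical: has the medium blank been subtracted?
#' @param scaled_by Positive scalar by which values were divided to match
#'   a reference dataset's mean (1 if unscaled).
#' @return An object of class `grav_rma`.
#' @export
rma_table <- function(values, samples, blank_subtracted = FALSE,
                      scaled_by = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != nrow(samples))
    stop("column count does not match sample metadata", call. = FALSE)
  if (!is.finite(scaled_by) || scaled_by <= 0)
    stop("scaled_by must be positive", call. = FALSE)
  colnames(values) <- samples$biological_sample_id
  structure(list(values = values,
                 samples = samples,
                 blank_subtracted = isTRUE(blank_subtracted),
                 scaled_by = scaled_by),
            class = "grav_rma")
}

#' @export
print.grav_rma <- function(x, ...) {
  cat(sprintf("RMA table: %d metabolites x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$blank_subtracted) "blank-subtracted net fluxes"
              else "raw scale"))
  if (x$scaled_by != 1)
    cat(sprintf("  scaled by %.6g to match reference\n", x$scaled_by))
  invisible(x)
}

assert_net <- function(table, what) {
  if (!inherits(table, "grav_rma") || !table$blank_subtracted)
    stop(what, " requires a blank-subtracted RMA table", call. = FALSE)
  invisible(table)
}
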