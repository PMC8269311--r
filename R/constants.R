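#' Pipeline constants
#'
#' All numeric thresholds used by the pipeline, collected in one place so
#' they can be overridden consistently. The defaults are the values used
#' throughout the analysis:
#'
#' * `lod`: raw signal (RMA units) regarded as close to the limit of
#'   detection; signals below it are treated as censorable.
#' * `impute_fraction`: fraction of the lowest signal observed in a whole
#'   dataset substituted for a missing technical replicate whose partner
#'   sits below `lod`, and for all-missing blanks.
#' * `fdr_upper`, `fdr_lower`: the two false-discovery-rate tiers of the
#'   significance banding ("++" below `fdr_upper`, "+" up to `fdr_lower`).
#' * `fc_increase`: fold change above which an effect counts as a strong
#'   increase (double or more).
#' * `fc_weak_lo`, `fc_weak_hi`: fold-change window of strongly diminished
#'   or weakly inverted effects (half or less, inverted if below 0).
#' * `fc_invert`: fold change below which an inversion keeps equal or
#'   larger effect strength (strong inversion).
#'
#' @param lod Limit-of-detection signal, RMA units.
#' @param impute_fraction Fraction of the dataset minimum used for
#'   below-LOD imputation.
#' @param fdr_upper Upper significance band threshold (FDR).
#' @param fdr_lower Lower significance band threshold (FDR).
#' @param fc_increase Strong-increase fold-change boundary.
#' @param fc_weak_lo,fc_weak_hi Weak/decreased effect fold-change window.
#' @param fc_invert Strong-inversion fold-change boundary.
#'
#' @return A named list of class `grav_constants`.
#' @examples
#' grav_constants()
#' grav_constants(fdr_upper = 0.2)
#' @export
grav_constants <- function(lod = 50,
                           impute_fraction = 1 / 5,
                           fdr_upper = 0.35,
                           fdr_lower = 0.50,
                           fc_increase = 2.0,
                           fc_weak_lo = -0.5,
                           fc_weak_hi = 0.5,
                           fc_invert = -1.0) {
  stopifnot(lod > 0, impute_fraction > 0,
            fdr_upper > 0, fdr_upper < fdr_lower, fdr_lower <= 1,
            fc_weak_lo < fc_weak_hi)
  structure(list(lod = lod,
                 impute_fraction = impute_fraction,
                 fdr_upper = fdr_upper,
                 fdr_lower = fdr_lower,
                 fc_increase = fc_increase,
                 fc_weak_lo = fc_weak_lo,
                 fc_weak_hi = fc_weak_hi,
                 fc_invert = fc_invert),
            class = "grav_constants")
}

#' @export
print.grav_constants <- function(x, ...) {
  cat("gravmet constants:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Default exclusion list of problematic metabolites
#'
#' Metabolites removed at the end of preprocessing because they carry no
#' interpretable biological signal in this assay: a fixative component
#' (Sucrose, long-term platform only, where the fixation fluid contains
#' sucrose), the retention-time reference alkane Nonadecane, two
#' ubiquitous metabolites whose changes are uninterpretable, and four
#' compounds without documented natural occurrence in humans.
#'
#' @return A data.frame with columns `name`, `reason`, `platform`
#'   (`"all"` or a specific platform).
#' @examples
#' default_exclusions()
#' @export
default_exclusions <- function() {
  data.frame(
    name = c("Sucrose", "Nonadecane", "Lactic acid", "Phosphoric acid",
             "Benzoic acid", "Diisopropylamine", "Edetic acid", "Oxamide"),
    reason = c("fixative_component", "reference_mixture",
               "uninterpretable_ubiquitous", "uninterpretable_ubiquitous",
               "not_in_human_dbs", "not_in_human_dbs",
               "not_in_human_dbs", "not_in_human_dbs"),
    platform = c("CELLBOX", rep("all", 7L)),
    stringsAsFactors = FALSE
  )
}
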