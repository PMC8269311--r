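#' Shared metabolites of two panels
#'
#' @param panel1,panel2 Metabolite id vectors.
#' @return Sorted intersection.
#' @export
shared_metabolites <- function(panel1, panel2) {
  sort(intersect(panel1, panel2))
}

#' Classify a metabolite into the cross-platform fold-change quadrants
#'
#' The two platforms' fold changes span a plane: the vertical axis is
#' the short-term contrast, the horizontal the long-term contrast. Each
#' axis is read as effect strength `s = |fc|` with a separate inversion
#' flag for `fc < 0` (inverted metabolites are an exception to the plain
#' quadrant reading since their direction of change flipped). Metabolites
#' with both effect strengths inside the center band did not react
#' strongly on either platform; otherwise "upper" means a short-term
#' strength increase (`s > 1`) and "right" a long-term increase.
#'
#' @param fc_short,fc_long Signed fold changes (short-term vertical,
#'   long-term horizontal).
#' @param center_lo,center_hi Effect-strength band of the center region.
#' @return A data.frame with `quadrant`, `inverted_short`,
#'   `inverted_long`.
#' @export
classify_quadrant <- function(fc_short, fc_long,
                              center_lo = 0.5, center_hi = 2.0) {
  stopifnot(center_lo < 1, center_hi > 1)
  s_short <- abs(fc_short)
  s_long <- abs(fc_long)
  quadrant <- ifelse(
    is.na(fc_short) | is.na(fc_long), NA_character_,
    ifelse(s_short >= center_lo & s_short <= center_hi &
             s_long >= center_lo & s_long <= center_hi, "center",
           paste0(ifelse(s_short > 1, "upper", "lower"),
                  ifelse(s_long > 1, "_right", "_left"))))
  data.frame(quadrant = quadrant,
             inverted_short = !is.na(fc_short) & fc_short < 0,
             inverted_long = !is.na(fc_long) & fc_long < 0,
             stringsAsFactors = FALSE)
}

#' Concordance of the direction of change across platforms
#'
#' `TRUE` when both platforms moved the metabolite the same way (both
#' more generation / less consumption, or both less generation /
#' stronger consumption); a zero direction on either platform is
#' non-concordant.
#'
#' @param dir_short,dir_long Directions of change (`-1`, `0`, `+1`).
#' @return Logical vector.
#' @export
concordance <- function(dir_short, dir_long) {
  !is.na(dir_short) & !is.na(dir_long) &
    dir_short == dir_long & dir_short != 0L
}

#' Cross-platform fold-change projection of shared metabolites
#'
#' Joins the differential records of the short-term microgravity
#' contrast and the long-term flight contrast on their shared
#' metabolites and classifies each metabolite by quadrant, inversion
#' flags, concordance of direction, significance bands (optionally also
#' the hypergravity contrast) and conserved-cluster membership.
#'
#' @param records_short Differential records, short-term microgravity
#'   contrast.
#' @param records_long Differential records, long-term flight contrast.
#' @param records_hypg Optional records of the hypergravity contrast.
#' @param clusters Optional `grav_clusters` with conserved clusters.
#' @param center_lo,center_hi Center band of [classify_quadrant()].
#' @return A data.frame of cross-platform records, one row per shared
#'   metabolite.
#' @export
cross_platform_map <- function(records_short, records_long,
                               records_hypg = NULL, clusters = NULL,
                               center_lo = 0.5, center_hi = 2.0) {
  shared <- shared_metabolites(records_short$metabolite_id,
                               records_long$metabolite_id)
  s <- records_short[match(shared, records_short$metabolite_id), ]
  l <- records_long[match(shared, records_long$metabolite_id), ]
  q <- classify_quadrant(s$fc, l$fc, center_lo, center_hi)
  band_hypg <- if (is.null(records_hypg)) NA_character_
  else records_hypg$band[match(shared, records_hypg$metabolite_id)]
  cluster_id <- rep(NA_character_, length(shared))
  if (!is.null(clusters) && length(clusters$clusters)) {
    for (k in seq_along(clusters$clusters)) {
      hit <- shared %in% clusters$clusters[[k]]
      cluster_id[hit] <- clusters$stats$cluster_id[k]
    }
  }
  out <- data.frame(metabolite_id = shared,
                    fc_short = s$fc,
                    fc_long = l$fc,
                    quadrant = q$quadrant,
                    inverted_short = q$inverted_short,
                    inverted_long = q$inverted_long,
                    concordant = concordance(s$direction, l$direction),
                    band_short = s$band,
                    band_long = l$band,
                    band_hypg = band_hypg,
                    cluster_id = cluster_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

band_mark <- function(band) {
  ifelse(is.na(band), "", c(pp = "++", p = "+", ns = "")[band])
}

#' Significance-band summary table across the three contrasts
#'
#' Reproduces the layout of a per-cluster significance overview: rows
#' are metabolites grouped by conserved cluster (ungrouped metabolites
#' last), columns carry the band marks ("++", "+", blank) of the
#' hypergravity, short-term microgravity and long-term contrasts.
#'
#' @param crossmap Output of [cross_platform_map()].
#' @param include Which metabolites to include: `"significant"` keeps
#'   metabolites in a cluster or significant in at least one contrast,
#'   `"all"` keeps every shared metabolite.
#' @return A data.frame with `cluster_id`, `metabolite_id`, `hypg`,
#'   `ug`, `longterm` mark columns.
#' @export
band_summary <- function(crossmap, include = c("significant", "all")) {
  include <- match.arg(include)
  marks <- data.frame(cluster_id = ifelse(is.na(crossmap$cluster_id), "",
                                          crossmap$cluster_id),
                      metabolite_id = crossmap$metabolite_id,
                      hypg = band_mark(crossmap$band_hypg),
                      ug = band_mark(crossmap$band_short),
                      longterm = band_mark(crossmap$band_long),
                      stringsAsFactors = FALSE)
  if (include == "significant") {
    keep <- marks$cluster_id != "" | marks$hypg != "" | marks$ug != "" |
      marks$longterm != ""
    marks <- marks[keep, , drop = FALSE]
  }
  marks <- marks[order(marks$cluster_id == "", marks$cluster_id,
                       marks$metabolite_id), , drop = FALSE]
  rownames(marks) <- NULL
  marks
}
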