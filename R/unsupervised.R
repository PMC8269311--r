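#' Principal component analysis of an RMA table
#'
#' PCA on centered, unscaled data with samples as observations and
#' metabolites as features. Component signs are fixed so the
#' largest-magnitude loading of each component is positive, making the
#' decomposition deterministic.
#'
#' @param table An [rma_table()] without missing values.
#' @param n_components Number of components to keep (default: all).
#' @return A list of class `grav_pca` with `scores` (sample x component),
#'   `loadings` (metabolite x component) and
#'   `explained_variance_fraction`.
#' @export
run_pca <- function(table, n_components = NULL) {
  x <- t(table$values)
  if (nrow(x) < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  if (anyNA(x)) stop("PCA requires a complete table", call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  evf <- if (total > 0) pc$sdev^2 / total else rep(0, length(pc$sdev))
  flip <- apply(pc$rotation, 2L, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  k <- if (is.null(n_components)) ncol(scores)
  else min(n_components, ncol(scores))
  structure(list(scores = scores[, seq_len(k), drop = FALSE],
                 loadings = loadings[, seq_len(k), drop = FALSE],
                 explained_variance_fraction = evf[seq_len(k)]),
            class = "grav_pca")
}

#' @export
print.grav_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("  explained variance fraction:",
      paste(sprintf("%.3f", x$explained_variance_fraction[
        seq_len(min(5L, length(x$explained_variance_fraction)))]),
        collapse = " "), "\n")
  invisible(x)
}

#' Heatmap matrix with clustering orders
#'
#' Standard-scales each metabolite (z-score across samples) and rescales
#' the standardized matrix into `[-1, 1]` by dividing by the global
#' maximum absolute standardized value. Row and column orders come from
#' complete-linkage hierarchical clustering of Euclidean distances.
#' Zero-variance metabolites map to an all-zero row (with a warning).
#'
#' @param table An [rma_table()] without missing values.
#' @return A list of class `grav_heatmap` with `values` in `[-1, 1]`,
#'   `row_order` and `col_order` permutations.
#' @export
heatmap_matrix <- function(table) {
  v <- table$values
  if (anyNA(v)) stop("heatmap requires a complete table", call. = FALSE)
  sds <- apply(v, 1L, sd)
  if (any(sds == 0))
    warning("zero-variance metabolite row(s) set to 0: ",
            paste(rownames(v)[sds == 0], collapse = ", "))
  z <- (v - rowMeans(v)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  mx <- max(abs(z))
  if (mx > 0) z <- z / mx
  row_order <- if (nrow(z) > 2L)
    hclust(dist(z), method = "complete")$order else seq_len(nrow(z))
  col_order <- if (ncol(z) > 2L)
    hclust(dist(t(z)), method = "complete")$order else seq_len(ncol(z))
  structure(list(values = z, row_order = row_order, col_order = col_order),
            class = "grav_heatmap")
}

#' Merge ground-control samples into their mean
#'
#' Replaces the listed ground samples by a single arithmetic-mean column,
#' used to visualise the average ground condition against the flight
#' samples.
#'
#' @param table An [rma_table()].
#' @param sample_ids Ground sample ids to merge.
#' @param merged_id Id of the merged column.
#' @return An [rma_table()] with the merged column in place of the first
#'   listed sample.
#' @export
merge_ground <- function(table, sample_ids, merged_id = "ground_mean") {
  idx <- match(sample_ids, table$samples$biological_sample_id)
  if (anyNA(idx)) stop("unknown sample id(s)", call. = FALSE)
  if (!all(table$samples$group[idx] == "ground"))
    stop("all merged samples must be ground controls", call. = FALSE)
  if (length(idx) == 1L) {
    out <- table
    out$samples$biological_sample_id[idx] <- merged_id
    colnames(out$values)[idx] <- merged_id
    return(out)
  }
  mean_col <- rowMeans(table$values[, idx, drop = FALSE])
  keep <- setdiff(seq_len(ncol(table$values)), idx[-1L])
  v <- table$values[, keep, drop = FALSE]
  s <- table$samples[keep, , drop = FALSE]
  pos <- match(idx[1L], keep)
  v[, pos] <- mean_col
  s$biological_sample_id[pos] <- merged_id
  s$measurement_id <- s$biological_sample_id
  rownames(s) <- NULL
  rma_table(v, s, blank_subtracted = table$blank_subtracted,
            scaled_by = table$scaled_by)
}

#' Flag leakage-outlier samples
#'
#' A leaking sample chamber concentrates the supernatant and inflates
#' the signal of nearly every metabolite. Each sample is scored by the
#' fraction of metabolites for which it holds the maximum value across
#' samples (ties are split equally among the tied samples); samples at
#' or above the threshold are flagged. Flagging never removes a sample:
#' removal is a separate, explicitly confirmed step ([drop_samples()]).
#'
#' @param table An [rma_table()] with at least 3 samples.
#' @param threshold Score at or above which a sample is flagged.
#' @return A data.frame with `sample_id`, `score`, `flagged`, sorted by
#'   decreasing score.
#' @export
flag_outlier_samples <- function(table, threshold = 0.8) {
  v <- table$values
  if (ncol(v) < 3L)
    stop("outlier flagging requires at least 3 samples", call. = FALSE)
  score <- numeric(ncol(v))
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    if (anyNA(x)) next
    mx <- max(x)
    at <- which(x == mx)
    score[at] <- score[at] + 1 / length(at)
  }
  score <- score / nrow(v)
  out <- data.frame(sample_id = table$samples$biological_sample_id,
                    score = score, flagged = score >= threshold,
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}
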