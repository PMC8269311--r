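#' Inter-metabolite Pearson correlation matrix
#'
#' Pairwise Pearson correlation of metabolite net-flux profiles over all
#' samples of a dataset, ignoring group labels: metabolites coupled by
#' shared biochemistry co-vary across samples regardless of condition.
#' Zero-variance metabolites get correlation 0 (with a warning) so the
#' matrix and its clustering stay total. Rows are ordered by
#' average-linkage hierarchical clustering of the correlation rows under
#' Euclidean distance.
#'
#' @param table A blank-subtracted [rma_table()] with >= 3 samples.
#' @return A list of class `grav_corr` with the symmetric matrix `r`,
#'   the clustering `order` and the `hclust` tree `hc`.
#' @export
correlation_matrix <- function(table) {
  assert_net(table, "correlation analysis")
  v <- table$values
  if (ncol(v) < 3L)
    stop("correlation requires at least 3 samples", call. = FALSE)
  if (anyNA(v)) stop("correlation requires a complete table", call. = FALSE)
  sds <- apply(v, 1L, sd)
  if (any(sds == 0))
    warning("zero-variance metabolite(s), correlations set to 0: ",
            paste(rownames(v)[sds == 0], collapse = ", "))
  r <- suppressWarnings(cor(t(v)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  hc <- if (nrow(r) > 2L) hclust(dist(r), method = "average") else NULL
  order <- if (is.null(hc)) seq_len(nrow(r)) else hc$order
  structure(list(r = r, order = order, hc = hc), class = "grav_corr")
}

#' @export
print.grav_corr <- function(x, ...) {
  cat(sprintf("correlation matrix: %d metabolites\n", nrow(x$r)))
  invisible(x)
}

#' Restrict a correlation matrix to a shared metabolite panel
#'
#' For cross-dataset comparison the matrices of both platforms are
#' reduced to the metabolites present in both. The first dataset's
#' restricted matrix is re-clustered and carries the ordering; the
#' second is re-indexed to that identical order (pass the first matrix's
#' id order via `order`).
#'
#' @param cm A `grav_corr`.
#' @param shared_ids Metabolite ids present in both panels.
#' @param order Optional character vector of ids fixing the output
#'   order; by default the restricted matrix is re-clustered.
#' @return A `grav_corr` over `shared_ids`.
#' @export
shared_panel_matrix <- function(cm, shared_ids, order = NULL) {
  if (!all(shared_ids %in% rownames(cm$r)))
    stop("shared ids missing from the correlation matrix", call. = FALSE)
  r <- cm$r[shared_ids, shared_ids, drop = FALSE]
  if (!is.null(order)) {
    if (!setequal(order, shared_ids))
      stop("order must be a permutation of shared_ids", call. = FALSE)
    r <- r[order, order, drop = FALSE]
    return(structure(list(r = r, order = seq_len(nrow(r)), hc = NULL),
                     class = "grav_corr"))
  }
  hc <- if (nrow(r) > 2L) hclust(dist(r), method = "average") else NULL
  ord <- if (is.null(hc)) seq_len(nrow(r)) else hc$order
  structure(list(r = r, order = ord, hc = hc), class = "grav_corr")
}

# all member sets of the internal nodes of an hclust tree
subtree_members <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    left <- hc$merge[k, 1L]
    right <- hc$merge[k, 2L]
    get <- function(idx) if (idx < 0) -idx else sets[[idx]]
    sets[[k]] <- c(get(left), get(right))
  }
  lapply(sets, function(i) hc$labels[i])
}

mean_abs_offdiag <- function(r, members) {
  sub <- abs(r[members, members, drop = FALSE])
  mean(sub[upper.tri(sub)])
}

#' Find metabolite clusters conserved across two datasets
#'
#' Candidate groups are taken from every cut height of the first
#' dataset's dendrogram (all subtrees). A group is accepted when its
#' mean pairwise absolute correlation reaches the threshold in BOTH
#' datasets (absolute, because strong anticorrelation is as much
#' evidence of coupling as strong correlation) and it has at least
#' `min_size` members. Only maximal accepted groups are returned, so no
#' reported cluster is contained in another.
#'
#' @param cm1,cm2 `grav_corr` objects over the same metabolite panel;
#'   `cm1` must carry a dendrogram (`hc`).
#' @param threshold Mean absolute correlation required in both datasets.
#' @param min_size Minimum cluster size.
#' @return A list of class `grav_clusters`: `clusters` (list of member
#'   id vectors), `stats` (data.frame with sizes and mean |r| in each
#'   dataset), `threshold`.
#' @export
find_conserved_clusters <- function(cm1, cm2, threshold = 0.8,
                                    min_size = 2L) {
  if (!setequal(rownames(cm1$r), rownames(cm2$r)))
    stop("correlation matrices must share the metabolite panel",
         call. = FALSE)
  empty <- structure(list(clusters = list(),
                          stats = data.frame(cluster_id = character(),
                                             size = integer(),
                                             mean_abs_r_1 = numeric(),
                                             mean_abs_r_2 = numeric(),
                                             members = character(),
                                             stringsAsFactors = FALSE),
                          threshold = threshold),
                     class = "grav_clusters")
  if (is.null(cm1$hc)) return(empty)
  candidates <- subtree_members(cm1$hc)
  accepted <- list()
  for (members in candidates) {
    if (length(members) < min_size) next
    m1 <- mean_abs_offdiag(cm1$r, members)
    m2 <- mean_abs_offdiag(cm2$r, members)
    if (m1 >= threshold && m2 >= threshold)
      accepted[[length(accepted) + 1L]] <-
        list(members = members, m1 = m1, m2 = m2)
  }
  if (!length(accepted)) return(empty)
  # maximal accepted groups: drop any contained in another
  keep <- rep(TRUE, length(accepted))
  for (i in seq_along(accepted)) {
    for (j in seq_along(accepted)) {
      if (i != j && keep[j] &&
          all(accepted[[i]]$members %in% accepted[[j]]$members) &&
          length(accepted[[i]]$members) < length(accepted[[j]]$members)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  accepted <- accepted[keep]
  stats <- data.frame(
    cluster_id = sprintf("cluster_%02d", seq_along(accepted)),
    size = vapply(accepted, function(a) length(a$members), 0L),
    mean_abs_r_1 = vapply(accepted, `[[`, 0, "m1"),
    mean_abs_r_2 = vapply(accepted, `[[`, 0, "m2"),
    members = vapply(accepted, function(a)
      paste(sort(a$members), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  structure(list(clusters = lapply(accepted, `[[`, "members"),
                 stats = stats, threshold = threshold),
            class = "grav_clusters")
}

#' @export
print.grav_clusters <- function(x, ...) {
  cat(sprintf("%d conserved cluster(s) at threshold %.2f\n",
              length(x$clusters), x$threshold))
  if (nrow(x$stats))
    print(x$stats[, c("cluster_id", "size", "mean_abs_r_1",
                      "mean_abs_r_2")], row.names = FALSE)
  invisible(x)
}
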