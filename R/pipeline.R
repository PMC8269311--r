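#' Pipeline run configuration
#'
#' Collects every knob of a full pipeline run. With `simulate = TRUE`
#' (default) the raw tables come from the synthetic generator; otherwise
#' `texus_table`/`texus_meta`/`cellbox_table`/`cellbox_meta` must point
#' to abundance tables and metadata sidecars on disk.
#'
#' @param seed Integer seed for the whole run (one RNG stream).
#' @param out_dir Run directory (created if absent).
#' @param simulate Generate synthetic inputs?
#' @param texus_table,texus_meta,cellbox_table,cellbox_meta Input file
#'   paths when `simulate = FALSE`.
#' @param constants [grav_constants()].
#' @param exclusions Problematic-metabolite list.
#' @param confirm_outliers Sample ids confirmed for removal after
#'   flagging, or `"auto"` to remove every flagged sample. Flagged but
#'   unconfirmed samples are reported and kept.
#' @param outlier_threshold Score threshold of [flag_outlier_samples()].
#' @param cluster_threshold,cluster_min_size Conserved-cluster mining
#'   parameters.
#' @param center_lo,center_hi Quadrant center band.
#' @param generator Arguments passed to [default_truth()] when
#'   simulating.
#' @return A list of class `grav_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("gravmet_run_"),
                            simulate = TRUE,
                            texus_table = NULL, texus_meta = NULL,
                            cellbox_table = NULL, cellbox_meta = NULL,
                            constants = grav_constants(),
                            exclusions = default_exclusions(),
                            confirm_outliers = "auto",
                            outlier_threshold = 0.8,
                            cluster_threshold = 0.8,
                            cluster_min_size = 2L,
                            center_lo = 0.5, center_hi = 2.0,
                            generator = list()) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = isTRUE(simulate),
                 texus_table = texus_table, texus_meta = texus_meta,
                 cellbox_table = cellbox_table, cellbox_meta = cellbox_meta,
                 constants = constants, exclusions = exclusions,
                 confirm_outliers = confirm_outliers,
                 outlier_threshold = outlier_threshold,
                 cluster_threshold = cluster_threshold,
                 cluster_min_size = as.integer(cluster_min_size),
                 center_lo = center_lo, center_hi = center_hi,
                 generator = generator),
            class = "grav_config")
}

#' Run the full two-platform analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> QC/outlier handling ->
#' differential -> correlation clusters -> cross-platform projection,
#' writing every intermediate as TSV into the run directory together
#' with a config snapshot, a line-oriented log and a machine-readable
#' summary. A fixed seed yields byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "grav_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(stage, fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  path <- function(...) file.path(config$out_dir, ...)

  snapshot <- config
  snapshot$constants <- unclass(config$constants)
  jsonlite::write_json(unclass(snapshot), path("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  ## stage: simulate / load ------------------------------------------------
  truth <- NULL
  if (config$simulate) {
    pair <- do.call(generate_pair,
                    c(list(seed = config$seed), config$generator))
    raw_tx <- pair$texus
    raw_cb <- pair$cellbox
    truth <- pair$truth
    write_abundance_table(raw_tx, path("texus_raw.tsv"),
                          path("texus_meta.tsv"),
                          path("texus_metabolites.tsv"))
    write_abundance_table(raw_cb, path("cellbox_raw.tsv"),
                          path("cellbox_meta.tsv"),
                          path("cellbox_metabolites.tsv"))
    jsonlite::write_json(truth_to_list(truth), path("truth.json"),
                         auto_unbox = TRUE, digits = NA)
    say("simulate", "generated synthetic pair (seed %d)", config$seed)
  } else {
    paths <- c(config$texus_table, config$texus_meta,
               config$cellbox_table, config$cellbox_meta)
    if (length(paths) < 4L || !all(file.exists(paths)))
      stop("preprocess: input tables missing and simulation disabled",
           call. = FALSE)
    raw_tx <- read_abundance_table(config$texus_table, config$texus_meta)
    raw_cb <- read_abundance_table(config$cellbox_table, config$cellbox_meta)
    say("simulate", "skipped; inputs loaded from disk")
  }

  ## stage: preprocess -----------------------------------------------------
  pre_tx <- preprocess_platform(raw_tx, config$constants, config$exclusions)
  pre_cb <- preprocess_platform(raw_cb, config$constants, config$exclusions,
                                reference = pre_tx$rma_unscaled_means)
  for (p in list(list("texus", pre_tx), list("cellbox", pre_cb))) {
    nm <- p[[1L]]; pre <- p[[2L]]
    write_results(data.frame(metabolite_id = rownames(pre$rma$values),
                             pre$rma$values, check.names = FALSE,
                             row.names = NULL),
                  path(sprintf("%s_rma.tsv", nm)))
    rep <- pre$report
    say("preprocess",
        "%s: %d unannotated removed, %d missingness-filtered, %d imputed, %d problematic removed, scale %.6g, %d metabolites",
        nm, rep$removed_unannotated, nrow(rep$filtered_missingness),
        rep$imputed_mean, nrow(rep$removed_problematic),
        rep$scale_factor, rep$n_metabolites_final)
    if (nrow(rep$filtered_missingness))
      for (i in seq_len(nrow(rep$filtered_missingness)))
        say("preprocess", "%s: removed %s (missingness rule %s)", nm,
            rep$filtered_missingness$metabolite_id[i],
            rep$filtered_missingness$rule[i])
    if (nrow(rep$removed_problematic))
      for (i in seq_len(nrow(rep$removed_problematic)))
        say("preprocess", "%s: removed %s (%s)", nm,
            rep$removed_problematic$metabolite_id[i],
            rep$removed_problematic$reason[i])
  }

  ## stage: qc -------------------------------------------------------------
  qc <- list()
  rmas <- list(texus = pre_tx$rma, cellbox = pre_cb$rma)
  for (nm in names(rmas)) {
    flags <- flag_outlier_samples(rmas[[nm]], config$outlier_threshold)
    write_results(flags, path(sprintf("%s_outlier_scores.tsv", nm)))
    flagged <- flags$sample_id[flags$flagged]
    confirmed <- if (identical(config$confirm_outliers, "auto")) flagged
    else intersect(flagged, config$confirm_outliers)
    for (s in flagged)
      say("qc", "%s: sample %s flagged as outlier (score %.3f)%s", nm, s,
          flags$score[flags$sample_id == s],
          if (s %in% confirmed) ", removed" else ", kept (unconfirmed)")
    if (length(confirmed))
      rmas[[nm]] <- drop_samples(rmas[[nm]], confirmed)
    pca <- run_pca(rmas[[nm]])
    write_results(data.frame(sample_id = rownames(pca$scores),
                             pca$scores, check.names = FALSE,
                             row.names = NULL),
                  path(sprintf("%s_pca_scores.tsv", nm)))
    hm <- heatmap_matrix(rmas[[nm]])
    write_results(data.frame(metabolite_id = rownames(hm$values),
                             hm$values, check.names = FALSE,
                             row.names = NULL),
                  path(sprintf("%s_heatmap.tsv", nm)))
    qc[[nm]] <- list(flags = flags, removed = confirmed, pca = pca,
                     heatmap = hm)
    say("qc", "%s: PC1 explains %.1f%% of variance", nm,
        100 * pca$explained_variance_fraction[1L])
  }

  ## stage: differential ---------------------------------------------------
  rec_hypg <- differential_single_sample(pre_tx, rmas$texus, "hypg",
                                         config$constants)
  rec_ug <- differential_single_sample(pre_tx, rmas$texus, "ug",
                                       config$constants)
  rec_cb <- differential_two_sample(rmas$cellbox, config$constants)
  write_results(rec_hypg, path("texus_hypg_records.tsv"))
  write_results(rec_ug, path("texus_ug_records.tsv"))
  write_results(rec_cb, path("cellbox_records.tsv"))
  write_results(bar_export(rmas$texus, rec_ug, config$constants$fdr_lower),
                path("texus_ug_bars.tsv"))
  write_results(bar_export(rmas$cellbox, rec_cb, config$constants$fdr_lower),
                path("cellbox_bars.tsv"))
  for (r in list(list("hypg", rec_hypg), list("ug", rec_ug),
                 list("longterm", rec_cb)))
    say("differential", "%s: %d of %d metabolites in band ++, %d in +",
        r[[1L]], sum(r[[2L]]$band == "pp"), nrow(r[[2L]]),
        sum(r[[2L]]$band == "p"))

  ## stage: clusters -------------------------------------------------------
  shared <- shared_metabolites(rownames(rmas$texus$values),
                               rownames(rmas$cellbox$values))
  cm_tx <- correlation_matrix(rmas$texus)
  cm_cb <- correlation_matrix(rmas$cellbox)
  cm1 <- shared_panel_matrix(cm_tx, shared)
  ord <- rownames(cm1$r)[cm1$order]
  cm2 <- shared_panel_matrix(cm_cb, shared, order = rownames(cm1$r))
  clusters <- find_conserved_clusters(cm1, cm2, config$cluster_threshold,
                                      config$cluster_min_size)
  write_results(data.frame(metabolite_id = rownames(cm1$r)[cm1$order],
                           cm1$r[cm1$order, cm1$order], check.names = FALSE,
                           row.names = NULL),
                path("texus_shared_correlation.tsv"))
  write_results(data.frame(metabolite_id = ord,
                           cm2$r[ord, ord], check.names = FALSE, row.names = NULL),
                path("cellbox_shared_correlation.tsv"))
  write_results(clusters$stats, path("conserved_clusters.tsv"))
  say("clusters", "%d shared metabolites, %d conserved cluster(s)",
      length(shared), length(clusters$clusters))

  ## stage: crossmap -------------------------------------------------------
  crossmap <- cross_platform_map(rec_ug, rec_cb, rec_hypg, clusters,
                                 config$center_lo, config$center_hi)
  summary_tab <- band_summary(crossmap)
  write_results(crossmap, path("crossmap.tsv"))
  write_results(summary_tab, path("band_summary.tsv"))
  say("crossmap", "%d shared metabolites projected; %d concordant",
      nrow(crossmap), sum(crossmap$concordant))

  writeLines(log_lines, path("run.log"))
  jsonlite::write_json(
    list(seed = config$seed,
         n_metabolites = list(texus = nrow(rmas$texus$values),
                              cellbox = nrow(rmas$cellbox$values),
                              shared = length(shared)),
         outliers_removed = unlist(lapply(qc, `[[`, "removed")),
         n_conserved_clusters = length(clusters$clusters)),
    path("summary.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = config$out_dir, truth = truth,
                 preprocess = list(texus = pre_tx, cellbox = pre_cb),
                 rma = rmas, qc = qc,
                 records = list(hypg = rec_hypg, ug = rec_ug,
                                longterm = rec_cb),
                 correlation = list(texus = cm1, cellbox = cm2),
                 clusters = clusters, crossmap = crossmap,
                 band_summary = summary_tab, log = log_lines))
}

truth_to_list <- function(truth) {
  x <- unclass(truth)
  x$blank_mean <- as.list(x$blank_mean)
  x$base_net <- as.list(x$base_net)
  x$effects <- lapply(x$effects, as.list)
  x
}
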