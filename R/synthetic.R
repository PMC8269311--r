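#' Construct a synthetic ground truth
#'
#' Describes the latent world from which [generate_platform()] draws raw
#' abundance tables: per-metabolite medium blank levels, ground-truth net
#' production (positive) or consumption (negative), multiplicative
#' gravity effects per condition (negative values flip the sign of the
#' net flux, i.e. production becomes consumption or vice versa),
#' correlated metabolite blocks, a leakage outlier sample, measurement
#' noise and detection-limit censoring.
#'
#' @param metabolite_id Ids of all metabolites in the world.
#' @param blank_mean Named or positional vector of medium blank signals.
#' @param base_net Signed ground-truth net flux per metabolite.
#' @param panels Named list with character vectors `TEXUS54` and
#'   `CELLBOX`: which metabolites each platform detects.
#' @param effects Named list `metabolite -> c(hypg=, ug=, longterm=)`
#'   multiplicative effects on the net flux (unlisted conditions and
#'   metabolites have effect 1).
#' @param cluster_blocks List of `list(members=, rho=)`: disjoint
#'   metabolite sets given a shared per-sample lognormal latent factor
#'   calibrated so the pairwise Pearson correlation of raw signals within
#'   the block equals `rho`.
#' @param outlier_sample_ids Biological sample ids whose raw values are
#'   globally inflated (leakage emulation).
#' @param outlier_inflation Inflation factor, must exceed 1.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   measurement noise.
#' @param missing_below_lod_prob Probability that a realised signal below
#'   `lod` is reported missing (MNAR censoring).
#' @param lod Limit-of-detection threshold (RMA units).
#' @param n_unannotated Named integer vector: number of extra unknown
#'   (unannotated) compounds appended per platform.
#' @param seed Seed recorded for provenance (the generator itself draws
#'   from the current RNG stream).
#' @return An object of class `grav_truth`.
#' @export
synthetic_truth <- function(metabolite_id, blank_mean, base_net,
                            panels = list(TEXUS54 = metabolite_id,
                                          CELLBOX = metabolite_id),
                            effects = list(),
                            cluster_blocks = list(),
                            outlier_sample_ids = character(),
                            outlier_inflation = 3,
                            noise_cv = 0.1,
                            missing_below_lod_prob = 0.5,
                            lod = 50,
                            n_unannotated = c(TEXUS54 = 0L, CELLBOX = 0L),
                            seed = NA_integer_) {
  metabolite_id <- as.character(metabolite_id)
  blank_mean <- setNames(as.numeric(blank_mean), metabolite_id)
  base_net <- setNames(as.numeric(base_net), metabolite_id)
  stopifnot(all(blank_mean >= 0), all(is.finite(base_net)))
  if (!all(unlist(panels) %in% metabolite_id))
    stop("panels reference unknown metabolites", call. = FALSE)
  if (!all(names(effects) %in% metabolite_id))
    stop("effect map references unknown metabolites", call. = FALSE)
  members <- unlist(lapply(cluster_blocks, `[[`, "members"))
  if (anyDuplicated(members))
    stop("cluster blocks must be disjoint", call. = FALSE)
  if (!all(members %in% metabolite_id))
    stop("cluster blocks reference unknown metabolites", call. = FALSE)
  if (length(outlier_sample_ids) && outlier_inflation <= 1)
    stop("outlier inflation factor must exceed 1", call. = FALSE)
  if (missing_below_lod_prob < 0 || missing_below_lod_prob > 1)
    stop("missing_below_lod_prob must lie in [0, 1]", call. = FALSE)
  structure(list(metabolite_id = metabolite_id,
                 blank_mean = blank_mean,
                 base_net = base_net,
                 panels = panels,
                 effects = effects,
                 cluster_blocks = cluster_blocks,
                 outlier_sample_ids = as.character(outlier_sample_ids),
                 outlier_inflation = outlier_inflation,
                 noise_cv = noise_cv,
                 missing_below_lod_prob = missing_below_lod_prob,
                 lod = lod,
                 n_unannotated = n_unannotated,
                 seed = seed),
            class = "grav_truth")
}

#' @export
print.grav_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic truth: %d metabolites ",
                     "(panels %d/%d, overlap %d)\n"),
              length(x$metabolite_id),
              length(x$panels$TEXUS54), length(x$panels$CELLBOX),
              length(intersect(x$panels$TEXUS54, x$panels$CELLBOX))))
  cat(sprintf("  %d planted effects, %d cluster blocks, %d outlier(s)\n",
              length(x$effects), length(x$cluster_blocks),
              length(x$outlier_sample_ids)))
  cat(sprintf("  noise_cv %.3g, P(missing | < LOD %g) = %.3g\n",
              x$noise_cv, x$lod, x$missing_below_lod_prob))
  invisible(x)
}

# Shared metabolite panel of the default world. `type` controls the scale
# of blank and net draws: "consumed" = medium component taken up by the
# cells (large blank, negative net), "secreted" = cellular product (small
# blank, positive net). Effects are multiplicative on the net flux for
# hypergravity, short-term microgravity and long-term microgravity.
default_shared_panel <- function() {
  e <- function(hypg = 1, ug = 1, longterm = 1) c(hypg = hypg, ug = ug,
                                                  longterm = longterm)
  list(
    list("Ornithine", "special_ornithine", e(-60, -41, 0.2)),
    list("Glyceric acid", "special_glyceric", e(-12, -4, 0.6)),
    list("2-Hydroxypyridine", "special_hydroxypyridine", e(-2, -1.5, 1)),
    list("Ketoleucine", "secreted", e(1, 2.5, 2.5)),
    list("3-Hydroxybutyric acid", "secreted", e(1.5, 1.9, 0.45)),
    list("Threose", "secreted", e(1, 1.5, 0.5)),
    list("L-Valine", "secreted", e(1, 1.6, 0.55)),
    list("L-Phenylalanine", "secreted", e(1, 1.4, 0.6)),
    list("L-Cysteine", "secreted", e(1, 1.3, 0.5)),
    list("L-Methionine", "secreted", e(1.2, 1.15, 0.55)),
    list("L-Proline", "secreted", e(2.6, 2.1, 0.5)),
    list("L-Arginine", "secreted", e(2.8, 2.2, 0.9)),
    list("myo-Inositol", "secreted", e(3.7, 2.3, 0.85)),
    list("L-Alanine", "secreted", e(2.2, 1.8, 1)),
    list("L-Threonine", "secreted", e(2.4, 1.6, 1)),
    list("D-Fructose", "consumed", e(0.3, 0.4, 1)),
    list("Glucose", "consumed", e(0.6, 0.45, 1.4)),
    list("Glycine", "secreted", e(1.8, 2.4, 0.3)),
    list("L-Tyrosine", "secreted", e(2.9, 1.9, 1)),
    list("L-Serine", "secreted", e(2.5, 1.7, 1)),
    list("4-Hydroxyproline", "secreted", e(2.7, 2.0, 1)),
    list("Beta-Alanine", "secreted", e(0.35, 0.4, 1)),
    list("Dihydrouracil", "secreted", e(0.3, 0.45, 1)),
    list("L-Tryptophan", "secreted", e(1, 1, 2.6)),
    list("Cholesterol", "secreted", e(2.6, 1.5, 1)),
    list("Fucose", "secreted", e(1, 1, 1.6)),
    list("L-Aspartic acid", "consumed", NULL),
    list("Glycerol-3-phosphate", "secreted", NULL),
    list("L-Leucine", "consumed", NULL),
    list("Pyroglutamic acid", "secreted", NULL),
    list("Erythronic acid", "secreted", NULL),
    list("3-amino-2-Piperidone", "secreted", NULL)
  )
}

YELLOW_BLOCK <- c("3-Hydroxybutyric acid", "Threose", "L-Valine",
                  "L-Phenylalanine", "L-Cysteine")
PINK_BLOCK <- c("L-Methionine", "L-Proline", "L-Arginine", "myo-Inositol")

draw_scales <- function(type) {
  switch(type,
         consumed = {
           b <- runif(1, 500, 1500)
           c(b, -runif(1, 0.30, 0.55) * b)
         },
         secreted = {
           b <- runif(1, 120, 260)
           c(b, runif(1, 2.5, 5.5) * b)
         },
         trace = {
           b <- runif(1, 25, 45)
           c(b, runif(1, 0.2, 0.8) * b)
         },
         special_ornithine = c(runif(1, 150, 250), -runif(1, 4, 10)),
         special_glyceric = c(runif(1, 900, 1100), runif(1, 40, 65)),
         special_hydroxypyridine = c(runif(1, 150, 220), runif(1, 25, 45)),
         stop("unknown metabolite type ", type, call. = FALSE))
}

# Shrink |net| so that no condition drives the noiseless signal below
# lod + 5; keeps the zero-noise world free of censoring except for trace
# metabolites, which are intentionally near the detection limit.
shrink_to_lod <- function(blank, net, effects, lod) {
  if (blank <= lod + 10) return(net)
  floor_sig <- lod + 5
  effs <- c(1, effects)
  minsig <- min(blank + net * effs)
  if (minsig < floor_sig)
    net <- net * (blank - floor_sig) / (blank - minsig)
  net
}

#' Default synthetic world
#'
#' Builds the package's reference ground truth: panels of 63 (short-term
#' platform) and 61 (long-term platform) annotated metabolites with a
#' 32-metabolite overlap, planted multiplicative gravity effects that
#' include sign inversions of magnitude 60, 41, 12, 4 and 2, two
#' correlated metabolite blocks (5 members at rho = 0.95, 4 members at
#' rho = 0.85), a near-detection-limit trace group on the long-term
#' platform, and one leakage outlier flight sample inflated threefold.
#' Blank levels and net fluxes are drawn from the current RNG stream;
#' call `set.seed()` first (or use [generate_pair()], which does).
#'
#' @param noise_cv Measurement noise coefficient of variation.
#' @param missing_below_lod_prob MNAR censoring probability below LOD.
#' @param outlier_inflation Leakage inflation factor (> 1) or `NULL` /
#'   `1` combined with empty `outlier_sample_ids` to disable.
#' @param outlier_sample_ids Sample ids to inflate.
#' @param with_effects Plant the differential gravity effects?
#' @param with_blocks Plant the correlated blocks?
#' @param n_shared,n_texus,n_cellbox Panel sizes (overlap and totals).
#' @param lod Detection limit (RMA units).
#' @return A `grav_truth`.
#' @export
default_truth <- function(noise_cv = 0.1,
                          missing_below_lod_prob = 0.5,
                          outlier_inflation = 3,
                          outlier_sample_ids = "FM_02",
                          with_effects = TRUE,
                          with_blocks = TRUE,
                          n_shared = 32, n_texus = 63, n_cellbox = 61,
                          lod = 50) {
  if (n_shared > n_texus || n_shared > n_cellbox)
    stop("overlap larger than a platform panel", call. = FALSE)
  shared <- default_shared_panel()
  if (n_shared < length(shared)) shared <- shared[seq_len(n_shared)]
  extra_shared <- max(0L, n_shared - length(shared))
  sh_names <- c(vapply(shared, `[[`, "", 1L),
                sprintf("SynMet_S%02d", seq_len(extra_shared)))
  sh_types <- c(vapply(shared, `[[`, "", 2L),
                rep(c("consumed", "secreted"), length.out = extra_shared))

  tx_fixed <- c("Nonadecane", "Lactic acid", "Benzoic acid",
                "Diisopropylamine")
  cb_fixed <- c("Sucrose", "Phosphoric acid", "Edetic acid", "Oxamide",
                "Rhamnose", "L-alpha-Aminobutyric acid",
                "3-Methyl-2-oxovaleric acid")
  n_tx_extra <- n_texus - n_shared
  n_cb_extra <- n_cellbox - n_shared
  tx_names <- c(tx_fixed[seq_len(min(length(tx_fixed), n_tx_extra))],
                sprintf("SynMet_T%02d",
                        seq_len(max(0L, n_tx_extra - length(tx_fixed)))))
  n_trace <- if (n_cb_extra >= length(cb_fixed) + 6L) 6L else 0L
  cb_names <- c(cb_fixed[seq_len(min(length(cb_fixed), n_cb_extra))],
                sprintf("SynTrace_C%02d", seq_len(n_trace)),
                sprintf("SynMet_C%02d",
                        seq_len(max(0L, n_cb_extra - length(cb_fixed) -
                                      n_trace))))
  tx_types <- rep(c("consumed", "secreted"), length.out = length(tx_names))
  cb_types <- rep(c("consumed", "secreted"), length.out = length(cb_names))
  cb_types[grepl("^SynTrace", cb_names)] <- "trace"
  cb_types[cb_names %in% c("Rhamnose", "L-alpha-Aminobutyric acid",
                           "3-Methyl-2-oxovaleric acid")] <- "secreted"

  ids <- c(sh_names, tx_names, cb_names)
  types <- c(sh_types, tx_types, cb_types)

  effects <- list()
  if (with_effects) {
    for (m in shared) if (!is.null(m[[3L]])) effects[[m[[1L]]]] <- m[[3L]]
    for (nm in intersect(c("Rhamnose", "L-alpha-Aminobutyric acid",
                           "3-Methyl-2-oxovaleric acid"), cb_names)) {
      effects[[nm]] <- c(hypg = 1, ug = 1,
                         longterm = switch(nm, "Rhamnose" = 0.05, 2.2))
    }
  }

  blank <- numeric(length(ids))
  net <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sc <- draw_scales(types[i])
    blank[i] <- sc[1L]
    eff <- effects[[ids[i]]]
    net[i] <- shrink_to_lod(sc[1L], sc[2L],
                            if (is.null(eff)) 1 else eff, lod)
  }

  blocks <- list()
  if (with_blocks && n_shared >= length(default_shared_panel())) {
    blocks <- list(list(members = YELLOW_BLOCK, rho = 0.95),
                   list(members = PINK_BLOCK, rho = 0.85))
  }

  synthetic_truth(ids, blank, net,
                  panels = list(TEXUS54 = c(sh_names, tx_names),
                                CELLBOX = c(sh_names, cb_names)),
                  effects = effects,
                  cluster_blocks = blocks,
                  outlier_sample_ids = outlier_sample_ids,
                  outlier_inflation = outlier_inflation,
                  noise_cv = noise_cv,
                  missing_below_lod_prob = missing_below_lod_prob,
                  lod = lod,
                  n_unannotated = c(TEXUS54 = 4L, CELLBOX = 4L))
}

#' Measurement layout of a platform
#'
#' The short-term design ("TEXUS54") has one flight sample per condition
#' (hypergravity and microgravity) and two ground controls, each a single
#' compartment measured in three technical replicates, plus three blank
#' replicates. The long-term design ("CELLBOX") has five flight samples
#' and three ground controls, each split over two hardware compartments
#' with recovered volumes used for in-silico signal combination; ground
#' compartments carry two technical replicates, flight compartments one,
#' and the medium blank six replicates.
#'
#' @param design `"TEXUS54"` or `"CELLBOX"`.
#' @param n_flight,n_ground Numbers of biological samples (CELLBOX
#'   layout; TEXUS54 always has hypg + ug flight samples).
#' @param ground_tech_reps,flight_tech_reps Technical replicates per
#'   compartment (CELLBOX).
#' @param tech_reps Technical replicates per sample (TEXUS54).
#' @param n_blank Blank replicates.
#' @param compartment_volumes Recovered volumes (mL) of the CELLBOX
#'   compartments.
#' @return A measurement metadata data.frame.
#' @export
platform_layout <- function(design = c("TEXUS54", "CELLBOX"),
                            n_flight = 5L, n_ground = 3L,
                            ground_tech_reps = 2L, flight_tech_reps = 1L,
                            tech_reps = 3L, n_blank = NULL,
                            compartment_volumes = c(6, 3)) {
  design <- match.arg(design)
  rows <- list()
  add <- function(sample, role, group, condition, comp, vol, reps) {
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1L]] <<-
        data.frame(measurement_id = sprintf("%s.%s.r%d", sample, comp, r),
                   platform = design, role = role, group = group,
                   condition = condition, biological_sample_id = sample,
                   compartment_id = comp, recovered_volume = vol,
                   tech_rep_index = r, stringsAsFactors = FALSE)
    }
  }
  if (design == "TEXUS54") {
    if (is.null(n_blank)) n_blank <- 3L
    add("TX_hypg", "sample", "flight", "hypg", "S1", 9, tech_reps)
    add("TX_ug", "sample", "flight", "ug", "S1", 9, tech_reps)
    for (g in seq_len(n_ground))
      add(sprintf("TX_G%d", g), "sample", "ground", "control", "S1", 9,
          tech_reps)
    add("BLANK_TX", "blank", "none", "none", "S1", 9, n_blank)
  } else {
    if (is.null(n_blank)) n_blank <- 6L
    vols <- compartment_volumes
    for (f in seq_len(n_flight)) {
      for (ci in seq_along(vols))
        add(sprintf("FM_%02d", f), "sample", "flight", "longterm",
            sprintf("C%d", ci), vols[ci], flight_tech_reps)
    }
    for (g in seq_len(n_ground)) {
      for (ci in seq_along(vols))
        add(sprintf("GM_%02d", g), "sample", "ground", "control",
            sprintf("C%d", ci), vols[ci], ground_tech_reps)
    }
    add("BLANK_CB", "blank", "none", "none", "C1", vols[1L], n_blank)
  }
  df <- do.call(rbind, rows)
  validate_measurements(df)
  df
}

block_sigma <- function(rho, noise_cv) {
  s2n <- log(1 + noise_cv^2)
  if (rho <= 0) return(0)
  if (rho * exp(s2n) >= 1)
    stop("block correlation rho unattainable at this noise level",
         call. = FALSE)
  sqrt(log((1 - rho) / (1 - rho * exp(s2n))))
}

#' Generate one platform's raw abundance table
#'
#' The noiseless signal of metabolite `m` in a sample with condition `c`
#' is `blank_mean[m] + base_net[m] * effect(m, c)`; blank measurements
#' carry `blank_mean[m]` alone. Members of a cluster block are multiplied
#' by a per-sample shared lognormal latent factor whose variance is
#' calibrated against the measurement noise so that the pairwise Pearson
#' correlation of block members equals the block's `rho`. All values are
#' then multiplied by lognormal noise with coefficient of variation
#' `noise_cv` (unit mean), outlier samples are inflated, values are
#' clipped at zero, and realised signals below the detection limit are
#' set missing with probability `missing_below_lod_prob`.
#'
#' With `noise_cv = 0` and censoring disabled every sample column equals
#' the noiseless signal exactly, so the full pipeline recovers planted
#' fold changes without error.
#'
#' @param design `"TEXUS54"` or `"CELLBOX"`.
#' @param truth A [synthetic_truth()].
#' @param layout Optional measurement layout ([platform_layout()]).
#' @return A [raw_table()].
#' @export
generate_platform <- function(design = c("TEXUS54", "CELLBOX"), truth,
                              layout = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(truth, "grav_truth"))
  if (is.null(layout)) layout <- platform_layout(design)
  panel <- truth$panels[[design]]
  if (!all(panel %in% truth$metabolite_id))
    stop("panel references unknown metabolites", call. = FALSE)
  n_unk <- as.integer(truth$n_unannotated[[design]])
  if (is.na(n_unk)) n_unk <- 0L
  unk_ids <- if (n_unk > 0L)
    sprintf("Unknown_%s_%02d", substr(design, 1, 2), seq_len(n_unk))
  else character()

  blank <- c(truth$blank_mean[panel],
             setNames(runif(n_unk, 80, 900), unk_ids))
  net <- c(truth$base_net[panel], setNames(numeric(n_unk), unk_ids))
  mets <- c(panel, unk_ids)
  n_m <- length(mets)
  n_c <- nrow(layout)

  eff_of <- function(m, cond) {
    e <- truth$effects[[m]]
    if (is.null(e) || is.na(e[cond])) 1 else unname(e[cond])
  }
  is_sample <- layout$role == "sample"
  expected <- matrix(rep(blank, n_c), nrow = n_m,
                     dimnames = list(mets, layout$measurement_id))
  for (j in which(is_sample)) {
    cond <- layout$condition[j]
    eff <- vapply(mets, eff_of, 0, cond = cond)
    expected[, j] <- blank + net * eff
  }

  # shared per-biological-sample latent factors inside cluster blocks
  bios <- unique(layout$biological_sample_id[is_sample])
  latent <- matrix(1, n_m, n_c)
  for (b in truth$cluster_blocks) {
    members <- intersect(b$members, mets)
    if (length(members) < 2L) next
    sig <- block_sigma(b$rho, truth$noise_cv)
    z <- setNames(rnorm(length(bios)), bios)
    fac <- exp(sig * z - sig^2 / 2)
    for (j in which(is_sample))
      latent[match(members, mets), j] <- fac[[layout$biological_sample_id[j]]]
  }

  s2n <- log(1 + truth$noise_cv^2)
  noise <- if (truth$noise_cv > 0)
    matrix(exp(rnorm(n_m * n_c, -s2n / 2, sqrt(s2n))), n_m, n_c)
  else matrix(1, n_m, n_c)

  values <- expected * latent * noise
  infl <- is_sample & layout$biological_sample_id %in% truth$outlier_sample_ids
  if (any(infl)) values[, infl] <- values[, infl] * truth$outlier_inflation
  values <- pmax(values, 0)

  if (truth$missing_below_lod_prob > 0) {
    u <- matrix(runif(n_m * n_c), n_m, n_c)
    values[values < truth$lod & u < truth$missing_below_lod_prob] <- NA
  }

  raw_table(values,
            metabolite_meta(mets,
                            annotated = c(rep(TRUE, length(panel)),
                                          rep(FALSE, n_unk))),
            layout)
}

#' Generate a paired two-platform synthetic dataset
#'
#' Seeds the RNG, builds (or accepts) a ground truth, and generates the
#' raw abundance tables of both platform designs from a single random
#' stream, so that a fixed seed reproduces the pair bit-identically.
#'
#' @param seed Integer seed for the whole draw.
#' @param truth Optional [synthetic_truth()]; by default [default_truth()]
#'   with the arguments below.
#' @param ... Passed to [default_truth()] when `truth` is `NULL`.
#' @return A list with elements `texus` (raw table, short-term design),
#'   `cellbox` (raw table, long-term design) and `truth`.
#' @examples
#' pair <- generate_pair(seed = 1)
#' pair$truth
#' @export
generate_pair <- function(seed = 1L, truth = NULL, ...) {
  set.seed(as.integer(seed))
  if (is.null(truth)) truth <- default_truth(...)
  truth$seed <- as.integer(seed)
  list(texus = generate_platform("TEXUS54", truth),
       cellbox = generate_platform("CELLBOX", truth),
       truth = truth)
}
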