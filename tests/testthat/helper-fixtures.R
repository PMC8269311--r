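# small in-code fixtures shared across test files

make_meta <- function(ids, role = "sample", group = "flight",
                      condition = "longterm", platform = "CELLBOX",
                      bio = ids, comp = "C1", vol = 1, rep = 1L) {
  measurement_meta(ids, platform = platform, role = role, group = group,
                   condition = condition, biological_sample_id = bio,
                   compartment_id = comp, recovered_volume = vol,
                   tech_rep_index = rep)
}

# sample-level RMA table (blank-subtracted) from a plain matrix
make_rma <- function(values, group, condition = NULL,
                     platform = "CELLBOX", scaled_by = 1) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("M%02d", seq_len(nrow(values)))
  ids <- colnames(values)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(condition))
    condition <- ifelse(group == "flight", "longterm", "control")
  samples <- make_meta(ids, group = group, condition = condition,
                       platform = platform)
  rma_table(values, samples, blank_subtracted = TRUE,
            scaled_by = scaled_by)
}

# raw table of one metabolite over 5 flight + 3 ground samples, used for
# missingness-filter cases
raw_5v3 <- function(flight, ground) {
  vals <- matrix(c(flight, ground), nrow = 1)
  ids <- c(sprintf("F%d", 1:5), sprintf("G%d", 1:3))
  raw_table(vals, metabolite_meta("M1"),
            make_meta(ids, group = rep(c("flight", "ground"), c(5, 3)),
                      condition = rep(c("longterm", "control"), c(5, 3))))
}

# independent Welch t-test oracle (statistic + Welch-Satterthwaite df)
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# all permutations of 1..n as a list of integer vectors
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub)
    for (i in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = i)
  out
}

# independent BH oracle: literal step-up definition on sorted p-values
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))), 0)
  out <- numeric(m)
  out[o] <- qs
  out
}
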