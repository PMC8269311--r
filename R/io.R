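#' Read a raw abundance table with its metadata sidecar
#'
#' The abundance file is TSV/CSV with a header row of measurement ids and
#' a first column of metabolite ids; empty cells or `"NA"` are missing
#' values. The sidecar (TSV/CSV, or JSON with the same fields) holds one
#' record per measurement column plus optional metabolite annotation
#' columns `metabolite_id`/`name`/`annotated`.
#'
#' @param path Abundance table file.
#' @param meta_path Measurement metadata file.
#' @param metabolite_meta_path Optional metabolite metadata file; by
#'   default all metabolites are taken as annotated.
#' @return A [raw_table()].
#' @export
read_abundance_table <- function(path, meta_path,
                                 metabolite_meta_path = NULL) {
  tab <- read_delim_auto(path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate metabolite ids in ", path, call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  meta <- if (grepl("\\.json$", meta_path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(meta_path), stringsAsFactors = FALSE)
  } else {
    read_delim_auto(meta_path)
  }
  meta$tech_rep_index <- as.integer(meta$tech_rep_index)
  meta$recovered_volume <- as.numeric(meta$recovered_volume)
  if (nrow(meta) != ncol(vals) ||
      !setequal(meta$measurement_id, colnames(vals)))
    stop("measurement metadata does not match table columns", call. = FALSE)
  meta <- meta[match(colnames(vals), meta$measurement_id), , drop = FALSE]
  rownames(meta) <- NULL
  mm <- if (is.null(metabolite_meta_path)) {
    metabolite_meta(ids)
  } else {
    m <- read_delim_auto(metabolite_meta_path)
    m <- m[match(ids, m$metabolite_id), , drop = FALSE]
    metabolite_meta(m$metabolite_id, m$name, as.logical(m$annotated))
  }
  raw_table(vals, mm, meta)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' Write a raw abundance table and its metadata sidecar
#'
#' Inverse of [read_abundance_table()]: missing entries are written as the
#' `"NA"` sentinel, numbers at 12 significant digits so that a read/write
#' cycle is lossless at that precision.
#'
#' @param table A [raw_table()].
#' @param path Output abundance TSV.
#' @param meta_path Output measurement metadata TSV.
#' @param metabolite_meta_path Optional output metabolite metadata TSV.
#' @return Invisibly, `table`.
#' @export
write_abundance_table <- function(table, path, meta_path,
                                  metabolite_meta_path = NULL) {
  df <- data.frame(metabolite_id = rownames(table$values),
                   format_num(table$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(table$measurements, meta_path)
  if (!is.null(metabolite_meta_path))
    write_tsv(table$metabolites, metabolite_meta_path)
  invisible(table)
}

format_num <- function(x) {
  if (is.matrix(x)) {
    out <- matrix(ifelse(is.na(x), NA_character_, sprintf("%.12g", x)),
                  nrow = nrow(x), dimnames = dimnames(x))
    as.data.frame(out, stringsAsFactors = FALSE)
  } else {
    ifelse(is.na(x), NA_character_, sprintf("%.12g", x))
  }
}

#' Write a results table as TSV
#'
#' Writes any record data.frame (differential records, cluster sets,
#' cross-platform records, ...) with a stable column order and fixed
#' decimal formatting; numeric values round-trip at 12 significant
#' digits. An empty record set yields a header-only file.
#'
#' @param records A data.frame of records.
#' @param path Output TSV path.
#' @return Invisibly, `records`.
#' @export
write_results <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format_num(out[[j]])
  }
  write_tsv(out, path)
  invisible(records)
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = "NA")
}
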