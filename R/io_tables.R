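## Tabular IO: docking-result tables, FAME tables, TSV/JSON report writers.
## CSV vs TSV chosen by extension; both carry a header row.

read_delim_auto <- function(path) {
  if (!file.exists(path))
    ltk_stop("ltk_missing_file", "file not found: %s", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}

#' Build a docking table
#'
#' One row per structure x ligand docking outcome: predicted affinity in
#' kcal/mol (more negative = stronger) and the catalytic distance in Angstrom
#' between the nucleophilic Ser O-gamma and the substrate acyl carbon.
#'
#' @param df data.frame with columns `structure`, `ligand`,
#'   `affinity_kcal_mol`, `distance_A` and optionally `organism`.
#' @return a data.frame of class `DockingTable`.
#' @export
docking_table <- function(df) {
  need <- c("structure", "ligand", "affinity_kcal_mol", "distance_A")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ltk_stop("ltk_missing_column", "docking table lacks column(s): %s",
             paste(miss, collapse = ", "))
  for (col in c("affinity_kcal_mol", "distance_A")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      ltk_stop("ltk_bad_number", "non-numeric value in column '%s'", col)
    df[[col]] <- v
  }
  if (any(df$distance_A < 0))
    ltk_stop("ltk_bad_number", "negative catalytic distance")
  key <- paste(df$structure, df$ligand, sep = "|")
  if (anyDuplicated(key))
    ltk_stop("ltk_duplicate_key", "duplicate (structure, ligand) pair: %s",
             key[duplicated(key)][1])
  rownames(df) <- NULL
  class(df) <- c("DockingTable", "data.frame")
  df
}

#' Read a docking-result table from CSV/TSV
#' @param path file with a header row naming at least `structure`, `ligand`,
#'   `affinity_kcal_mol`, `distance_A`.
#' @return a [docking_table()].
#' @export
read_docking_table <- function(path) docking_table(read_delim_auto(path))

#' Write a docking table to CSV/TSV (separator from extension)
#' @param table a `DockingTable`.
#' @param path output file.
#' @export
write_docking_table <- function(table, path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Build a FAME table
#'
#' Gas-chromatography FAME amounts per TLC band: one row per (band, fatty
#' acid), amounts in mol or any consistent unit.
#'
#' @param df data.frame with columns `band`, `fatty_acid`, `amount`.
#' @return a data.frame of class `FameTable`.
#' @export
fame_table <- function(df) {
  need <- c("band", "fatty_acid", "amount")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ltk_stop("ltk_missing_column", "FAME table lacks column(s): %s",
             paste(miss, collapse = ", "))
  df$amount <- suppressWarnings(as.numeric(df$amount))
  if (any(is.na(df$amount)))
    ltk_stop("ltk_bad_number", "non-numeric FAME amount")
  if (any(df$amount < 0))
    ltk_stop("ltk_bad_number", "negative FAME amount")
  key <- paste(df$band, df$fatty_acid, sep = "|")
  if (anyDuplicated(key))
    ltk_stop("ltk_duplicate_key", "duplicate (band, fatty acid) pair")
  rownames(df) <- NULL
  class(df) <- c("FameTable", "data.frame")
  df
}

#' Read a FAME amount table from CSV/TSV
#' @param path file with header `band`, `fatty_acid`, `amount`.
#' @return a [fame_table()].
#' @export
read_fame_table <- function(path) fame_table(read_delim_auto(path))

#' Write a data.frame as a TSV report (atomically)
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv_report <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a list as a JSON report (atomically)
#' @param x list.
#' @param path output file.
#' @export
write_json_report <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
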