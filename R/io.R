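#' Read a well-level measurement table
#'
#' Reads a CSV of per-well screen measurements and validates it against a
#' plate layout: every (plate, well) must exist in the layout, counts must
#' be non-negative, and roles/annotations are back-filled from the layout
#' where the table leaves them blank. Row order is preserved.
#'
#' @param path CSV path with header columns `plate_id`, `well`,
#'   `cell_count`, `fov_used`, `ecad_raw` and optionally `role`,
#'   `gene_symbol`, `duplex_index`, `sparse_terminated`.
#' @param layout A `plate_layout` covering the plates in the table.
#' @return A data frame of well records (one per input row).
#' @export
read_well_table <- function(path, layout) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "cell_count", "fov_used", "ecad_raw")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("well table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(empty_well_table())
  key <- paste(df$plate_id, toupper(df$well))
  lkey <- paste(layout$plate_id, toupper(layout$well))
  unknown <- !(key %in% lkey)
  if (any(unknown))
    stop("row ", which(unknown)[1], ": well ", df$well[unknown][1],
         " on plate ", df$plate_id[unknown][1], " is not in the layout")
  bad <- which(df$cell_count < 0)
  if (length(bad))
    stop("row ", bad[1], ": negative cell_count (", df$cell_count[bad[1]], ")")
  bad <- which(df$ecad_raw < 0)
  if (length(bad))
    stop("row ", bad[1], ": negative ecad_raw (", df$ecad_raw[bad[1]], ")")
  m <- match(key, lkey)
  if (is.null(df$role)) df$role <- layout$role[m]
  df$role[is.na(df$role) | df$role == ""] <- layout$role[m][is.na(df$role) | df$role == ""]
  if (is.null(df$gene_symbol)) df$gene_symbol <- layout$gene_symbol[m]
  if (is.null(df$duplex_index)) df$duplex_index <- layout$duplex_index[m]
  if (is.null(df$sparse_terminated)) df$sparse_terminated <- FALSE
  df$duplex_index <- as.integer(df$duplex_index)
  ok <- is.na(df$duplex_index) | df$duplex_index %in% 0:4
  if (any(!ok))
    stop("row ", which(!ok)[1], ": duplex_index must be 0 (SMARTpool) or 1-4")
  df[c("plate_id", "well", "role", "gene_symbol", "duplex_index",
       "cell_count", "fov_used", "sparse_terminated", "ecad_raw")]
}

empty_well_table <- function() {
  data.frame(plate_id = character(), well = character(), role = character(),
             gene_symbol = character(), duplex_index = integer(),
             cell_count = numeric(), fov_used = numeric(),
             sparse_terminated = logical(), ecad_raw = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a well table to CSV
#'
#' @param wells A well-table data frame (see [read_well_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read named RNA sequences from FASTA or two-column TSV
#'
#' Sequence names must be unique; sequences are upper-cased and DNA input
#' is converted to RNA (T -> U). Any character outside {A, C, G, U} after
#' conversion is an error.
#'
#' @param path A FASTA file (any line starting with `>`) or a two-column
#'   tab-separated file (`name<TAB>sequence`, no header).
#' @return A named character vector of RNA sequences.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">mir-x", "UAAUACUGCC"), tf)
#' read_sequences(tf)
#' @export
read_sequences <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    set <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("TSV sequence file must have two columns")
    seqs <- toupper(df[[2]])
    names(seqs) <- df[[1]]
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence name(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("non-nucleotide character in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Write the per-gene screen report
#'
#' Serializes a per-gene results table (normalized folds, bins, filter
#' trail, final class) to CSV with a fixed, deterministic column order so
#' that writing and re-reading are bit-exact inverses.
#'
#' @param results Data frame carrying at least `gene_symbol` and
#'   `filter_trail`; any additional columns are preserved.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(results, path) {
  lead <- intersect(c("gene_symbol", "candidate_class", "fold_ecad",
                      "fold_count", "z_ecad", "cv_bin", "ecad_bin",
                      "rpkm", "pro_survival", "anti_proliferative",
                      "n_active", "validated", "filter_trail"),
                    names(results))
  ord <- c(lead, setdiff(names(results), lead))
  utils::write.csv(results[ord], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_screen_report
#' @export
read_screen_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write RPKM expression tables
#'
#' @param path CSV with columns `gene_symbol` and `rpkm`.
#' @param expr Data frame with those columns.
#' @return A data frame (`read_expression_table`) or `path` invisibly.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_symbol", "rpkm"), names(df))
  if (length(miss)) stop("expression table missing: ", paste(miss, collapse = ", "))
  if (any(df$rpkm < 0)) stop("negative RPKM value")
  df
}

#' @rdname read_expression_table
#' @export
write_expression_table <- function(expr, path) {
  utils::write.csv(expr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write siRNA duplex tables
#'
#' Duplex tables are tab-separated with columns `gene`, `duplex_index`,
#' `sense`, `antisense` (5'->3', 19-mer RNA).
#'
#' @param path TSV path.
#' @param duplexes Data frame with the four columns above.
#' @return A data frame, or `path` invisibly.
#' @export
read_duplex_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "duplex_index", "sense", "antisense"), names(df))
  if (length(miss)) stop("duplex table missing: ", paste(miss, collapse = ", "))
  df$sense <- toupper(gsub("T", "U", df$sense, fixed = TRUE))
  df$antisense <- toupper(gsub("T", "U", df$antisense, fixed = TRUE))
  df
}

#' @rdname read_duplex_table
#' @export
write_duplex_table <- function(duplexes, path) {
  utils::write.table(duplexes, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
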