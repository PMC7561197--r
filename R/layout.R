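#' Well-position coordinate conversion
#'
#' Plate coordinates are printed as letter row (A-P) plus 1-based column
#' (1-24), e.g. "B03". Internally wells are indexed 0-based in row-major
#' order (A01 = 0, A02 = 1, ..., P24 = 383). These two functions are exact
#' inverses of one another.
#'
#' @param well Character vector of well names such as "A01" or "A1".
#' @param index Integer vector of 0-based row-major well indices.
#' @param n_col Number of plate columns (24 for 384-well plates).
#' @return `well_to_index()` returns 0-based integers; `index_to_well()`
#'   returns zero-padded well names.
#' @examples
#' well_to_index("A01")  # 0
#' index_to_well(383)    # "P24"
#' @export
well_to_index <- function(well, n_col = 24L) {
  well <- toupper(trimws(well))
  ok <- grepl("^[A-P][0-9]{1,2}$", well)
  if (any(!ok)) stop("malformed well position: ", paste(well[!ok], collapse = ", "))
  row <- match(substr(well, 1, 1), LETTERS)
  col <- as.integer(substring(well, 2))
  if (any(col < 1L | col > n_col)) stop("column out of range in: ",
                                        paste(well[col < 1L | col > n_col], collapse = ", "))
  as.integer((row - 1L) * n_col + (col - 1L))
}

#' @rdname well_to_index
#' @export
index_to_well <- function(index, n_col = 24L) {
  index <- as.integer(index)
  if (any(index < 0L | index >= 16L * n_col)) stop("well index out of range")
  row <- index %/% n_col + 1L
  col <- index %% n_col + 1L
  sprintf("%s%02d", LETTERS[row], col)
}

#' Build a 384-well plate layout
#'
#' Constructs the control layout of the primary SMARTpool screen or the
#' deconvolution validation screen. Controls occupy the edge control block
#' (columns 2 and 23, with any overflow in column 24); sample wells are
#' columns 3-22 (320 wells); column 1 (and the unused remainder of column
#' 24) is empty.
#'
#' Per plate the primary layout carries 16 mock wells and 6 wells each of
#' siCDH1, siZEB1 and siPLK1; the deconvolution layout carries 31 mock, 13
#' each siCDH1/siZEB1 and 4 siPLK1.
#'
#' @param type `"primary"` or `"deconvolution"`.
#' @param plate_id Plate identifier string.
#' @return A `plate_layout`: a data frame with columns `plate_id`, `well`,
#'   `role` (sample / mock / siCDH1 / siZEB1 / siPLK1 / empty),
#'   `gene_symbol`, `duplex_index`; 384 rows, attribute `layout_type`.
#' @examples
#' lay <- plate_layout("primary", "P01")
#' table(lay$role)
#' @export
plate_layout <- function(type = c("primary", "deconvolution"),
                         plate_id = "P01") {
  type <- match.arg(type)
  roles <- rep("empty", 384L)
  rows16 <- function(col) well_to_index(sprintf("%s%02d", LETTERS[1:16], col))
  col2 <- rows16(2L); col23 <- rows16(23L); col24 <- rows16(24L)
  if (type == "primary") {
    # 16 mock fill column 2; 6 + 6 + 4 controls in column 23; the 2
    # remaining siPLK1 wells overflow into column 24 rows A-B.
    roles[col2 + 1L] <- "mock"
    roles[col23[1:6] + 1L] <- "siCDH1"
    roles[col23[7:12] + 1L] <- "siZEB1"
    roles[col23[13:16] + 1L] <- "siPLK1"
    roles[col24[1:2] + 1L] <- "siPLK1"
  } else {
    # 31 mock + 13 + 13 + 4 = 61 control wells across columns 2/23/24.
    roles[col2 + 1L] <- "mock"
    roles[col23[1:15] + 1L] <- "mock"
    roles[col23[16] + 1L] <- "siCDH1"
    roles[col24[1:12] + 1L] <- "siCDH1"
    roles[col24[13:16] + 1L] <- "siPLK1"
    # 13 siZEB1 displace the last 13 sample wells of column 22
    col22 <- rows16(22L)
    roles[col22[4:16] + 1L] <- "siZEB1"
  }
  sample_cols <- 3:22
  for (cc in sample_cols) {
    idx <- rows16(cc)
    roles[idx + 1L][roles[idx + 1L] == "empty"] <- "sample"
  }
  out <- data.frame(
    plate_id = plate_id,
    well = index_to_well(0:383),
    role = roles,
    gene_symbol = NA_character_,
    duplex_index = NA_integer_,
    stringsAsFactors = FALSE
  )
  attr(out, "layout_type") <- type
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Check a plate layout against its declared control totals
#'
#' @param layout A `plate_layout`.
#' @return `TRUE` invisibly; otherwise an error naming the mismatch.
#' @export
validate_plate_layout <- function(layout) {
  if (nrow(layout) != 384L) stop("layout must have exactly 384 wells")
  if (anyDuplicated(layout$well)) stop("duplicate well positions in layout")
  type <- attr(layout, "layout_type")
  want <- switch(type,
    primary = c(mock = 16L, siCDH1 = 6L, siZEB1 = 6L, siPLK1 = 6L),
    deconvolution = c(mock = 31L, siCDH1 = 13L, siZEB1 = 13L, siPLK1 = 4L),
    stop("unknown layout type: ", type)
  )
  got <- table(layout$role)
  for (r in names(want)) {
    n <- if (r %in% names(got)) as.integer(got[[r]]) else 0L
    if (n != want[[r]])
      stop(sprintf("layout '%s': expected %d %s wells, found %d",
                   type, want[[r]], r, n))
  }
  # controls confined to the declared control columns
  ctrl_cols <- if (type == "primary") c(2L, 23L, 24L) else c(2L, 22L, 23L, 24L)
  col_of <- well_to_index(layout$well) %% 24L + 1L
  bad <- layout$role %in% names(want) & !(col_of %in% ctrl_cols)
  if (any(bad))
    stop("control wells outside declared control columns: ",
         paste(layout$well[bad], collapse = ", "))
  invisible(TRUE)
}

#' Assign library genes to the sample wells of one or more plates
#'
#' @param genes Character vector of gene symbols (one SMARTpool each).
#' @param type Layout type passed to [plate_layout()].
#' @param plate_prefix Prefix for generated plate identifiers.
#' @return A multi-plate layout data frame (rbind of `plate_layout`s) with
#'   `gene_symbol` filled for as many sample wells as there are genes.
#' @export
assign_genes <- function(genes, type = "primary", plate_prefix = "P") {
  per_plate <- sum(plate_layout(type)$role == "sample")
  n_plates <- max(1L, ceiling(length(genes) / per_plate))
  plates <- lapply(seq_len(n_plates), function(i) {
    lay <- plate_layout(type, sprintf("%s%02d", plate_prefix, i))
    take <- genes[((i - 1L) * per_plate + 1L):min(i * per_plate, length(genes))]
    take <- take[!is.na(take)]
    slots <- which(lay$role == "sample")[seq_along(take)]
    lay$gene_symbol[slots] <- take
    lay$role[setdiff(which(lay$role == "sample"),
                     slots)] <- "empty"  # unused sample wells stay empty
    lay
  })
  out <- do.call(rbind, plates)
  attr(out, "layout_type") <- type
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Read and write plate layouts as CSV
#'
#' @param layout A `plate_layout` data frame.
#' @param path CSV file path.
#' @param type Layout type to stamp on the read object.
#' @return `read_plate_layout()` returns a `plate_layout`;
#'   `write_plate_layout()` returns `path` invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path, type = "primary") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "role", "gene_symbol", "duplex_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("layout file missing columns: ", paste(miss, collapse = ", "))
  df$duplex_index <- as.integer(df$duplex_index)
  attr(df, "layout_type") <- type
  class(df) <- c("plate_layout", "data.frame")
  df
}
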