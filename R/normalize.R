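# Normalization cascade: replicate averaging on raw values, per-plate
# fold-change to the mock-control mean, then a single screen-wide robust
# Z-score over the library sample wells.

#' Average duplicate-plate well tables
#'
#' Arithmetic mean of `cell_count`, `fov_used` and `ecad_raw` per well;
#' annotations are taken from the first table and must match the second.
#' Averaging happens on raw values, before mock normalization.
#'
#' @param tableA,tableB Well tables covering identical (plate, well) sets
#'   with identical annotations.
#' @return An averaged well table.
#' @export
average_replicates <- function(tableA, tableB) {
  keyA <- paste(tableA$plate_id, tableA$well)
  keyB <- paste(tableB$plate_id, tableB$well)
  onlyA <- setdiff(keyA, keyB); onlyB <- setdiff(keyB, keyA)
  if (length(onlyA) || length(onlyB))
    stop("replicate tables cover different wells: ",
         paste(c(onlyA, onlyB), collapse = ", "))
  m <- match(keyA, keyB)
  same <- function(col) identical(tableA[[col]],
                                  tableB[[col]][m])
  for (col in c("role", "gene_symbol"))
    if (!same(col)) stop("replicate annotation mismatch in column ", col)
  out <- tableA
  out$cell_count <- (tableA$cell_count + tableB$cell_count[m]) / 2
  out$fov_used <- (tableA$fov_used + tableB$fov_used[m]) / 2
  out$ecad_raw <- (tableA$ecad_raw + tableB$ecad_raw[m]) / 2
  out$sparse_terminated <- tableA$sparse_terminated & tableB$sparse_terminated[m]
  out
}

#' Per-plate fold change to the mock-control mean
#'
#' Divides each well's `ecad_raw` and `cell_count` by the arithmetic mean
#' of the same plate's mock wells (mock wells are normalized too, so their
#' folds average exactly 1 per plate).
#'
#' @param wells A well table (one replicate-averaged screen).
#' @return The table with added columns `fold_ecad`, `fold_count`.
#' @export
fold_vs_mock <- function(wells) {
  out <- wells
  out$fold_ecad <- NA_real_
  out$fold_count <- NA_real_
  for (p in unique(wells$plate_id)) {
    sel <- wells$plate_id == p
    mock <- sel & wells$role == "mock"
    if (!any(mock))
      stop("plate ", p, " has no mock wells; cannot normalize")
    me <- mean(wells$ecad_raw[mock])
    mc <- mean(wells$cell_count[mock])
    if (!is.finite(me) || me <= 0)
      stop("plate ", p, ": mock mean Ecad score is ", me,
           "; refusing to divide")
    if (!is.finite(mc) || mc <= 0)
      stop("plate ", p, ": mock mean cell count is ", mc,
           "; refusing to divide")
    out$fold_ecad[sel] <- wells$ecad_raw[sel] / me
    out$fold_count[sel] <- wells$cell_count[sel] / mc
  }
  out
}

#' Robust Z-score
#'
#' `z = (x - median(x)) / (1.4826 * MAD(x))`, the standard outlier-
#' resistant standardization for screening data. The reference population
#' is whatever is passed in; for the screen this is the library sample
#' wells only (controls excluded), pooled across all plates since folds
#' are already plate-normalized.
#'
#' @param x Numeric vector of (mock-normalized) folds; length >= 3.
#' @return Numeric vector of robust Z-scores.
#' @examples
#' robust_z(c(0.8, 0.9, 1.0, 1.1, 1.2, 1.6))
#' @export
robust_z <- function(x) {
  if (length(x) < 3L) stop("robust_z needs at least 3 values")
  med <- stats::median(x)
  s <- stats::mad(x, constant = 1.4826)
  if (s == 0)
    stop("MAD is zero: the input is degenerate (more than half the values ",
         "are identical); robust Z-scores are undefined for it")
  (x - med) / s
}

#' Per-gene normalized scores for a screen
#'
#' Runs the full normalization: average the duplicate plates, fold to the
#' per-plate mock mean, and robust Z over the library sample wells.
#'
#' @param tableA,tableB The duplicate-plate well tables.
#' @return A data frame of per-gene scores: `gene_symbol`, `duplex_index`,
#'   `plate_id`, `well`, `cell_count`, `fov_used`, `fold_ecad`,
#'   `fold_count`, `z_ecad` (sample wells only; controls retain their
#'   folds with `z_ecad = NA`).
#' @export
gene_scores <- function(tableA, tableB) {
  avg <- average_replicates(tableA, tableB)
  fold <- fold_vs_mock(avg)
  lib <- fold$role == "sample" & !is.na(fold$gene_symbol)
  fold$z_ecad <- NA_real_
  fold$z_ecad[lib] <- robust_z(fold$fold_ecad[lib])
  fold
}
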