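# Cell-viability binning and the proliferation classifications derived
# from the field-of-view acquisition behaviour.

#' Bin a cell-count fold into CV1 / CV2 / LC
#'
#' CV1: fold >= 0.7 of mock; CV2: 0.5 <= fold < 0.7; LC (Low Count, the
#' exclusion bin): fold < 0.5. The three bins partition the non-negative
#' folds exhaustively and exclusively.
#'
#' @param fold_count Numeric vector of cell-count folds vs mock (>= 0).
#' @param cfg A [screen_config()].
#' @return Character vector in `{"CV1", "CV2", "LC"}`.
#' @examples
#' bin_viability(c(0.7, 0.5, 0.49))
#' @export
bin_viability <- function(fold_count, cfg = screen_config()) {
  if (any(fold_count < 0)) stop("negative cell-count fold")
  ifelse(fold_count >= cfg$cv1_min, "CV1",
         ifelse(fold_count >= cfg$cv2_min, "CV2", "LC"))
}

#' Flag pro-survival (toxic-knockdown) genes
#'
#' A gene is pro-survival when its knockdown left fewer than
#' `low_count_cells` cells despite the full field budget being acquired
#' (the classic "< 1500 cells in 25 fields" exclusion), or when acquisition
#' was terminated by a sparse run. Flagged genes are excluded from
#' E-cadherin regulator candidacy.
#'
#' @param cell_count Averaged raw cell count per gene.
#' @param fov_used Fields of view acquired.
#' @param sparse_terminated Logical; acquisition ended by a sparse run.
#' @param cfg A [screen_config()].
#' @return Logical vector.
#' @export
classify_pro_survival <- function(cell_count, fov_used,
                                  sparse_terminated = FALSE,
                                  cfg = screen_config()) {
  (cell_count < cfg$low_count_cells & fov_used >= cfg$max_fields) |
    rep_len(sparse_terminated, length(cell_count))
}

#' Fast-growth FOV cutoff from the mock wells
#'
#' The cutoff is two standard deviations below the mock mean field count,
#' rounded up to the operative integer: `c = ceiling(mean - 2 * sd)`. A
#' gene counts as fast-growing (anti-proliferative knockdown) when
#' `fov_used <= c`. With the screen's mock statistics (mean 20, sd 3.13)
#' this gives c = 14, i.e. the "< 15 FOV" rule.
#'
#' @param mock_fov Numeric vector of mock-well `fov_used` values (n >= 2).
#' @return A list with `cutoff` (integer) and `raw` (the real-valued
#'   mean - 2 sd).
#' @examples
#' fov_cutoff(c(17, 20, 23, 20))
#' @export
fov_cutoff <- function(mock_fov) {
  if (length(mock_fov) < 2L) stop("need at least 2 mock FOV values")
  m <- mean(mock_fov)
  s <- stats::sd(mock_fov)
  if (s == 0)
    stop("mock FOV standard deviation is zero; the cutoff mean - 2*sd is ",
         "degenerate. Check that fov_used varies across mock wells.")
  raw <- m - 2 * s
  list(cutoff = as.integer(ceiling(raw)), raw = raw)
}

#' Flag anti-proliferative genes
#'
#' A knockdown is anti-proliferative when the well reached the target cell
#' count unusually fast (`fov_used <= cutoff`) while showing no change in
#' membrane E-cadherin (`ecad_bin == "NC"`); an E-cadherin regulator
#' phenotype takes precedence.
#'
#' @param fov_used Fields of view per gene.
#' @param cutoff Integer cutoff from [fov_cutoff()].
#' @param ecad_bin Character vector of Ecad bins (`"High"`, `"NC"`,
#'   `"Low"`).
#' @return Logical vector.
#' @export
classify_anti_proliferative <- function(fov_used, cutoff, ecad_bin) {
  fov_used <= cutoff & ecad_bin == "NC"
}

#' Per-gene viability calls for a scored screen
#'
#' Combines [bin_viability()], [classify_pro_survival()] and
#' [classify_anti_proliferative()] into one call table, cross-checking the
#' LC bin (fold-based) against the raw low-count rule and warning on
#' disagreement.
#'
#' @param scores A scored well table from [gene_scores()] (must carry
#'   `fold_ecad` and `fold_count`; library sample wells and mock wells).
#' @param cfg A [screen_config()].
#' @return Data frame: `gene_symbol`, `cv_bin`, `pro_survival`,
#'   `anti_proliferative`, `fov_used`, `fov_cutoff`.
#' @export
viability_calls <- function(scores, cfg = screen_config()) {
  lib <- scores[scores$role == "sample" & !is.na(scores$gene_symbol), ]
  ecad_bin <- bin_ecad(lib$fold_ecad, cfg)
  cv <- bin_viability(lib$fold_count, cfg)
  ps <- classify_pro_survival(lib$cell_count, lib$fov_used,
                              lib$sparse_terminated, cfg)
  mismatch <- xor(cv == "LC", ps)
  if (any(mismatch))
    warning(sum(mismatch), " gene(s) where the fold-based LC bin and the ",
            "raw low-count rule disagree (borderline wells): ",
            paste(utils::head(lib$gene_symbol[mismatch], 5), collapse = ", "))
  mock_fov <- scores$fov_used[scores$role == "mock"]
  fc <- fov_cutoff(mock_fov)
  ap <- classify_anti_proliferative(lib$fov_used, fc$cutoff, ecad_bin) & !ps
  data.frame(gene_symbol = lib$gene_symbol, cv_bin = cv,
             pro_survival = ps, anti_proliferative = ap,
             fov_used = lib$fov_used, fov_cutoff = fc$cutoff,
             stringsAsFactors = FALSE)
}
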