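# Candidate-selection cascade and the deconvolution validation rule.
#
# Cascade order (each gene carries a pass/fail trail; a gene failing an
# earlier filter is never evaluated by a later one):
#   LC exclusion -> Ecad bin (keep High and Low) -> RPKM >= 1 ->
#   seed exclusion (High candidates only) -> deconvolution 2-of-4 rule.

#' Bin an Ecad fold into High / NC / Low
#'
#' High (siZEB1-like): fold >= 1.6; Low (siCDH1-like): fold <= 0.2; NC
#' otherwise. Both printed cutoffs are inclusive, so a fold exactly at a
#' cutoff is in its bin.
#'
#' @param fold_ecad Numeric vector of Ecad folds vs mock (>= 0).
#' @param cfg A [screen_config()].
#' @return Character vector in `{"High", "NC", "Low"}`.
#' @examples
#' bin_ecad(c(1.6, 0.2, 1.0))
#' @export
bin_ecad <- function(fold_ecad, cfg = screen_config()) {
  if (any(fold_ecad < 0)) stop("negative Ecad fold")
  ifelse(fold_ecad >= cfg$fold_high, "High",
         ifelse(fold_ecad <= cfg$fold_low, "Low", "NC"))
}

#' Primary-screen candidate selection with a per-gene filter trail
#'
#' Applies the ordered cascade to the per-gene scores: low-count (LC)
#' exclusion, Ecad binning (only High and Low proceed), expression filter
#' (RPKM >= 1), and seed exclusion (applied to High candidates only, where
#' miR-200 mimicry inflates the phenotype). Every gene carries an ordered
#' trail recording each filter's outcome; filters after the first failure
#' are recorded as not evaluated.
#'
#' @param scores Scored well table from [gene_scores()].
#' @param viability Viability calls from [viability_calls()].
#' @param expression Expression table (`gene_symbol`, `rpkm`).
#' @param seed_flags Data frame from [scan_duplex_table()], or `NULL` to
#'   skip the seed filter (no flags available).
#' @param cfg A [screen_config()].
#' @param missing_expression `"error"` (default) or `"keep"` for genes
#'   absent from the expression table.
#' @return Data frame, one row per library gene: folds, `z_ecad`,
#'   `ecad_bin`, `cv_bin`, `rpkm`, `candidate_class` (`"ecad_high"`,
#'   `"ecad_low"` or `NA`), `candidate` flag, `filter_trail`.
#' @export
primary_candidates <- function(scores, viability, expression,
                               seed_flags = NULL, cfg = screen_config(),
                               missing_expression = c("error", "keep")) {
  missing_expression <- match.arg(missing_expression)
  lib <- scores[scores$role == "sample" & !is.na(scores$gene_symbol), ]
  vm <- match(lib$gene_symbol, viability$gene_symbol)
  if (anyNA(vm)) stop("viability calls missing for: ",
                      paste(lib$gene_symbol[is.na(vm)][1:min(5, sum(is.na(vm)))],
                            collapse = ", "))
  em <- match(lib$gene_symbol, expression$gene_symbol)
  if (anyNA(em) && missing_expression == "error")
    stop("gene(s) missing from expression table: ",
         paste(lib$gene_symbol[is.na(em)][1:min(5, sum(is.na(em)))],
               collapse = ", "))
  rpkm <- expression$rpkm[em]
  sm <- if (!is.null(seed_flags)) match(lib$gene_symbol, seed_flags$gene_symbol)
        else rep(NA_integer_, nrow(lib))
  n <- nrow(lib)
  ecad_bin <- bin_ecad(lib$fold_ecad, cfg)
  trail <- character(n)
  cand_class <- rep(NA_character_, n)
  candidate <- logical(n)
  for (i in seq_len(n)) {
    steps <- character(0)
    # 1. low-count exclusion
    lc_fail <- viability$cv_bin[vm[i]] == "LC" | viability$pro_survival[vm[i]]
    steps <- c(steps, paste0("LC:", if (lc_fail) "fail" else "pass"))
    if (lc_fail) {
      trail[i] <- finish_trail(steps, c("ecad_bin", "rpkm", "seed"))
      next
    }
    # 2. Ecad bin: keep High and Low
    steps <- c(steps, paste0("ecad_bin:", ecad_bin[i]))
    if (ecad_bin[i] == "NC") {
      trail[i] <- finish_trail(steps, c("rpkm", "seed"))
      next
    }
    # 3. expression filter
    rp_fail <- !is.na(rpkm[i]) && rpkm[i] < cfg$rpkm_min
    if (is.na(rpkm[i])) {
      steps <- c(steps, "rpkm:missing")
    } else {
      steps <- c(steps, paste0("rpkm:", if (rp_fail) "fail" else "pass"))
    }
    if (rp_fail) {
      trail[i] <- finish_trail(steps, "seed")
      next
    }
    # 4. seed exclusion (High candidates only)
    if (ecad_bin[i] == "High" && !is.na(sm[i]) && seed_flags$exclusion[sm[i]]) {
      steps <- c(steps, "seed:fail")
      trail[i] <- paste(steps, collapse = ";")
      next
    }
    steps <- c(steps, if (ecad_bin[i] == "High") "seed:pass" else "seed:na")
    candidate[i] <- TRUE
    cand_class[i] <- if (ecad_bin[i] == "High") "ecad_high" else "ecad_low"
    trail[i] <- paste(steps, collapse = ";")
  }
  data.frame(gene_symbol = lib$gene_symbol,
             fold_ecad = lib$fold_ecad, fold_count = lib$fold_count,
             z_ecad = lib$z_ecad, ecad_bin = ecad_bin,
             cv_bin = viability$cv_bin[vm], rpkm = rpkm,
             pro_survival = viability$pro_survival[vm],
             anti_proliferative = viability$anti_proliferative[vm],
             candidate = candidate, candidate_class = cand_class,
             filter_trail = trail, stringsAsFactors = FALSE)
}

finish_trail <- function(steps, skipped) {
  paste(c(steps, paste0(skipped, ":not_evaluated")), collapse = ";")
}

#' Test one deconvolution duplex for activity
#'
#' One-tailed unpaired Student's t-test of the duplex replicate folds
#' against the mock folds, in the direction of the candidate class
#' (greater for `ecad_high`, less for `ecad_low`). The duplex is active
#' only when the p-value clears `alpha` AND its mean fold clears the
#' class bin threshold — a consistent but tiny shift does not count.
#'
#' @param duplex_folds Numeric vector (>= 2) of the duplex's replicate
#'   Ecad folds.
#' @param mock_folds Numeric vector (>= 2) of mock folds.
#' @param direction `"up"` or `"down"`.
#' @param cfg A [screen_config()].
#' @param var_equal Use the equal-variance Student test (default; Welch if
#'   `FALSE`).
#' @return A list of class `duplex_call`: `mean_fold`, `p_value`,
#'   `direction`, `threshold_met`, `significant`, `active`.
#' @export
duplex_activity <- function(duplex_folds, mock_folds,
                            direction = c("up", "down"),
                            cfg = screen_config(), var_equal = TRUE) {
  direction <- match.arg(direction)
  if (length(duplex_folds) < 2L || length(mock_folds) < 2L)
    stop("need at least 2 replicate wells per duplex and 2 mock wells")
  alt <- if (direction == "up") "greater" else "less"
  p <- if (stats::sd(duplex_folds) == 0 && stats::sd(mock_folds) == 0) {
    # degenerate (e.g. all zeros vs all zeros): no evidence either way
    if (mean(duplex_folds) == mean(mock_folds)) 1 else 0
  } else {
    stats::t.test(duplex_folds, mock_folds, alternative = alt,
                  var.equal = var_equal)$p.value
  }
  mf <- mean(duplex_folds)
  thr <- if (direction == "up") mf >= cfg$fold_high else mf <= cfg$fold_low
  structure(list(mean_fold = mf, p_value = p, direction = direction,
                 threshold_met = thr, significant = p < cfg$alpha,
                 active = thr && p < cfg$alpha),
            class = "duplex_call")
}

#' Validate a gene from its four duplex calls
#'
#' @param calls A list of exactly 4 `duplex_call`s (duplexes 1-4).
#' @param cfg A [screen_config()].
#' @return A list: `n_active`, `active_duplexes` (indices), `validated`
#'   (`n_active >= min_active_duplexes`).
#' @export
validate_gene <- function(calls, cfg = screen_config()) {
  if (length(calls) != 4L)
    stop("validate_gene expects exactly 4 duplex calls, got ", length(calls))
  act <- vapply(calls, function(cl) isTRUE(cl$active), logical(1))
  list(n_active = sum(act), active_duplexes = which(act),
       validated = sum(act) >= cfg$min_active_duplexes)
}

#' Split validated genes into negative and positive regulator lists
#'
#' Validated `ecad_high` genes are negative regulators of E-cadherin
#' (their knockdown raises membrane E-cadherin, siZEB1-like); validated
#' `ecad_low` genes are positive regulators (siCDH1-like). The lists are
#' disjoint and alphabetically ordered.
#'
#' @param verdicts Data frame with `gene_symbol`, `candidate_class`,
#'   `validated`.
#' @return A list with `negative_regulators` and `positive_regulators`
#'   (character vectors).
#' @export
classify_regulators <- function(verdicts) {
  v <- verdicts[verdicts$validated, ]
  if (anyDuplicated(v$gene_symbol))
    stop("gene(s) validated in both classes: ",
         paste(unique(v$gene_symbol[duplicated(v$gene_symbol)]), collapse = ", "))
  list(
    negative_regulators = sort(v$gene_symbol[v$candidate_class == "ecad_high"]),
    positive_regulators = sort(v$gene_symbol[v$candidate_class == "ecad_low"])
  )
}

#' Run the deconvolution validation on a well table
#'
#' For each candidate gene, folds each deconvolution plate to its mock
#' mean, tests the four duplexes with [duplex_activity()] in the gene's
#' candidate direction, applies the 2-of-4 rule and (for `ecad_high`
#' candidates with seed flags) the seed rescue logic.
#'
#' @param wells Deconvolution well table (individual duplex wells with
#'   `duplex_index` 1-4 plus mock wells).
#' @param candidates Data frame with `gene_symbol` and `candidate_class`
#'   for the genes under validation.
#' @param seed_flags Optional [scan_duplex_table()] output.
#' @param cfg A [screen_config()].
#' @return A list with `verdicts` (per-gene data frame: `n_active`,
#'   `validated`, `seed_excluded`, `filter_trail`) and `duplex_calls`
#'   (per-duplex data frame).
#' @export
run_deconvolution <- function(wells, candidates, seed_flags = NULL,
                              cfg = screen_config()) {
  folded <- fold_vs_mock(wells)
  mock_folds <- folded$fold_ecad[folded$role == "mock"]
  dup_rows <- list(); ver_rows <- list()
  for (g in candidates$gene_symbol) {
    cls <- candidates$candidate_class[candidates$gene_symbol == g][1]
    dir <- if (cls == "ecad_high") "up" else "down"
    calls <- lapply(1:4, function(di) {
      f <- folded$fold_ecad[!is.na(folded$gene_symbol) &
                              folded$gene_symbol == g &
                              folded$duplex_index == di]
      duplex_activity(f, mock_folds, dir, cfg)
    })
    ver <- validate_gene(calls, cfg)
    seed_excl <- FALSE
    if (!is.null(seed_flags) && cls == "ecad_high") {
      srow <- seed_flags[seed_flags$gene_symbol == g, ]
      if (nrow(srow) && srow$n_matching[1] > 0) {
        fl <- list(gene_symbol = g,
                   matching_duplexes = as.integer(strsplit(
                     srow$matching_duplexes[1], ",")[[1]]))
        seed_excl <- seed_exclusion(fl, "deconvolution",
                                    ver$active_duplexes, cfg)
      }
    }
    validated <- ver$validated && !seed_excl
    dup_rows[[g]] <- data.frame(
      gene_symbol = g, duplex_index = 1:4,
      mean_fold = vapply(calls, `[[`, numeric(1), "mean_fold"),
      p_value = vapply(calls, `[[`, numeric(1), "p_value"),
      direction = dir,
      active = vapply(calls, `[[`, logical(1), "active"),
      stringsAsFactors = FALSE)
    ver_rows[[g]] <- data.frame(
      gene_symbol = g, candidate_class = cls,
      n_active = ver$n_active, seed_excluded = seed_excl,
      validated = validated,
      filter_trail = paste0("deconvolution:", ver$n_active, "_of_4",
                            if (seed_excl) ";seed:fail" else ""),
      stringsAsFactors = FALSE)
  }
  list(verdicts = do.call(rbind, ver_rows),
       duplex_calls = do.call(rbind, dup_rows))
}
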