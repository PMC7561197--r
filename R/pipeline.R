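#' Run the full screen analysis end to end on synthetic data
#'
#' Convenience driver used by the examples, the command-line entry point
#' and the end-to-end recovery tests: simulates a duplicate-plate primary
#' screen from planted effect specifications, normalizes it, applies the
#' viability, expression and seed filters, simulates and analyses the
#' deconvolution screen for the surviving candidates, and returns the
#' regulator lists alongside the ground truth.
#'
#' @param genes An [effect_spec()] table (the planted truth).
#' @param expression Optional RPKM table; defaults to all genes expressed.
#' @param duplex_table Optional duplex sequence table for seed scanning;
#'   `NULL` skips the seed filter.
#' @param noise_sd Log-normal noise sd for both screens.
#' @param wells_per_duplex Replicate wells per duplex in deconvolution.
#' @param seed Master RNG seed.
#' @param cfg A [screen_config()].
#' @return A list: `scores`, `viability`, `primary` (candidate table with
#'   trails), `deconvolution` (verdicts + duplex calls), `regulators`
#'   (negative/positive lists), `truth`, `funnel` (per-stage counts).
#' @export
run_screen_pipeline <- function(genes, expression = NULL,
                                duplex_table = NULL, noise_sd = 0.1,
                                wells_per_duplex = 3L, seed = 1L,
                                cfg = screen_config()) {
  scr <- make_screen(genes, "primary", noise_sd = noise_sd,
                     seed = derive_seed(seed, "primary"), cfg = cfg)
  scores <- gene_scores(scr$replicates[[1]], scr$replicates[[2]])
  viab <- viability_calls(scores, cfg)
  if (is.null(expression))
    expression <- data.frame(gene_symbol = genes$gene_symbol,
                             rpkm = 10, stringsAsFactors = FALSE)
  seed_flags <- if (!is.null(duplex_table))
    scan_duplex_table(duplex_table, mir200_family(cfg), cfg) else NULL
  primary <- primary_candidates(scores, viab, expression, seed_flags, cfg)
  cand <- primary[primary$candidate, c("gene_symbol", "candidate_class")]
  decon <- NULL
  regulators <- list(negative_regulators = character(0),
                     positive_regulators = character(0))
  if (nrow(cand)) {
    truth_cand <- scr$truth[match(cand$gene_symbol, scr$truth$gene_symbol), ]
    dscr <- make_deconvolution_screen(truth_cand,
                                      wells_per_duplex = wells_per_duplex,
                                      noise_sd = noise_sd,
                                      seed = derive_seed(seed, "deconv"),
                                      cfg = cfg)
    decon <- run_deconvolution(dscr$wells, cand, seed_flags, cfg)
    regulators <- classify_regulators(decon$verdicts)
  }
  funnel <- c(
    library_genes = nrow(genes),
    low_count_excluded = sum(grepl("^LC:fail", primary$filter_trail)),
    ecad_high = sum(primary$ecad_bin == "High" &
                      !grepl("^LC:fail", primary$filter_trail)),
    ecad_low = sum(primary$ecad_bin == "Low" &
                     !grepl("^LC:fail", primary$filter_trail)),
    rpkm_excluded = sum(grepl("rpkm:fail", primary$filter_trail)),
    seed_excluded = sum(grepl("seed:fail", primary$filter_trail)),
    deconvolved = nrow(cand),
    negative_regulators = length(regulators$negative_regulators),
    positive_regulators = length(regulators$positive_regulators)
  )
  list(scores = scores, viability = viab, primary = primary,
       deconvolution = decon, regulators = regulators,
       truth = scr$truth, funnel = funnel)
}

#' Summarize pipeline recovery against the planted truth
#'
#' @param result Output of [run_screen_pipeline()].
#' @return A list with `sensitivity` (recovered planted regulators /
#'   planted regulators), `fdp` (false-discovery proportion among called
#'   regulators), and `toxic_sensitivity` (planted toxic genes flagged
#'   pro-survival).
#' @export
recovery_summary <- function(result) {
  truth <- result$truth
  planted_up <- truth$gene_symbol[truth$effect_class == "ecad_up"]
  planted_dn <- truth$gene_symbol[truth$effect_class == "ecad_down"]
  called <- c(result$regulators$negative_regulators,
              result$regulators$positive_regulators)
  tp <- sum(result$regulators$negative_regulators %in% planted_up) +
    sum(result$regulators$positive_regulators %in% planted_dn)
  n_planted <- length(planted_up) + length(planted_dn)
  toxic <- truth$gene_symbol[truth$effect_class == "toxic"]
  ps <- result$viability$gene_symbol[result$viability$pro_survival]
  list(
    sensitivity = if (n_planted) tp / n_planted else NA_real_,
    fdp = if (length(called)) 1 - tp / length(called) else 0,
    toxic_sensitivity = if (length(toxic)) mean(toxic %in% ps) else NA_real_
  )
}

#' Write a JSON summary report of a pipeline run
#'
#' @param result Output of [run_screen_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_report <- function(result, path) {
  jsonlite::write_json(list(
    funnel = as.list(result$funnel),
    negative_regulators = result$regulators$negative_regulators,
    positive_regulators = result$regulators$positive_regulators
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
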