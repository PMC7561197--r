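#' Screen configuration
#'
#' Bundles every threshold and layout constant of the screening workflow in
#' one versioned record: the Ecad-score fold cutoffs and their robust-Z
#' equivalents, the cell-viability bin boundaries, the imaging-cytometer
#' acquisition constants, the expression filter, the deconvolution decision
#' rule, and the geometric parameters of image quantification.
#'
#' Defaults are the published workflow constants: Ecad High at >= 1.6-fold
#' of mock, Low at <= 0.2-fold (robust-Z equivalents 5.16 and 0.036 reported
#' for audit); CV1 at >= 0.7-fold of mock cell count, CV2 at >= 0.5; the low
#' count (LC) exclusion at < 1500 cells in 25 fields of view; a target cell
#' count of 3000 with at most 25 fields, a 14-cell minimum per field and a
#' run of at most 6 consecutive sparse fields; an RPKM >= 1 expression
#' filter; and the "at least 2 of 4 active duplexes" validation rule with a
#' one-tailed t-test at alpha = 0.05.
#'
#' @param fold_high Ecad fold-vs-mock at or above which a well is binned
#'   High (siZEB1-like).
#' @param fold_low Ecad fold-vs-mock at or below which a well is binned Low
#'   (siCDH1-like).
#' @param z_high,z_low Robust-Z equivalents of the fold cutoffs, reported
#'   alongside the operative fold thresholds for audit.
#' @param cv1_min,cv2_min Cell-count fold-vs-mock lower bounds of the CV1
#'   and CV2 viability bins; folds below `cv2_min` are Low Count (LC).
#' @param low_count_cells Raw averaged cell count below which a well that
#'   used the full field budget is a low-count (pro-survival) well.
#' @param target_cells Acquisition target cell count per well.
#' @param max_fields Maximum fields of view acquired per well.
#' @param min_cells_per_field Below this per-field cell count a field is
#'   "sparse".
#' @param max_sparse_fields Longest tolerated run of consecutive sparse
#'   fields; one more ends acquisition.
#' @param rpkm_min Minimum RPKM for a gene to be considered expressed.
#' @param min_active_duplexes Deconvolution validation rule: a gene is a
#'   hit when at least this many of its four duplexes are active.
#' @param alpha One-tailed t-test significance level for duplex activity.
#' @param ring_width_px Ring expansion (pixels) from the nucleus edge used
#'   to build the whole-cell mask.
#' @param fibre_min_length_px Minimum skeletal length (pixels) for a
#'   detected structure to count as an E-cadherin fibre.
#' @param seed_length,seed_start Seed definition for off-target scanning:
#'   `seed_length` nucleotides starting at 1-based position `seed_start` of
#'   the guide strand (default heptamer at positions 2-8).
#' @param nucleus_min_area_px Minimum connected-component area (pixels)
#'   retained as a nucleus.
#' @param intensity_k Robust threshold multiplier: objects must exceed
#'   median + `intensity_k` * MAD of their channel.
#' @param mask_exclude_nuclei Logical; if `TRUE` the fibre-counting mask is
#'   the dilated ring only, excluding the nuclear footprint itself.
#' @param field_size_px Side length of a (square) synthetic field image.
#' @param min_separation_px Minimum centre-to-centre distance between
#'   synthetic nuclei.
#' @param rng_seed Integer seed recorded with the configuration.
#' @param schema_version Configuration schema version string.
#'
#' @return An object of class `screen_config` (a validated named list).
#' @examples
#' cfg <- screen_config()
#' cfg$fold_high
#' @export
screen_config <- function(fold_high = 1.6,
                          fold_low = 0.2,
                          z_high = 5.16,
                          z_low = 0.036,
                          cv1_min = 0.7,
                          cv2_min = 0.5,
                          low_count_cells = 1500,
                          target_cells = 3000,
                          max_fields = 25,
                          min_cells_per_field = 14,
                          max_sparse_fields = 6,
                          rpkm_min = 1.0,
                          min_active_duplexes = 2,
                          alpha = 0.05,
                          ring_width_px = 8,
                          fibre_min_length_px = 7,
                          seed_length = 7L,
                          seed_start = 2L,
                          nucleus_min_area_px = 20,
                          intensity_k = 4,
                          mask_exclude_nuclei = FALSE,
                          field_size_px = 512L,
                          min_separation_px = 30,
                          rng_seed = 1L,
                          schema_version = "1") {
  cfg <- structure(
    list(
      schema_version = as.character(schema_version),
      fold_high = fold_high, fold_low = fold_low,
      z_high = z_high, z_low = z_low,
      cv1_min = cv1_min, cv2_min = cv2_min,
      low_count_cells = low_count_cells,
      target_cells = target_cells,
      max_fields = as.integer(max_fields),
      min_cells_per_field = as.integer(min_cells_per_field),
      max_sparse_fields = as.integer(max_sparse_fields),
      rpkm_min = rpkm_min,
      min_active_duplexes = as.integer(min_active_duplexes),
      alpha = alpha,
      ring_width_px = ring_width_px,
      fibre_min_length_px = fibre_min_length_px,
      seed_length = as.integer(seed_length),
      seed_start = as.integer(seed_start),
      nucleus_min_area_px = nucleus_min_area_px,
      intensity_k = intensity_k,
      mask_exclude_nuclei = isTRUE(mask_exclude_nuclei),
      field_size_px = as.integer(field_size_px),
      min_separation_px = min_separation_px,
      rng_seed = as.integer(rng_seed)
    ),
    class = "screen_config"
  )
  validate_screen_config(cfg)
}

#' Validate a screen configuration
#'
#' Checks the internal consistency constraints of a [screen_config()]:
#' ordering of the fold and viability cutoffs, positivity of all counts,
#' the identity `low_count_cells == cv2_min * target_cells` linking the LC
#' bin to the raw-count exclusion, and the admissibility of the seed
#' coordinates.
#'
#' @param cfg A `screen_config` object (or a plain named list of the same
#'   shape, e.g. as read back from YAML).
#' @return The validated object, invisibly classed as `screen_config`.
#' @export
validate_screen_config <- function(cfg) {
  stopifnot(is.list(cfg))
  need <- names(formals(screen_config))
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("screen_config missing fields: ", paste(missing, collapse = ", "))
  with(cfg, {
    if (!(fold_low < 1 && 1 < fold_high))
      stop("require fold_low < 1 < fold_high")
    if (!(cv2_min < cv1_min))
      stop("require cv2_min < cv1_min")
    if (!(alpha > 0 && alpha < 1))
      stop("require 0 < alpha < 1")
    counts <- c(low_count_cells, target_cells, max_fields,
                min_cells_per_field, max_sparse_fields,
                min_active_duplexes, seed_length, seed_start)
    if (any(counts <= 0))
      stop("all count-valued fields must be strictly positive")
    if (abs(low_count_cells - cv2_min * target_cells) > 1e-9)
      stop("consistency check failed: low_count_cells must equal ",
           "cv2_min * target_cells (", cv2_min * target_cells, ")")
    if (seed_start + seed_length - 1L > 19L)
      stop("seed window exceeds the 19-nt duplex guide strand")
  })
  structure(cfg, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("screen_config (schema ", x$schema_version, ")\n", sep = "")
  cat(sprintf("  Ecad bins: High >= %.2g-fold, Low <= %.2g-fold (Z audit: %.3g / %.3g)\n",
              x$fold_high, x$fold_low, x$z_high, x$z_low))
  cat(sprintf("  Viability: CV1 >= %.2g, CV2 >= %.2g, LC < %.2g-fold; LC raw < %d cells\n",
              x$cv1_min, x$cv2_min, x$cv2_min, as.integer(x$low_count_cells)))
  cat(sprintf("  Acquisition: target %d cells, max %d fields, sparse < %d cells, run <= %d\n",
              as.integer(x$target_cells), x$max_fields,
              x$min_cells_per_field, x$max_sparse_fields))
  cat(sprintf("  Hit rule: >= %d of 4 duplexes active at one-tailed alpha %.3g; RPKM >= %.2g\n",
              x$min_active_duplexes, x$alpha, x$rpkm_min))
  invisible(x)
}

#' Read and write screen configurations as YAML
#'
#' The configuration is serialized as YAML with its `schema_version` field.
#' On reading, unknown keys are errors (a silently ignored or defaulted
#' threshold would corrupt hit calls downstream), and the full consistency
#' validation is re-run.
#'
#' @param cfg A `screen_config`.
#' @param path File path.
#' @return `read_screen_config()` returns a validated `screen_config`;
#'   `write_screen_config()` returns `path` invisibly.
#' @export
write_screen_config <- function(cfg, path) {
  cfg <- validate_screen_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  validate_screen_config(raw)
}

# Run expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed for a named random substream
#'
#' Hashes the master seed together with any number of key components
#' (plate, well, field, replicate, ...) into a new 32-bit integer seed, so
#' that parts of a simulation can be regenerated independently without
#' replaying the whole random stream.
#'
#' @param seed Master integer seed.
#' @param ... Key components (coerced to character).
#' @return An integer seed in \[0, 2^31).
#' @examples
#' derive_seed(1, "plate", "P01", "rep", 2)
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}
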