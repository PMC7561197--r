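# Image-based Ecad quantification: nuclei segmentation in the Hoechst
# channel, ring-expanded whole-cell mask, fibre detection in the
# E-cadherin channel, and the per-well score
#   Ecad score = total fibres within the cell mask / total cells,
# summed over all fields of the well before dividing.
#
# All intensity thresholds are expressed in robust units (median + k*MAD
# of the field) so that rescaling the detector gain leaves every count
# unchanged.

#' Segment nuclei in the Hoechst channel
#'
#' Robust global threshold (median + k*MAD), hole filling, minimum-area
#' filter, and a watershed split (seeded by the distance map) for touching
#' blobs.
#'
#' @param channel1 Numeric matrix, the nuclei channel.
#' @param cfg A [screen_config()] (`intensity_k`, `nucleus_min_area_px`).
#' @return A list with `labels` (integer label matrix) and `count`.
#' @export
segment_nuclei <- function(channel1, cfg = screen_config()) {
  if (!is.matrix(channel1) || !is.numeric(channel1))
    stop("channel1 must be a numeric matrix")
  thr <- stats::median(channel1) + cfg$intensity_k * stats::mad(channel1)
  mask <- channel1 > thr
  if (!any(mask)) return(list(labels = matrix(0L, nrow(channel1), ncol(channel1)),
                              count = 0L))
  m <- EBImage::Image(mask * 1)
  m <- EBImage::fillHull(m)
  m <- EBImage::opening(m, EBImage::makeBrush(3, shape = "diamond"))
  dm <- EBImage::distmap(m)
  lab <- EBImage::watershed(dm, tolerance = 1.5, ext = 3)
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which(areas >= cfg$nucleus_min_area_px)
  labmat <- EBImage::imageData(lab)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labmat), ncol(labmat))
  nz <- labmat > 0
  out[nz] <- relab[labmat[nz]]
  list(labels = out, count = length(keep))
}

#' Build the ring-expanded whole-cell mask
#'
#' The nucleus footprint is dilated outward by `ring_width_px` pixels
#' (disc structuring element); the union over cells is the whole-cell mask
#' within which fibres are counted. Larger ring widths strictly contain
#' smaller ones. If `cfg$mask_exclude_nuclei` is set, the nuclear
#' footprint itself is removed from the mask (ring-only counting).
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param ring_width_px Ring expansion in pixels (>= 0).
#' @param cfg A [screen_config()].
#' @return Logical matrix mask.
#' @export
build_cell_mask <- function(labels, ring_width_px = NULL,
                            cfg = screen_config()) {
  if (is.null(ring_width_px)) ring_width_px <- cfg$ring_width_px
  if (ring_width_px < 0) stop("ring width must be non-negative")
  nuc <- labels > 0
  if (ring_width_px == 0) {
    mask <- nuc
  } else {
    size <- 2 * ceiling(ring_width_px) + 1
    brush <- EBImage::makeBrush(size, shape = "disc")
    mask <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(nuc * 1), brush)) > 0
  }
  if (cfg$mask_exclude_nuclei) mask <- mask & !nuc
  mask
}

#' Detect E-cadherin fibres in the staining channel
#'
#' Bright structures above the robust threshold (median + k*MAD) are
#' labelled; a connected component is retained as a fibre when its major
#' axis length is at least `fibre_min_length_px` and it intersects the
#' whole-cell mask. The fibre count is the number of retained segments,
#' not their total length.
#'
#' @param channel2 Numeric matrix, the E-cadherin channel.
#' @param mask Logical matrix from [build_cell_mask()], or `NULL` to count
#'   everywhere.
#' @param cfg A [screen_config()].
#' @return Data frame with one row per fibre: `length` (major axis, px)
#'   and centroid `cx`, `cy` (pixels, 0-based).
#' @export
detect_fibres <- function(channel2, mask = NULL, cfg = screen_config()) {
  if (!is.matrix(channel2) || !is.numeric(channel2))
    stop("channel2 must be a numeric matrix")
  thr <- stats::median(channel2) + cfg$intensity_k * stats::mad(channel2)
  bin <- channel2 > thr
  empty <- data.frame(length = numeric(0), cx = numeric(0), cy = numeric(0))
  if (!any(bin)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labmat <- EBImage::imageData(lab)
  n <- max(labmat)
  if (n == 0) return(empty)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1, dimnames = list(NULL, names(mom)))
  len <- mom[, "m.majoraxis"]
  keep <- len >= cfg$fibre_min_length_px
  if (!is.null(mask)) {
    in_mask <- vapply(seq_len(n), function(i) any(mask[labmat == i]), logical(1))
    keep <- keep & in_mask
  }
  data.frame(length = len[keep],
             cx = mom[keep, "m.cx"] - 1,
             cy = mom[keep, "m.cy"] - 1)
}

#' Quantify one field: cell count and in-mask fibre count
#'
#' @param field A `field_image` (see [make_field_image()] /
#'   [read_field_tiff()]).
#' @param cfg A [screen_config()].
#' @return A list with `cell_count`, `fibre_count`.
#' @export
quantify_field <- function(field, cfg = screen_config()) {
  seg <- segment_nuclei(field$nuclei, cfg)
  mask <- build_cell_mask(seg$labels, cfg = cfg)
  fib <- detect_fibres(field$ecad, mask, cfg)
  list(cell_count = seg$count, fibre_count = nrow(fib))
}

#' Well-level Ecad score from per-field quantifications
#'
#' Total fibres across all fields divided by total cells across all fields
#' (sum before divide, so the score is invariant to how cells and fibres
#' are split across fields). Defined as 0 when both totals are 0.
#'
#' @param fields A list of per-field quantifications, each with elements
#'   `cell_count` and `fibre_count` (e.g. from [quantify_field()]).
#' @return The raw Ecad score (fibres per cell).
#' @examples
#' score_well(list(list(cell_count = 40, fibre_count = 20),
#'                 list(cell_count = 20, fibre_count = 10)))  # 0.5
#' @export
score_well <- function(fields) {
  if (length(fields) == 0L) stop("score_well requires at least one field")
  cells <- sum(vapply(fields, `[[`, numeric(1), "cell_count"))
  fibres <- sum(vapply(fields, `[[`, numeric(1), "fibre_count"))
  if (cells < 0 || fibres < 0) stop("negative counts")
  if (cells == 0) {
    if (fibres == 0) return(0)
    stop("fibres detected but zero cells counted")
  }
  fibres / cells
}

#' Emulate the imaging cytometer's field-acquisition rule
#'
#' Fields are consumed in order until (i) the cumulative cell count
#' reaches `target_cells`, (ii) `max_fields` fields have been acquired, or
#' (iii) a run of more than `max_sparse_fields` consecutive sparse fields
#' (fewer than `min_cells_per_field` cells) occurs — whichever comes
#' first.
#'
#' @param field_cells Integer vector of per-field cell counts, in
#'   acquisition order. Must supply at least `max_fields` entries or end
#'   earlier by the other rules.
#' @param cfg A [screen_config()].
#' @return A list with `fields_used`, `total_cells`, and `terminated_by`
#'   in `{"target_reached", "max_fields", "sparse_run"}`.
#' @examples
#' acquire_fields(rep(150, 25))$fields_used  # 20 fields to 3000 cells
#' @export
acquire_fields <- function(field_cells, cfg = screen_config()) {
  if (length(field_cells) == 0L) stop("empty field stream")
  total <- 0
  run <- 0L
  for (i in seq_along(field_cells)) {
    total <- total + field_cells[i]
    run <- if (field_cells[i] < cfg$min_cells_per_field) run + 1L else 0L
    if (total >= cfg$target_cells)
      return(list(fields_used = i, total_cells = total,
                  terminated_by = "target_reached"))
    if (run > cfg$max_sparse_fields)
      return(list(fields_used = i, total_cells = total,
                  terminated_by = "sparse_run"))
    if (i == cfg$max_fields)
      return(list(fields_used = i, total_cells = total,
                  terminated_by = "max_fields"))
  }
  list(fields_used = length(field_cells), total_cells = total,
       terminated_by = "max_fields")
}

#' Quantify a directory of field TIFFs into a well table
#'
#' Consumes TIFFs named `<plate>_<well>_f<index>.tiff`, scores each well
#' by [score_well()] over its fields, and emits the standard well table.
#'
#' @param dir Directory of two-channel field TIFFs.
#' @param layout A `plate_layout` for role annotation.
#' @param cfg A [screen_config()].
#' @return A well-table data frame.
#' @export
quantify_fields_dir <- function(dir, layout, cfg = screen_config()) {
  files <- list.files(dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (!length(files)) stop("no TIFF fields found in ", dir)
  base <- sub("\\.tiff?$", "", basename(files))
  parts <- regmatches(base, regexec("^(.+)_([A-P][0-9]{2})_f([0-9]+)$", base))
  ok <- lengths(parts) == 4L
  if (any(!ok)) stop("unparseable field file name: ", basename(files)[!ok][1])
  info <- data.frame(file = files,
                     plate_id = vapply(parts, `[[`, character(1), 2),
                     well = vapply(parts, `[[`, character(1), 3),
                     stringsAsFactors = FALSE)
  keys <- unique(info[c("plate_id", "well")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- info[info$plate_id == keys$plate_id[i] & info$well == keys$well[i], ]
    quants <- lapply(sub$file, function(f) quantify_field(read_field_tiff(f), cfg))
    lkey <- layout$plate_id == keys$plate_id[i] & layout$well == keys$well[i]
    data.frame(plate_id = keys$plate_id[i], well = keys$well[i],
               role = if (any(lkey)) layout$role[lkey][1] else NA_character_,
               gene_symbol = if (any(lkey)) layout$gene_symbol[lkey][1] else NA_character_,
               duplex_index = NA_integer_,
               cell_count = sum(vapply(quants, `[[`, numeric(1), "cell_count")),
               fov_used = length(quants),
               sparse_terminated = FALSE,
               ecad_raw = score_well(quants),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
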