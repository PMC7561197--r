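# Synthetic two-channel fluorescence fields with exact ground truth.
#
# Channel 1 emulates Hoechst-stained nuclei (Gaussian blobs at
# rejection-sampled centres with a minimum separation); channel 2 emulates
# junctional E-cadherin immunostaining as curvilinear fibre arcs hugging
# the perinuclear ring where cell-cell boundaries sit. The per-well fibre
# total is Poisson(n_cells * lambda). No optics model beyond additive
# background and Gaussian read noise.

#' Generate one synthetic two-channel field image
#'
#' @param n_cells Number of nuclei to place (>= 0).
#' @param lambda Planted mean fibre count per cell (>= 0); the well-level
#'   ground-truth Ecad rate.
#' @param noise Gaussian read-noise standard deviation (intensity units,
#'   images are scaled to \[0, 1\]).
#' @param seed Integer seed; identical seeds give identical images.
#' @param cfg A [screen_config()] supplying field size, minimum nucleus
#'   separation and ring geometry.
#' @return A list of class `field_image` with elements `nuclei` and `ecad`
#'   (numeric matrices in \[0, 1\]), and `truth`: a list with `centres`
#'   (n x 2 matrix, 0-based row/col pixel coordinates), `n_cells`,
#'   `n_fibres` (exact drawn count) and `lambda`.
#' @examples
#' f <- make_field_image(12, lambda = 1, seed = 7)
#' f$truth$n_cells
#' @export
make_field_image <- function(n_cells, lambda, noise = 0.01, seed = 1L,
                             cfg = screen_config()) {
  stopifnot(n_cells >= 0, lambda >= 0)
  sz <- cfg$field_size_px
  with_rng(seed, {
    centres <- place_centres(n_cells, sz, cfg$min_separation_px)
    ch1 <- matrix(0.05, sz, sz)
    ch2 <- matrix(0.05, sz, sz)
    nucleus_r <- 6
    if (n_cells > 0) {
      for (i in seq_len(n_cells))
        ch1 <- splat_gaussian(ch1, centres[i, 1], centres[i, 2],
                              sigma = nucleus_r / 1.8, amp = 0.6)
    }
    n_draw <- if (n_cells > 0 && lambda > 0) stats::rpois(1, n_cells * lambda) else 0L
    n_fibres <- 0L
    if (n_draw > 0) {
      # Fibres hug the perinuclear ring on two radial tiers (at most 2
      # arcs per tier in disjoint semicircular sectors), so distinct
      # drawn fibres stay distinct image structures: tiers are separated
      # radially, sector gaps keep arc ends apart, and at the configured
      # minimum nucleus separation two cells' outer tiers cannot touch.
      # Per-cell fibre counts are therefore capped at 4; ground truth
      # records the drawn count.
      tiers <- c(nucleus_r + 1.5, nucleus_r + 6.5)
      len <- cfg$fibre_min_length_px * 3
      owner <- sample.int(n_cells, n_draw, replace = TRUE)
      per_cell <- pmin(tabulate(owner, n_cells), 4L)
      n_fibres <- sum(per_cell)
      for (i in which(per_cell > 0)) {
        cy <- centres[i, 1]; cx <- centres[i, 2]
        tier_of <- rep_len(1:2, per_cell[i])
        for (t in 1:2) {
          k <- sum(tier_of == t)
          if (k == 0) next
          r <- tiers[t]
          rot <- stats::runif(1, 0, 2 * pi)
          sector <- 2 * pi / k
          for (j in seq_len(k)) {
            arc_px <- min(len, 0.7 * sector * r)
            arc <- arc_px / r
            th <- rot + (j - 0.5) * sector
            tt <- seq(th - arc / 2, th + arc / 2,
                      length.out = max(8L, ceiling(arc_px * 3)))
            ys <- cy + r * sin(tt); xs <- cx + r * cos(tt)
            ch2 <- splat_curve(ch2, ys, xs, amp = 0.45)
          }
        }
      }
    }
    if (noise > 0) {
      ch1 <- ch1 + matrix(stats::rnorm(sz * sz, 0, noise), sz, sz)
      ch2 <- ch2 + matrix(stats::rnorm(sz * sz, 0, noise), sz, sz)
    }
    ch1 <- pmin(pmax(ch1, 0), 1)
    ch2 <- pmin(pmax(ch2, 0), 1)
    structure(list(
      nuclei = ch1, ecad = ch2,
      truth = list(centres = centres, n_cells = as.integer(n_cells),
                   n_fibres = as.integer(n_fibres), lambda = lambda)
    ), class = "field_image")
  })
}

# Rejection-sample n centres in [margin, sz-margin]^2 with pairwise
# distance >= min_sep; errors out when the field cannot hold them.
place_centres <- function(n, sz, min_sep, margin = 16) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  # hard capacity bound: even optimal hexagonal packing cannot exceed this
  capacity <- ceiling(1.2 * ((sz - 2 * margin) / min_sep + 1)^2)
  if (n > capacity)
    stop("cannot place ", n, " nuclei at minimum separation ", min_sep,
         " in a ", sz, "x", sz, " field")
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("cannot place ", n, " nuclei at minimum separation ", min_sep,
           " in a ", sz, "x", sz, " field")
    cand <- stats::runif(2, margin, sz - margin)
    if (placed == 0L ||
        min((pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2) >= min_sep^2) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  colnames(pts) <- c("row", "col")
  pts
}

# Add a 2-D Gaussian bump at (cy, cx) into a local window of img.
splat_gaussian <- function(img, cy, cx, sigma, amp) {
  sz <- nrow(img)
  r <- ceiling(3 * sigma)
  ys <- max(1, floor(cy - r)):min(sz, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(sz, ceiling(cx + r))
  g <- outer(ys - cy, xs - cx, function(dy, dx) exp(-(dy^2 + dx^2) / (2 * sigma^2)))
  img[ys, xs] <- img[ys, xs] + amp * g
  img
}

# Stamp an anti-aliased ~2 px wide curve through the (ys, xs) polyline.
splat_curve <- function(img, ys, xs, amp) {
  sz <- nrow(img)
  keep <- ys > 2 & ys < sz - 1 & xs > 2 & xs < sz - 1
  ys <- ys[keep]; xs <- xs[keep]
  if (!length(ys)) return(img)
  for (dy in -1:1) for (dx in -1:1) {
    w <- amp * exp(-(dy^2 + dx^2) / 1.2)
    iy <- round(ys) + dy; ix <- round(xs) + dx
    idx <- unique(cbind(iy, ix))
    img[idx] <- pmax(img[idx], 0.05 + w)
  }
  img
}

#' Write a field image to a two-page 16-bit TIFF
#'
#' @param field A `field_image` from [make_field_image()].
#' @param path Output TIFF path (page 1 nuclei, page 2 E-cadherin).
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  img <- EBImage::Image(c(t(field$nuclei), t(field$ecad)),
                        dim = c(ncol(field$nuclei), nrow(field$nuclei), 2))
  EBImage::writeImage(img, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-page field TIFF back into a `field_image`
#'
#' @param path TIFF written by [write_field_tiff()].
#' @return A `field_image` without ground truth (`truth = NULL`).
#' @export
read_field_tiff <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) != 3L || d[3] != 2L)
    stop("expected a 2-channel field TIFF, got dimensions ",
         paste(d, collapse = "x"))
  a <- EBImage::imageData(img)
  structure(list(nuclei = t(a[, , 1]), ecad = t(a[, , 2]), truth = NULL),
            class = "field_image")
}
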