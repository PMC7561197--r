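test_that("nuclei segmentation recovers separated nuclei and merges touching ones", {
  f <- make_field_image(12, 0, seed = 2)
  expect_equal(segment_nuclei(f$nuclei, cfg0)$count, 12L)
  blank <- matrix(0.05, 128, 128)
  expect_equal(segment_nuclei(blank, cfg0)$count, 0L)
  expect_error(segment_nuclei(array(0, c(4, 4, 2)), cfg0), "numeric matrix")

  # two nuclei at generous separation segment as 2; at zero separation as 1
  two_at <- function(sep) {
    ch <- matrix(0.05, 128, 128)
    ch <- ecadscreen:::splat_gaussian(ch, 64, 64 - sep / 2, 3.3, 0.6)
    ch <- ecadscreen:::splat_gaussian(ch, 64, 64 + sep / 2, 3.3, 0.6)
    segment_nuclei(ch, cfg0)$count
  }
  expect_equal(two_at(2 * cfg0$min_separation_px), 2L)
  expect_equal(two_at(0), 1L)
})

test_that("cell mask is the ring-dilated nucleus footprint, monotone in width", {
  f <- make_field_image(6, 0, seed = 4)
  seg <- segment_nuclei(f$nuclei, cfg0)
  m0 <- build_cell_mask(seg$labels, 0, cfg0)
  expect_equal(m0, seg$labels > 0)
  m4 <- build_cell_mask(seg$labels, 4, cfg0)
  m8 <- build_cell_mask(seg$labels, 8, cfg0)
  expect_gt(sum(m4), sum(m0))
  expect_true(all(m4[m0]))       # larger width contains smaller
  expect_true(all(m8[m4]))
  expect_error(build_cell_mask(seg$labels, -1), "non-negative")

  # two adjacent nuclei: masks merge once the rings span half the gap
  ch <- matrix(0.05, 160, 160)
  ch <- ecadscreen:::splat_gaussian(ch, 80, 60, 3.3, 0.6)
  ch <- ecadscreen:::splat_gaussian(ch, 80, 100, 3.3, 0.6)
  seg2 <- segment_nuclei(ch, cfg0)
  expect_equal(seg2$count, 2L)
  n_components <- function(mask) max(EBImage::bwlabel(EBImage::Image(mask * 1)))
  expect_equal(n_components(build_cell_mask(seg2$labels, 2, cfg0)), 2L)
  expect_equal(n_components(build_cell_mask(seg2$labels, 18, cfg0)), 1L)
})

test_that("fibre detection matches planted truth and respects the mask", {
  fz <- make_field_image(20, 0, seed = 6)
  expect_equal(quantify_field(fz)$fibre_count, 0L)

  f <- make_field_image(25, 1.0, seed = 42)
  q <- quantify_field(f)
  expect_lte(abs(q$fibre_count - f$truth$n_fibres), 2)

  # planted structures entirely outside the mask are not counted
  ch2 <- matrix(0.05, 256, 256)
  tt <- seq(0, 2, length.out = 60)
  ch2 <- ecadscreen:::splat_curve(ch2, 200 + 10 * sin(tt), 200 + 10 * cos(tt), 0.45)
  mask <- matrix(FALSE, 256, 256)
  mask[1:50, 1:50] <- TRUE
  expect_equal(nrow(detect_fibres(ch2, mask, cfg0)), 0L)
  expect_equal(nrow(detect_fibres(ch2, NULL, cfg0)), 1L)
})

test_that("detection is invariant to detector gain", {
  f <- make_field_image(15, 1.0, seed = 13)
  q1 <- quantify_field(f)
  f2 <- list(nuclei = pmin(f$nuclei * 2, 1), ecad = pmin(f$ecad * 2, 1))
  class(f2) <- "field_image"
  q2 <- quantify_field(f2)
  expect_equal(q1$cell_count, q2$cell_count)
  expect_equal(q1$fibre_count, q2$fibre_count)
})

test_that("well score is sum-before-divide and partition-invariant", {
  expect_equal(score_well(list(list(cell_count = 60, fibre_count = 30))), 0.5)
  expect_equal(score_well(list(list(cell_count = 10, fibre_count = 29),
                               list(cell_count = 50, fibre_count = 1))), 0.5)
  # all-zero fibre fields score 0 (the siCDH1 phenotype)
  expect_equal(score_well(list(list(cell_count = 100, fibre_count = 0))), 0)
  expect_equal(score_well(list(list(cell_count = 0, fibre_count = 0))), 0)
  expect_error(score_well(list()), "at least one field")
})

test_that("acquisition stops at target, field budget, or a sparse run", {
  a <- acquire_fields(rep(150, 25), cfg0)
  expect_equal(a$fields_used, 20L)
  expect_equal(a$terminated_by, "target_reached")
  expect_gte(a$total_cells, cfg0$target_cells)

  expect_equal(acquire_fields(rep(200, 25), cfg0)$fields_used, 15L)

  b <- acquire_fields(rep(100, 30), cfg0)
  expect_equal(b$fields_used, 25L)
  expect_equal(b$terminated_by, "max_fields")

  # 6 consecutive sparse fields are tolerated; the 7th ends acquisition
  s <- acquire_fields(c(rep(5, 10)), cfg0)
  expect_equal(s$fields_used, 7L)
  expect_equal(s$terminated_by, "sparse_run")
  mixed <- acquire_fields(c(rep(5, 6), 100, rep(5, 7), rep(100, 20)), cfg0)
  expect_equal(mixed$terminated_by, "sparse_run")
  expect_equal(mixed$fields_used, 14L)
  expect_error(acquire_fields(integer(0)), "empty field stream")
})

test_that("field TIFFs round-trip through disk", {
  f <- make_field_image(8, 1, seed = 21)
  tf <- tempfile(fileext = ".tiff")
  write_field_tiff(f, tf)
  back <- read_field_tiff(tf)
  expect_equal(dim(back$nuclei), dim(f$nuclei))
  expect_lt(max(abs(back$nuclei - f$nuclei)), 1 / 65535 + 1e-6)
  q1 <- quantify_field(f); q2 <- quantify_field(back)
  expect_equal(q1$cell_count, q2$cell_count)
  expect_equal(q1$fibre_count, q2$fibre_count)
})
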