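test_that("configuration enforces its internal consistency constraints", {
  expect_s3_class(screen_config(), "screen_config")
  # LC identity: cv2_min * target_cells must equal low_count_cells
  expect_equal(cfg0$cv2_min * cfg0$target_cells, cfg0$low_count_cells)
  expect_error(screen_config(low_count_cells = 1400), "consistency")
  expect_error(screen_config(fold_high = 0.9), "fold_low < 1 < fold_high")
  expect_error(screen_config(cv1_min = 0.4), "cv2_min < cv1_min")
  expect_error(screen_config(alpha = 1.2), "alpha")
  expect_error(screen_config(seed_start = 15, seed_length = 7), "seed window")
})

test_that("configuration YAML round-trips and rejects unknown keys", {
  tf <- tempfile(fileext = ".yaml")
  cfg <- screen_config(rng_seed = 99L)
  write_screen_config(cfg, tf)
  back <- read_screen_config(tf)
  expect_equal(unclass(back), unclass(cfg))
  txt <- readLines(tf)
  writeLines(c(txt, "mystery_threshold: 3"), tf)
  expect_error(read_screen_config(tf), "unknown configuration key")
})

test_that("well coordinates convert both ways and reject malformed input", {
  expect_equal(well_to_index("A01"), 0L)
  expect_equal(well_to_index("P24"), 383L)
  expect_equal(index_to_well(well_to_index(c("B03", "H12", "P01"))),
               c("B03", "H12", "P01"))
  all_wells <- index_to_well(0:383)
  expect_equal(well_to_index(all_wells), 0:383)
  expect_error(well_to_index("Q01"), "malformed")
  expect_error(well_to_index("A25"), "column out of range")
  expect_error(index_to_well(384), "out of range")
})

test_that("layout control totals match the published plate designs", {
  p <- plate_layout("primary")
  expect_silent(validate_plate_layout(p))
  tp <- table(p$role)
  expect_equal(as.integer(tp[c("mock", "siCDH1", "siZEB1", "siPLK1")]),
               c(16L, 6L, 6L, 6L))
  expect_equal(sum(p$role == "sample"), 320L)
  d <- plate_layout("deconvolution")
  expect_silent(validate_plate_layout(d))
  td <- table(d$role)
  expect_equal(as.integer(td[c("mock", "siCDH1", "siZEB1", "siPLK1")]),
               c(31L, 13L, 13L, 4L))
})

test_that("well tables round-trip through CSV and validate against layout", {
  scr <- tiny_screen(10)
  lay <- scr$layout
  tab <- scr$replicates[[1]]
  tf <- tempfile(fileext = ".csv")
  write_well_table(tab, tf)
  back <- read_well_table(tf, lay)
  expect_equal(back$ecad_raw, tab$ecad_raw)
  expect_equal(back$cell_count, tab$cell_count)
  expect_equal(back$role, tab$role)
  expect_equal(sum(back$role == "mock"), 16L)

  # header-only file -> empty collection
  writeLines("plate_id,well,cell_count,fov_used,ecad_raw", tf)
  expect_equal(nrow(read_well_table(tf, lay)), 0L)

  # negative count errors citing the offending row
  bad <- tab
  bad$cell_count[3] <- -5
  write_well_table(bad, tf)
  expect_error(read_well_table(tf, lay), "row 3.*negative cell_count")

  # unknown well position
  bad <- tab
  bad$well[1] <- "A01"  # empty corner well, not in the recorded table rows
  bad$plate_id[1] <- "NOPE"
  write_well_table(bad, tf)
  expect_error(read_well_table(bad_path <- tf, lay), "not in the layout")
})

test_that("sequence reader handles FASTA, TSV, T->U and bad input", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">m1", "UAAUACUGCC", ">m2", "ACGUACGUAC",
               ">m3", "GGGCCCAAAU", ">m4", "UUUACGUACG", ">m5", "CAGUCAGUCA"), fa)
  s <- read_sequences(fa)
  expect_length(s, 5)
  expect_named(s, c("m1", "m2", "m3", "m4", "m5"))

  tsv <- tempfile(fileext = ".tsv")
  writeLines("dna\tACGTACGT", tsv)
  expect_equal(unname(read_sequences(tsv)), "ACGUACGU")

  writeLines(c(">a", "ACGX"), fa)
  expect_error(read_sequences(fa), "non-nucleotide")
  writeLines(c(">a", "ACGU", ">a", "ACGU"), fa)
  expect_error(read_sequences(fa), "duplicate")
})

test_that("screen report writing is a bit-exact round trip", {
  tf <- tempfile(fileext = ".csv")
  # empty result -> header-only file
  empty <- data.frame(gene_symbol = character(), filter_trail = character(),
                      stringsAsFactors = FALSE)
  write_screen_report(empty, tf)
  expect_equal(nrow(read_screen_report(tf)), 0L)

  res <- data.frame(
    gene_symbol = sprintf("G%02d", 1:10),
    candidate_class = rep(c("ecad_high", NA), 5),
    fold_ecad = round(seq(0.1, 2.4, length.out = 10), 6),
    cv_bin = rep(c("CV1", "LC"), 5),
    filter_trail = paste0("LC:", rep(c("pass", "fail"), 5),
                          ";ecad_bin:", rep(c("High", "not_evaluated"), 5)),
    stringsAsFactors = FALSE)
  write_screen_report(res, tf)
  back <- read_screen_report(tf)
  expect_equal(back[names(res)], res)
  # the trail column serializes both Ecad and viability flags verbatim
  expect_match(back$filter_trail[1], "LC:pass;ecad_bin:High")
})
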