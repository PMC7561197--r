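test_that("Ecad bins use inclusive printed cutoffs and are exhaustive", {
  expect_equal(bin_ecad(1.6, cfg0), "High")
  expect_equal(bin_ecad(0.2, cfg0), "Low")
  expect_equal(bin_ecad(1.0, cfg0), "NC")
  expect_equal(bin_ecad(1.599, cfg0), "NC")
  expect_equal(bin_ecad(0.201, cfg0), "NC")
  x <- seq(0, 3, by = 0.01)
  expect_true(all(bin_ecad(x, cfg0) %in% c("High", "NC", "Low")))
  expect_error(bin_ecad(-1), "negative")
})

test_that("the candidate cascade applies filters in order with a full trail", {
  # ten genes, one fate each, hand-enumerated expectation
  g <- sprintf("G%02d", 1:10)
  scores <- data.frame(
    plate_id = "P1", well = index_to_well(32 + 0:9), role = "sample",
    gene_symbol = g, duplex_index = 0L,
    cell_count = c(900, 3000, 3000, 3000, 3000, 3000, 3000, 3000, 950, 3000),
    fov_used = c(25, rep(20, 7), 25, 20), sparse_terminated = FALSE,
    ecad_raw = 1,
    fold_ecad = c(2.0, 2.0, 0.1, 1.0, 1.8, 2.2, 0.15, 1.7, 0.1, 1.61),
    fold_count = c(0.3, 1, 1, 1, 1, 1, 1, 1, 0.31, 1),
    z_ecad = 0, stringsAsFactors = FALSE)
  viab <- viability_calls(rbind(scores,
    within(scores[1:4, ], { role <- "mock"; gene_symbol <- NA; fov_used <- c(19, 20, 21, 20)
                            fold_count <- 1; cell_count <- 3000 })), cfg0)
  expr <- data.frame(gene_symbol = g,
                     rpkm = c(5, 5, 5, 5, 0.5, 5, 0.2, 5, 5, 5))
  fam <- mir200_family(cfg0)
  pools <- do.call(rbind, lapply(seq_along(g), function(i)
    make_duplex_set(g[i], "AAUACUG",
                    n_matching = ifelse(i %in% c(6, 8), 1, 0),
                    avoid_seeds = fam$seeds, seed = i)))
  flags <- scan_duplex_table(pools, fam, cfg0)
  out <- primary_candidates(scores, viab, expr, flags, cfg0)

  # hand enumeration:
  # G01 toxic-high  -> LC fail          G02 clean high -> candidate high
  # G03 clean low   -> candidate low    G04 NC         -> dropped at bin
  # G05 high, rpkm 0.5 -> rpkm fail     G06 high + seed -> seed fail
  # G07 low, rpkm 0.2  -> rpkm fail     G08 high + seed -> seed fail
  # G09 toxic-low   -> LC fail          G10 high at 1.61 -> candidate high
  expect_equal(out$candidate,
               c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$candidate_class[c(2, 3, 10)],
               c("ecad_high", "ecad_low", "ecad_high"))
  expect_match(out$filter_trail[1], "^LC:fail")
  expect_match(out$filter_trail[1], "ecad_bin:not_evaluated")
  expect_match(out$filter_trail[4], "ecad_bin:NC;rpkm:not_evaluated")
  expect_match(out$filter_trail[5], "rpkm:fail;seed:not_evaluated")
  expect_match(out$filter_trail[6], "seed:fail$")
  # order-faithfulness: a gene failing early is never evaluated later
  expect_false(grepl("seed:(pass|fail)", out$filter_trail[1]))
  # missing expression entry fails loudly by default
  expect_error(primary_candidates(scores, viab, expr[-2, ], flags, cfg0),
               "missing from expression")
})

test_that("duplex activity needs both significance and the fold threshold", {
  up <- duplex_activity(c(1.9, 2.1, 2.0), c(1.0, 0.95, 1.05), "up", cfg0)
  expect_true(up$active)
  # oracle: equal-variance one-tailed t-test computed independently
  p_oracle <- t.test(c(1.9, 2.1, 2.0), c(1.0, 0.95, 1.05),
                     alternative = "greater", var.equal = TRUE)$p.value
  expect_equal(up$p_value, p_oracle, tolerance = 1e-12)
  expect_lt(up$p_value, 0.05)
  expect_gte(up$mean_fold, cfg0$fold_high)

  # identical to mock: inactive
  null <- duplex_activity(c(1.0, 0.95, 1.05), c(1.0, 0.95, 1.05), "up", cfg0)
  expect_false(null$active)

  # consistent small shift: significant but below the class threshold
  small <- duplex_activity(c(1.30, 1.31, 1.29, 1.30),
                           c(1.00, 1.01, 0.99, 1.00), "up", cfg0)
  expect_true(small$significant)
  expect_false(small$threshold_met)
  expect_false(small$active)

  dn <- duplex_activity(c(0.05, 0.1, 0.08), c(1.0, 0.95, 1.05), "down", cfg0)
  expect_true(dn$active)
  expect_error(duplex_activity(1.0, c(1, 1, 1), "up"), "at least 2")
})

test_that("gene validation applies the at-least-2-of-4 rule monotonically", {
  mk <- function(actives) lapply(1:4, function(i) list(active = i %in% actives))
  expect_false(validate_gene(mk(integer(0)), cfg0)$validated)
  expect_false(validate_gene(mk(1), cfg0)$validated)
  expect_true(validate_gene(mk(c(1, 3)), cfg0)$validated)
  expect_true(validate_gene(mk(1:3), cfg0)$validated)
  expect_true(validate_gene(mk(1:4), cfg0)$validated)
  # monotone: adding an active duplex never un-validates
  for (k in 2:3) {
    base <- validate_gene(mk(1:k), cfg0)$validated
    expect_true(validate_gene(mk(1:(k + 1)), cfg0)$validated >= base)
  }
  expect_error(validate_gene(mk(1)[1:3], cfg0), "exactly 4")
})

test_that("regulator classification splits classes and orders alphabetically", {
  v <- data.frame(
    gene_symbol = c("ZEB1", "APPLE", "CDH1", "BANANA", "NOPE"),
    candidate_class = c("ecad_high", "ecad_high", "ecad_low", "ecad_low", "ecad_high"),
    validated = c(TRUE, TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  regs <- classify_regulators(v)
  expect_equal(regs$negative_regulators, c("APPLE", "ZEB1"))
  expect_equal(regs$positive_regulators, c("BANANA", "CDH1"))
  dup <- rbind(v, data.frame(gene_symbol = "ZEB1", candidate_class = "ecad_low",
                             validated = TRUE))
  expect_error(classify_regulators(dup), "both classes")
  none <- v; none$validated <- FALSE
  expect_equal(lengths(classify_regulators(none)),
               c(negative_regulators = 0L, positive_regulators = 0L))
})

test_that("deconvolution rescues seeded genes only with seed-free support", {
  fam <- mir200_family(cfg0)
  # two ecad_up candidates: SEEDY has 1 seeded duplex and only that duplex
  # active; MULTI has 1 seeded duplex but 3 active duplexes
  truth <- effect_spec(c("SEEDY", "MULTI"), "ecad_up",
                       n_active_duplexes = c(1L, 3L),
                       seed_carrier_duplexes = list(1L, 1L))
  dscr <- make_deconvolution_screen(truth, wells_per_duplex = 3,
                                    noise_sd = 0.05, seed = 8, cfg = cfg0)
  pools <- rbind(
    make_duplex_set("SEEDY", "AAUACUG", 1, avoid_seeds = fam$seeds, seed = 1),
    make_duplex_set("MULTI", "AAUACUG", 1, avoid_seeds = fam$seeds, seed = 2))
  flags <- scan_duplex_table(pools, fam, cfg0)
  cand <- data.frame(gene_symbol = c("SEEDY", "MULTI"),
                     candidate_class = "ecad_high", stringsAsFactors = FALSE)
  out <- run_deconvolution(dscr$wells, cand, flags, cfg0)
  v <- out$verdicts
  expect_false(v$validated[v$gene_symbol == "SEEDY"])
  expect_true(v$validated[v$gene_symbol == "MULTI"])
  expect_true(v$seed_excluded[v$gene_symbol == "SEEDY"])
  expect_false(v$seed_excluded[v$gene_symbol == "MULTI"])
})
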