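test_that("seed extraction takes guide positions 2-8 and validates input", {
  # miRBase v19 mature sequences of the two miR-200 seed groups
  expect_equal(mature_to_seed("UAAUACUGCCUGGUAAUGAUGA", cfg0), "AAUACUG")
  expect_equal(mature_to_seed("UAACACUGUCUGGUAACGAUGU", cfg0), "AACACUG")
  expect_equal(mature_to_seed("TAATACTGCCTGGTAATGATGA", cfg0), "AAUACUG")
  expect_error(mature_to_seed("UAAUAC", cfg0), "shorter than the seed window")

  d <- list(sense = "GCAGUAUUAACGAUCGAUC", antisense = "AAAUACUGCAUCGAUCGUU")
  expect_equal(guide_seed(d, cfg0), "AAUACUG")
  expect_error(guide_seed(list(sense = "ACGU"), cfg0), "missing the antisense")
})

test_that("the bundled miR-200 family yields its two seed groups", {
  fam <- mir200_family(cfg0)
  expect_length(fam$members, 5)
  expect_setequal(fam$seeds, c("AAUACUG", "AACACUG"))
  # every guide built from a family seed is flagged by scan_pool
  d <- make_duplex_set("X", "AACACUG", n_matching = 2,
                       avoid_seeds = fam$seeds, seed = 3)
  fl <- scan_pool("X", d, fam, cfg0)
  expect_equal(fl$matching_duplexes, 1:2)
  expect_equal(fl$matched_family, "miR-200")
  expect_true(fl$exclusion)
})

test_that("pool scanning agrees exactly with the brute-force oracle", {
  fam <- mir200_family(cfg0)
  n_flagged <- 0L
  for (i in 1:400) {
    pool <- random_pool(sprintf("R%03d", i), seed = i)
    expected <- brute_force_scan(pool, fam$seeds)
    got <- scan_pool(pool$gene[1], pool, fam, cfg0)
    expect_identical(got$matching_duplexes, as.integer(expected))
    n_flagged <- n_flagged + length(expected)
  }
  # planted pools across all n_matching levels agree too
  for (nm in 0:4) for (s in fam$seeds) {
    pool <- make_duplex_set("P", s, nm, avoid_seeds = fam$seeds,
                            seed = nm * 7 + 1)
    got <- scan_pool("P", pool, fam, cfg0)
    expect_identical(got$matching_duplexes, as.integer(brute_force_scan(pool, fam$seeds)))
    expect_length(got$matching_duplexes, nm)
  }
  expect_error(scan_pool("X", random_pool("X", 1)[c(1, 1, 2, 3), ], fam),
               "duplicate duplex")
  expect_error(scan_pool("X", random_pool("X", 1)[1:3, ], fam), "exactly 4")
})

test_that("exclusion never fires on seed-free pools", {
  fam <- mir200_family(cfg0)
  for (i in 1:50) {
    pool <- make_duplex_set(sprintf("N%02d", i), "AAUACUG", n_matching = 0,
                            avoid_seeds = fam$seeds, seed = 1000 + i)
    fl <- scan_pool(pool$gene[1], pool, fam, cfg0)
    expect_false(fl$exclusion)
    expect_false(seed_exclusion(fl, "primary", cfg = cfg0))
  }
})

test_that("seed exclusion excludes at pool stage but rescues multi-duplex hits", {
  flag <- list(gene_symbol = "G", matching_duplexes = 1L,
               matched_family = "miR-200")
  # SMARTpool stage: any seed match excludes
  expect_true(seed_exclusion(flag, "primary", cfg = cfg0))
  # deconvolution: only the seeded duplex active -> stays excluded
  expect_true(seed_exclusion(flag, "deconvolution", active_duplexes = 1L,
                             cfg = cfg0))
  # the multi-duplex pattern: seeded duplex plus two seed-free actives
  expect_false(seed_exclusion(flag, "deconvolution",
                              active_duplexes = c(1L, 2L, 3L), cfg = cfg0))
  # two actives but both seeded -> excluded
  flag2 <- list(gene_symbol = "G", matching_duplexes = c(1L, 2L))
  expect_true(seed_exclusion(flag2, "deconvolution",
                             active_duplexes = c(1L, 2L), cfg = cfg0))
  # no seed match: never excluded
  flag0 <- list(gene_symbol = "G", matching_duplexes = integer(0))
  expect_false(seed_exclusion(flag0, "primary", cfg = cfg0))
})
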