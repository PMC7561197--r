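# miRNA seed-sequence off-target analysis: flag siRNA duplexes whose
# guide-strand seed (positions 2-8 by default) is identical to a seed of
# the miR-200 family, and apply the pool-stage exclusion / deconvolution-
# stage rescue logic. Matching is exact string identity over {A,C,G,U};
# no G:U wobble.

#' Extract the seed from a mature miRNA sequence
#'
#' The seed is the `seed_length`-mer starting at 1-based position
#' `seed_start` (canonical heptamer, positions 2-8).
#'
#' @param mature RNA sequence(s) (character vector, `T` accepted and
#'   mapped to `U`).
#' @param cfg A [screen_config()].
#' @return Character vector of seeds.
#' @examples
#' mature_to_seed("UAAUACUGCCUGGUAAUGAUGA")  # "AAUACUG"
#' @export
mature_to_seed <- function(mature, cfg = screen_config()) {
  mature <- toupper(gsub("T", "U", mature, fixed = TRUE))
  end <- cfg$seed_start + cfg$seed_length - 1L
  short <- nchar(mature) < end
  if (any(short))
    stop("sequence shorter than the seed window (need >= ", end, " nt): ",
         paste(mature[short], collapse = ", "))
  substr(mature, cfg$seed_start, end)
}

#' Extract the seed of a duplex guide (antisense) strand
#'
#' @param duplex A list or one-row data frame with `sense` and `antisense`
#'   19-mers (5'->3' RNA).
#' @param cfg A [screen_config()].
#' @return The guide-strand seed heptamer.
#' @export
guide_seed <- function(duplex, cfg = screen_config()) {
  if (is.null(duplex$antisense) || is.na(duplex$antisense[1]) ||
      !nzchar(duplex$antisense[1]))
    stop("duplex record is missing the antisense (guide) strand")
  mature_to_seed(duplex$antisense, cfg)
}

#' Build a seed family from mature miRNA sequences
#'
#' @param family_name Family label (e.g. `"miR-200"`).
#' @param members Named character vector of mature RNA sequences (names
#'   are miRNA identifiers), e.g. from [read_sequences()].
#' @param cfg A [screen_config()].
#' @return A list of class `seed_family`: `family_name`, `members`,
#'   `seeds` (deduplicated seed set).
#' @export
seed_family <- function(family_name, members, cfg = screen_config()) {
  structure(list(
    family_name = family_name,
    members = members,
    seeds = unique(unname(mature_to_seed(members, cfg)))
  ), class = "seed_family")
}

#' The bundled miR-200 family (miRBase v19 mature sequences)
#'
#' Convenience loader for the FASTA shipped with the package
#' (hsa-miR-200a/b/c-3p, hsa-miR-141-3p, hsa-miR-429), whose seeds form
#' the two groups `AAUACUG` and `AACACUG`.
#'
#' @param cfg A [screen_config()].
#' @return A `seed_family`.
#' @export
mir200_family <- function(cfg = screen_config()) {
  path <- system.file("extdata", "mir200_family_mirbase_v19.fasta",
                      package = "ecadscreen", mustWork = TRUE)
  seed_family("miR-200", read_sequences(path), cfg)
}

#' Scan a 4-duplex SMARTpool for family-seed matches
#'
#' @param gene Gene symbol.
#' @param duplexes Data frame with 4 rows (`duplex_index` 1-4, `sense`,
#'   `antisense`).
#' @param families A `seed_family` or list of them.
#' @param cfg A [screen_config()].
#' @return A list of class `seed_flag`: `gene_symbol`,
#'   `matching_duplexes` (integer subset of 1:4), `matched_family`
#'   (character, `NA` if none), `exclusion` (pool-stage flag:
#'   `TRUE` iff any duplex matches).
#' @export
scan_pool <- function(gene, duplexes, families, cfg = screen_config()) {
  if (inherits(families, "seed_family")) families <- list(families)
  if (nrow(duplexes) != 4L)
    stop("scan_pool expects exactly 4 duplexes, got ", nrow(duplexes))
  if (anyDuplicated(duplexes$duplex_index))
    stop("duplicate duplex indices for gene ", gene)
  seeds7 <- vapply(seq_len(4L), function(i)
    guide_seed(duplexes[i, , drop = FALSE], cfg), character(1))
  hit_fam <- rep(NA_character_, 4L)
  for (fam in families) {
    h <- seeds7 %in% fam$seeds & is.na(hit_fam)
    hit_fam[h] <- fam$family_name
  }
  matching <- duplexes$duplex_index[!is.na(hit_fam)]
  structure(list(
    gene_symbol = gene,
    matching_duplexes = as.integer(sort(matching)),
    matched_family = if (length(matching)) stats::na.omit(hit_fam)[1] else NA_character_,
    exclusion = length(matching) > 0L
  ), class = "seed_flag")
}

#' Seed-based exclusion / rescue decision
#'
#' At the SMARTpool (primary) stage a gene with any seed-matching duplex
#' is excluded from Ecad-High candidacy: a single miR-200 mimic in the
#' pool can drive the whole pool's phenotype. At the deconvolution stage
#' the gene is rescued (retained) when at least `min_active_duplexes`
#' duplexes are active of which at least one is seed-free — the pattern by
#' which a gene with one seed-carrying duplex but independent on-target
#' activity survives the filter.
#'
#' @param flag A `seed_flag` from [scan_pool()].
#' @param stage `"primary"` or `"deconvolution"`.
#' @param active_duplexes Integer vector of active duplex indices
#'   (deconvolution stage only).
#' @param cfg A [screen_config()].
#' @return `TRUE` if the gene is excluded, `FALSE` if retained.
#' @export
seed_exclusion <- function(flag, stage = c("primary", "deconvolution"),
                           active_duplexes = integer(0),
                           cfg = screen_config()) {
  stage <- match.arg(stage)
  if (!length(flag$matching_duplexes)) return(FALSE)
  if (stage == "primary") return(TRUE)
  seed_free_active <- setdiff(active_duplexes, flag$matching_duplexes)
  rescued <- length(active_duplexes) >= cfg$min_active_duplexes &&
    length(seed_free_active) >= 1L
  !rescued
}

#' Scan every gene's pool in a duplex table
#'
#' @param duplex_table Data frame with columns `gene`, `duplex_index`,
#'   `sense`, `antisense` (4 rows per gene).
#' @param families A `seed_family` or list of them.
#' @param cfg A [screen_config()].
#' @return Data frame: `gene_symbol`, `n_matching`, `matching_duplexes`
#'   (comma-separated), `matched_family`, `exclusion`.
#' @export
scan_duplex_table <- function(duplex_table, families, cfg = screen_config()) {
  genes <- unique(duplex_table$gene)
  rows <- lapply(genes, function(g) {
    fl <- scan_pool(g, duplex_table[duplex_table$gene == g, ], families, cfg)
    data.frame(gene_symbol = g,
               n_matching = length(fl$matching_duplexes),
               matching_duplexes = paste(fl$matching_duplexes, collapse = ","),
               matched_family = fl$matched_family,
               exclusion = fl$exclusion,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
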