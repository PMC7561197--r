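# Whole-screen simulator: duplicate 384-well plates with planted per-gene
# effect classes and exact ground truth, the study conditions every
# downstream stage is tested against.
#
# Noise model: multiplicative log-normal on Ecad scores and per-field cell
# densities (well data are non-negative and right-skewed; the screen
# reports no noise model of its own). The imaging cytometer is emulated
# per well: fields of ~154 cells (mock) are acquired until the 3000-cell
# target, the 25-field budget, or a sparse run ends acquisition, so mock
# wells need 20 +/- 3 fields, toxic wells exhaust the field budget below
# 1500 cells, and anti-proliferative wells reach target in few fields.

#' Build a table of planted per-gene effect specifications
#'
#' @param gene_symbol Character vector of gene names.
#' @param effect_class One of `"null"`, `"ecad_up"`, `"ecad_down"`,
#'   `"toxic"`, `"anti_proliferative"` (recycled).
#' @param ecad_fold_effect Multiplicative effect on the Ecad score relative
#'   to mock (default by class: 2.0 up, 0.1 down, 1.0 otherwise).
#' @param count_fold_effect Multiplicative effect on cell density relative
#'   to mock (default 0.25 toxic, 1.8 anti-proliferative, 1.0 otherwise).
#' @param n_active_duplexes How many of the 4 deconvolution duplexes carry
#'   the effect (default 4 for regulators, 0 otherwise).
#' @param seed_carrier_duplexes List column (or single integer vector) of
#'   duplex indices carrying a miR-200 family seed; `NULL` for none.
#' @param cfg A [screen_config()]; class invariants are checked against its
#'   thresholds.
#' @return A data frame of effect specifications, one row per gene.
#' @export
effect_spec <- function(gene_symbol,
                        effect_class = "null",
                        ecad_fold_effect = NULL,
                        count_fold_effect = NULL,
                        n_active_duplexes = NULL,
                        seed_carrier_duplexes = NULL,
                        cfg = screen_config()) {
  n <- length(gene_symbol)
  effect_class <- rep_len(effect_class, n)
  bad <- !effect_class %in% c("null", "ecad_up", "ecad_down", "toxic",
                              "anti_proliferative")
  if (any(bad)) stop("unknown effect class: ", paste(unique(effect_class[bad]), collapse = ", "))
  if (is.null(ecad_fold_effect))
    ecad_fold_effect <- c(null = 1, ecad_up = 2.0, ecad_down = 0.1,
                          toxic = 1, anti_proliferative = 1)[effect_class]
  if (is.null(count_fold_effect))
    count_fold_effect <- c(null = 1, ecad_up = 1, ecad_down = 1,
                           toxic = 0.25, anti_proliferative = 1.8)[effect_class]
  if (is.null(n_active_duplexes))
    n_active_duplexes <- ifelse(effect_class %in% c("ecad_up", "ecad_down"), 4L, 0L)
  ecad_fold_effect <- rep_len(ecad_fold_effect, n)
  count_fold_effect <- rep_len(count_fold_effect, n)
  n_active_duplexes <- as.integer(rep_len(n_active_duplexes, n))
  if (is.null(seed_carrier_duplexes)) seed_carrier_duplexes <- vector("list", n)
  if (!is.list(seed_carrier_duplexes))
    seed_carrier_duplexes <- rep(list(seed_carrier_duplexes), n)
  up <- effect_class == "ecad_up"
  if (any(up & ecad_fold_effect < cfg$fold_high))
    stop("ecad_up genes must have ecad_fold_effect >= fold_high")
  dn <- effect_class == "ecad_down"
  if (any(dn & ecad_fold_effect > cfg$fold_low))
    stop("ecad_down genes must have ecad_fold_effect <= fold_low")
  tox <- effect_class == "toxic"
  if (any(tox & count_fold_effect >= cfg$cv2_min))
    stop("toxic genes must have count_fold_effect < cv2_min")
  ap <- effect_class == "anti_proliferative"
  if (any(ap & (count_fold_effect <= 1 |
                ecad_fold_effect <= cfg$fold_low |
                ecad_fold_effect >= cfg$fold_high)))
    stop("anti_proliferative genes need count_fold_effect > 1 and a no-change Ecad effect")
  out <- data.frame(gene_symbol = gene_symbol, effect_class = effect_class,
                    ecad_fold_effect = ecad_fold_effect,
                    count_fold_effect = count_fold_effect,
                    n_active_duplexes = n_active_duplexes,
                    stringsAsFactors = FALSE)
  out$seed_carrier_duplexes <- seed_carrier_duplexes
  out
}

# lognormal multiplicative noise with unit median
lnoise <- function(n, sd) if (sd > 0) exp(stats::rnorm(n, 0, sd)) else rep(1, n)

# Emulate per-well acquisition from a constant underlying field density:
# returns fov_used, cell_count, sparse flag under the target/max/sparse
# stopping rules.
simulate_acquisition <- function(density, cfg) {
  density <- max(0, density)
  per_field <- round(density)
  if (per_field < cfg$min_cells_per_field) {
    fov <- min(cfg$max_fields, cfg$max_sparse_fields + 1L)
    return(list(fov_used = fov, cell_count = per_field * fov,
                sparse = TRUE))
  }
  fov_target <- ceiling(cfg$target_cells / max(per_field, 1L))
  fov <- min(cfg$max_fields, fov_target)
  list(fov_used = as.integer(fov), cell_count = per_field * fov,
       sparse = FALSE)
}

#' Simulate a duplicate-plate siRNA screen with known ground truth
#'
#' Generates the well tables of a screen run on duplicate plates: mock
#' wells drawn from the null distribution, control wells expressing their
#' class phenotypes (siZEB1 Ecad-up, siCDH1 raw Ecad score exactly 0,
#' siPLK1 toxic), and sample wells expressing their planted
#' [effect_spec()] multiplicatively on the mock means with log-normal
#' noise.
#'
#' @param genes An [effect_spec()] data frame.
#' @param layout_type `"primary"` or `"deconvolution"`.
#' @param noise_sd Log-normal noise standard deviation (log scale) on
#'   Ecad scores.
#' @param count_noise_sd Log-normal noise sd on per-well cell density;
#'   the default reproduces the mock wells' observed field-of-view
#'   statistics (20 +/- 3.1 fields to reach the target count).
#' @param seed Integer master seed; per-plate/replicate substreams are
#'   derived deterministically.
#' @param mock_ecad Mock-well mean raw Ecad score (fibres/cell).
#' @param mock_density Mock-well median cells per field, calibrated so
#'   that under the count noise the simulated mock wells average 20
#'   fields of view to the 3000-cell target, the observed mock behaviour.
#' @param plate_bias_sd Optional per-plate multiplicative bias (log-sd);
#'   default 0 (no batch structure).
#' @param cfg A [screen_config()].
#' @return A list with `replicates` (list of two well tables), `layout`,
#'   and `truth` (the effect-spec table with plate/well assignment).
#' @export
make_screen <- function(genes, layout_type = "primary", noise_sd = 0.1,
                        count_noise_sd = 0.18, seed = 1L, mock_ecad = 0.5,
                        mock_density = 154, plate_bias_sd = 0,
                        cfg = screen_config()) {
  layout <- assign_genes(genes$gene_symbol, type = layout_type)
  validate_layout_capacity(genes, layout)
  m <- match(layout$gene_symbol, genes$gene_symbol)
  plates <- unique(layout$plate_id)
  reps <- lapply(1:2, function(rep_i) {
    tabs <- lapply(plates, function(p) {
      sub <- layout[layout$plate_id == p, ]
      sub_m <- match(sub$gene_symbol, genes$gene_symbol)
      with_rng(derive_seed(seed, "plate", p, "rep", rep_i), {
        n <- nrow(sub)
        bias <- if (plate_bias_sd > 0) exp(stats::rnorm(1, 0, plate_bias_sd)) else 1
        ecad_fold <- rep(NA_real_, n)
        count_fold <- rep(NA_real_, n)
        ecad_fold[sub$role == "mock"] <- 1
        count_fold[sub$role == "mock"] <- 1
        ecad_fold[sub$role == "siZEB1"] <- 2.5
        count_fold[sub$role == "siZEB1"] <- 1
        ecad_fold[sub$role == "siCDH1"] <- 0     # raw score exactly 0
        count_fold[sub$role == "siCDH1"] <- 1
        ecad_fold[sub$role == "siPLK1"] <- 1
        count_fold[sub$role == "siPLK1"] <- 0.25
        smp <- sub$role == "sample" & !is.na(sub_m)
        ecad_fold[smp] <- genes$ecad_fold_effect[sub_m[smp]]
        count_fold[smp] <- genes$count_fold_effect[sub_m[smp]]
        keep <- !is.na(ecad_fold)
        sub <- sub[keep, ]
        ecad_fold <- ecad_fold[keep]; count_fold <- count_fold[keep]
        nk <- nrow(sub)
        ecad_raw <- mock_ecad * bias * ecad_fold * lnoise(nk, noise_sd)
        ecad_raw[ecad_fold == 0] <- 0
        density <- mock_density * bias * count_fold * lnoise(nk, count_noise_sd)
        acq <- lapply(density, simulate_acquisition, cfg = cfg)
        data.frame(
          plate_id = sub$plate_id, well = sub$well, role = sub$role,
          gene_symbol = sub$gene_symbol,
          duplex_index = ifelse(sub$role == "sample", 0L, NA_integer_),
          cell_count = vapply(acq, `[[`, numeric(1), "cell_count"),
          fov_used = vapply(acq, `[[`, numeric(1), "fov_used"),
          sparse_terminated = vapply(acq, `[[`, logical(1), "sparse"),
          ecad_raw = ecad_raw,
          stringsAsFactors = FALSE
        )
      })
    })
    do.call(rbind, tabs)
  })
  truth <- genes
  gm <- match(genes$gene_symbol, layout$gene_symbol)
  truth$plate_id <- layout$plate_id[gm]
  truth$well <- layout$well[gm]
  list(replicates = reps, layout = layout, truth = truth)
}

validate_layout_capacity <- function(genes, layout) {
  n_slots <- sum(!is.na(layout$gene_symbol))
  if (n_slots < nrow(genes))
    stop("more genes (", nrow(genes), ") than available sample wells (",
         n_slots, ")")
  invisible(TRUE)
}

#' Simulate the deconvolution validation screen for candidate genes
#'
#' Each candidate gene's four duplexes are screened individually with
#' `wells_per_duplex` replicate wells on deconvolution-layout plates.
#' Exactly `n_active_duplexes` duplexes (lowest indices first, always
#' including any seed-carrier duplex) express the gene's Ecad effect; the
#' rest behave as null.
#'
#' @param truth An [effect_spec()] table for the candidate genes.
#' @param wells_per_duplex Replicate wells per individual duplex.
#' @inheritParams make_screen
#' @return A list with `wells` (one well table; mock wells included per
#'   plate) and `truth`.
#' @export
make_deconvolution_screen <- function(truth, wells_per_duplex = 3L,
                                      noise_sd = 0.1, count_noise_sd = 0.18,
                                      seed = 1L, mock_ecad = 0.5,
                                      mock_density = 154,
                                      cfg = screen_config()) {
  lay1 <- plate_layout("deconvolution", "D01")
  slots_per_plate <- sum(lay1$role == "sample")
  jobs <- expand.grid(duplex_index = 1:4, rep = seq_len(wells_per_duplex),
                      gene = truth$gene_symbol, stringsAsFactors = FALSE)
  jobs <- jobs[order(match(jobs$gene, truth$gene_symbol),
                     jobs$duplex_index, jobs$rep), ]
  n_plates <- ceiling(nrow(jobs) / slots_per_plate)
  rows <- list()
  for (p in seq_len(n_plates)) {
    pid <- sprintf("D%02d", p)
    lay <- plate_layout("deconvolution", pid)
    take <- jobs[((p - 1) * slots_per_plate + 1):min(p * slots_per_plate, nrow(jobs)), ]
    well_rows <- with_rng(derive_seed(seed, "deconv", pid), {
      ctrl <- lay[lay$role != "sample" & lay$role != "empty", ]
      nc <- nrow(ctrl)
      ecad_fold <- c(mock = 1, siZEB1 = 2.5, siCDH1 = 0, siPLK1 = 1)[ctrl$role]
      count_fold <- c(mock = 1, siZEB1 = 1, siCDH1 = 1, siPLK1 = 0.25)[ctrl$role]
      ctrl_ecad <- mock_ecad * ecad_fold * lnoise(nc, noise_sd)
      ctrl_ecad[ecad_fold == 0] <- 0
      ctrl_density <- mock_density * count_fold * lnoise(nc, count_noise_sd)
      tm <- match(take$gene, truth$gene_symbol)
      active <- mapply(function(di, gi) {
        carriers <- truth$seed_carrier_duplexes[[gi]]
        act <- unique(c(carriers, setdiff(1:4, carriers)))[seq_len(truth$n_active_duplexes[gi])]
        di %in% act
      }, take$duplex_index, tm)
      g_ecad_fold <- ifelse(active, truth$ecad_fold_effect[tm], 1)
      g_count_fold <- ifelse(active, truth$count_fold_effect[tm], 1)
      ns <- nrow(take)
      smp_ecad <- mock_ecad * g_ecad_fold * lnoise(ns, noise_sd)
      smp_ecad[g_ecad_fold == 0] <- 0
      smp_density <- mock_density * g_count_fold * lnoise(ns, count_noise_sd)
      smp_wells <- lay$well[lay$role == "sample"][seq_len(ns)]
      density <- c(ctrl_density, smp_density)
      acq <- lapply(density, simulate_acquisition, cfg = cfg)
      data.frame(
        plate_id = pid,
        well = c(ctrl$well, smp_wells),
        role = c(ctrl$role, rep("sample", ns)),
        gene_symbol = c(rep(NA_character_, nc), take$gene),
        duplex_index = c(rep(NA_integer_, nc), take$duplex_index),
        cell_count = vapply(acq, `[[`, numeric(1), "cell_count"),
        fov_used = vapply(acq, `[[`, numeric(1), "fov_used"),
        sparse_terminated = vapply(acq, `[[`, logical(1), "sparse"),
        ecad_raw = c(ctrl_ecad, smp_ecad),
        stringsAsFactors = FALSE
      )
    })
    rows[[p]] <- well_rows
  }
  list(wells = do.call(rbind, rows), truth = truth)
}

#' Generate a 4-duplex siRNA set with controlled seed-sequence content
#'
#' Builds four 19-mer duplexes (sense + antisense) for one gene in which
#' exactly `n_matching` guide (antisense) strands carry `family_seed` at
#' the configured seed positions; the remaining guides are verified
#' seed-free against every seed in `avoid_seeds` by exhaustive substring
#' check at the seed window.
#'
#' @param gene Gene symbol.
#' @param family_seed Heptamer RNA seed to plant (e.g. `"AAUACUG"`), or
#'   `NULL` for none.
#' @param n_matching How many of the four guides carry the seed (0-4).
#' @param avoid_seeds Seeds the unseeded guides must not carry (defaults
#'   to `family_seed`).
#' @param seed RNG seed.
#' @param cfg A [screen_config()] supplying seed coordinates.
#' @return A data frame with columns `gene`, `duplex_index`, `sense`,
#'   `antisense`.
#' @export
make_duplex_set <- function(gene, family_seed = NULL, n_matching = 0L,
                            avoid_seeds = family_seed, seed = 1L,
                            cfg = screen_config()) {
  if (n_matching < 0L || n_matching > 4L)
    stop("n_matching must be between 0 and 4")
  if (!is.null(family_seed)) {
    family_seed <- toupper(gsub("T", "U", family_seed, fixed = TRUE))
    if (nchar(family_seed) != cfg$seed_length)
      stop("family_seed must be ", cfg$seed_length, " nt")
  } else if (n_matching > 0L) {
    stop("n_matching > 0 requires a family_seed")
  }
  bases <- c("A", "C", "G", "U")
  with_rng(seed, {
    guides <- character(4)
    for (i in 1:4) {
      repeat {
        g <- paste(sample(bases, 19, replace = TRUE), collapse = "")
        if (i <= n_matching) {
          substr(g, cfg$seed_start, cfg$seed_start + cfg$seed_length - 1L) <- family_seed
          break
        }
        win <- substr(g, cfg$seed_start, cfg$seed_start + cfg$seed_length - 1L)
        if (!win %in% avoid_seeds) break
      }
      guides[i] <- g
    }
    data.frame(
      gene = gene, duplex_index = 1:4,
      sense = vapply(guides, rna_revcomp, character(1), USE.NAMES = FALSE),
      antisense = guides,
      stringsAsFactors = FALSE
    )
  })
}

# reverse complement of an RNA string
rna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

#' Generate a synthetic RPKM expression table
#'
#' Exactly `floor(frac_low * N)` genes receive an RPKM drawn below 1
#' (uniform on (0.01, 1)); the remainder draw log-normal values >= 1.
#'
#' @param genes Character vector of gene symbols.
#' @param frac_low Proportion of genes below the RPKM = 1 expression
#'   filter.
#' @param seed RNG seed.
#' @return Data frame with columns `gene_symbol`, `rpkm`.
#' @export
make_expression_table <- function(genes, frac_low = 0.1, seed = 1L) {
  if (frac_low < 0 || frac_low > 1) stop("frac_low must be in [0, 1]")
  n <- length(genes)
  n_low <- floor(frac_low * n)
  with_rng(seed, {
    low_idx <- if (n_low > 0) sample.int(n, n_low) else integer(0)
    rpkm <- 1 + stats::rlnorm(n, meanlog = 1.5, sdlog = 1)
    if (n_low > 0) rpkm[low_idx] <- stats::runif(n_low, 0.01, 0.999)
    data.frame(gene_symbol = genes, rpkm = rpkm, stringsAsFactors = FALSE)
  })
}
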