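---
title: "Methods: quantifying and screening membrane-associated E-cadherin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and screening membrane-associated E-cadherin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecadscreen)
```

## The problem

In *APC*-mutant colorectal cancer cells such as SW480, E-cadherin is
largely absent from cell-cell junctions, and restoring it suppresses the
tumourigenic phenotype. A genome-wide siRNA screen can ask which genes
control the amount of E-cadherin held at the membrane: knock every gene
down one at a time, immunostain E-cadherin, and quantify the junctional
signal per well. `ecadscreen` implements the full analysis chain for such
a screen — image quantification, plate normalization, viability
filtering, sequence-level off-target exclusion, and duplex-level
validation — together with a synthetic-data generator that stands in for
the raw plates and images, so every stage can be tested against known
ground truth.

## The Ecad score

Each well is imaged in two channels: Hoechst-stained nuclei and
E-cadherin immunostaining. Junctional E-cadherin appears as elongated
"fibres" along cell-cell boundaries, and the phenotype is scored as

> **Ecad score** = total number of E-cadherin fibres detected within the
> whole-cell mask of a well / total number of cells in that well.

The implementation (`segment_nuclei()`, `build_cell_mask()`,
`detect_fibres()`, `score_well()`) follows the classical high-content
recipe:

1. **Nuclei**: robust global threshold at `median + k * MAD` of the
   nuclei channel (`intensity_k`, default 4), hole filling, a
   minimum-area filter (`nucleus_min_area_px`, default 20 px), and a
   distance-map watershed to split touching nuclei. Expressing the
   threshold in robust units makes every count invariant to detector
   gain: doubling all intensities doubles the median and the MAD and
   leaves the segmentation unchanged (this is a tested property).
2. **Whole-cell mask**: the nucleus footprint dilated outward by
   `ring_width_px` (default 8 px) with a disc structuring element — the
   "ring expansion" used by imaging cytometers to approximate the cell
   body without a membrane marker. The mask is monotone in the ring
   width. Whether the nuclear footprint itself is excluded from fibre
   counting is configurable (`mask_exclude_nuclei`, default `FALSE`,
   i.e. the full dilated mask counts).
3. **Fibres**: bright structures above the robust threshold in the
   E-cadherin channel are labelled as connected components; a component
   is a fibre when its major-axis length is at least
   `fibre_min_length_px` (default 7 px) and it intersects the cell mask.
   The *count of retained segments* — not their total length — is the
   fibre quantity, because the score is defined as a number of fibres
   per cell. We use component-level length filtering rather than a
   ridge-filter/skeletonization chain: on images in scope (thin,
   non-crossing junctional arcs) the two agree, the component route has
   no tuning parameters beyond the length threshold, and it is exactly
   testable against planted ground truth. The operator set is recorded
   in the configuration so alternatives can be swapped.
4. **Score**: fibres and cells are summed across all fields of a well
   *before* dividing, so the score is invariant to how cells are
   partitioned across fields, and a well with zero cells and zero fibres
   scores 0 (the knockdown-of-*CDH1* phenotype is exactly 0).

## Field acquisition

The imaging cytometer does not take a fixed number of fields: it acquires
until a target cell count is reached. `acquire_fields()` emulates the
rule set: stop when cumulative cells reach `target_cells` (3000), or
after `max_fields` (25) fields, or when more than `max_sparse_fields`
(6) *consecutive* fields each hold fewer than `min_cells_per_field` (14)
cells. At a typical mock density of ~150 cells/field the target is
reached in 20 fields; wells that exhaust all 25 fields with fewer than
1500 cells are the "low count" wells of the viability filter. The number
of fields used is itself informative: wells that reach target unusually
fast contain knockdowns that *increase* proliferation.

## Normalization

Screens run on duplicate plates. The cascade
(`average_replicates()` → `fold_vs_mock()` → `robust_z()`, wrapped by
`gene_scores()`) is:

1. **Replicate averaging** on *raw* values (cell counts and Ecad
   scores), before any normalization; mock means are then taken from the
   averaged table.
2. **Intra-plate**: every well's Ecad score and cell count are divided
   by the arithmetic mean of the same plate's mock wells, so mock folds
   average exactly 1 per plate and plate-to-plate staining differences
   cancel.
3. **Inter-plate**: a robust Z-score over the mock-normalized folds,
   `z = (x - median) / (1.4826 * MAD)`, computed over *all library
   sample wells of the screen pooled* (controls excluded). Folds are
   already plate-normalized, so a single screen-wide reference
   population is the right scale; per-plate Z would re-estimate scale
   from ~320 wells and add noise. A zero MAD (degenerate synthetic
   input) is an error with guidance, never a silent division by zero.
   Median ties use the standard midpoint convention.

Candidate selection operates on the *fold* cutoffs (High at >= 1.6-fold
of mock, Low at <= 0.2-fold); the equivalent robust-Z cutoffs (5.16 and
0.036) are carried in the configuration and reported alongside for
audit. The workflow treats the two as equivalent descriptions of the
same boundary; the folds are the operative rule here because they are
anchored directly to the control phenotypes (siZEB1-like and
siCDH1-like) and do not depend on the library's dispersion. Both printed
cutoffs are read inclusively, so a well at exactly 1.6 or exactly 0.2 is
in its bin.

## Viability and proliferation

Cell-count folds are binned into CV1 (>= 0.7), CV2 (>= 0.5 and < 0.7)
and LC (< 0.5); the three bins partition the non-negative folds.
LC wells — equivalently, fewer than 1500 cells after the full 25-field
budget, since 0.5 x 3000 = 1500 (an identity the configuration
validator enforces) — mark **pro-survival** genes and are excluded from
regulator candidacy. CV1 and CV2 genes are both retained: the published
workflow states only that LC is excluded, and down-weighting CV2 would
discard replicable intermediate-toxicity regulators.

**Anti-proliferative** genes are called from acquisition speed: the
fast-growth cutoff is two standard deviations below the mock mean field
count, `fov_cutoff()` returning `ceiling(mean - 2*sd)`. With the mock
statistics of a primary screen (mean 20, sd 3.13 fields) this gives 14,
i.e. the "fewer than 15 fields" rule. We use `ceiling` rather than
`floor(x) + 1`: the two agree everywhere except when `mean - 2*sd` is an
exact integer, where `ceiling` keeps the cutoff *at* that integer — a
well exactly 2 SD fast is called fast. A gene is anti-proliferative only
if it also shows no E-cadherin change (NC bin); a regulator phenotype
takes precedence, and pro-survival and anti-proliferative are mutually
exclusive by construction.

## Seed-sequence off-target exclusion

The miR-200 family (miR-200a/b/c, miR-141, miR-429) represses ZEB1 and
thereby raises E-cadherin. An siRNA duplex whose guide strand happens to
carry a miR-200 **seed** (guide positions 2-8; the two family seed
groups are `AAUACUG` and `AACACUG`) can phenocopy that effect on target
genes it never touches. `scan_pool()` flags any 4-duplex SMARTpool
containing such a guide, by exact string identity at the seed window
(no G:U wobble — the filter implements sequence *identity*). The seed
coordinates are configurable (`seed_start`, `seed_length`) so the
hexamer-2-7 variant can be tested, since the vendor tool that originally
performed this scan is unpublished; positions 2-8 are the canonical
choice. The bundled miRBase v19 mature sequences are a replaceable FASTA
fixture.

Exclusion logic (`seed_exclusion()`):

* **Pool stage**: any seed-carrying duplex excludes the gene from
  Ecad-High candidacy — one miR-200 mimic among four duplexes is enough
  to drive the pooled phenotype.
* **Deconvolution stage**: the gene is *rescued* when at least
  `min_active_duplexes` (2) duplexes are independently active and at
  least one of them is seed-free — the pattern of a genuine regulator
  that happens to contain one seeded duplex.

The filter is applied to Ecad-High candidates only: seed-driven
repression of ZEB1 inflates High scores specifically, and the published
workflow describes the scan in that context.

## Deconvolution and hit calling

Candidates surviving the cascade (LC exclusion → Ecad bin → RPKM >= 1
expression filter → seed exclusion) are re-screened with each of their
four duplexes individually. `duplex_activity()` calls a duplex active
when **both**:

1. a one-tailed unpaired Student's t-test of its replicate folds against
   the mock folds (in the candidate's direction) gives p < 0.05, and
2. its mean fold clears the class threshold (>= 1.6 up, <= 0.2 down),

so a consistent but tiny shift never validates. Welch's test is
available via a flag; the default is the equal-variance Student form. No
multiple-testing correction is applied at the duplex stage — the
at-least-2-of-4 replication rule (`validate_gene()`) is the error
control, and it is monotone: adding an active duplex can never
un-validate a gene. Validated Ecad-High genes are **negative
regulators** of E-cadherin, validated Ecad-Low genes **positive
regulators**; each gene carries an ordered filter trail proving which
cascade step decided its fate (a gene failing an early filter is never
evaluated by a later one).

Genes missing from the expression table are an error by default
(`missing_expression = "keep"` opts out): silently passing an unmeasured
gene through an expression filter would corrupt the candidate list.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is verified.

**Field images** (`make_field_image()`): nuclei are Gaussian blobs at
rejection-sampled centres with a minimum separation (default 30 px in a
512 x 512 field, standing in for a 20x field of view); fibres are
anti-aliased arcs hugging a perinuclear ring, with the per-well total
drawn as Poisson(cells x lambda). Each cell's fibres occupy disjoint
angular sectors on two radial tiers, so distinct drawn fibres stay
distinct image structures and the planted count is an exact oracle for
the detector; per-cell counts are capped at 4 (the cap is recorded in
the ground truth, which always equals what was actually drawn). Additive
Gaussian read noise and a flat background complete the model.
Deliberately *not* modelled: point-spread blur, uneven illumination,
vignetting, debris, crossing or branching fibres, and cytoplasmic
background staining. Passing image tests therefore show the detector is
correct on clean junctional geometry, not that it is robust to every
real-world artefact — the robust thresholds transfer, but real screens
should verify the length threshold against their own optics.

**Screens** (`make_screen()`): 384-well plates in duplicate with the
published control layouts (primary: 16 mock and 6 each
siCDH1/siZEB1/siPLK1 per plate; deconvolution: 31 mock, 13 each
siCDH1/siZEB1, 4 siPLK1). Mock wells draw from the null distribution;
siCDH1 wells have raw score exactly 0; siPLK1 wells are toxic. Sample
wells express planted per-gene effects (`effect_spec()`) —
`ecad_up` (default fold 2.0), `ecad_down` (0.1), `toxic` (count fold
0.25), `anti_proliferative` (count fold 1.8), or null —
multiplicatively on the mock mean. Noise is multiplicative log-normal
(well data are non-negative and right-skewed; the original screen
reports no noise model): sd 0.1 on Ecad scores, and sd 0.18 on per-well
cell density. The density noise and the mock density (154 cells/field)
are calibrated once against the published mock acquisition statistics —
20 +/- 3.1 fields of view to reach 3000 cells — so that the simulated
viability and proliferation calls face realistic dispersion; they were
not revisited afterwards. Plate-to-plate batch structure is off by
default (`plate_bias_sd = 0`) because the original screen reports none;
the hook exists for robustness experiments. All generators are pure
functions of (specification, seed), with per-plate and per-well
substreams derived by hashing (`derive_seed()`), so any part of a screen
can be regenerated independently.

**Sequences and expression** (`make_duplex_set()`,
`make_expression_table()`): 4-duplex siRNA sets with an exact,
brute-force-verifiable number of seed-carrying guides, and RPKM tables
with an exact floor(frac_low x N) low-expression subset.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale: image
recovery uses 50 wells x 2 fields x 25 cells (about one minute), the
end-to-end recovery screen uses 200 genes (10 up at fold 2.0, 10 down at
0.1, 5 toxic, 5 anti-proliferative, 170 null; duplicate plates; 3 wells
per duplex in deconvolution), and the seed matcher is checked against a
brute-force oracle on 1000 random pools. The genome-scale funnel counts
of a real screen (hundreds of candidates from ~18,000 genes) depend on
that screen's unreleased raw data and are not reproduced here; the
package's claims are the property-level ones above.

Conventions: well coordinates are letter row + 1-based column ("B03");
internal well indices are 0-based row-major; pixel coordinates are
0-based (row, col). CSVs are comma-separated, UTF-8, "." decimal. The
configuration serializes to YAML with a schema version, and unknown keys
are errors, not warnings — a silently defaulted threshold would corrupt
hit calls.

## Known limitations

* The fibre detector counts connected components; fibres that genuinely
  cross or touch in real images would merge. At the fibre densities in
  scope (lambda <= 2 per cell) the planted-recovery error is within
  +/- 2 fibres per field.
* The per-gene primary screen places one SMARTpool well per replicate
  plate; spatial (edge/drift) effects are not modelled or corrected
  (no B-score/loess), matching the published workflow.
* The seed filter knows only the miR-200 family; genome-wide 3'UTR
  target prediction is out of scope.
* The deconvolution screen of the original study was run at higher cell
  density and passage to widen the Ecad dynamic range; here that is at
  most a parameter difference (noise, effect sizes) since no
  quantitative change was published.
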