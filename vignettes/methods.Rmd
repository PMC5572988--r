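---
title: "ctcscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctcscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcscope)
```

## Overview

ctcscope models an *enrichment-free* approach to circulating tumour cell
(CTC) detection: every nucleated cell recovered from a blood sample is
deposited on slides, stained with DAPI (nucleus), cytokeratin (CK,
epithelial cytoplasm) and CD45 (leukocyte membrane) plus an optional
fourth marker channel, imaged, and classified cell by cell. CTC candidates
are the rare DAPI(+) cells that fail the CD45 leukocyte gate. Because no
physical enrichment step discards cells, the analytical questions are
questions about a *detector*: how many deposited cells are recovered, how
linear is enumeration across spike-in levels, how often does a
leukocyte-only slide produce a false CTC, and how repeatable is the count
across tests, runs and operators.

The package contains six cooperating modules:

1. **synth** — a synthetic slide generator with per-cell ground truth,
2. **segment** — nucleus detection and per-cell feature extraction,
3. **classify** — an auditable rule base over five CTC subtypes plus
   cluster detection and per-slide enumeration,
4. **validate** — the analytical-validation statistics and study designs,
5. **biomarker** — fourth-channel quantitation, two-colour FISH counting
   with PTEN/CEP10 status calls, and windowed copy-number profiles,
6. **report / CLI** — study drivers, structured JSON/CSV reports, and a
   thin command-line interface (`inst/scripts/ctcscope`).

All statistical and design choices below are the package's own; parameter
defaults are stated with units and every threshold is user-settable.

## The synthetic slide model

### Desk scale

A physical slide in this workflow carries on the order of $3\times10^6$
nucleated cells. Rendering that many cells is pointless for a testable
model, so a "slide" is represented by a single tile at a reduced scale:
by default a $1600\times1600$ px tile at 0.8 µm/px (10X-class sampling)
carrying 5000 white blood cells (WBCs). The ratio
$3\times10^6/\texttt{wbc\_count}$ is recorded as `scale_factor` in every
slide's metadata, and all reported statistics (percent recovery, percent
CV, $r^2$, specificity) are scale-free ratios, so they do not depend on
the absolute background count. The test suite uses smaller tiles again
(down to $384^2$) for structural checks; those sizes are runtime choices,
not model parameters.

### Appearance model

Cells are rendered hard-edged and then passed through a single optical
model per channel:

* **Nuclei** are near-circular ellipses (eccentricity ≤ 0.15). WBC nuclear
  diameters are drawn from a truncated normal, mean 8 µm (SD 0.8); tumour
  cell-line control (CLC) nuclei mean 14 µm (SD 1.2); the *small* subtype
  mean 6.8 µm, at or below the WBC population.
* **Cytoplasmic / membrane markers** (CK, CD45, M4) are rendered as full
  discs of radius nucleus + `ring_width` (2.5 µm): a cell's marker signal
  surrounds and overlaps its nucleus, as in a stained cell.
* **PSF**: each channel is convolved once with a Gaussian of
  $\sigma = 0.8$ µm (truncated at $3\sigma$).
* **Noise**: Poisson shot noise on the blurred signal plus background
  (100 counts/channel), plus Gaussian read noise (SD 5).
* Per-cell amplitudes vary log-free with a 10 % coefficient of variation
  around channel means (DAPI 500, CK 400, CD45 350 above background).

Subtypes are rendered from their *definitions*: traditional CLCs are
CK+/CD45− with large intact nuclei; small CLCs identical but with
WBC-sized nuclei; clusters are rigid chains of 2–5 traditional cells
placed in contact (3 µm nuclear gaps, inside merged cytoplasm);
CK-negative CLCs carry no CK signal; apoptotic CLCs have either a
*fragmented* nucleus (2–5 fragments of radius 1.6–2.0 µm on a ring inside
the cytoplasm, kept pairwise separated so each survives as its own
connected component) or a *condensed* nucleus (area shrunk to 0.35× the
typical WBC nuclear area with a 3.2× DAPI amplitude).

Two acellular confounders exercise specificity: CK-positive debris (discs
with no nucleus) and sub-cellular DAPI speckle (0.6 µm dots below the
minimum nuclear area).

### Deposition and spiking

Each nominally deposited WBC is retained with probability
`deposition_retention` (default 0.88, a typical measured recovery of this
kind of deposition process); the observed nucleated-cell recovery of the
pipeline therefore reproduces that benchmark. Spiking supports three
modes: `deterministic` (exactly `n_clc` CLCs — a verified spike count;
this is the mode used for linearity), `binomial` and `poisson` (retention
thins the spike).

Placement is random–sequential with pairwise clearances enforced through
a spatial hash: CLCs receive full cytoplasm clearance from every other
object (so marker halos never bleed across a classification boundary),
while WBC halos may touch — harmless, because cluster calls only consider
CTC-classified cells. A packing-feasibility bound (total effective
footprint ≤ 55 % of the tile) turns impossible densities into a typed
`ctcscope_density_error` instead of an endless rejection loop.

Determinism: every slide is generated under a child seed derived from the
master seed and the slide index; identical (config, `n_clc`, index) gives
bit-identical rasters without touching the caller's RNG state.

## Segmentation

The DAPI channel is smoothed (Gaussian, 1 µm), thresholded with global
Otsu *floored* at background median + 5 MADs (so blank rasters yield no
foreground), hole-filled, and declumped with a distance-transform
watershed (tolerance 1.6 µm). Apoptotic nuclear fragments are then
regrouped: connected components with area ≤ 20 µm² that fall within a
12 µm grouping radius of each other *and* share the same connected
CK-positive cytoplasm component are unioned into one cell. Groups below
the 12 µm² minimum nuclear area are dropped (this is what removes DAPI
speckle).

Features per cell: area, equivalent diameter, convex-hull solidity
(pixel-corrected, clamped to 1), fragment count, and background-
subtracted channel means — DAPI over the nucleus, markers over a
cytoplasm *ring* built by dilating each nucleus by 2 µm and clipping
against neighbours with a nearest-nucleus partition. Background is the
per-channel median outside all dilated cells; its MAD provides the
pixel-noise floor used by the gates. The ring partition's 8-connectivity
adjacency also yields the touching-cell graph used for cluster detection.

## Classification

All gates are *slide-internal*: the WBC population on the same slide is
the null. A provisional CD45 gate (CD45 mean above half the upper-
quartile level and above 5× the pixel-noise floor) collects the WBC
reference population; at least `min_wbc` (100) CD45+ cells are required,
otherwise a typed reference failure is raised. From the reference:

* CK+ : CK ring mean > WBC CK level + 5 MADs,
* CD45+ : CD45 ring mean > the derived CD45 threshold (negative-population
  median + 5 MADs, capped at half the WBC median),
* intact : single fragment, solidity ≥ 0.85, and not condensed,
* condensed : nuclear area ≤ 0.85 × WBC median area *and* DAPI mean ≥
  1.4 × WBC median,
* small : equivalent diameter ≤ the WBC median diameter.

The rule table, in order: CD45+ → **WBC**; CK+ and not intact →
**apoptotic CTC**; CK+ and intact → **traditional** or **small CTC** by
size; CK−, CD45−, intact → **CK-negative CTC**; anything else →
**unclassified**. Calls are a pure function of the stored boolean gates
(`call_from_gates()`), so every call is auditable from the gate record.

**Why 0.85 / 1.4 for the condensed gate?** At 0.8 µm/px with a ~1 px PSF,
the Otsu mask of a small bright nucleus inflates roughly twofold in area
while its mean intensity dilutes correspondingly. The intuitive factors
("half the area, twice the brightness") describe the *pre-optics* object,
not its image: measured contrasts of a condensed nucleus at this sampling
are 0.67–0.80× area and 1.6–1.8× mean DAPI. The brightness conjunct does
the discriminating (normal-brightness cells sit about 4 SD below 1.4× at
the 10 % amplitude CV), and 0.85 leaves the area conjunct a > 3 SD margin
on both sides instead of splitting the condensed population. CD45+ cells
are gated to WBC before intactness is consulted, so this gate cannot
affect specificity.

**Clusters** are connected components of the touching-cytoplasm graph
restricted to CTC-called cells, with ≥ 2 members and at least one
traditional CTC. Cluster members keep their subtype counts and the
cluster count is reported alongside, so either counting convention can be
derived. `enumerate_slide()` guarantees the partition invariant: WBC +
four subtypes + unclassified always sums to the nucleated-cell count.

## Validation statistics

* `percent_recovery()`: $100\,\cdot$ observed / nominal nucleated cells.
* `fit_linearity()`: unweighted OLS of per-slide detected CLCs on nominal
  concentration; $r^2$ is the squared Pearson correlation; ≥ 3 distinct
  levels are required. The standard design is 6 slides at each of 6, 12,
  25, 50, 100 and 300 CLCs/slide.
* `ctc_per_ml()`: the enumeration unit is a *test* of two replicate
  slides; CTC/mL = summed count / (2 × `ml_per_slide`), default
  10 mL / 12 slides.
* `precision_study()`: four %CVs per dilution from test-level CTC/mL
  values under the standard design (three operators; five runs in total —
  the reference operator on three days, the other two once each; three
  tests per run): intra-assay (reference operator's first run),
  inter-assay (all tests), intra-operator (reference operator's three
  runs), inter-operator (each operator's first run). Incomplete designs
  raise a typed error naming every gap.
* `specificity_summary()`: total CTC-subtype calls over unspiked slides.

## Biomarker modules

**FISH.** `count_fish_signals()` is a scale-normalized
Laplacian-of-Gaussian blob detector: local maxima of the LoG response
inside the nuclear mask above a robust prominence threshold (out-of-mask
median + 8 MADs), with greedy non-maximum suppression at one spot
diameter. Spots closer than about $2\sigma$ merge — the detector's stated
resolution limit. PTEN status versus the CEP10 reference: 0 PTEN signals
= homozygous loss, PTEN < CEP10 = heterozygous loss, otherwise
non-deleted; CEP10 > 2 flags polyploidy; a cell with zero signals in both
colours is uncountable (NA), not a loss call.

**CNV.** `cnv_profile()` depth-normalizes per-window read counts (100 kb
fixed windows, 0-based half-open) by library size and reports
$\log_2$ sample/control per window; zero-control windows are NA, zero-
sample windows $-\infty$. `call_gene_amplification()` averages the finite
ratios of windows overlapping the gene and calls amplification at ≥ +1
(one extra doubling). The profile is invariant to sequencing depth by
construction.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(tile_shape = c(512, 512), wbc_count = 300, seed = 7)
s <- generate_slide(cfg, n_clc = 10)
res <- enumerate_slide(s$slide)
res$counts

vs <- run_validation_study(cfg, concentrations = c(3, 6, 12),
                           slides_per_concentration = 2, n_unspiked = 2)
vs$linearity$r_squared
```

## Limitations

* The generator is a geometric phantom: no tissue autofluorescence,
  uneven illumination, focus drift, staining batch effects, or imaging
  -plane artifacts. Specificity results measure the pipeline's behaviour
  on the modelled confounders (acellular CK debris, DAPI speckle) only.
* Wet-lab variability (pipetting, deposition CV across operators) is not
  modelled; the precision machinery is validated against its statistical
  definitions, not against laboratory CV magnitudes.
* The classifier is intentionally a transparent rule base, not a trained
  model; it presumes the slide-internal WBC population is large enough to
  serve as its own null (`min_wbc`).
* Cluster placement renders compact chains; sprawling or overlapping 3-D
  clusters are out of scope.
* FISH counting resolves spots separated by more than ~2 spot sigmas;
  tighter doublets undercount by design.
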