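---
title: "Quantifying polarity-protein dependencies from internally controlled imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polarity-protein dependencies from internally controlled imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Comparing fluorescence intensities *between strains* is one of the least
reliable measurements in cell biology: lamp intensity, camera settings,
mounting, media and temperature all drift between acquisitions, and any of
them can masquerade as a biological effect. The assay `poldep` implements
removes these nuisances by construction: wild-type cells carrying a red
spindle-pole-body (SPB) tag are mixed on the same coverslip with deletion
cells lacking the tag, so every field of view contains its own control.
Each GFP-tagged polarity marker is imaged in each deletion background; every
deletion cell is compared only with wild-type cells *from the same image*,
and only ratios of background-corrected intensities ever leave a field.
This is the internal-control property the package preserves end to end: a
global rescaling of any field changes no normalised value, effect size or
call (it is enforced as an exact test).

The biology behind the screen: fission yeast grows from its cell tips.
Microtubules deliver a tip complex (Tea1, Tea2, Tea4, Tip1, Mal3), Mod5
anchors it at the membrane, the formin For3 nucleates actin cables, and the
myosin-V Myo52 transports cargo along them; together they control NETO, the
switch from monopolar to bipolar growth. Deleting one component and
quantifying another's distribution, over all marker x deletion pairs, gives
a genetic dependency matrix and, from it, a signed regulatory network.

## The synthetic-data generator

The simulator produces the same raw data the microscope would: two-channel
stacks of 31 z-slices spaced 0.2 µm, with pixel-size metadata, written as
multi-page float TIFFs (or kept in memory). It exists so that every
downstream stage is testable against known ground truth; it is not a
mechanistic model of microtubule or motor biology.

Forward model, per field:

* **Geometry.** Cells are capsules ("stadium" profiles) with interphase
  dimensions: length uniform in 7–14 µm, width 3.5 µm; the poles are the
  extreme points of the rounded caps. Cells are placed by rejection
  sampling (up to 500 attempts per cell), keeping masks ≥ 2 µm apart and
  ≥ 1.5 µm from the field border. The clearance mirrors the analysable
  cells of a sparse mount: a 3 µm measurement disc centred on a tip needs
  roughly its own radius of free space to measure one cell and not its
  neighbour.
* **Photometry.** Amplitudes are areal photon densities (photons/µm² of
  projected cell), so rendered intensities are independent of pixel size.
  GFP = a uniform cytosolic plateau (default 1.5e4) plus isotropic Gaussian
  tip spots (σ 0.45 µm, brighter-tip peak 5e5) at the two poles; the
  dimmer-tip amplitude is `β` times the brighter one, with `β` drawn per
  cell from a Beta distribution whose mean is the bipolarity parameter
  (default 0.5, precision 8) — the population is a mix of pre-NETO
  (monopolar) and post-NETO (bipolar) cells. Per-cell expression
  variability is log-normal (sdlog 0.2 overall, 0.1 per compartment).
  Control cells additionally carry 1 or 2 red SPB puncta (σ 0.25 µm
  lateral, 0.3 µm axial, peak 6e5) near mid-cell; deletion cells have no
  red signal.
* **Ground-truth effects.** A deletion's phenotype is three positive
  multipliers on the deletion cells' baseline end/cytosol amplitudes plus
  an additive shift of the bipolarity parameter. Presets: `"null"` (all 1),
  `"literature"` (a qualitative encoding of the headline dependencies, e.g.
  polar Tip1 up without Myo52, polar Tea1 down without Tea2), and
  `"planted"` (a recovery benchmark: 20 affected matrix entries at
  multipliers 0.5/1.5 plus three −0.4 bipolarity shifts).
* **Optics and camera.** Each channel is blurred laterally with a Gaussian
  PSF (σ 0.15 µm; separable banded-matrix convolution, border photons
  truncated, never re-normalised, so blur is strictly linear), distributed
  over z with a chord-thickness profile (GFP; the cell is a 3.5 µm cylinder
  lying on the coverslip) or a narrow Gaussian (red SPB), then per voxel:
  Poisson shot noise, Gaussian read noise (σ 2 counts) and a constant
  camera offset (10 counts). Each term switches off independently, which
  gives exact noise-free images for the conservation and background
  oracles. The per-voxel step is compiled (a ziggurat normal sampler and
  PTRS Poisson over one `mt19937_64` stream per field) because a
  study-scale run draws ~10⁹ voxels.
* **Determinism.** All randomness flows from one master seed through
  documented sub-seeds (`subseed(seed, stage, index)`); a field's geometry,
  amplitudes and noise reproduce exactly, independently of processing
  order, and identical (design, seed) pairs give byte-identical annotation
  tables.

What the generator deliberately does **not** emulate: septating or bent
cells (septation exists only as a QC heuristic tested on painted fixtures),
photobleaching, stage drift, chromatic offsets between channels,
out-of-field light, or any mechanistic microtubule/motor dynamics — effects
are phenomenological multipliers. Tests passing on these synthetics
therefore validate the *measurement and inference chain*, not the ability
to segment difficult real micrographs.

## The quantification chain

`quantify_field()` mirrors the manual bench protocol:

1. **Maximum projection** over the 31 z-slices, per channel (exact
   per-pixel max; checked against a brute-force loop).
2. **Segmentation.** Pixels above 1.8 x the image median (the robust
   background level of a sparse field) form the mask; closing then opening
   with a 3-px disc removes speckle, holes are filled. A fixed
   median-multiple is used instead of a two-class (Otsu) split because a
   field can legitimately contain two cytosolic brightness classes — e.g.
   a deletion that halves the marker's cytosolic pool — and a two-class
   threshold then lands *between* them and silently drops most deletion
   cells, biasing the internal control. Components too large to be one
   cell are split by a watershed on the distance map (touching rods neck
   at their contact); splitting every component instead would fragment dim
   rods at the shallow necks their own bright tip bulbs create.
3. **Rod QC.** Length gate 5.5–18 µm (the mask includes the blur halo, so
   the gate is wider than the true 7–14 µm), aspect ≥ 1.5, width ≤ 5 µm,
   no border contact, and a septum heuristic (a transverse intensity ridge
   at mid-cell along the spine profile). Every excluded cell carries an
   explicit flag; per field, segmented = analysed + excluded.
4. **Poles.** Initial poles are the extremal mask pixels along the
   principal axis; each is then re-centred on the local maximum of the
   3 x 3-smoothed projection within 1.2 µm. The mask extreme sits at the
   tip of the blur halo, ~1 µm beyond the cell end and dependent on tip
   brightness; the tip signal itself is the anchor a human would centre an
   ROI on. Refined poles land within 0.5 µm of ground truth.
5. **Genotype.** A cell is `control` if its brightest in-mask red pixel
   reaches 5 x the median red background, `deletion` below 3 x, `ambiguous`
   between (excluded). Hysteresis makes the call robust to single noisy
   pixels; accuracy on default-noise synthetics exceeds 99 %.
6. **ROIs.** Mean and max intensity in 3 µm-diameter discs (radius rounded
   to the nearest pixel, so results are bit-stable for a given pixel size)
   at each refined pole and at the mask centroid; the cytosol disc drops
   pixels above its own 90th percentile first (the "non-foci" rule, a
   deterministic surrogate for the experimenter avoiding bright puncta).
   Discs with less than 80 % of their area in-image exclude the cell. The
   background is the mean of the candidate cell-free disc (≥ 1 µm from
   every mask) with minimal intensity variance — deterministic, ties to
   the first candidate in row-major order; fields with no cell-free disc
   are rejected with a warning. All values are recorded raw and
   background-corrected; **End1** is the end with the brighter corrected
   mean, and the bipolarity index is corrected End2/End1 clamped to [0, 1]
   (0 when End1 ≤ 0).

## Statistics

* **Normalisation.** Within each field, every cell's corrected compartment
  values are divided by the mean over that field's control cells; control
  cells are normalised by their own mean, so the control average is exactly
  1 per field. Fields with no usable control (none present, or a
  non-positive control mean) are dropped with a warning.
* **Matrix entries.** Per (marker, deletion, compartment):
  `rel_diff = mean(deletion)/mean(control) − 1` on normalised values, and a
  two-sided Welch t-test on log-transformed values — intensity ratios are
  right-skewed, and the log scale makes the test a test of fold change.
  Non-positive normalised values (possible for dim markers after
  background correction) cannot enter the log test and are counted in
  `n_dropped`. Arms under 100 analysed cells are flagged `underpowered`,
  never silently dropped.
* **Calling.** Benjamini–Hochberg across all entries jointly (error control
  over the whole matrix, ~243 tests in the default design);
  `increase`/`decrease` requires `q ≤ α` (default 0.05) *and*
  `|rel_diff| ≥ 0.10`. The minimum-effect gate keeps trivially small but
  highly significant differences out of the network. Because "End1 = the
  brighter end" selects a maximum of two noisy values, null calibration is
  always run through the full pipeline including End assignment, not on
  ideal Gaussians; the selection bias cancels between co-imaged arms.
* **NETO calls.** Per pair, a rank-based (Wilcoxon) comparison of the
  per-cell bipolarity index between arms, BH-adjusted across pairs;
  `shifted` requires `q ≤ α`. The bipolar/monopolar dichotomy at index
  ≥ 0.5 is reported as a descriptive summary only — the distribution test
  drives the call. Note the measured index compresses towards 1 relative
  to the true tip-amplitude ratio because the end disc also contains
  cytosolic signal; since both arms compress identically this does not
  affect the test.
* **Matrix statistic.** Whether the original analysis used the disc mean
  or max is not recorded; both are measured and carried through, and the
  matrix statistic is configurable (`statistic = "mean"` by default —
  means are better behaved under Poisson noise in a maximum projection).

## Network and loop taxonomy

Edges run deletion → marker. A polar `decrease` call (either end; two-end
conflicts resolved by the larger `|rel_diff|`, both calls kept in the
`basis` field) gives sign `+` — the upstream protein is *required* for
polar localisation; an `increase` gives `−` — the upstream protein *limits*
polar accumulation. Cytosol-only calls never create polar edges. NETO
`shifted` flags are carried on matching edges.

Two-protein loops classify by their sign pair: `(+,+)` positive
amplification, `(−,−)` negative reduction, `(+,−)` direct unidirectional.
Longer cycles are enumerated by rooted depth-first search — each simple
cycle explored only from its lexicographically smallest node, so it is
reported exactly once in canonical rotation, regardless of edge order
(checked exhaustively against a permutation brute force on all graphs up to
six nodes). The overall feedback sign is the product of edge signs
(negative iff the count of negative edges is odd); loops whose edges are
*all* positive are flagged separately, matching the convention that a
"positive loop" is an all-positive-edge cycle. On the curated reference
edge set shipped in `inst/extdata/` (loader: `reference_edges()`), the
three all-positive cycles each contain Tea1 — the hub of the polarity
network. The reference set is deliberately partial (it covers what the
published text states, not the full figure), and two of the five edges of
the large negative loop carry signs inferred only from that loop's overall
negative sign, as noted in the fixture's `evidence` column.

## Numerical and design choices

* Pixel size defaults to 0.1 µm/px (typical 100x/1.45 NA camera sampling)
  and is configurable everywhere; the `"scaled"` profile (0.2 µm/px,
  256-px fields, 13 cells/field) is used for study-scale simulations,
  trading lateral sampling for throughput at unchanged z-sampling.
* The test suite and the acceptance script size their simulations as
  follows, as the package's own benchmark conditions: unit tests run on
  192–256-px fields of 5–13 cells; the study-scale benchmark is the full
  9 x 10 grid at 116 planned cells per arm (≈ 18,800 planned, ≥ 18,000
  analysed after the ~2–3 % QC exclusion rate); the null calibration
  sub-samples 400 30-cell entries from the unaffected combinations.
* Float TIFF pages hold only [0, 1]; stacks are stored as
  `(x − offset)/scale` with both constants in the manifest (read noise can
  push a few counts below zero) and restored on read to float32 precision.
* Ties: background-ROI candidates tie to the first in row-major order;
  ROI refinement ties to `which.max`'s first index; both make
  quantification fully deterministic for a given image.
* `alpha` above 0.1 is accepted with a warning; configuration errors are
  collected and reported together with field names, never partially
  defaulted.

## Known limitations

* Segmentation is tuned to rod-shaped interphase cells on synthetic
  backgrounds; bent, T-shaped or dividing cells are excluded by QC rather
  than handled, and real micrographs with debris or uneven illumination
  will need parameter adjustment (`quantify_params()`).
* The effect model is per-combination multipliers: no cell-cycle
  dependence, no interaction between markers, no partial-penetrance
  mixtures.
* The bipolarity index saturates for very bright cytosol (tip discs
  contain cytosolic signal), so absolute index values should not be
  compared across markers with very different tip-to-cytosol ratios; the
  within-pair shift test is unaffected.
* Edge signs summarise polar compartments only; cytosolic (stability)
  effects appear in the matrix but not in the network by default.
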