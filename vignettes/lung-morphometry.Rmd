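---
title: "Quantifying terminal air-space development from micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying terminal air-space development from micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmorph)
```

## The measurement problem

In contrast-stained micro-CT of a developing lung, soft tissue is rendered
bright (phosphotungstic acid or iodine staining) and the gas-filled lumen
dark. From such a volume one wants four quantities per specimen: the lung
volume $V_L$, the volume $V_A$ and surface area $S_A$ of the *terminal*
air spaces (the gas-exchanging compartment distal to the conducting
airways), and the characteristic air-space diameter and septum thickness
from line-intercept morphometry. Followed across age groups, these numbers
trace sacculation and alveolarization: terminal air spaces become smaller
and more numerous, septa thin, and the surface-to-volume ratio of the
air spaces rises.

`lungmorph` implements that measurement chain: seeded region growing of
the air lumen within a gray-tolerance band; voxel-count volume and
isosurface surface-area estimators with the ROI-subtraction rule
$V_A = V(\text{entire air}) - V(\text{tree})$,
$S_A = S(\text{entire air}) - S(\text{tree})$; fractionator-style
line-intercept stereology; and allometric analysis of the morphometric
table packaged with the package. Because no image data of the original
study are deposited, the 3D stages are validated against a synthetic
developing-lung phantom with voxel-level ground truth, plus analytic
calibration shapes.

## Segmentation model

The region grower accepts a voxel if and only if it is connected to the
seed (trachea centre) through voxels whose gray value lies in
$[c - t, c + t]$, where $t$ is the tolerance (default 1100, the centre of
the 1000--1200 range the original workflow used on 16-bit data) and $c$ is
the band centre. Two deliberate choices:

* **Band centre.** $c$ defaults to the median gray of the $3^3$
  neighbourhood of the seed rather than the single seed voxel. A human
  operator picks a representative air value; a single voxel draws from the
  noise distribution, and an unlucky draw shifts the whole band by several
  noise SDs. An explicit `seed_gray` overrides this.
* **Connectivity.** Face connectivity (6) by default, so that growth
  cannot slip diagonally through a one-voxel corner of a thin septum.

Tolerance misconfiguration on real data floods the background; the guard
limit (`max_voxels`) turns that into a distinct leak error rather than a
silently absurd mask. After growth, only the seed-connected component is
kept (`exclude_external_air`, the automated counterpart of visually
excluding gut gas and other air), and isolated interior voxels that noise
pushed out of the band are filled (`fill_noise_voxels`): a non-air voxel
with five or six of its face neighbours in air cannot be a wall, because
resolvable septa are at least two voxels thick. Without this step,
single-voxel speckle splits line intercepts and inflates the measured
surface area.

The tree/terminal boundary is an anatomical judgement, not an image
property, so `split_tree_terminal` requires it as input: the phantom truth
tree, or user-supplied boundary voxels at the bronchiole outlets. When an
external tree mask is clipped to the segmented lumen, it is first dilated
by one voxel so that the partial-volume halo along the airway walls is
assigned to the tree, not counted as terminal air.

## Volume, surface and the subtraction rule

Volume is the voxel count times the voxel volume. Surface area defaults to
a triangulated isosurface (marching tetrahedra at iso-level 0.5) of the
indicator smoothed with a one-voxel-SD Gaussian; the raw voxel-face count
is kept as a diagnostic because it overestimates curved surfaces by a
factor approaching 3/2 (the staircase bias — both estimators are reported
against a calibration sphere in the test suite: the isosurface is within
0.5%, the face count near 1.5x). The subtraction rule for $S_A$ is applied
literally, as in the original workflow: it is a bookkeeping difference of
two ROI surfaces, not the geometric surface of the terminal region, and it
is documented as such wherever it is reported.

Units are fixed: micrometres inside the package, mm³/mm² in every output.

## Stereology

The fractionator protocol divides the slice range containing measurable
air spaces into `n_sections = 8` intervals, draws one random start, and
samples every interval at the same offset. On each sampled section a
random test line is cast and the first five air-space and five septum
intercepts along it are measured (more lines are cast if one line does not
supply them), giving 40 intercepts per quantity per lung. An air intercept
is a maximal run of measured air bounded by tissue on both sides; a septum
intercept is a tissue run bounded by measured air on both sides, which
automatically excludes pleural and hilar tissue. By default measurement is
restricted to the terminal air spaces, with conducting-airway lumina
treated as a third class that invalidates any run it borders; a flag
switches to the entire air lumen.

Three numerical choices matter:

* **Line casting is offset-uniform (IUR).** A line through a uniform
  random point with a uniform angle has a triangular perpendicular-offset
  density: it oversamples profiles near the section centre and
  systematically shortens the intercept sample (about 12% on a calibration
  sphere). Drawing the angle uniformly and the perpendicular offset
  uniformly across the section makes the sampling length-unbiased; this is
  the standard stereological test-line construction, and the package uses
  it for measurement and ground truth alike.
* **Sub-voxel sampling with a resolvability floor.** Lines are sampled at
  a quarter of the voxel spacing for chord-length accuracy, and intercepts
  shorter than two voxels are discarded: a grazing line flickers across a
  profile rim and sheds sub-voxel fragments that no observer would record,
  and which otherwise dominate the small-chord tail.
* **Section refocusing.** A section that cannot supply its quota (for
  example one grazing the organ pole) is moved to the nearest workable
  slice, as an operator would refocus; an error is raised only if no slice
  in the interval works.

If a line supplies more than the needed intercepts, the *first* five along
the line are taken, not the five largest, to avoid size selection bias.

## The phantom: what it emulates, and what it does not

`generate_stage_phantom` builds a six-lobe lung (four right, two left, as
in the opossum) as two staggered rings of lobar air sacs fed by a trachea
and per-lobe bronchial tubes, embedded in a contiguous tissue mass.
Septation is modelled as rounds of planar septa of the stage's septum
thickness through each sac's centroid, at random orientation, each pierced
by an aperture so the air remains one connected lumen — the geometric
essence of saccular subdivision without its histology. Rendering assigns
air 5000, tissue 8000 and background 2000 on the 16-bit scale, blurs with
a half-voxel Gaussian (partial volume) and adds Gaussian noise
(SD 400), clipped to $[0, 65535]$.

The gray defaults are chosen so the canonical tolerance band of 1100
around an air seed lands at the midpoint of the blurred air--tissue edge
while tissue remains ~4.75 noise SDs outside the band. A much larger
contrast (tissue near 30000) with the same band would place the
segmentation boundary ~1.7 blur SDs inside the air and provably cap the
achievable overlap with truth (Dice ≤ ~0.91 at noise SD 800), i.e. it
would make the segmentation benchmark unachievable for any algorithm
faithful to the fixed-band rule. The chosen contrast-to-noise ratio (7.5)
is the regime where the published fixed-band workflow is actually usable.

Stage parameters follow the packaged morphometric table: the target mean
intercept diameter and septum thickness per age group, with septation
rounds increasing from 0 (birth: one large sac per lobe, opening directly
from its lobar bronchus) to 4, and voxel spacing chosen per stage so septa
stay at least two voxels (10 µm at birth down to 5 µm at 57 dpn). Because
the mean line intercept of a convex body is $4V/S$ ($= \tfrac{2}{3}d$ for
a sphere), the initial sacs are sized at $1.5\times$ the target intercept,
inflated per septation round by the measured intercept shrink of a round
(exactly $2/3$ for the first centroid split of a sphere, ~0.77 for later
rounds on irregular chambers, with a 0.935 correction for measuring
voxelized geometry under the chord protocol — constants calibrated once on
the generator itself and fixed). Ground-truth diameter and septum are
*defined* as the dense large-sample limit of the same per-section-weighted
intercept protocol, so measurement and truth estimate the same quantity.

What the phantom does **not** emulate: X-ray physics (no
projection/reconstruction — gray values are synthesized directly),
vascular structures, alveolar-duct micro-anatomy, pores of Kohn, curved or
branching septa, stain gradients, and organ-scale growth (later stages are
scaled-down parenchyma specimens, correct in intercept statistics and
topology but not in absolute organ volume). Passing the phantom suite
therefore demonstrates correctness of the measurement chain under the
stated noise/contrast model — not segmentation robustness on pathological
real-world scans.

A note on phantom septum thickness at birth: with zero septation rounds
the only "septa" are the tissue gaps between neighbouring lobar sacs, so
the measured septum intercept at the earliest stages reflects sac spacing
rather than the stage's septum target; from the first septation round
onward the inserted septa dominate. The septum column is therefore used
qualitatively (it decreases across stages) rather than as a recovery
target.

## Sizes and determinism

Default stage phantoms run 2.5–6 million voxels and generate in 4–10 s
each; the full validation (oracle equivalence, calibration shapes,
three-stage recovery, five-stage monotone sweep) completes in about a
minute. All randomness — phantom geometry, rendering noise, fractionator
start, line casting — is governed by explicit integer seeds; a pipeline
run is reproduced bit for bit from its configuration, and the global seed
expands to per-stage seeds by fixed offsets so stages can be re-run
independently.

## The packaged specimen table

`load_table1()` returns the 35-specimen morphometric table (4 late-fetal,
31 postnatal) on which the allometric analysis operates; group rows are
always recomputed, never stored. Two caveats the validation harness makes
explicit:

* Four published summary cells are internally inconsistent under any
  single rounding convention (two septum SDs printed 0 where the
  individuals give 0.58/0.71, one SD printed with a truncated last digit,
  one group mean off by 0.01); `validate_against_table1()` flags exactly
  these and the package reports its recomputed values.
* The published body-mass correlations (0.987/0.915/0.971 for
  $V_L$/$V_A$/$S_A$) are not reproducible from the table's individuals
  under raw or log10 Pearson (which give 0.994/0.977/0.928 and
  0.994/0.992/0.984); the harness computes both conventions and reports
  the disagreement rather than picking whichever looks closer.

```{r}
val <- validate_against_table1()
val$correlations
```

## Worked example

```{r, eval = FALSE}
# a newborn-stage phantom and the full measurement chain
report <- run_pipeline(list(stage = "neonate", seed = 1))
report
```

The report carries the measured $V_L$, $V_A$, $S_A$, the Dice overlap of
the segmented air against truth, the intercept summary (40 diameters, 40
septa) and a manifest of every seed and parameter used. On real volumes,
`read_volume()` + `segment_airspaces()` + `specimen_metrics()` +
`measure_lung()` compose the same chain; TIFF input requires the voxel
spacing explicitly, because every reported quantity depends on it and a
silent default would corrupt all of them.

## Known limitations

* The surface subtraction $S_A$ inherits the original rule's conceptual
  quirk (shared tree/terminal interfaces do not cancel); comparisons with
  geometric surfaces of the terminal region alone should use
  `mask_surface_area(terminal_mask)` directly.
* Region growing is fully 3D; the original vendor workflow may have mixed
  2D growth with manual propagation, which cannot be reproduced exactly.
* With noise SD at its default, about 0.6% of air voxels fall outside the
  tolerance band; hole filling recovers the isolated ones, but clustered
  dropouts near walls remain the main residual error in $V_A$ (1–8%
  across stages).
* The intercept estimator is resolution-floored at two voxels; at 57 dpn
  (5 µm spacing, 51 µm target) the floor truncates roughly the smallest
  percentile of true chords.
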