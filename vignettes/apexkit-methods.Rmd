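---
title: "Methods: quantifying oriented growth and regulatory binding in the shoot apex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying oriented growth and regulatory binding in the shoot apex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexkit)
```

apexkit quantifies early stem development from single-time-point data: it
calls recently formed cell walls and their 3D orientation in segmented
confocal volumes of the shoot apical meristem, compares division-orientation
distributions between meristem zones, aligns and measures clonally marked
sectors across apices, and filters replicate ChIP-seq peaks with a positional
Monte Carlo enrichment test. This vignette explains the models and
procedures, the parameters that matter, and the design choices made where a
published description left the design open.

## Detecting recent divisions from wall-stain intensity

Plant cells place their new wall perpendicular to the mitotic spindle, so a
fixed, stained apex retains a record of recent division orientations:
modified pseudo-Schiff propidium-iodide staining cross-links the dye to wall
polysaccharides, and thinner — newer — walls fluoresce less. Given a 3D
segmentation (a labeled volume) co-registered with the stain channel, the
package:

1. **Extracts facets.** A facet is the full shared interface between two
   6-connected cell labels (faces only; edge/corner contacts do not make a
   wall). All shared voxel faces of a label pair are merged into one facet,
   because two adjacent cells share one biological wall. Per facet we record
   the physical area (sum of per-face areas, honouring anisotropic voxel
   spacing), the area-weighted centroid of face midpoints, and the **signal
   density**: the area-weighted mean, over face elements, of the mean
   intensity of the two flanking voxels. Facets with fewer than
   `min_face_elements = 5` faces are discarded as segmentation noise.
2. **Calls new walls.** A facet is called a new wall when its signal density
   is minimal among the eligible facets of *both* adjacent cells. Facets
   touching the background are never eligible. The rule is rank-based: any
   monotone rescaling of facet densities leaves the call set unchanged. Ties
   within a relative tolerance (`tie_tol`, default `1e-9`, i.e. exact ties)
   call every tied facet; each cell otherwise contributes at most one call.
3. **Measures orientation.** Each facet's best-fitting plane is the total
   least-squares plane of its face midpoints: the normal is the eigenvector
   of the smallest eigenvalue of the centred second-moment matrix. Fits are
   refused (and angles left undefined) below 4 points or when the points are
   essentially collinear.

Both orientation angles are defined on the plane **normal**, folded into
[0°, 90°]:

* **angle to the main axis** — `acos(|n · a|)` with `a` the stem axis. A
  transversal wall (plane perpendicular to the axis, as in the rib meristem)
  scores near 0°; a wall containing the axis scores 90°. The normal-based
  convention is chosen so the rib meristem's transversal walls form a
  distinct low-angle class.
* **radial angle** — `acos(|n · r|)` with `r` the unit radial direction at
  the wall's centre of mass (the component of `centroid − summit` orthogonal
  to the axis). A wall *facing the central axis* (normal radial) scores near
  0°. The angle is undefined (reported `NA`, never 0) within
  `min_radius = 1` µm of the axis, where no radial direction exists.

The reference frame (summit point plus unit axis direction) is supplied per
apex; `estimate_frame()` provides a default (axis from configuration, summit
as the centroid of the topmost tissue voxels). Depth below the summit is
measured axially — `(summit − p) · a` — rather than as Euclidean distance to
the summit; the Euclidean alternative changes region membership only near
the dome shoulder.

## Zonation and distribution comparisons

Three canonical regions partition the apex in depth/radius coordinates
(µm): the apical region AR (depth 0–30, radius 0–40), the rib-meristem core
RC (depth 30–60, radius 0–40) and the rib-meristem periphery RP (depth
30–60, radius 40–50). Windows are half-open `[min, max)` so the shared
boundaries belong unambiguously to the deeper/outer region (the published
region definitions do not state boundary inclusion). Angle values are pooled
across apices per genotype; per-apex summaries remain available by grouping.

Distributions are compared with a two-sided Mann–Whitney U test implemented
in-package: for `min(n1, n2) <= 8` the p-value comes from exact enumeration
of the rank-sum permutation distribution via a dynamic programme over
midranks — exact under ties, where the textbook exact tables do not apply —
and otherwise from the tie-corrected normal approximation with continuity
correction. The two-sided exact p is `min(1, 2·min(P(R ≤ r), P(R ≥ r)))`.
Box summaries use midpoint-interpolated quantiles (R type 5) and 1.5 × IQR
whiskers with explicit outlier lists; the quantile convention is fixed and
documented because boxplot conventions differ between plotting libraries.
No multiple-testing correction is applied across the region × metric grid;
tests are reported raw.

## Clonal sector analysis

Sectors (clones marked by a heat-shock-induced recombination event) are
landmarked manually, one point per cell. Apices are aligned by a rigid
transform only: the summit translates to the origin and the axis rotates
onto +z by the minimal rotation; the azimuth is left untouched because no
azimuthal landmark exists across apices. Per sector we measure the centre
of mass, the principal axis (direction of greatest scatter of the landmark
cloud, sign-folded), the vertical angle to the stem axis, the radial angle
to the radial direction at the centre of mass (undefined within 1 µm of the
axis), the cell count, and the length as the extent of landmark projections
onto the principal axis. Length is projection extent rather than
farthest-pair distance; for elongated sectors the two differ negligibly, and
the choice is recorded here. Growth *rate* is deliberately not computed — a
single time point cannot give one. Projections for display follow the
published convention: a vertical view down the axis, and a radial view in
the plane through each sector's centre of mass and the axis, signed so
left/right placement matches the vertical view.

## Replicate-consensus ChIP-seq peaks and positional enrichment

Peak handling uses narrowPeak (0-based half-open) coordinates throughout;
GFF3 input is converted from 1-based closed on read and back on write.

* **Consensus.** A consensus region is a maximal interval covered by at
  least one peak with q ≤ 10⁻³ in *every* treatment replicate, at least
  50 nt long, and overlapping no control-replicate peak by even 1 nt.
  Controls are used as called, with no q threshold — any called control
  signal disqualifies. The implementation is an endpoint sweep over
  per-replicate merged intervals; the test suite checks it against a
  per-base coverage-mask oracle.
* **Attribution.** A region is attributed to a gene when its *center* lies
  within 3 kb upstream to 1.5 kb downstream of the coding sequence,
  strand-adjusted, and no other gene's CDS lies entirely between the center
  and the target CDS (strand-agnostic, whole-CDS containment). The center
  anchor makes attribution deterministic; an any-overlap mode is available
  by flag. A region may be attributed to several flanking genes.
* **Positional enrichment.** Each observed center is classified as promoter
  (5′ of the transcript), transcribed, or downstream (3′), with priority
  transcribed > promoter > downstream where extended spans overlap. The
  null places the same number of centers uniformly within the union of the
  attributed genes' extended spans and classifies them identically; the
  statistic is the promoter + downstream count and
  `p = (1 + #{sims ≥ observed}) / (n_sims + 1)`, bounded below by
  `1/(n_sims + 1)` (10,000 simulations by default). Because the statistic
  is a discrete count, ties between observed and simulated values make this
  estimator slightly conservative; calibration checks therefore use enough
  sites (200) that the tie mass is small.
* **Motif input.** Sequences ±75 nt around each observed center (151-nt
  windows) and a 10× larger control set at uniform random genome positions
  are exported as FASTA for external motif discovery; windows are clipped at
  chromosome bounds with a warning. Motif discovery itself is out of scope.
* **Set overlap.** Overlap between attributed target genes and any other
  gene set (e.g. differentially expressed genes) is tested with Fisher's
  exact test over a stated gene universe.

## The synthetic-data generators

Every analysis input can be generated with known ground truth, so the whole
toolkit is testable without external data. The generators aim for
*detectability structure*, not biophysical realism.

**Meristem volumes.** A paraboloid-capped dome is tessellated into cells by
nearest-seed partition of uniformly sampled seeds (target cell diameter
9 µm). Planted divisions split selected mother cells by a plane through the
cell centroid whose normal is drawn from a per-region orientation mode with
a folded-normal tilt (`angle_sd`, default 10°): *transversal* (normal along
the axis), *radial* (normal along the radial direction — the wall faces the
central axis), *anticlinal* (normal tangential), or *isotropic*. The radial
mode deliberately encodes peripheral, rib-zone-widening divisions as walls
facing the axis (radial angle near 0°, axis angle near 90°): daughters
displaced along the radius widen the tissue, and this convention is the one
under which core and periphery differ on *both* orientation metrics, as the
wild-type contrast requires. Stain rendering gives wall-adjacent voxels the
old-wall intensity (0.7 a.u.), voxels flanking only a planted wall the
new/old ratio (default 0.5), interiors 5%, plus Gaussian noise (default
10% of the old-wall intensity), clamped to [0, 1].

Two geometry presets exist. The default benchmark dome (radius 28 µm,
depth 40 µm) holds ~120 cells and plants 100 divisions, so most cells carry
a recent division — as in real tissue, where every cell's weakest wall is
simply its newest. This matters for precision: the weakest-for-both-cells
rule has no absolute threshold, so a pair of non-divided cells whose shared
facet is mutually weakest is always called; keeping few non-divided cells
keeps such calls rare. The zonation preset (radius 55 µm, depth 66 µm,
~650 cells) spans all three canonical regions and plants 60/85/85 divisions
in AR/RC/RP.

**Sectors.** Chains of 6–14 landmarks at 6 µm steps along a planted
direction (vertical, radial or tangential mode plus tilt), centred on an
origin sampled inside the region window (padded 1 µm so jittered centres of
mass stay classifiable), with 1 µm isotropic landmark jitter, distributed
over apices with random rigid frames. Ground truth records each sector's
actually sampled direction, ideal length and cell count.

**Toy genomes.** Random sequence; non-overlapping, strand-assigned genes
(CDS 0.9–2.4 kb, 150 nt UTRs, ≥5.2 kb intergenic gaps so attribution
windows stay clean); 50 true binding sites placed by a positional bias
(default 60% promoter / 10% transcribed / 30% downstream, ≥60 nt from zone
edges). Each treatment replicate re-emits every true site with ±20 nt
start/end jitter and a passing q-value (−log₁₀ q uniform on [3, 30]), plus
replicate-specific noise peaks placed by rejection so they can never form a
three-way consensus; controls avoid the true sites, emulating background
absent at bound loci. With zero jitter the consensus regions reproduce the
planted sites exactly.

## What the synthetic tests do and do not show

Passing on generator data demonstrates that the algorithms implement their
stated rules (oracle equivalence), that detection meets its benchmark at a
realistic contrast (recall and precision above 0.9 with new walls at half
the old-wall intensity under 10% voxel noise), and that planted
orientation structure propagates through detection to the zone statistics.
It does **not** demonstrate robustness to segmentation errors, uneven
staining depth, anisotropic point-spread blurring, or mis-specified
reference frames — none of which the forward model emulates. Real q-value
and fold-enrichment distributions, assembly gaps and overlapping gene models
are likewise not emulated.

## Numerical choices and problem sizes

* Voxel centres sit at `(index − 0.5) × spacing`; arrays are `(y, x, z)`
  with z as TIFF page order; all physical coordinates are `(x, y, z)` µm.
* Labels are written as 16-bit integer TIFF (exact round-trip); intensities
  as 32-bit float in [0, 1] arbitrary units.
* Plane fits refuse rank-deficient inputs rather than guessing; undefined
  angles are `NA` end to end, never 0.
* Monte Carlo p-values use the add-one estimator; seeded runs are
  bit-reproducible (`with_seed()` restores the caller's RNG state).
* Statistical recovery bounds are asserted distributionally. At the
  benchmark conditions the plane-normal error is Rayleigh-like with rms
  ≈ 0.9°, so "within 2°" is checked as a 90th-percentile bound (mean < 1°)
  rather than on every draw; sector-angle recovery (rms ≈ 2–3° at 1 µm
  jitter on ≥30 µm chains) is treated the same way. The continuity-corrected
  normal approximation to the Mann–Whitney p differs from the exact value by
  ≈ 0.001 on average at n = 20/20, with a worst case near 0.005.
* Repeated-simulation checks run at reduced sizes chosen once: the
  core/periphery contrast uses 1.5 µm voxels for the single wild-type-like
  volume and 2 µm voxels for the 50 mutant-like replicates; Monte Carlo
  calibration uses 1,000 runs of 200 simulations at 200 null sites.

## Worked example

```{r example, eval = FALSE}
library(apexkit)

sim <- simulate_meristem(sim_meristem_params(seed = 1))
fac <- detect_divisions(sim$labels, sim$intensity, sim$frame)
score_new_walls(fac, sim)

wt <- simulate_meristem(zonation_sim_params("wildtype", seed = 1))
wfac <- detect_divisions(wt$labels, wt$intensity, wt$frame,
                         regions = default_regions())
summarize_by_region(wfac)
compare_zone_angles(wfac, "RC", "RP", "angle_to_axis")
plot_angle_boxes(wfac, "angle_to_axis")
```

## Known limitations

* One facet per label pair: genuinely disconnected double interfaces
  between the same two cells are merged (a split mode is a possible
  extension, not currently exposed).
* The new-wall caller is rank-based with no absolute intensity threshold;
  in tissue with few recent divisions it will still call each cell's
  weakest wall somewhere. Downstream filtering by signal density remains
  the user's choice.
* Depth is axial; apices whose region boundaries were drawn by surface
  distance would need the Euclidean option.
* The Monte Carlo p is conservative for small site counts because the
  count statistic ties frequently.
* Gene attribution assumes single-transcript gene models (one CDS span per
  gene); splice variants collapse to their outermost CDS span.
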