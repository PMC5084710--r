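# apexkit

Quantitative analysis of oriented growth and regulatory binding in the shoot
apex, from single-time-point data.

Stems form in the shoot apical meristem's rib zone, where the *orientation*
of cell divisions — not just their rate — shapes the tissue. Live imaging
cannot reach these deep layers, but because plant cells build their new wall
perpendicular to the mitotic spindle, a fixed, wall-stained apex still
records the 3D orientation of its recent divisions: newer walls are thinner
and fluoresce less. `apexkit` turns that observation into a measurement
pipeline, and pairs it with the clonal-sector and ChIP-seq analyses used to
connect rib-zone growth to its transcriptional regulators.

The package is written for developmental biologists working in R: every
analysis function takes and returns tibbles, results have `tidy()` /
`glance()` methods, and each result type has a ggplot2 display.

## What it computes

**Division detection and orientation** (`extract_facets()`,
`call_new_walls()`, `detect_divisions()`). From a segmented 3D label volume
plus the co-registered wall-stain channel, every cell–cell facet gets an
area, a signal density (mean stain of the flanking voxels, area-weighted),
and a best-fitting plane. A facet is called a *new wall* when its signal
density is the minimum for **both** adjacent cells. Orientation is measured
on the plane normal **n**, folded into [0°, 90°]:

- angle to the main axis: `acos(|n · a|)` — transversal walls ≈ 0°;
- radial angle: `acos(|n · r|)`, with **r** the radial unit vector at the
  wall's centre of mass — walls facing the central axis ≈ 0°, undefined on
  the axis.

**Zonation statistics** (`default_regions()`, `classify_facets()`,
`summarize_by_region()`, `compare_zone_angles()`). Walls are assigned to the
apical region (depth 0–30 µm, radius 0–40 µm), rib-meristem core (30–60,
0–40) or periphery (30–60, 40–50) and compared with a Mann–Whitney U test
that is exact (tie-aware enumeration) for small samples and
normal-approximated with tie and continuity corrections otherwise.

**Clonal sectors** (`align_apex()`, `measure_sectors()`,
`project_sectors()`, `compare_sector_stats()`). Landmarked clones from many
apices are aligned rigidly into a common frame (summit at origin, axis up),
then measured: centre of mass, principal axis, vertical/radial angles, cell
count, length.

**ChIP-seq consensus and positional enrichment** (`consensus_regions()`,
`assign_to_genes()`, `positional_enrichment()`, `export_motif_sequences()`,
`overlap_fisher()`). Peaks present at q ≤ 10⁻³ in all three treatment
replicates, overlapping ≥ 50 nt and absent from all controls become
consensus regions; regions are attributed to genes within 3 kb upstream /
1.5 kb downstream of the coding sequence (strand-aware, no intervening CDS);
enrichment of peak centers in promoter + downstream zones versus transcribed
regions is tested against 10,000 random placements; ±75 nt windows are
exported as FASTA for motif discovery.

**Synthetic data with ground truth** (`simulate_meristem()`,
`simulate_sectors()`, `simulate_genome_peaks()`). Seeded generators produce
every input above — tessellated dome volumes with planted division planes,
sector chains with known axes, toy genomes with positionally biased
replicate peaks — so the full toolkit runs and is tested without any
external dataset.

## Worked example

```r
library(apexkit)

# a synthetic apex: ~120 cells, 100 planted divisions, new walls at half
# the old-wall stain intensity, 10% voxel noise
sim <- simulate_meristem(sim_meristem_params(seed = 1))
fac <- detect_divisions(sim$labels, sim$intensity, sim$frame, verbose = TRUE)
#> 1204 facets (1100 eligible), 100 called as new walls
score_new_walls(fac, sim)
#> # A tibble: 1 x 5
#>   n_true n_called true_positives recall precision
#>    <int>    <int>          <int>  <dbl>     <dbl>
#> 1    100      100            100      1         1
```

All 100 planted divisions are recovered with no false calls at these
conditions. The zonation contrast works the same way:

```r
wt <- simulate_meristem(zonation_sim_params("wildtype",
                                            spacing = c(1.5, 1.5, 1.5),
                                            seed = 7))
wfac <- detect_divisions(wt$labels, wt$intensity, wt$frame,
                         regions = default_regions())
compare_zone_angles(wfac, "RC", "RP", "angle_to_axis")
#> Mann-Whitney U test (normal approximation (tie-corrected, continuity-corrected))
#>   U = 129, n = 89/83, two-sided p = 6.59768e-28
```

The rib-meristem core's transversal walls (angle to axis near 0°) separate
sharply from the periphery's radial walls (near 90°); a "mutant-like"
simulation that draws core orientations from the periphery's distribution
abolishes the contrast. See the methods vignette
(`vignettes/apexkit-methods.Rmd`) for the models, conventions and the
design decisions behind them.

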