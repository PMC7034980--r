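# junctmorph

Per-junction morphometry of cell–cell contacts in fluorescence images.

Cell–cell adhesion phenotypes — fragmentation of E-cadherin staining,
undulation of contacts that have lost tension, redistribution of
receptors into denser clusters — are invisible to whole-image intensity
averages. `junctmorph` quantifies them junction by junction. It reduces
a single-channel image of a junctional marker (E-cadherin, VE-cadherin,
β-catenin, ...) to a one-pixel-wide boundary skeleton, detects the
tricellular **corners** where three or more cells meet, cuts the
skeleton into corner-to-corner **interfaces**, deduplicates junctions
shared by two cells, and measures each interface inside a user-set
dilation band (1–9 px).

Per junction, the package reports:

* **Primary parameters** — interface contour (geodesic length along the
  skeleton, in px; 1 per orthogonal and √2 per diagonal step),
  straight-line interface length (Euclidean corner-to-corner distance),
  interface area (band pixel count), junction contour and straight-line
  junction length (between the outermost above-threshold staining
  pixels), junction area, fragmented junction contour (summed lengths of
  the individual staining fragments), marker area, marker intensity.
* **Secondary parameters** — interface/junction linearity index
  (contour ⁄ straight length, ≥ 1; 1 = taut, > 1 = undulated), coverage
  index (100 · fragmented contour ⁄ interface contour, %), interface
  occupancy (100 · marker area ⁄ interface area, %), intensity per
  interface area, and cluster density (marker intensity ⁄ marker area —
  high when receptors pack into dense clusters).

Interactive correction is replaced by scripted, reproducible inputs:
edit scripts add/remove skeleton segments, manual corners can be added
or removed, and a PSNR quality gate (reliable automatic skeletons above
≈ 22 dB) flags images too noisy for automation. A second co-registered
marker channel can be measured inside the first marker's bands. Group
comparison uses Mann–Whitney (2 groups) or ANOVA + Games–Howell (≥ 3),
and control-normalized median fingerprints (controls = 100) summarize a
phenotype across parameters.

A synthetic-monolayer generator (`generate_monolayer`) renders Voronoi
epithelia with exact geometric and photometric ground truth —
controllable cell count, staining width and intensity, interface
undulation, programmed coverage fraction, cytoplasmic background, and
Gaussian noise — so every stage of the pipeline is testable without
external data.

## Worked example

```r
library(junctmorph)

# a clean synthetic monolayer: 16 cells, continuous staining
sc <- generate_monolayer(scene_spec(n_cells = 16, seed = 5,
                                    width = 320L, height = 320L))
jm <- junction_map(sc$image, threshold = 50, dilation = 2)
jm
#> <junction_map> 5 measured junction(s) (threshold 50, dilation 2)
#>   28 interface(s) excluded
#>   median coverage index: 100.0%
#>   median interface linearity: 1.081
```

Five interior junctions are measured; the 28 exclusions (border cells,
paths ending at the image edge) are listed in `jm$log` with reasons.
Continuous staining gives a coverage index of 100 %; linearity ≈ 1.08
reflects straight contacts read with the weighted step metric.

```r
head(as.data.frame(jm)[, c("interface_id", "m1_interface_contour",
                           "m1_coverage_index",
                           "m1_interface_linearity_index",
                           "m1_interface_occupancy",
                           "m1_cluster_density")], 3)
#>   interface_id m1_interface_contour m1_coverage_index
#> 1           12                59.94               100
#> 2           14                58.41               100
#> 3           16                45.28               100
#>   m1_interface_linearity_index m1_interface_occupancy m1_cluster_density
#> 1                         1.08                  62.53                200
#> 2                         1.01                  63.95                200
#> 3                         1.09                  65.86                200
```

Each row is one junction: a ~60 px interface whose band is ~64 %
occupied by staining of mean above-threshold intensity 200 A.U.
Comparing against a fragmented scene (programmed coverage 30 %,
measured over the corrected skeleton from the scene's ground truth):

```r
sc2 <- generate_monolayer(scene_spec(n_cells = 16, seed = 6,
                                     width = 320L, height = 320L,
                                     coverage_fraction = 0.3))
jm2 <- junction_map(sc2$image, threshold = 50, dilation = 2,
                    interfaces = truth_interfaces(sc2))
tab <- rbind(transform(as.data.frame(jm),  junction_class = "control"),
             transform(as.data.frame(jm2), junction_class = "fragmented"))

compare_groups(tab, "m1_coverage_index")
#> Mann-Whitney U on 'm1_coverage_index': global p = 0.00749
#>   group1     group2 statistic       p
#>  control fragmented        25 0.00749

normalize_profile(tab, "control",
                  parameters = c("m1_coverage_index", "m1_cluster_density"))
#> junction fingerprint (control 'control' = 100, center = median)
#>       group          parameter normalized       p significant note
#>  fragmented  m1_coverage_index       29.8 0.00749        TRUE
#>  fragmented m1_cluster_density      100.0 1.00000       FALSE
```

The fingerprint recovers the programmed phenotype: coverage drops to
~30 % of control (significant), while cluster density — the staining's
own mean intensity, unchanged by fragmentation — stays at 100.

`write_junction_csv(jm, "junctions.csv")` writes the canonical
per-junction CSV; `plot(jm)` overlays skeleton and numbered corners on
the image. A command-line front end with `analyze`, `simulate`,
`compare` and `fingerprint` subcommands ships in
`inst/cli/junctmorph-cli.R`.

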