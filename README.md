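# stemscan

Single-scan terrestrial laser scanning (TLS) of small plantation plots:
from raw polar scan records to per-tree **DBH**, **height** and **position**.

A low-cost TLS built from a 2-D line scanner on a rotating platform records,
for every laser return, a slant range *R*, an intensity *I*, a vertical angle
*θ* and a horizontal angle *φ*. stemscan turns a single such scan of a
10 m × 10 m plantation plot into a tree-level inventory:

1. **Scan geometry** — polar records to Cartesian clouds
   (*x* = *R* cos *θ* cos *φ*, *y* = *R* cos *θ* sin *φ*, *z* = *R* sin *θ*)
   and cylindrical range/intensity maps.
2. **Trunk detection** — slice the cloud at breast height (1.3 m ± 5 cm),
   cluster the slice with a range-adaptive adjacency threshold
   *d* < *k*·max(*d*<sub>AB</sub>, *d*<sub>AC</sub>) built from the
   law-of-cosines spacing of lattice-adjacent rays (*k* = 1.5), and accept
   clusters whose Pratt-fitted diameter is a plausible stem diameter.
3. **Circle fitting** — Pratt and Taubin algebraic fits
   (A(x²+y²) + Bx + Cy + D = 0, Pratt normalization B² + C² − 4AD = 1) and
   Gauss–Newton geometric refinement.
4. **Local ground** — per-tree RANSAC plane on the lowest 10 cm slab of a
   0.6 m cylinder; the circle center projected onto the plane is the local
   zero-height point *p*<sub>zero</sub> and the tree position.
5. **Tree metrics** — DBH from a re-slice 1.3 m above *p*<sub>zero</sub>;
   height as *z*(*p*<sub>top</sub>) − *z*(*p*<sub>zero</sub>), where
   *p*<sub>top</sub> survives a 10-nearest-neighbour outlier filter on the
   top 0.5 m of the crown (points with mean neighbour distance above the
   grand mean are outliers).
6. **Evaluation** — one-to-one stem matching (correct / false / omission,
   detection rate) and bias/RMSE statistics against reference tables.
7. **Scan simulator** — seeded synthetic plantation plots (grid planting
   with vacancies, Gaussian DBH and height, flat/tilted/undulating ground,
   sparse crown elements) scanned by exact first-return ray casting on the
   instrument's angular lattice with Gaussian range noise, giving every
   stage a known ground truth.

The methods vignette (`vignettes/single-scan-inventory.Rmd`) documents the
models, parameters and design choices in detail.

## Worked example

Simulate one plantation plot under the study conditions (1.6 m × 2.8 m
planting grid, DBH ~ N(12.11, 2.37²) cm, height ~ N(8.43, 0.78²) m, 12 mm
range noise, scanner on a 1.5 m tripod at the plot center) and process it:

```r
library(stemscan)

cfg  <- scannerConfig(delta_phi = 0.1)        # 0.1667 deg x 0.1 deg lattice
plt  <- generatePlot(seed = 101)              # 17 stems on the grid
scan <- simulateScan(plt, cfg, scanner_pos = c(0, 0, 1.5), seed = 201)
rep  <- processPlot(scan$records, cfg, scanner_height = 1.5, seed = 301)
#> cloud: 1913916 points
#> transect at z = -0.20 m: 47 clusters, 16 accepted candidates
#> trees: 16 reported, 16 with DBH, 16 with height

m <- matchTrees(rep[, c("x_m", "y_m")], scan$truth[, c("x", "y")], 0.5)
m$n_correct                       # 16 of 17 stems found (one occluded)
errorStats(rep$dbh_cm[m$pairs$est],   scan$truth$dbh_cm[m$pairs$ref])$rmse
#> [1] 1.14566        # cm
errorStats(rep$height_m[m$pairs$est], scan$truth$height_m[m$pairs$ref])$bias
#> [1] -0.01050723    # m (tops undershoot by about a lattice step)
```

`processPlot()` returns one row per tree
(`id, x_m, y_m, dbh_cm, height_m, ground_inclination_deg, n_points, rms_m,
flags`); `writeTreeReport()` serializes it. The packaged field campaign
tables are available via `fieldDetectionCounts()` / `fieldTreePositions()`:

```r
detectionSummary(fieldDetectionCounts())
#>     plot n_trees correct false omission detection_rate_pct stem_density_ha
#> 1      1      16      16     0        0          100.00000            1600
#> 2      2      14      13     0        1           92.85714            1400
#> 3      3      22      19     0        3           86.36364            2200
#> 4      4      17      16     0        1           93.75000            1700
#> 5 pooled      69      64     0        5           92.75362            1725
```

## Command line

A thin Rscript wrapper is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "stemscan", package = "stemscan"))')
Rscript $CLI simulate --seed 7 --out-dir demo        # scan.csv, truth.csv, scene.ply
Rscript $CLI metrics  --scan demo/scan.csv --out demo/trees.csv
Rscript $CLI evaluate --report demo/trees.csv --reference demo/truth.csv
Rscript $CLI maps     --scan demo/scan.csv --kind range
```

All subcommands are seeded and byte-reproducible.

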