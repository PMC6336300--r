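---
title: "Single-scan terrestrial laser scanning of plantation plots: methods"
author: "stemscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-scan terrestrial laser scanning of plantation plots: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemscan)
```

## The measurement problem

A tripod-mounted terrestrial laser scanner (TLS) built from a 2-D line
sensor on a rotating platform records, for every laser return, the slant
range $R$, an intensity $I$, the vertical angle $\theta$ set by the sensor's
angular step, and the horizontal angle $\varphi$ set by the platform
rotation. From a *single* scan per plot — no multi-scan registration — the
package estimates, for every tree in a small plantation plot, the three
quantities a forest inventory needs: the diameter at breast height (DBH,
1.3 m above local ground), the total tree height, and the stem position.

stemscan implements the full processing chain plus a scan simulator with
known ground truth, so that every stage can be validated at desk scale.

## Scan geometry

With the scanner at the origin, $z$ up and $x$ toward $\varphi = 0$, a
return converts to Cartesian coordinates by the spherical relations

$$x = R\cos\theta\cos\varphi,\quad y = R\cos\theta\sin\varphi,\quad
z = R\sin\theta,$$

evaluated with signed trigonometry so the same formula holds in every
quadrant, including the sensor's over-zenith part of the sweep. $\theta$ is
the elevation from the horizontal plane.

The sensor's 190° window is a mounting choice. stemscan mounts it (by
default) as $\theta \in [-95^\circ, 95^\circ]$ — from 5° past nadir to 5°
past zenith. With the full 360° platform rotation this covers the whole
sphere and, critically, the ground around the tripod, which the
ground-fitting stage needs. The raw sensor frame (0–190°) maps to this
mounted frame by a constant 90° offset; `ScannerConfig@fov_theta` exposes
the interval for other mountings.

Two returns on lattice-adjacent rays separated by an angular step
$\Delta$ are a distance

$$d = \sqrt{R_a^2 + R_b^2 - 2 R_a R_b \cos\Delta}$$

apart (law of cosines); `adjacentDistance()` implements this and the
clustering threshold below builds on it. `resolutionMetrics()` reports the
beam footprint (divergence × distance; 4.7 cm at 10 m for the 4.7 mrad
beam) and the vertical point spacing ($\text{distance}\times\tan
\Delta\theta \approx 3$ cm at 10 m at the 0.1667° step) — the two figures
that bound sensible plot sizes for the single-scan method.

## Trunk detection

The cloud is sliced at breast height (±5 cm). Slice points are projected
onto the horizontal plane and clustered by single-linkage connected
components: two points link when their planar distance is below

$$d_{threshold} = k \cdot \max(d_{AB}, d_{AC}),$$

where $d_{AB}$ and $d_{AC}$ are the expected adjacent-ray spacings at the
points' ranges for the horizontal and vertical steps, and $k = 1.5$ absorbs
range noise and trunk-surface irregularity. Because the threshold depends on
range, near and far trunks cluster equally well. For non-adjacent pairs the
spacings are evaluated at the mean of the two ranges — the adjacency rule
only defines them for lattice neighbors, and the mean is the symmetric
choice. A small-slice $O(n^2)$ union–find oracle in the test suite checks
the partition exactly.

Every cluster of at least `min_cluster_size` points (default 10 — below
that a circle fit is not stable) is fitted with the Pratt method, and a
candidate is accepted only when the fitted diameter lies within plausible
stem limits (defaults 0.05–0.30 m, configurable per plot). This diameter
gate is the package's concrete reading of "consistent with a circle": it
rejects the two classic failure modes — a short arc from a partially
shadowed trunk whose fitted diameter explodes, and clusters of branch
returns or noise. An optional RMS-residual gate exists but is off by
default; the diameter limits alone reproduce the intended behavior.
Rejected clusters are reported with their reason (`rejected_size`,
`rejected_diameter`, `rejected_degenerate`) so detection bookkeeping is
auditable.

## Circle fitting

An algebraic circle is $A(x^2+y^2) + Bx + Cy + D = 0$ with the Pratt
normalization $B^2 + C^2 - 4AD = 1$, under which the radius is $1/(2|A|)$
and the center $(-B/2A, -C/2A)$. Three fitters are provided:

* **Pratt** minimizes $\sum_i (Az_i + Bx_i + Cy_i + D)^2$, $z_i = x_i^2 +
  y_i^2$, subject to the Pratt constraint, solved as the generalized
  eigenproblem of the moment matrix against the constant constraint
  matrix. Among admissible eigenpairs (real, normalizable, non-negative
  objective) the smallest-objective one is taken.
* **Taubin** uses the constraint $4A^2\bar z + 4AB\bar x + 4AC\bar y + B^2
  + C^2 = 1$. The offset $D$ does not enter the constraint and is
  eliminated analytically, leaving a $3\times3$ symmetric-definite
  generalized eigenproblem solved by Cholesky reduction. The result is
  renormalized to the Pratt convention for comparability.
* **Gauss–Newton** refines any initial circle (Pratt by default) by
  minimizing the orthogonal distances $\sum_i
  (\sqrt{(x_i-x_c)^2+(y_i-y_c)^2} - r)^2$ with step halving, so the
  objective is monotone non-increasing.

All fits are exact (to 1e−9) on noiseless circles; on noisy arcs the three
agree within a millimeter at realistic noise, and the geometric residual of
Gauss–Newton never exceeds the algebraic fits'. The pipeline uses Pratt by
default: non-iterative, and in this setting as accurate as the geometric
fit to within a millimeter. Data are centered at their centroid before the
eigen-solves; collinearity is detected by the second singular value of the
centered design (threshold 1e−12 relative) and raises a degenerate-fit
error.

## Local ground and the zero point

For each candidate, the points in a 0.8 m cylinder around the stem are
extracted; ground fitting uses the lowest ~10 cm slab of a 0.6 m cylinder,
which contains ground returns *and* trunk-bottom points. RANSAC (random
3-point hypotheses, inlier tolerance 2 cm, 200 iterations, consensus
threshold 50% — the tolerance matches the instrument's 12 mm range noise,
and the iteration count makes a good hypothesis overwhelmingly likely at
these outlier fractions) fits the local plane and rejects the trunk
points; the consensus plane is refined by orthogonal least squares on the
inliers. No plot-wide DTM is built: a local plane per tree is cheaper and
sufficient on the gentle terrain the method targets.

The refined circle center projected vertically onto the plane is the local
zero-height point $p_{zero}$ — simultaneously the tree position and the
origin for breast height and tree height. Projection is vertical rather
than along the plane normal; at the ~3° inclinations the method tolerates
the difference is below 0.2%, and at a 3° tilt the breast-height error
across a 0.2 m stem is about 1 cm. Planes steeper than 45° are rejected as
non-ground; inclinations above 10° raise a quality flag (a tilt-corrected
breast height is out of scope, so steep trees are flagged rather than
silently corrected).

## DBH, height and position

DBH is estimated by re-slicing at $z(p_{zero}) + 1.3\,$m (±5 cm — the same
thickness as the detection transect, exposed as a parameter) within the
tree cylinder and fitting with Pratt; the new center refines the tree
position and the zero point once more.

Height needs the uppermost *tree* point. Returns near a leaf-off tree top
are a mix of stem/branch hits and sparse twig or noise returns, so the top
0.5 m window $V_{top}$ ($|z_{max} - z_p| < 0.5$ m) is filtered: for each of
its $M$ points the distances to its 10 nearest neighbors are averaged into
$md_i$, the grand mean $md$ of the $md_i$ is formed, and points with
$md_i \le md$ are tree points while the rest are outliers. Since
$\min_i md_i \le md$ the tree set is never empty. $p_{top}$ is the highest
tree point (ties broken by input order, keeping output deterministic), and

$$\text{height} = z(p_{top}) - z(p_{zero}),$$

clamped at zero with a quality flag if negative. When $M \le 10$ the
neighbor count drops to $M-1$ (the rule is silent for tiny windows; this
keeps it defined), and a single-point window is its own $p_{top}$.
Neighboring crowns reaching into the 0.8 m cylinder are not specially
handled — a known limitation of the cylinder method.

`processPlot()` chains all stages and emits one report row per accepted
candidate with flags (`no_ground`, `no_dbh`, `no_height`, `steep_ground`,
`negative_height_clamped`); a failure at one tree never aborts the plot.

## The scan simulator

`generatePlot()` emulates the plantation study conditions: a
1.6 m (north–south) × 2.8 m (west–east) planting grid with per-node vacancy
probability 0.05 (dead trees removed; this reproduces the observed
~1700 stems/ha pooled density), DBH drawn from $N(12.11, 2.37^2)$ cm and
height from $N(8.43, 0.78^2)$ m, truncated positive. Stems are placed at
cell centers so that no planting row passes exactly through a plot-center
scan position — the same consideration that guides scan placement in the
field. Stems are vertical cylinders (optional linear taper, with the radius
anchored at breast height so the truth table stays exact); crowns are
sparse small spheres in the top 15% of each stem, enough to exercise the
top filter; there are no leaves (the method targets leaf-off conditions).

`simulateScan()` casts one exact ray per lattice cell and keeps the nearest
intersection with any stem, crown element or the ground surface, so
occlusion (shadowing) holds by construction; beam width is *not*
convolved — the simulator stays an analytic oracle, and divergence is only
reported through `resolutionMetrics()`. Range noise is zero-mean Gaussian
with the instrument's ±12 mm accuracy interpreted as 1-σ (the error
distribution is not documented; Gaussian is the conventional reading and
the σ is configurable), and returns outside 0.7–80 m are dropped. Intensity
follows a plain cosine-incidence model. Ground surfaces are flat, tilted or
undulating — the last reproduces the terrain on which single-slice
detection genuinely fails. All draws are seeded; one vacancy draw per grid
node precedes all attribute draws, so raising the vacancy probability under
a fixed seed only removes stems.

What the simulator does *not* emulate — beam-width mixing at stem edges,
understory, bark roughness, wind motion, leaf-on canopies, radiometric
realism — bounds what passing tests mean: they validate the geometry and
the algorithmic chain, not field performance on difficult scenes.

## Evaluation

`matchTrees()` pairs estimated with reference stems by greedy one-to-one
nearest-neighbor matching within 0.5 m (about a third of the minimum
planting spacing; the field matching was done by hand against a surveyed
stem map, so the tolerance is this package's choice and a CLI flag).
Unmatched references are omissions, unmatched estimates false detections,
and the detection rate is correct/reference. `errorStats()` reports
bias (mean of estimate − reference) and RMSE, with percentages relative to
the reference mean — the standard definitions used for TLS inventory
accuracy.

## Numerical and design choices, in brief

* Angles are degrees at every API boundary, radians internally.
* Map cells with no return hold `NA`; duplicate cells keep the nearest
  return (first-return logic) with a warning.
* Records outside the 0.7–80 m measuring range are dropped, never clamped.
* The horizontal step $\Delta\varphi$ is a free parameter rather than a
  derived quantity of rotation speed and line rate: the achieved value
  depends on sensor timing that is not modeled. The field setting (1°/s
  rotation) corresponds to ~0.1° at the 50 Hz line rate, and 0.1° is the
  default.
* $\varphi = 0$ is fixed at the +x axis; the instrument's azimuth origin is
  arbitrary anyway, and evaluation is translation/rotation tolerant via
  position matching.
* Eigen-solver branch selection for Pratt: smallest non-negative
  constrained objective among normalizable real eigenpairs.
* RANSAC is seeded explicitly everywhere; `processPlot()` derives one seed
  per tree from its `seed` argument, so whole-plot runs are reproducible.

## Problem sizes used in the checks

The packaged validation runs four simulated 10 m × 10 m plots at the full
study lattice (0.1667° × 0.1°, about 4 million rays and ~1.8 million
returns per plot) for the closed-loop accuracy surrogate, and coarser
lattices (0.25°–2°) wherever the property under test is step-size
independent — exactness of the geometry, clustering equivalence with the
brute-force oracle, occlusion logic, and CLI reproducibility. These sizes
were chosen so the whole suite validates the full-resolution pipeline while
staying quick to run.

## Known limitations

Single-slice detection fails on strongly undulating ground (the breast
height of different trees then falls at very different cloud heights); bent
stems and leaf-on canopies are out of scope; heights are discretization-
limited from below (the top lattice row undershoots the true tip by up to
the local vertical spacing), so a small negative height bias is expected
and observed; and the DBH of small-diameter stems is noise-limited — at
12 mm range noise on a ~6 cm radius the algebraic fit's small-arc bias is a
visible part of the error budget.
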