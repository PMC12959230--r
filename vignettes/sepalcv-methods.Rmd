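---
title: "Methods: quantifying sepal robustness and its link to wild-type expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sepal robustness and its link to wild-type expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepalcv)
```

## The analysis model

`sepalcv` asks whether the phenotypic variability of single-gene knockout
mutants carries information about the wild-type behaviour of the knocked-out
gene. The phenotype is the final (growth-arrested) sepal, summarized by four
shape parameters per organ: area, length, width and aspect ratio. The design
is batch-matched: every mutant is grown and measured alongside its own
wild-type (`col0`) control batch, and all mean comparisons are within batch.

Three statistics drive everything:

* **Dispersion.** For a genotype and parameter, `CV² = (sd/mean)²` with the
  sample (n−1) standard deviation. CV² is dimensionless, so calibration
  errors and unit choices cancel; this is also why the screens are
  unaffected by the mm-per-pixel factor used in morphometrics.
* **Batch-corrected effect.**
  `rel_effect = (mean_mutant − mean_control)/mean_control`, used in absolute
  value: the screens care about the magnitude of a mutant's shift, not its
  direction.
* **Pearson screens.** Each screen correlates a response (|rel_effect| or
  CV² of one parameter, across mutants) with an expression covariate of the
  mapped genes in wild type (expression CV², or log₁₀ mean expression),
  with the two-sided p-value from the exact t-transform on n−2 degrees of
  freedom. The full grid is 2 responses × 4 parameters × 2 covariates = 16
  screens. Raw p-values are reported; `run_screens(p_adjust=)` exposes a
  correction hook, off by default, because the screens are reported
  per-hypothesis rather than as a family.

Assumptions worth stating: sepals are treated as independent within a
genotype; mutants are treated as exchangeable units in the correlation
(n = 16 is small, hence the resilience layer); and the t-based p-value
assumes approximate bivariate normality across mutants, which is why the
package verifies its null calibration by simulation rather than taking it
on faith.

The logarithm base for mean expression is 10. This is a display convention
only: Pearson r and p are invariant under affine maps of either variable,
and a change of log base is exactly such a map. The test suite asserts this
by comparing base-10 against natural-log runs.

Mutants whose mapped gene has zero mean expression cannot enter log-scale
screens; they are excluded with an explicit warning and listed in the
screen table's rejects, rather than silently dropped.

## Resilience experiments

With 16 mutants a single influential genotype can make or break a
correlation, so the package re-tests every screen two ways.

**Subsampling.** Each replicate draws a fixed number of sepals (default 30)
per mutant without replacement, recomputes each mutant's CV², and re-runs
the Pearson test against the unchanged expression covariate (the covariate
is a property of the gene, not of the sampled sepals, so re-deriving it per
replicate would be a no-op). The report keeps every (r, p) pair and the
fraction of replicates significant at α. The RNG substream of each
(mutant, replicate) pair is keyed by a hash of the genotype label, which
makes reports independent of the row order of the input table — an
invariant the tests assert by shuffling.

**Leave-x-out.** After removing any fixed exclusions (the *pmr6* mutant is
the canonical example of an influential outlier), the procedure enumerates
every selection of x distinct remaining mutants, drops each selection, and
recomputes the test. The default enumeration counts *ordered* selections
without repetition — n!/(n−x)! tests, i.e. 16, 240 and 3360 for
x = 1, 2, 3 on 16 mutants, and 15, 210, 2730 after excluding *pmr6*. The
ordered convention repeats each unordered subset x! times; it is provided
because those are the test counts such screens conventionally report, and
`ordered = FALSE` gives the non-redundant binomial counts. The two
conventions yield the same multiset of (r, p) values up to the x!
repetition, which the suite checks exactly by enumerating both ways.

`pvalue_distribution()` summarizes a report as a kernel density of
log₁₀(p), renormalized by its trapezoid integral so the area under every
curve is exactly 1 — reports with 16 and 3360 tests can be overlaid on
equal footing. A report in which every test returns the same p (e.g.
leave-0-out) is flagged as a point mass instead of smoothed.

## Morphometrics

Photographs are assumed dark-background/bright-organ, which makes global
Otsu thresholding adequate; connected components above a minimum pixel
count (default 50 px) become object masks. The outer boundary is the
0.5-level marching-squares isoline of the zero-padded mask, so vertices sit
on pixel-box edges and the polygon area tracks the pixel count within ~2%
for objects of ≥ 1000 px. Alignment translates the arc-length-weighted
vertex centroid to the origin and rotates the principal axis (largest
variance direction, arc-length weighted) onto the vertical; if the
horizontal extent still exceeds the vertical one (exact ties included),
an extra quarter turn is applied, so length ≥ width and aspect ratio ≥ 1
by construction rather than by luck. Length is the principal-axis extent
and width the orthogonal extent — not Feret diameters — matching the
flattened top-view convention. Area is the shoelace polygon area times the
squared calibration; calibration defaults to 1 (pixel units), which is
harmless downstream because every screen statistic is unit-invariant.

Numerical conventions: image ingestion is row 1 = top with y downward;
coordinates are flipped to the mathematical convention before alignment.
RGB images are collapsed by Rec. 709 luminance. PNG and TIFF are read;
JPEG is not.

## The synthetic-data generator

The generator exists so the entire pipeline is testable, with known ground
truth, at the design scale of a real screen: 11 control batches, 16 mutants,
39–90 sepals per genotype (drawn uniformly), and a 27-sepal wild-type
expression matrix. With 16 mutants the genotypes carry the cell-wall mutant
names (including `pmr6`), so exclusion experiments read naturally.

Per-sepal length and width are independent gamma draws parameterized by
(mean, CV²) — strictly positive, and matching exactly the two moments the
analysis consumes. The distributional family of real sepal measurements is
not known to the package; gamma is a stand-in choice, not an inference.
Area is `0.75·length·width` (an ovate blade fills about three quarters of
its bounding box) and aspect ratio is `length/width` of the same sepal, so
the deterministic relations a measurement pipeline would produce are
preserved; true area CV² is `(1+c)(1+c)−1` for the equal length/width CV²
split `c = √(1+CV²_area)−1`, and the analogous closed forms give the aspect
truth.

Defaults, chosen once as plausible study conditions: control mean area
2.3 mm² (≈ 2.5 × 1.2 mm blade), control area CV² 0.01, lognormal mutant
mean shifts with sd 0.05 (and batch-to-batch control drift at 0.4 of
that, so a zero `effect_scale` collapses to an exact null), mapped-gene
log₁₀ mean expression uniform on [1, 4], planted slope 0.012 CV²(area) per
decade, and genotype-level lognormal CV² scatter with sd 0.15. At those
values the realized mutant-level correlation between area CV² and log mean
expression is around 0.8 — strong but not degenerate — which is what makes
the recovery property (detection in ≥ 95% of seeds at n = 16) hold without
being trivial. The expression cloud follows
`CV² ≈ 0.02 + 3/mean` with lognormal scatter and a 5% fraction of
10×-inflated highly variable genes, reproducing the qualitative decreasing
mean–CV² scatter of sepal transcriptomes without fitting any real dataset.

What the generator does *not* emulate: developmental stage structure,
growth dynamics, correlated length–width noise within a sepal, batch ×
genotype interactions, or RNA-seq count noise (the expression matrix is
already on a normalized scale). Passing tests therefore demonstrate the
statistical machinery, not the biology of any particular dataset.

Synthetic contours are superellipses `|x/b|^p + |y/a|^p = 1` with the
exponent as tip sharpness (p = 2 is an ellipse, giving the analytic πab
area oracle used in tests), optionally with multiplicative radial vertex
noise. Rasterization is an even-odd scan-line fill over pixel centers —
deterministic and unantialiased, so background pixels hold the background
intensity exactly and foreground fractions can be checked by pixel
counting.

## Seeding and reproducibility

Every generator function evaluates under a temporary RNG state derived from
the config seed (ground truth, expression draws and measurement draws use
separate fixed offsets, which is what lets `simulate_expression()` and
`simulate_measurements()` agree without sharing state), and restores the
caller's RNG afterwards. Identical configs are bit-identical, which the
suite asserts, and `run_pipeline()` reruns byte-identically from the same
YAML config and seed.

## Problem sizes used by the tests and the acceptance script

The packaged checks run the full design (16 mutants × 39–90 sepals) for
single fits, 1000 × 30-sepal subsampling replicates (the acceptance script
averages the significance fraction over 10 independent study draws,
because one draw of 16 gene means carries study-level sampling variance
that a fixed real dataset does not), complete leave-1/2/3-out
enumerations, and 200-seed loops for null calibration (rejection rate
within the exact binomial 99.9% band around 5%) and recovery power. The
200-seed loops use a 16-gene expression matrix: the background cloud does
not enter any screen, so dropping it changes nothing but runtime. All of
this completes in a few minutes on one CPU.

## Known limitations

* n = 16 mutants bounds the power and stability of every screen; the
  resilience layer characterizes, but cannot remove, that limitation.
* CV² estimates from ~30–90 sepals are themselves noisy (relative sd about
  `√(2/n)`), which attenuates observed correlations relative to the
  planted truth.
* The confound screen (CV² vs sample size) is undefined when all mutants
  share one n; `sepal_screen()` records it as absent in that case.
* The morphometrics layer assumes one dominant, roughly convex organ per
  mask; touching sepals are not split, and holes in a mask are ignored in
  favour of the outer boundary.
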