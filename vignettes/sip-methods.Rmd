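---
title: "Models and methods behind SIPquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind SIPquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SIPquant)
```

# The measurement problem

DNA stable isotope probing separates DNA along a CsCl buoyant-density
gradient. Heavy-isotope incorporation raises a genome's equilibrium
density, so an actively assimilating population's abundance profile over
the collected fractions shifts toward the heavy end relative to an
unlabeled control. Everything in this package reduces to estimating that
shift per genome, deciding when it is real, and quantifying what it
implies about isotopic enrichment.

Two facts make this harder than it sounds. First, sequencing yields
compositional data: coverage within a fraction library says nothing
absolute until it is calibrated, which is what the sequin internal
standards are for. Second, the shift of interest is small — a fully
realistic 32 % atom fraction excess (AFE) moves a genome by roughly
0.017 g/mL, two to three fractions — so noise in the per-fraction
abundances propagates directly into the enrichment estimate.

# From coverage to absolute abundance

Each fraction library receives a mix of synthetic sequin standards of
known concentration. `fitScalingModels()` regresses known concentration
on observed sequin coverage per library and `scaleToAbsolute()` applies
the fit to the genome rows.

Choices made here, and why:

* **Log–log regression by default** (`logTransform = TRUE`). Sequins span
  orders of magnitude in concentration. An untransformed fit estimates an
  additive intercept whose error is on the scale of the low-concentration
  standards; applied to fractions where a genome is genuinely absent,
  that error (after clamping at zero) floods the profile tails with
  phantom abundance and drags every weighted density toward the middle of
  the gradient. In our simulations at 20 % coverage noise this inflated
  the AFE of unlabeled genomes by ~0.2 — a catastrophic bias. The log–log
  fit has no additive floor, only multiplicative error, and is the common
  choice in the sequin-calibration literature. The untransformed fit
  remains available for comparison.
* **Coefficient-of-variation gate.** Within each library, sequins are
  assessed per concentration group; a group whose coverages have
  CoV = 100·sd/mean above 250 % is dropped before the regression. The
  grouping unit (per concentration group, within each library) is a
  package decision; the quantity being thresholded is not uniquely pinned
  down by the method descriptions in the field.
* **Cook's-distance filtering.** With ordinary least squares, points with
  Cook's D above 4/n are removed and the model refit exactly once, which
  keeps the procedure deterministic. The conventional rule is flagging
  D > 4/n; the inverted reading (D > n/4, which removes almost nothing)
  is exposed as `cooksCutoff = "n/4"` for users who want it. A robust
  (Huber IRLS, `MASS::rlm`) alternative is available as
  `method = "robust"`.
* **Clamping.** Negative predicted concentrations (possible with a
  negative intercept in the untransformed fit) are clamped to zero
  because the weighted-density model requires non-negative abundance.
* **Per-library sequin dose factors.** Designs that dose more sequin mix
  into the middle fractions than the tails are handled by per-library
  multipliers of the reference concentrations (`doseFactors`), which the
  simulator records with the dataset and the readers round-trip.

Alternative abundance measures — relative coverage, relative abundance ×
DNA concentration, relative coverage × DNA concentration, and raw
coverage — are provided for method comparison
(`relativeCoverage()`, `abundanceByDNA()`, `unscaledCoverage()`).

# Spike-in quality control

Pre-centrifugation spike-ins have distinct expected peak densities. For
every sample, `spikeinQC()` takes each spike-in's observed peak as the
density of its argmax fraction (no smoothing — the simplest deterministic
reading of "peak") and passes the sample only if all spike-ins are
detected and the observed peaks, walked in expected order, never strictly
decrease. A tie — two spike-ins peaking in the same fraction — is
tolerated, because with closely spaced spike-ins ordinary coverage noise
can move an argmax by one fraction, whereas a strict inversion indicates
a physically reordered gradient. `runPipeline()` excludes failed samples
before any model sees the data.

# AFE estimation

The qSIP model converts the relative shift of the abundance-weighted mean
buoyant density into an atom fraction excess through three molecular
weights (`mLight()`, `mLab()`, `mHeavyMax()`); the constants are those of
the carbon formulation, kept overridable per isotope because the heavy-max
relation is published in its <sup>13</sup>C form while an
<sup>18</sup>O variant of the AFE equation exists
(`isotopeParams()`). The ΔBD model (`deltaBDAFE()`) divides the shift by
I<sub>max</sub>, the maximum linear shift at 100 % labeling.
I<sub>max</sub> has **no default**: it depends on isotope and gradient
conditions (see Birnie & Rickwood's treatment of isopycnic
centrifugation), so it is a required user input.

Decisions:

* **Condition means.** W<sub>Light</sub>/W<sub>Lab</sub> are unweighted
  arithmetic means of per-replicate W<sub>ij</sub>; replicates are the
  unit of biological replication. Replicates where a genome is entirely
  absent contribute nothing (rather than a zero), and a genome absent
  from a whole condition has no estimate.
* **Bootstrap.** `estimateAFE()` resamples whole replicates with
  replacement, independently within condition (default `nBoot = 1000`),
  and reports percentile intervals, which are deterministic given the
  seed. Draws in which a genome vanishes from a condition are discarded
  and counted; more than 50 % discards flags the estimate unstable. The
  draws are retained on the result so `adjustCI()` can recompute
  intervals at Bonferroni (1 − α/m) or false-coverage-rate
  (1 − R·q/m over the R selected genomes) levels without re-running.
* **No clamping of the point estimate.** AFE may be negative; labeling
  decisions use CI bounds against a threshold (`afeThresholdCall()`),
  with 0 recovering the usual "significantly above zero" rule.
* **Known limitation.** With three replicates per condition, percentile
  bootstrap intervals undercover: across 100 simulated 3v3 datasets at
  20 % coverage noise, nominal 95 % intervals covered the truth ~81 % of
  the time. No resampling scheme over three exchangeable replicates
  attains the nominal level; more replicates, not more bootstrap draws,
  is the remedy. Interval-based calls should be read accordingly, and
  the multiplicity adjustments above mitigate the resulting
  false-positive pressure in practice.

# Incorporator identification

HR-SIP (`hrSip()`) tests each genome for higher absolute abundance in a
heavy window (default 1.71 g/mL — just above the theoretical density of
50.4 % GC DNA, 1.709 g/mL — up to the maximum treatment density).
MW-HR-SIP (`mwHrSip()`) uses three overlapping windows, 1.71–1.74,
1.72–1.75, 1.73–1.76 g/mL. Both scan sparsity thresholds 0–30 % by 5 %:
at threshold *s* only genomes present (abundance strictly positive) in
more than *s* of the window fractions are tested, and the threshold with
the most rejections is used for the final calls.

* **Test backend.** The default two-group test is a one-sided Welch
  t-test on log1p absolute abundance of per-sample window totals — a
  deliberate, documented simplification relative to the
  negative-binomial Wald test used by the HTSSIP lineage; the backend is
  pluggable (`testFun`) for anyone who wants to drop in another
  two-group contract. Degenerate inputs are defined: both groups constant
  and equal gives p = 1; insufficient replication marks the genome
  untestable (NA) rather than erroring.
* **Correction scope.** Within each window, BH correction runs across
  that window's testable genomes; a genome is labeled if significant in
  any window. Pooling the correction across windows was evaluated and
  discards too much power: with 3v3 replicates the smallest achievable
  one-sided Welch p is on the order of 10⁻³, so tripling the family size
  routinely pushes true positives past the 5 % threshold.
* **Filters.** `coverageFilter()` retains genomes whose mean total
  coverage (mean over samples of summed per-fraction coverage) reaches
  the threshold, inclusive; raising the threshold, or the minimum AFE,
  can only shrink the labeled set.
* **Combining methods.** `consensusCalls()` defaults to intersection:
  false positives of density-shift models and of window tests tend not
  to overlap, so requiring agreement removes them; union mode exists for
  completeness. The sequential workflow (`sequentialWorkflow()`) is
  usually preferable: MW-HR-SIP first, then bootstrap qSIP restricted to
  the candidates, with the interval adjustment computed over the reduced
  set — fewer hypotheses, tighter adjusted intervals, same final
  specificity.

`performanceMetrics()` scores calls against known truth with
specificity = TN/(FP+TN), sensitivity = TP/(TP+FN), and balanced accuracy
as their mean.

# The simulator

`simulateSipExperiment()` generates the full input bundle — genome,
sequin and spike-in coverage over replicated gradients, fraction
metadata, references, and a truth table — from a `simConfig()`. It
emulates:

* a community panel plus one labeled focal genome
  (`defaultGenomePanel()`: 10 unlabeled genomes, GC 0.30–0.70, total
  abundances spread 16-fold; focal genome GC 0.504 at 32 % AFE, the
  design of a spiked-isolate validation experiment);
* 3 control + 3 treatment replicates of 16 fractions spanning
  1.67–1.77 g/mL;
* per-genome Gaussian spread along the gradient with
  `peakSd = 0.006` g/mL — there is no field-anchored dispersion model, so
  this was set once so a genome spans roughly 4–6 fractions, and not
  revisited;
* multiplicative lognormal coverage noise (`coverageNoiseCv`, mean 1),
  per-library sequencing depth variation (`depthLogSd`), and a linear
  sequin response through the same depth factor, so sequin scaling can
  genuinely undo depth variation;
* sequins in four 4-fold concentration groups, dosed 3× into the middle
  eight fractions versus the tails;
* six spike-ins whose expected peaks tile the grid in close pairs
  (fractions 3/4, 7/8, 11/12) — mirroring a six-spike-in design spanning
  37–63 % GC, and chosen so that even a single adjacent-fraction
  transposition of a gradient provably perturbs the observed peak order;
* gradient accidents (`disturbGradient()`: adjacent-pair swap, an
  involution, or a full shuffle) and read subsampling
  (`diluteCoverage()`: Poisson thinning of the implied read counts).

Two numerical points matter for exactness. The labeled peak position is
obtained by inverting the qSIP model (`labeledCenterDensity()`), so the
noiseless pipeline round-trips AFE by construction; and because a
Gaussian renormalized on a truncated, discrete grid does *not* have its
weighted mean at the analytic center (edge truncation alone shifts it by
up to ~10⁻⁴ g/mL), the fraction weights receive a closed-form tilt
correction, w′ = w·(1 + λ(ρ − c)) with λ chosen so the discretized mean
equals the center exactly. Mass is conserved by renormalization. Mixtures
of unlabeled and labeled DNA are sums of per-component placements; since
the weighted mean is linear in mass, a mixture is exactly equivalent to
uniform labeling at the mass-weighted AFE, which the tests verify.

What the simulator does **not** model: read mapping noise and reference
bias, chimeric or contaminated bins, GC-dependent sequencing bias, and
gradient-to-gradient density miscalibration. Passing tests therefore
demonstrate correctness of the estimators under the stated generative
model, not robustness to artifacts outside it. One visible consequence:
under pure Poisson thinning the density signal survives to roughly one
read per sample, so coverage-dilution degradation only appears once the
diluted genome approaches absence — the validation suite's dilution
series therefore starts from a genome at the low-coverage end (0.02×
total) so the factor grid {1, 0.1, 0.01, 0.001} actually crosses the
detection floor. On real data, detection failures begin at substantially
higher coverage.

# MAG dereplication

`clusterMAGs()` consumes a precomputed pairwise gANI/AF table (computing
the similarities is out of scope), takes the minimum of the two
orientations of each pair, thresholds inclusively (defaults
gANI ≥ 96.5, AF ≥ 30 — species-level delineation), and single-linkage
clusters via connected components. Representatives are chosen by highest
completeness, then lowest contamination, then greatest length — the
criteria are standard, their order is a package decision since no
canonical order exists. The test suite checks the clustering against an
independent brute-force component search on random graphs up to 50
nodes.

# Problem sizes in the validation suite

The simulation-backed checks use 11–50 genomes × 96 fraction libraries,
20 seeds for the stochastic properties (rank recovery at 20 % noise, null
false-positive control, dilution monotonicity), 100–1000 bootstrap draws,
and a 15-point GC × AFE grid for the noiseless round-trip at 10⁻⁶
tolerance. These sizes were chosen so each property is measured on the
same replicate structure as the default study design (3v3 × 16
fractions) with seed-averaged stochastic margins.
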