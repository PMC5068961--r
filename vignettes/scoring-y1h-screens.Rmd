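---
title: "Scoring arrayed yeast one-hybrid screens: model and design choices"
author: "y1hscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring arrayed yeast one-hybrid screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(y1hscreen)
```

## The assay and what the pipeline computes

A yeast one-hybrid (Y1H) screen asks which transcription factors (TFs) can
bind a DNA sequence of interest. Each DNA "bait" is integrated upstream of a
*HIS3* reporter in a yeast strain; each TF "prey" is fused to the Gal4
activation domain (AD). When the TF binds the bait, the reporter is
expressed and the cell grows on medium lacking histidine. Selection
stringency is tuned with 3-amino-1,2,4-triazole (3AT), a competitive
inhibitor of the His3 enzyme: the more 3AT, the more reporter output is
needed to grow, so each bait is screened at several 3AT concentrations
(chosen per bait by a wet-lab self-activation pre-screen, which enters this
package only as the bait's configured level list).

The screens this package scores are arrayed: a 384-position TF collection is
spotted in quadruplicate onto 1536-position selection plates, so every
bait–TF combination appears as a 2×2 "quartet" of replicate colonies on a
16×24 quartet grid. Plates are imaged after 7 and 10 days and quantified by
a colony quantifier in the Gitter family, yielding one table of colony
pixel areas and circularity flags per plate. From there the pipeline is:

1. **Quartet assembly** — group wells into quartets, take the natural log of
   each present, circular colony's pixel area. A pixel area of 0 means "no
   colony detected" and never enters as ln(0).
2. **Quartet QC** — exclude quartets that (a) have fewer than two
   detectable circular colonies, (b) have mean ln-area < 2, or (c) have an
   index of dispersion (sample variance / mean of the ln-areas) > 0.2.
   Surviving quartets are summarised by their mean ln-area.
3. **Plate background** — correct a detected edge effect, screen outliers
   with an iterative Grubbs test, and estimate the plate's background mean
   and SD from the survivors.
4. **Scoring** — every QC-passing quartet (including Grubbs-removed
   outliers, which is where true interactions end up) gets
   z = (value − mean)/SD and a one-sided upper-tail normal p-value.
5. **Calling** — a bait–TF pair is called an interaction when p < 0.005 at
   two or more 3AT levels on day 7.

## Quartet QC choices

The three filters run in the order a → b → c, and the first failing rule
labels the quartet. Rule (a) is read as "fewer than two" present, circular
colonies: the single-colony case is the stated rule, and a zero-colony
quartet is strictly less informative, so it is excluded for the same
reason. Both the mean-area rule and the dispersion rule operate on the
ln-scale areas, because areas are logged before any quartet statistic is
formed. The dispersion index uses the sample (n − 1) variance; with the
0.2 cutoff this is what makes the filter reproducible, so it is stated
here explicitly. Exclusion is by strict inequality: a quartet at mean
exactly 2, or dispersion exactly 0.2, survives. The mean and dispersion
are computed over the detected, circular colonies only — absent colonies
are not counted as zeros; rule (a) already handles sparse quartets.

## Plate background: order of operations

The background distribution is described as outlier-screened **and**
edge-corrected, and Z-scores are computed from edge-corrected values. The
pipeline therefore applies **edge correction first**, then Grubbs
screening of the corrected values, then background estimation. Running the
outlier screen on uncorrected values would let a strong edge effect
masquerade as a cloud of outliers; correcting first lets the Grubbs test
see a homogeneous background. Both alphas default to 0.05 and are
arguments, as is the order-sensitive choice of the Welch (unequal
variance) t-test for the edge comparison — the strata have 144 edge
versus 240 interior quartets and no reason to share a variance.

The edge set is the outermost **two** quartet rows and columns (quartet
granularity, 144 of 384 positions). When the t-test is significant, edge
values are shifted by −(mean(edge) − mean(interior)). The shift is applied
symmetrically — also when the edge mean is *below* the interior mean —
because a one-sided rule would leave an undefined branch; the typical and
motivating case is excess edge growth, and the downward shift recovers it.

The Grubbs screen is two-sided and iterative (remove the most extreme
value, re-test, repeat), with the critical value
((n−1)/√n)·√(t²/(n−2+t²)), t the upper α/(2n) Student-t quantile on n−2
degrees of freedom. One-pass versus iterative and the alpha are not
dictated by the procedure's description; iterative two-sided at 0.05 is
the conventional default and both are exposed as arguments. Removed
quartets are *not* discarded: they are scored against the survivor
background like everything else — a planted or real interaction is
usually exactly the quartet the Grubbs screen removes.

Control quartets (untransformed cells, AD-only) contribute to the
background distribution and are scored, but never produce interaction
records; they are a QC channel. A plate with fewer than three QC-passing
quartets, or zero background spread, is unscorable; its pairs are
reported as untested rather than negative, as are all pairs on plates
excluded for contamination.

## Calling and sensitivity

Significance is strict: p < 0.005 calls, p = 0.005 does not. The consensus
rule counts **distinct 3AT levels** (not plates or days) with a
significant record at the calling day; the headline call set uses day 7
and ≥ 2 levels, with day 10 retained for sensitivity analysis. The
`sensitivityCurve()` function recomputes the screen-level hit count — the
number of distinct TFs with at least one qualifying bait — over a grid of
thresholds, for each day and each minimum-level requirement, pooled
across 3AT levels and also per single level. Pooled and per-level curves
are labelled in the output rather than collapsed, since baits may be
screened at different level sets.

## The synthetic-screen generator

Real plate images are not shipped; the generator emits screens with the
statistical structure the pipeline assumes, plus the ground truth to score
recovery. The model is deliberately the analysis model run forwards:

* Well ln-areas are normal around a plate background mean μ0 (default
  6.5 ≈ ln 665 pixels) with total SD σ0 (default 0.4).
* Replicate spots of one transformant are clones, so they share a
  quartet-level offset; by default that offset carries 0.5 of σ0 (the
  remaining variance is well-level noise). This is a modelling choice, not
  a measured quantity.
* A planted interaction adds δ ≥ 0 to the quartet's mean at the configured
  (bait, 3AT level) combinations — per-level δ so that the ≥ 2-level
  consensus rule can be exercised with interactions present at some levels
  and absent at others.
* An edge-affected plate adds a constant to the ln-areas of the 144 edge
  quartets.
* Pixel areas are round(exp(x)); noncircular and missing-colony artifacts
  are injected per well at configurable rates (default 1% each).
* The same seed yields an identical screen.

Defaults mirror the screen architecture the pipeline targets: 670 TFs on
two 384-position arrays (25 empty-well and 24 AD-only controls per array,
at fixed positions), 26 tested baits (8 mel, 9 pse, 9 will) at three 3AT
levels each, days 7 and 10 — 312 plates. What the generator does **not**
emulate: image-level artifacts (glare, grid misdetection), growth kinetics
over time (day 7 and day 10 are drawn independently rather than as one
growing colony), spatial autocorrelation beyond the edge strata, and
bait-specific background levels. Passing tests on synthetic screens
therefore demonstrate the statistics are implemented and calibrated as
specified, not that the thresholds are optimal for any particular real
screen.

## Calibrated null rates

The nominal per-quartet false-positive rate at p < 0.005 is not exactly
0.005: the Grubbs screen trims the tails before the mean and SD are
estimated (biasing the SD slightly down but removing the draws that would
have been extreme), and both moments are finite-sample estimates from
≈ 380 values. Rather than pretend the nominal rate holds, the package
freezes empirically calibrated values (`nullCallRates()`): the
per-quartet rate 0.004771 (calibrated over 600 null plates, ≈ 2 × 10⁵
quartets) and the consensus-call rate 6.47 × 10⁻⁵ per tested pair
(calibrated over 300 null screens, ≈ 2 × 10⁵ pairs; consistent with the
3·p² expectation for ≥ 2 of 3 independent levels). Property tests assert
fresh simulations stay within three binomial SDs of these constants.

## Numerical and degenerate-input choices

* pixel_area = 0 ⇒ `present = FALSE`; ln() is never taken at 0.
* All cutoffs are strict inequalities exactly as printed (mean < 2,
  dispersion > 0.2, p < 0.005 exclude/call).
* SDs are sample (n − 1) throughout.
* Grubbs on a zero-spread vector returns no outliers; an all-constant
  plate is unscorable rather than producing infinite Z-scores.
* The edge t-test on essentially constant strata is treated as
  "no effect detected" rather than an error.
* Ties in the Grubbs most-extreme value resolve to the first index
  (continuous data make this vanishingly rare).
* Test-count arithmetic reports both the nominal 670 × 26 = 17,420 and an
  exclusion-adjusted count (e.g. one contaminated array half removes 335
  pairs for that bait: 17,085), with the half-array figure documented as
  approximate.

## Problem sizes used by the test suite

The suite runs the full 312-plate default screen once for the Z-score and
sensitivity-curve properties, 20 three-plate screens for planted-recall,
20 six-plate null screens for the false-positive band, 100 single-plate
screens for edge-effect detection, and 1,000 random vectors (n ≤ 20) for
the Grubbs oracle comparison — sizes chosen so the whole suite completes
in well under a minute while keeping every binomial band meaningful.

## Known limitations

* Interactions detectable only at low 3AT (e.g. a repressor binding that
  yields weak reporter output) are outside the consensus rule by design
  and will be missed.
* No multiple-testing correction is applied within a plate; the fixed
  threshold plus multi-level consensus plays that role.
* Cross-plate normalisation is limited to the per-plate background model;
  systematic batch effects across plates are not modelled.
* The RNAi phenotype table and nuclear-receptor annotations are inputs
  transcribed from published results; the package joins them, it does not
  re-derive them.
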