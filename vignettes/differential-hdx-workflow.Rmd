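---
title: "Differential HDX-MS filtering and visualization with hdxdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential HDX-MS filtering and visualization with hdxdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxdiff)
```

## The measurement and the question

Backbone amide hydrogens exchange with solvent deuterium at rates set by
hydrogen bonding and solvent accessibility. In a differential HDX-MS
experiment the same protein is measured in two states — a reference (wild
type, apo) and an altered state (mutant, ligand-bound) — at several
labelling times, and the question is which peptides show a *significant*
difference in deuterium uptake. Upstream vendor software handles peptide
identification and mass assignment and exports peptide-level tables;
hdxdiff starts from those tables.

Two inputs are understood, in a remappable CSV dialect whose default
header names follow the DynamX export convention:

* the **state** file: one row per protein / peptide / state / exposure,
  with peptide bounds, sequence, the maximum possible uptake, and the
  mean and standard deviation of observed uptake across replicates;
* the **difference** file: one row per peptide / exposure with the signed
  uptake difference between two states.

Because the difference file does not record which state was subtracted
from which, the sign convention (`state_order`) is a required run
parameter and is echoed into every output. Exposure 0 is the unlabelled
control: rows are kept on parse but excluded from all timepoint
statistics and plots. The replicate count *N* is likewise not a column
in the export; it is a run parameter with default 3.

## The confidence-limit model

Rather than testing each peptide separately, the workflow pools the
dispersion of *all* peptide differences at a labelling time into one
global band about zero. With σ<sub>t</sub> the sample standard deviation
(denominator *n* − 1) of the per-peptide uptake differences at exposure
*t*, *N* replicates, and α the two-tailed Student-*t* critical value at
*N* − 1 degrees of freedom:

* per-timepoint limit: (σ<sub>t</sub> / √N) · α — a standard error scaled
  by the critical value;
* summed limit (differences aggregated over all *n* timepoints):
  α · √( Σ<sub>t</sub> σ<sub>t</sub>² / N ) — errors propagate as a
  simple sum of variances, and the expression reduces exactly to the
  per-timepoint limit when n = 1.

Defaults are the triplicate design: N = 3, df = 2, 98% confidence, hence
α = 6.965 (9.925 at 99%). An explicit `alpha_override` reproduces
published critical values independent of the quantile routine. Peptides
with |ΔD| strictly greater than the limit are significant — deprotected
if positive, protected if negative; equality with the limit is
classified non-significant, the conservative reading of "outside the
limits". Woods plots always draw *both* the 98% and 99% bands (dashed
and dotted) even though only one filters, so the effect of tightening or
relaxing the filter is visible at a glance.

Design choices worth stating explicitly, since the underlying formulas
are sometimes typeset ambiguously in the literature:

* the per-timepoint divisor is √N (a standard error), not N — this is
  the standard form of the pooled-dispersion confidence interval for HDX
  differences, and it is a single code path should an alternative
  reading ever be needed;
* in the summed form, the number of timepoints enters only as the
  summation bound; only N scales the summed variance. Any other reading
  would break the n = 1 reduction to the per-timepoint limit;
* σ<sub>t</sub> is estimated from the spread of per-peptide differences
  (the only dispersion recoverable from a difference file alone). When
  per-peptide pooled SDs are present, `method = "pooled"` uses their
  mean instead; the spread estimator is the default. Both the 98% and
  99% bands share the same dispersion estimate per timepoint.

A consequence users should understand: the spread-based σ<sub>t</sub>
includes any *true* differences present, so a dataset where a large
fraction of peptides genuinely shifts will have inflated limits. The
statistic presumes that most peptides are null — the usual situation of
a localized conformational change — and is conservative otherwise. No
per-peptide testing or multiple-testing correction is attempted; the
global band *is* the method.

## Per-residue maps and projections

Peptide-level results are flattened to residue tracks (1-based,
inclusive bounds): coverage (is the residue spanned by any peptide),
redundancy (how many distinct peptides span it, after collapsing rows
identical in protein/start/end/sequence/modification — charge states
arrive pre-merged), and projection payloads. For structure projection,
each residue covered by at least one significant peptide carries the
combined payload of those peptides — absolute ΔD in Da, or ΔRFU, the
difference scaled by the peptide's maximum uptake. Overlaps resolve by
`mean` (default; smooth and robust) or `max_magnitude` (the single
largest effect wins; ties resolve deterministically to the
earliest-starting peptide). Residues covered only by non-significant
peptides carry 0 and render white; uncovered residues stay missing and
render grey. No attempt is made to deconvolve residue-level uptake from
overlapping peptides — that is a research problem in its own right, and
the per-residue values here are display summaries, not estimates of
single-residue exchange.

Coverage and redundancy computation is delegated to `IRanges::coverage`;
the test suite checks it against an independent brute-force per-residue
scan on randomly generated maps.

PyMOL scripts are plain-text command files: a grey base coat over the
whole chain, then run-length-merged `color 0xRRGGBB, chain A and resi
i-j` commands, so every residue ends with exactly one effective color.
Ramps are linear in RGB from white to the pole color (red for
deprotected, blue for protected, magenta for redundancy), normalized by
the dataset maximum. Hex literals avoid dependence on the viewer's named
palettes; an optional residue offset handles construct-vs-structure
numbering shifts. Headers omit the date by default so identical inputs
give byte-identical files.

## The synthetic generator

Everything above is testable without any experimental download because
the package ships a ground-truthed generator. It emulates:

* a random sequence with controlled proline density (default 5%);
  prolines and each peptide's first residue carry no observable amide,
  so `MaxUptake` = peptide length − 1 − internal prolines;
* per-residue first-order exchange: residue *i* contributes
  1 − exp(−k<sub>i</sub>t) Da at exposure *t*, with rates drawn
  log-normal (default meanlog log 0.05, sdlog 1.5 min⁻¹) so that the
  default exposures 0.5, 5, 30, 240 min span the saturation curve. This
  is phenomenological, not intrinsic-rate chemistry — no pH/temperature
  model, no back-exchange — but it yields exact closed-form oracles,
  which is what the downstream statistics need;
* a peptide map tiling the protein with configurable start spacing,
  copies per start and length distribution, with deliberate uncovered
  gaps; the defaults produce roughly 90% coverage and maximum redundancy
  above 10 on a 490-residue protein;
* effect blocks that *multiply* the altered state's rates (factor < 1
  protects, > 1 deprotects), so the true ΔD varies with exposure and
  per-timepoint vs summed classification genuinely differ;
* replicate noise: each of N replicate measurements adds Gaussian noise
  of stated SD (default 0.05 Da); reported means and SDs are computed
  across replicates, and the difference table is the difference of the
  replicate means with SDs pooled as a sum of variances. Exposure-0 rows
  are written with uptake exactly 0.

What the generator does **not** emulate — back-exchange, isotope
envelopes, peptide misassignment, systematic between-run drift,
heteroscedastic noise — bounds what passing tests show: they validate
the statistics, flattening and export contracts, not robustness to every
artifact of real instrument data.

## Calibration and recovery checks

The test suite includes two simulation-based checks of the 98% filter,
run at sizes chosen to keep the default suite fast while leaving no
statistical ambiguity:

* **null calibration** — no true effects, triplicate 0.05 Da noise, 4
  exposures, a dense map of more than 5000 peptides on an 8500-residue
  protein. The observed per-peptide difference noise is
  0.05·√(2/3) ≈ 0.041 Da while the limit sits near 0.165 Da (about 4
  noise SDs), so far less than 2% of null peptide-timepoints may be
  flagged; the observed rate is orders of magnitude below that bound.
* **recovery** — two 41-residue blocks with strong rate factors (0.02
  and 50) on a 10000-residue protein, i.e. sparse localized effects that
  leave the pooled dispersion near the noise floor. Of the
  peptide-timepoints whose true shift is at least twice the applied
  limit, at least 99% must be flagged with the correct sign.

## Numerical and rendering choices

* Dispersion requires at least 2 difference records per exposure; fewer
  is a hard error, not a silent zero.
* Duplicate (peptide, state, exposure) rows are a hard error — silent
  aggregation would corrupt σ<sub>t</sub>. Unparseable numeric rows are
  skipped and counted in the parse report; negative uptake is tolerated
  with a warning (measurement noise).
* Summed-mode aggregation uses each peptide's available nonzero
  exposures, recording the count, since missingness handling is
  otherwise undefined.
* Woods plots share a symmetric y range across panels (max |ΔD| padded
  10%) so panels are comparable; more than 8 timepoints paginate into
  multiple figures (8 per page). Band legends print the limits as ±Da to
  two decimals. ΔRFU as a y metric drops the bands, which are defined in
  Da.
* Vector figures use the cairo SVG device with a non-raster colorbar;
  identical inputs yield byte-identical SVG output, which the tests
  verify end-to-end along with the CSVs and .pml scripts.
* RFU is not clamped; values outside [−1.2, 1.2] warn (back-exchange and
  noise can push slightly past 1), and `max_uptake = 0` yields NA with a
  warning rather than aborting the run.

## Limitations

* The global band assumes exchange-difference dispersion is comparable
  across the peptide ensemble; strongly heteroscedastic data (very short
  vs very long peptides) would call for the pooled-SD estimator or a
  per-peptide hybrid test, which is out of scope here.
* Structure projection assumes the CSV numbering matches the structure's
  author numbering up to a constant offset.
* No parsing of raw spectra or vendor session files, no butterfly or
  difference plots, and no interactive cursor — the figures and CSVs are
  the interface.
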