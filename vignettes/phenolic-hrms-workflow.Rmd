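---
title: "Profiling cellular phenolic compounds from direct-infusion HRMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling cellular phenolic compounds from direct-infusion HRMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolms)
```

## The problem

Microalgae and protists such as *Euglena gracilis* respond to sub-lethal
metal exposure (Cd, Cu, Co, ...) by remodelling their secondary
metabolism, in particular the production of phenolic compounds that
chelate metal ions and scavenge reactive oxygen species. Untargeted
direct-infusion negative-mode high-resolution mass spectrometry of
phenolic extracts yields peak lists — (m/z, intensity, S/N) triples —
from which the phenolic complement can be characterized without compound
identification: every peak is assigned a molecular formula, formulas are
classified as phenolic or not from their elemental composition, and the
phenolic subset is summarized by abundance, diversity and
composition-derived indices. `phenolms` implements that entire workflow,
together with a ground-truth-known synthetic-data generator so every
stage can be validated end to end.

## Peak-list processing

Raw peak lists are cleaned in the order real acquisitions require:

1. **Quality filter** (`filter_quality()`): keep peaks with S/N strictly
   above 4, then keep peaks at or above 0.1 % of the most intense
   surviving peak. The relative-intensity reference is the base peak of
   the *same* list after S/N filtering — so the base peak always
   survives and the filter is idempotent.
2. **Blank subtraction** (`subtract_blank()`): every sample m/z within 5
   ppm of any blank m/z is removed.
3. **Replicate consensus** (`replicate_consensus()`): only peaks matched
   across *all* technical replicates (greedy nearest-first one-to-one
   matching within 5 ppm) are kept. The consensus m/z is the
   intensity-weighted mean — which also averages down the replicate mass
   errors — and the consensus intensity is the arithmetic mean, so the
   number of replicates does not inflate abundance.
4. **Fraction merging** (`merge_fractions()`): chromatographic fractions
   are unioned; coincident peaks are summed (total intensity is
   conserved).

The 5 ppm matching tolerance is half the 10 ppm assignment window: wide
enough to absorb instrument error, narrow enough never to merge two
distinct assignable masses. It is configurable everywhere it is used.

## Formula assignment

`enumerate_candidates()` enumerates **all** CHNOS formulas within the
element bounds C 1–50, H 1–100, O 1–30, N 0–2, S 0–2 whose deprotonated
ion `[M−H]⁻` (m/z = neutral monoisotopic mass − 1.007276 Da, electron
included) lies within 10 ppm of the observed m/z. The implementation
loops over (N, S, C, O) and solves the hydrogen count from the mass
window, which is exhaustively equivalent to the full five-element grid
because adjacent H counts are ~1.008 Da apart — far wider than any
realistic ppm window; the equivalence is verified in the test suite
against a brute-force grid oracle. Candidates must pass a minimal
chemical validity screen: rings-plus-double-bonds
$\mathrm{RDBE} = 1 + C - H/2 + N/2 \ge 0$ and integer-valued (an
even-electron neutral molecule). No element-ratio priors or isotope
scoring are applied: only the stated criteria.

`assign_formulas()` gives each peak the candidate with the smallest
absolute ppm error, ties broken toward fewer heteroatoms and then lower
mass. The mass calibration anchor is catechin, whose `[M−H]⁻` ion
computes to m/z 289.072:

```{r}
round(ion_mz(parse_formula("C15H14O6")), 3)
```

### How reliable is a 10 ppm assignment?

A point worth being explicit about, because it bounds what any such
workflow can claim: the space of valid CHNOS formulas is dense, and its
density grows with mass. Measuring the distance from each formula to its
nearest valid competitor:

```{r competitor-spacing, eval = FALSE}
lib <- generate_formula_library(150, phenolic_fraction = 0.4, seed = 2)
spacing <- vapply(seq_len(nrow(lib)), function(i) {
  cand <- enumerate_candidates(lib$mz[i], tol_ppm = 10)
  min(abs(cand$error_ppm[cand$formula != lib$formula[i]]), Inf)
}, numeric(1))
tapply(spacing, cut(lib$mz, c(100, 300, 500, 700, 1000)), median)
```

the median nearest-competitor spacing falls from roughly 8 ppm below
m/z 300 to about 2 ppm at m/z 300–500 and **below 1 ppm above m/z 500**.
With a realistic mass-error scale of ~2 ppm per replicate (~1.4 ppm
after duplicate consensus), nearest-match assignment is therefore
near-certain below m/z 300 but increasingly ambiguous above it — no
ranking rule can beat this, because picking the nearest candidate *is*
the maximum-likelihood rule under a symmetric error model. In the
package's own end-to-end simulations at 2 ppm error, about a third of
peaks above m/z 400 are assigned a near-degenerate neighbour rather than
the true formula. Summary statistics that weight by intensity
(`rel_intensity_pct` in particular) inherit this ambiguity: a single
intense peak whose wrong assignment crosses the phenolic boundary can
shift the phenolic share by percentage points. Conclusions drawn from
formula-level statistics at this tolerance should be treated as
composition-space estimates, not per-compound identifications; the
zero-noise limit (below) verifies that the pipeline itself adds no error
beyond this intrinsic ambiguity.

## Molecular descriptors and phenolic classification

For a formula $\mathrm{C}_c\mathrm{H}_h\mathrm{N}_n\mathrm{O}_o\mathrm{S}_s$:

* elemental ratios O/C, H/C, N/C, S/C (`elemental_ratios()`);
* double-bond equivalents in the oxygen/sulfur-corrected convention used
  throughout this workflow, $\mathrm{DBE} = 1 + C - O - S - (N+H)/2$,
  which can be negative for highly oxygenated formulas; the textbook
  rings-plus-unsaturations count $1 + C - H/2 + N/2$ is always reported
  alongside it (`dbe()`);
* the modified aromaticity index
  $\mathrm{AI_{mod}} = \dfrac{1 + C - O/2 - S - (N+H)/2}{C - O/2 - N - S}$,
  set to 0 when the denominator is non-positive or the numerator
  negative, following common FT-MS practice (`aimod()`);
* the nominal oxidation state of carbon
  $\mathrm{NOSC} = 4 - (4C + H - 3N - 2O - 2S)/C$ (`nosc()`).

A formula is **phenolic** when it falls in the phenolic region of van
Krevelen space with sub-aromatic character:
$0.6 < \mathrm{H/C} < 1.5$, $0.3 < \mathrm{O/C} < 0.85$ and
$\mathrm{AI_{mod}} < 0.67$, all inequalities strict. Classification
depends only on the formula, never on intensity.

`summarize_phenolics()` reports, over the phenolic-flagged peaks: the
relative intensity as a percentage of the total signal of **all**
processed peaks (assigned or not — the only definition that needs no
extra convention; a `denominator = "assigned"` alternative is provided),
the number of distinct phenolic formulas, the intensity-weighted average
m/z, intensity-weighted means of all indices, and the Gini–Simpson
abundance diversity
$D_A = 1 - \sum_i p_i^2$ over sum-normalized per-formula intensities
(peaks sharing a formula are summed first). $D_A$ is 0 for a single
formula and at most $1 - 1/N$, attained exactly at equal abundances; all
of these statistics are invariant to rescaling every intensity by a
constant.

## Mass-difference networks

`build_network()` treats each phenolic m/z as a node and emits an edge
for every unordered pair whose mass difference matches a biochemical
transformation — an amino-acid residue, nucleobase, sugar or acyl
increment, and related small metabolites — within tolerance. All
qualifying (pair, transformation) combinations are kept as parallel
edges; dropping multi-edges would need an arbitrary priority rule.

A subtlety: "±2 ppm" of *what*? 2 ppm of a 57 Da residue mass is 0.1
mDa, tighter than any instrument delivers for a difference of two
measured masses. Because instrumental error scales with measured m/z and
both members of a pair carry it, the tolerance is referenced to the
**larger member of the pair**: `tol_ppm * 1e-6 * mz_hi`. An absolute
window (`mode = "mda"`, default 0.5 mDa) is available for users who
prefer it; the mode used is recorded in the network object.

Transformations are grouped by heteroatom content — S-containing
(group 1), N only (2), N and O (3), O only (4) — derived from each
transformation's formula. The shipped table of 41 entries
(`default_transformations()`) is a package-curated stand-in built from
amino-acid residues, nucleobases and common increments with masses
computed from their formulas; laboratories with their own metabolite
list replace it via `load_transformations()`, which cross-checks any
formula column against the computed monoisotopic mass within 1 mDa.

## Dose–response and EC50

`fit_ec50()` fits the four-parameter log-logistic
$y = \mathrm{bottom} + \dfrac{\mathrm{top} - \mathrm{bottom}}
{1 + (d/\mathrm{EC_{50}})^{\mathrm{hill}}}$
on log10 dose with bottom constrained non-negative (a two-parameter
variant pins bottom = 0 and top at the lowest-dose mean). Live-cell
counts carry multiplicative, roughly constant-CV error, so the residuals
are minimized on the **log-response** scale by default: response-scale
least squares under multiplicative noise is badly heteroscedastic — in
simulation at 10 % CV it roughly doubles to triples the median EC50
error — whereas the log scale stabilizes the variance and properly
weights the informative transition region. `scale = "linear"` restores
plain least squares (and is used automatically when responses contain
zeros). A deterministic multistart grid (hill ∈ {0.5, 1, 2, 4} × EC50 at
the dose quartiles) feeds a Levenberg–Marquardt optimizer; the best
converged start by residual sum of squares wins, so a given table always
produces the same fit. The standard error of EC50 is obtained from the
fit curvature by the delta method; $r^2$ is computed on the fitted
scale, and an EC50 outside the tested dose range is flagged
extrapolated.

The generator `generate_dose_response()` emulates a metal exposure
series: 8 doses in half-log (3.16-fold) serial dilution spanning 1.75
decades on each side of the true EC50, run in biological duplicate, with
mean-preserving lognormal noise. On noiseless data the fit recovers the
generating EC50 to better than 0.1 % with $r^2 = 1$; at 10 % CV the
median absolute relative error is a few percent (the test suite runs
this recovery study over 200 seeds).

## Group statistics

`compare_groups()` applies a Shapiro–Wilk normality screen per group,
pairwise two-sample Wilcoxon rank-sum tests (exact p-values for small
tie-free samples), and a compact letter display at α = 0.05 derived
deterministically from the maximal cliques of the non-significance
graph. No multiple-testing correction is applied by default, matching
the per-pair α policy such studies state; Holm or any other
`p.adjust()` method can be switched on. With duplicate samples the exact
rank-sum test cannot reach p < 0.05 at all — the function warns about
this power limit rather than hiding it.

## The synthetic-data generator

`simulate_ground_truth()` builds the known truth behind one sample:

* a formula library within the element bounds, drawn in **ratio space**
  (H/C 0.62–1.48 and O/C 0.32–0.83 for phenolic formulas, H/C 0.4–2.0
  and O/C 0.02–1.0 otherwise, scaled with a uniformly drawn carbon
  count, low heteroatom counts preferred) rather than uniformly over the
  element grid — uniform grid draws are dominated by chemically absurd
  compositions; every formula is even-electron with RDBE ≥ 0 and an
  `[M−H]⁻` m/z inside 100–1000;
* lognormal true intensities (heavy-tailed, as in electrospray peak
  lists), optionally rescaled so the phenolic share of total intensity
  equals an exact planted value;
* noise/contaminant m/z placed at least 25 ppm from every true ion and
  shared **identically** between all replicates and the blank, so blank
  subtraction is exactly testable;
* an S/N model with a constant noise floor at one fifth of the weakest
  true intensity: every true peak clears S/N > 4 by construction, while
  a configurable fraction of the noise peaks is planted below it.

`generate_peaklists()` then applies multiplicative Gaussian mass error
(default 2 ppm — well inside the 10 ppm assignment window; instrument
accuracy is a free parameter) and mean-preserving lognormal intensity
jitter (default CV 0.1) per replicate. All generators are
seed-deterministic: the same seed gives bit-identical output.
`simulate_experiment()` assembles a four-group study — control plus
three metal treatments in technical duplicate — with planted phenolic
intensity shares of 2.04 % (control) and 2.88 / 2.95 / 3.02 % (metal
groups; the middle value is a midpoint, as the emulated design reports
only a range for its metal cultures).

What the generator does **not** emulate: isotopologue patterns, adducts
and clusters, in-source fragmentation, chromatographic peak shape,
correlated (batch) mass drift, and compound identities behind the
formulas. Passing the end-to-end tests therefore demonstrates that the
pipeline's algebra and bookkeeping are correct under the stated noise
model — not that real spectra are free of the confounders above.

In the zero-noise limit the full pipeline provably reproduces the
generator's truth exactly: the surviving formula set, the phenolic
subset, $D_A$, the weighted average m/z and every weighted index agree
with values computed directly from the truth table (this is an
acceptance test). At 2 ppm error, assignment accuracy is limited by the
formula-space density discussed above; the package reports what the
chemistry allows rather than tuning the simulation to flatter itself.

## Problem sizes and numerical choices

The validation suite uses libraries of 15–60 formulas, 4–10 noise peaks,
duplicate replicates, networks up to 200 nodes against the 41-entry
transformation table, and 200-seed recovery studies for EC50 — sizes at
which every oracle (full-grid enumeration, brute-force pairwise
matching, exact rank-sum enumeration) can be computed exactly.
Floating-point guards of 1e-9 relative are applied at strict-inequality
boundaries (ppm windows, hydrogen-count bounds); ties in greedy peak
matching break toward the lower m/z; weighted means over zero total
weight and diversity over empty intensity sets are errors, not silent
NAs; an empty transformation match yields an all-zero network summary
rather than a failure.
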