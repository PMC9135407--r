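---
title: "Methods: scoring, triage and downstream analysis of an HSC inactivation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, triage and downstream analysis of an HSC inactivation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscTriage)
```

# The screening problem

Activated hepatic stellate cells (HSCs) are the myofibroblasts that
deposit scar collagen in liver fibrosis. When HSCs revert to a
quiescent-like state they re-accumulate lipid droplets, so a phenotypic
screen can read out inactivation as the fraction of cells whose Bodipy
(lipid) stain exceeds an imaging threshold. `hscTriage` implements the
computational side of such a screen end to end: plate-level scoring and
hit calling, consolidation of wells into unique chemical structures,
structural clustering and liability filtering, a qPCR secondary screen
on fibrosis marker genes (*COL1A1*, *ACTA2*) against a stable reference
(*PSMB2*), dose-response scoring with EC50 estimation, and the
pharmacokinetic and microsomal-clearance arithmetic used to judge in
vivo exposure of a candidate.

Each plate carries DMSO wells as negative controls and nortriptyline
wells (a tricyclic antidepressant that induces HSC inactivation) as
positive controls; experimental compounds run in duplicate.

# Primary-screen scoring model

For a compound with duplicate wells the raw score combines three
components, all in percent-positive units:

* **baseline distance** — the duplicate-mean percent-positive minus the
  plate baseline, taken as the 75th percentile (linear interpolation) of
  experimental duplicate means;
* **toxicity penalty** — the one-sided relative cell-count deficit of
  the compound wells versus the mean nortriptyline cell count, times
  100. Counts above the control level earn no bonus: proliferation is
  not rewarded;
* **reproducibility penalty** — half the absolute difference of the two
  replicates (their mean absolute deviation).

`score = distance − w_tox·toxicity − w_rep·reproducibility`, with both
weights defaulting to 1. The additive unit-weight combination is the
simplest reading of "penalized", and the weights are exposed so users
can reproduce alternative readings. The baseline is computed over
experimental wells only: control wells sit at the extremes of the plate
distribution by design and would bias a pooled percentile.

Scores are then normalized per plate with the control score medians:

$$\mathrm{Scaled} = \frac{-(\tilde m_{nor} - score)}{|\tilde m_{nor} - \tilde m_{DMSO}|}$$

so the nortriptyline median maps to 0 and the DMSO median to −1.
Control wells are scored with the same distance-minus-toxicity formula
(no reproducibility term, as controls are not compound duplicates). A
plate whose control medians coincide carries no normalization
information and is flagged degenerate and excluded.

Hit calling applies two rules per plate: Scaled above a fixed cutoff of
0.85 (the value the original screen derived as the top decile of
nortriptyline wells), plus a rescue rule keeping each plate's top three
experimental entries regardless of the cutoff, so plate-specific effects
cannot silence an entire plate. An optional mode re-derives the cutoff
per plate as the 90th percentile of nortriptyline Scaled values.
Ranking ties break deterministically by compound id.

# What the synthetic screen emulates

`simulate_screen()` generates the per-well tables the scorer consumes:
384-well plates with 16 DMSO and 16 nortriptyline wells (control-well
counts are asserted configuration, not an inference), 160 experimental
compounds in duplicate, an additive plate shift (SD 2 percentage
points), a minority of true actives with a configurable
percent-positive effect, and compound-specific toxicity applied
multiplicatively to expected cell counts.

Cell counts are negative-binomial (size 1000 at mean 1000 cells/well,
i.e. a count CV near 4.5%, typical of automated seeding). Positive
counts are beta-binomial given the realized cell count, with the
overdispersion solved per well so the percent-positive SD matches the
configured replicate noise (default 3 percentage points); a Gaussian
option exists for closed-form checks. The control levels default to
10 ± 3% positive for DMSO and 18 ± 4% for nortriptyline. That control
window is a deliberate design point: the positive control must sit near
the top decile of experimental wells with a gap to DMSO wide enough
that the fixed 0.85 cutoff lands *below* strong actives. If the count
dispersion is made much heavier, the noise floor of the one-sided
toxicity penalty widens the apparent control gap and the same cutoff
drifts above a +25-point active — an emulated screen tuned that way
would not function as a screen, and no cutoff-based calling could
recall its planted actives.

The generator starts at per-well counts; image segmentation and
per-plate intensity thresholds are upstream of the model and out of
scope. Features of real screens it does not emulate: spatial
within-plate gradients (edge effects), liquid-handling failures,
compound fluorescence artifacts, and day/batch drift beyond the additive
plate shift. Passing recovery tests on these simulations therefore
demonstrates correctness of the scoring and calling machinery under the
assumed noise model, not robustness to every real-plate pathology.

All generators take an explicit seed, restore the caller's RNG state,
and reproduce byte-identical tables for identical configuration.

# Structure handling and clustering

Standardization removes counterions (the fragment with the most heavy
atoms is kept; ties break to the lexicographically smallest canonical
string), applies Open Babel's charge neutralization as the fixed
protonation normalization, and emits Open Babel canonical SMILES plus
the Hill-order formula. The canonical dialect is one toolkit's, fixed
and versioned in the cascade manifest; equality of strings across
toolkits is not promised, only within-run consistency and correct
equivalence classes (verified on the packaged 60-entry toy library,
which collapses to 48 unique structures by construction).

Fingerprints are Open Babel extended-connectivity fingerprints of
radius 2 (ECFP4) over 4096 bits; similarity is Tanimoto on bits.
Clustering is deterministic leader-style sphere exclusion: compounds
sorted by descending best Scaled value (ties by id), each unassigned
compound in turn becomes a leader and captures everything within the
distance threshold. Every member is within the threshold of its
*leader*; separately, the member minimizing mean distance to the
cluster is recorded as the *center* and drives representative
selection ("the strongest hit with the most common structure"): among
the most-central half of members (configurable fraction), the highest
Scaled value wins, ties to smaller mean distance, then id. A `target_k`
mode bisects the threshold to a requested cluster count — cluster
counts from commercial clustering tools are not reproducible
bit-for-bit, so a target count is an input here, not an emergent check.

Liability triage removes PAINS matches (packaged catalog: a curated
subset of the published quinone, catechol, rhodanine, azo, phenolic
Mannich and related families; a full catalog can be supplied in the
same two-column format), frequent hitters (historical hit rate above
20% or more than 10 total hits, both exposed), optional
similarity-to-reference exclusions (Tanimoto to nortriptyline at or
above a configurable cutoff), and formula duplicates (best Scaled kept
per formula).

# The qPCR secondary screen

The multiplexed assay measures a target gene and the reference gene in
the same well, so the model regresses the target Ct on the reference Ct
(continuous covariate) with plate and chemical as categorical effects
and DMSO as the reference level — one joint ordinary-least-squares fit
across plates, which is what the model notation implies; with a single
plate the plate term is dropped. Each chemical's coefficient is its
delta-Ct versus DMSO; fold change is `efficiency^(−ΔCt)` with
efficiency defaulting to 2 (one cycle = twofold). P-values are the
coefficient t-tests; FDR is Benjamini–Hochberg across chemicals within
each gene — the standard screening default, scoped within gene because
the advancement criteria are per-gene. A chemical perfectly confounded
with plate is a hard error naming the chemical; a chemical with a
single replicate is flagged and reported without a p-value.

Advancement requires all three of: *COL1A1* fold change below 0.5 at
FDR < 0.05, *ACTA2* fold change below 0.5 at FDR < 0.05, and
plate-adjusted reference-gene (*PSMB2*) relative expression within
[0.2, 2.0] of DMSO — the last computed from the chemical coefficient of
`ct_ref ~ plate + chemical`, consistent with the plate-blocked design.

Reference-gene selection is a two-stage screen over candidate
housekeeping genes: keep genes with across-condition SD of log2
expression at most 0.15, then genes whose activated-versus-inactivated
fold change differs from 1 by at most 10%, ranked finally by measured
Ct SD ascending.

# Dose-response fitting and the priority rubric

Raw readouts are normalized to %CTL — 0 at the DMSO mean, 100 at the
nortriptyline mean. Concentrations whose mean cell count falls below
half the DMSO reference are excluded from fitting as toxic and recorded
on the fit object.

The four-parameter logistic
`f(c) = bottom + (top − bottom)/(1 + (ec50/c)^hill)` is fitted by
Levenberg–Marquardt least squares with EC50 on the log10 scale.
Initialization: bottom/top from the extremes of per-concentration
means, EC50 at the concentration nearest half-span, hill = 1; bounds
hill ∈ [0.2, 10] and EC50 within 100× the tested range — standard
robust 4PL practice. Initialization is deterministic, so identical data
give identical fits. A flat series (response SD below tolerance) is
returned as a converged no-response fit rather than being sent to the
optimizer, whose gradient is degenerate there. An EC50 outside the
tested range is flagged extrapolated.

The human curve-review rubric is rendered quantitatively, applied
top-down so exactly one branch fires: Priority 1 needs an increase at
1 µM, a sigmoidal fit (converged, span > 20 %CTL, R² ≥ 0.8) and at
least two increased pre-toxic concentrations; Priority 2 needs
increases at both of the two highest concentrations (3.03 and 10 µM)
with %CTL ≥ 70 at 10 µM; Priority 3 is the same with %CTL < 70;
Priority 4 is an increase only at 10 µM; Priority 5 is flat.
"Increased" defaults to %CTL ≥ 20. These thresholds are quantitative
stand-ins for rater judgment and are all exposed. Compounds pass the
screen when their mean priority is at least as good as the
nortriptyline reference; because the original scores were ordinal
ratings whose direction is ambiguous in prose, the comparison direction
is a flag, defaulting to "numerically lower is better".

# PK and microsomal stability

Non-compartmental analysis takes Cmax/Tmax from the observed maximum,
AUC0–t by the linear trapezoid (a log-trapezoid flag exists and is
exact on exponential decay segments), and the terminal slope by OLS on
ln(C) over all quantifiable post-Tmax points (minimum 3; index override
available — the original profile's selection is not recoverable, so the
default is the least discretionary rule). t½ = ln 2/λz;
AUC0–∞ adds the Clast/λz tail; Vss/F = (Dose/AUC0–∞)·MRT with
MRT = AUMC0–∞/AUC0–∞, the method recorded in the result. Below-limit
values ("no peak") are missing, never zero. Doses in mg/kg convert to
nmol/kg via the molecular weight so that volumes come out in L/kg with
concentrations in nmol/L. With fewer than three terminal points the
terminal-phase quantities degrade to `NA` with a warning rather than
discarding Cmax and AUC0–t.

Microsomal depletion: OLS of ln(remaining) on time gives the
semilogarithmic slope, t½ = ln 2/(−slope), and
`CL_int [µl/min/mg] = (ln 2/(t½ · protein))·1000` with protein in
mg/ml (assay default 0.5). A non-negative slope is a no-depletion flag
(t½ = ∞, CL_int = 0), not an error. Group summaries use the sample SD
(n−1) and CV% = 100·SD/mean, undefined at zero mean.

# Numerical and testing choices

Problem sizes in the test-suite simulation studies were chosen so the
whole suite runs in about a minute: hit recovery uses 20 independent
10-plate screens (3,200 compounds each); the qPCR recovery study uses
200 simulated experiments with 4 replicates at 0.2 Ct noise; EC50
recovery uses 100 curves with duplicate wells at 8 concentrations and
3 %CTL noise; clustering is cross-checked against a brute-force
sphere-exclusion reference on a 30-compound fixture at three
thresholds; hit calling is cross-checked against an exhaustive two-rule
oracle on 1,000 random 20-entry plates. Under these conditions
measured recall of strong (+25 point, non-toxic) actives is ≈0.98 with
no false positives among cutoff hits, the mean recovered fold change at
ΔCt = 1 is ≈0.50 with null type-I error ≈0.05, and the median EC50
log-error is ≈0.03 decades — the acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch.

# Known limitations

* The Scaled cutoff of 0.85 is kept as a fixed default; its original
  derivation (per-plate nortriptyline percentile) is available as a
  mode but the two are only equivalent if the simulated control spread
  matches the original screen's.
* PAINS coverage is a curated subset; a full published catalog should
  be supplied for production triage.
* The clustering algorithm is a deterministic stand-in for an
  unspecified commercial implementation; partition counts are
  reproducible only through `target_k`.
* NCA assumes extravascular-style sampling of a single profile; no
  compartmental modeling, protein-binding correction or allometry.
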