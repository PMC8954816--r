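---
title: "Exact-mass metabolite identification, calibration statistics and NCA: methods"
author: "dmpkid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact-mass metabolite identification, calibration statistics and NCA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmpkid)
```

This vignette is the package's account of its methods: the models and
procedures, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators emulate,
and the numerical choices made where the design was genuinely open.

## Exact-mass arithmetic

All mass computation rests on a pinned table of monoisotopic atomic
masses (H 1.00782503207, C 12 exactly, N 14.0030740048, O 15.9949146196,
plus S, P, halogens and the common adduct metals). Pinning the constants
inside the package makes every m/z bit-reproducible. Protonated-ion m/z
uses the electron-corrected proton mass 1.00727646 Da rather than the
hydrogen-atom mass; the ~0.5 mDa difference matters at the fourth
decimal place, and the proton mass is what reproduces the reference
characterization table exactly at 4 dp. Reported m/z round half away
from zero at 4 decimals (`round_half_up()`); internal computation keeps
full double precision.

Formula parsing strips underscores and whitespace first, so subscript
renderings such as `C_24_H_29_N_3_O_2_` copied from typeset tables parse
identically to `C24H29N3O2`. An element symbol with no digit has count 1.

The shipped characterization table (`daporinad_metabolites()`) carries
both the as-printed and corrected formula columns: two printed formulas
are internally inconsistent with their own m/z and transformation label
(the amide-hydrolysis product, whose printed formula does not match m/z
261.1961 while C16H24N2O does and equals parent − C8H5NO; and the
di-desaturation rows, where the printed formula matches saturation while
m/z 388.2020 matches C24H25N3O2). The m/z and transformation columns are
treated as authoritative because every other row reproduces from them
exactly; each correction is recorded in the table's `note` column.

## Biotransformation chains and peak annotation

A biotransformation rule is a signed elemental delta with a multiplicity
cap: oxidation {O:+1} up to 3x (tri-oxidation is the deepest chain
observed), desaturation {H:−2} up to 2x, saturation {H:+2}, amide
hydrolysis {C:−8, H:−5, N:−1, O:−1} (net loss of the pyridine-acryloyl
acyl moiety C8H5NO, nominally 131 amu), and the two hydrolysis
follow-ups expressed as net deltas to C16H21NO3 (carboxylation) and
C16H23NO2 (hydroxylation). Chain enumeration expands every multiset of
rule applications up to `max_steps` (default 3), prunes chains that
would drive an element count negative, and deduplicates identical net
compositions keeping the fewest-step version (so desaturation +
saturation collapses into the parent). Chains that combine two cleavage
rules are chemically implausible but harmless: none falls within
tolerance of a real metabolite mass, and pruning them would require
structure knowledge the engine deliberately does not have.

Annotation accepts every chain within `tol_ppm` of a peak and ranks
candidates by fewest steps, then smallest |ppm|; all survivors are kept
rather than silently dropped, and unmatched peaks are returned in a side
table. The default 5 ppm reflects the observed error scale of a
well-calibrated qTOF (reference errors all ≤ 2.8 ppm) with headroom but
no cross-talk between candidate masses. Tolerance behaves monotonically:
shrinking it can only remove annotations, which is asserted as a
property test. Positional isomers (several mono-oxidations, for
instance) receive the same chain and are distinguished only by retention
time, which is exactly how the reference table treats them.

## Moiety localization from fragment shifts

The parent fragments into two diagnostic series: amine-side
(4-butylpiperidine half: 261.1961, its −NH3 partner 244.1696, and
140.1434) and acyl-side (pyridine-acryloyl half: 132.0444, −HCN
105.0335, −CO 104.0495). The template stores neutral fragment formulas;
observed m/z is the protonated form, so the m/z are derived, not
hard-coded.

`localize_modification()` brute-forces every partition of a chain's
steps between the two moieties, predicts each template fragment shifted
by the exact mass of the steps assigned to its moiety, and scores the
partition by how many predicted fragments appear in the spectrum within
`frag_tol_mda` (default 10 mDa, because product ions are conventionally
reported at 2 dp, making 5 mDa of pure rounding possible before any
measurement error). The best partition's assignment is returned
(`amine_side`, `acyl_side`, or `both` for a split); a tie between
partitions with different assignments, or fewer than 2 matched
fragments, yields `unlocalized` — one matching fragment is no evidence,
since the unshifted series always matches trivially for some partition.
The tests hold this implementation against an independent oracle that
exhaustively enumerates per-step assignment vectors.

## The TiCl3 N-oxide differential

Titanium(III) chloride reduces N-oxides back to the parent amine. An
annotation carrying at least one oxidation step is flagged as an N-oxide
when (a) its peak intensity in the treated sample drops to at most
(1 − `drop_fraction`) of control, and (b) some individual peak one
oxygen lighter (m/z − 15.9949) gains intensity relative to its own
control counterpart. Two deliberate choices here:

* The source material gives no quantitative threshold for
  "disappears/appears"; `drop_fraction = 0.8` (an 80% drop) and "any
  gain" for the partner are the package's defaults, and both are
  explicit parameters.
* The partner is searched at any retention time by default
  (`partner_rt_tol = NULL`) rather than only near the N-oxide or the
  parent: the reduction product of, say, an N-oxide of a desaturation
  metabolite is a desaturation metabolite, which elutes wherever that
  species elutes. The gain test is peak-wise, not summed over the m/z
  channel, because co-eluting N-oxides at the partner m/z collapse at
  the same time and would otherwise mask the gain.
* The partner window is anchored at the annotation's theoretical m/z
  minus one oxygen: the assigned composition is mass-error-free, so only
  the partner peak's own measurement error enters the ppm window.

Species without an oxidation step are `untested`; an annotation whose
peak cannot be found in the control table is `untested` with a warning
record rather than an error.

## Calibration and qualification statistics

The calibration model is `ratio = a·x² + b·x + c` fit by weighted least
squares with weights 1/x² on the nominal concentration — the standard
bioanalytical weighting that equalizes relative residuals across a
2000-fold range (weights use nominal, not fitted, concentration). The
curve metric is the Pearson correlation between observed and fitted
ratios, which is 1 exactly in the noiseless case; the reference protocol
requires ≥ 0.99. At least 6 distinct levels are required (the design
uses 8 in duplicate).

Back-calculation solves the quadratic exactly and selects the real root
in [0, 2·ULOQ]; if both roots qualify, the one inside the calibrated
range wins, and anything still ambiguous raises an error rather than
guessing. Results outside [LLOQ, ULOQ] are flagged BLQ/ALQ but never
clamped, and the dilution factor multiplies the result afterwards.

Accuracy is mean(measured)/nominal × 100; precision is the sample (n−1)
CV. Both are scale-equivariant. The acceptance band is ±25% at every
level including the LLOQ (the fit-for-purpose criterion for
discovery-stage work; regulated assays would use 15/20%). Intra-run
statistics are per run per level; inter-run pools all replicates of all
runs. Percentages are reported at 3 significant figures with half-up
rounding; note that a mean of 6220 against 6670 is 93.25% → 93.3 under
this convention.

## Non-compartmental analysis

The NCA is deliberately the simplest defensible reading of standard
IV-bolus methodology:

* Linear trapezoid throughout (not log-down) for AUC and AUMC.
* λz from ordinary least squares of log-concentration on time over
  candidate windows (last k points, k ≥ 3, excluding Tmax), selected by
  adjusted R², ties toward more points; λz must be positive, and a
  window with no measurable log-decline is skipped, so a flat profile
  raises a terminal-phase-undefined error.
* C(0) for the 0-to-first-sample segment is back-extrapolated
  log-linearly from the first two positive concentrations (an IV bolus
  has its true maximum at t = 0); this is switchable off. Cmax/Tmax are
  read from the observations, not the extrapolation.
* Tails: AUC∞ = AUClast + clast/λz; AUMC∞ adds clast·tlast/λz + clast/λz².
* Cl = dose/AUC∞ (dose in ng/kg, so Cl is in mL/min/kg), MRT =
  AUMC∞/AUC∞, Vss = Cl·MRT. Cl uses the extrapolated AUC even though
  summary tables conventionally print AUClast.
* Leading BLQ observations are zeroed; trailing BLQs are dropped before
  λz fitting.

Hamilton pooling weights each time point by its trapezoidal time
interval, (t[i+1] − t[i−1])/2 with half-intervals at the ends,
normalized to 1. The testable contract is the identity pooled
concentration = AUClast/(tlast − tfirst), which holds for any profile by
construction.

Dose proportionality reports dose-normalized AUC and Cmax ratios between
consecutive doses and the power-model exponent from OLS of log(AUC) on
log(dose); a normalized AUC ratio above 1.25 (configurable) flags
supra-proportionality. On the reference study's group means this yields
1.04 for the 5→10 mg/kg step (proportional) and 1.65 for 10→30
(supra-proportional), matching the qualitative finding of saturable
elimination.

## What the simulators emulate, and what they do not

All generators use mean-1 multiplicative lognormal noise:
concentrations, areas and intensities are positive, and additive
Gaussian noise would produce negative values at the LLOQ end.

* `sim_calibration_batch()`: duplicate standards at the eight study
  levels (1.02–2220 ng/mL) and triplicate QCs at {15.0, 165, 1820},
  from a quadratic forward model. Default coefficients a = −1e−7,
  b = 2e−3, c = 1e−3 give a mildly saturating but monotone response over
  [0, 2·ULOQ], the typical TOF-detector shape that motivates quadratic
  regression in the first place.
* `sim_pk_profiles()`: two-compartment macro-constant disposition,
  c(t) = dose·(A·e^(−αt) + B·e^(−βt)), defaults A = 960, B = 220 ng/mL
  per mg/kg, α = 0.08/min, β = 0.0131/min — chosen to echo the reference
  study's scale (Cmax ≈ 5.5 µg/mL at 5 mg/kg, terminal half-life
  ≈ 53 min) — on the study sampling grid {2, 10, 30, 60, 120, 240, 420}
  min with n = 3 per dose group. The saturable mode divides β by
  (1 + (dose − 10)/20) above 10 mg/kg, which makes the 30 mg/kg group
  supra-proportional as observed in vivo.
* `sim_peak_tables()`: each ground-truth species becomes a peak at its
  theoretical m/z with Normal ppm jitter (σ = 1.5 ppm, the observed
  mass-error scale) at its reference retention time; MS2 spectra come
  from the fragment template shifted per the ground-truth moiety
  partition and reported at 2 dp; under TiCl3 the N-oxides lose 95% of
  their intensity and their reduction products gain it, co-eluting with
  an existing one-oxygen-lighter species when one exists and appearing
  as a new peak otherwise. Metabolite intensities are arbitrary fixed
  values: relative abundances are not part of the reference surface and
  nothing downstream depends on them.

The simulators do not emulate chromatographic peak shape, isotope
envelopes, matrix effects, in-source fragmentation, or retention-time
drift. Passing the round-trip tests therefore demonstrates that the
annotation/localization/differential logic is self-consistent under
realistic mass error and intensity noise — not that it would survive
co-eluting isobars or poor centroiding in raw vendor data.

## Problem sizes and recovery bands used by the tests

Estimator-recovery properties are evaluated at sizes where the estimator
error, not the discretization, dominates: the λz and Cl recovery tests
use a 22-point rich sampling grid over 1–420 min with the study's group
size (n = 3, group-mean parameter per seed), where noiseless Cl bias is
about −1%. On the sparse 7-point study grid the linear trapezoid
overestimates AUC of the convex decay by ~9%, and the suite asserts this
degradation explicitly (dense < rich < sparse error, monotone). The
calibration correlation test uses the study design verbatim (8 levels in
duplicate, 5% CV). Statistical sanity of the noise model is checked at
n = 1000 replicates.

## Known limitations

* Annotation is composition-level only: positional isomers share a chain
  and are separated by retention time alone, and no structure (SMILES,
  fragmentation trees) is modelled.
* The fragment template is parent-specific; metabolites that cleave the
  scaffold (amide hydrolysis and its follow-ups) cannot be localized by
  shift logic and the simulator emits only their surviving fragments.
* Phase II conjugates (glucuronide, GSH) are expressible as custom rules
  but ship unexercised — the reference study found phase I metabolism
  only.
* λz window selection by adjusted R² is the field convention but is
  noise-fragile on short windows; single-subject λz at 10% noise can
  err by >5%, which is why recovery bands are stated at group level.
* The ±25% acceptance band, 5 ppm / 10 mDa tolerances and the 0.8 drop
  fraction are defaults of a discovery-stage, fit-for-purpose workflow,
  not regulatory constants; all are parameters.
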