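---
title: "Methods: DVH-based late-toxicity risk models and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DVH-based late-toxicity risk models and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvhrisk)
```

## Problem and scope

Thoracic radiotherapy for Hodgkin lymphoma irradiates young patients with
long life expectancy, so late effects — radiation-induced cardiac mortality
and secondary lung/breast cancers — can dominate the clinical trade-off
between treatment techniques. `dvhrisk` turns per-organ dose-volume
histograms (DVHs) into risk estimates for these three endpoints and into
cohort-level modality comparisons. It deliberately starts *after* treatment
planning: dose calculation, optimization and contouring are out of scope,
and DVHs are taken as given (or synthesized, see below).

## The DVH data model

A differential DVH is a contiguous sequence of half-open dose bins
`[lo, hi)` whose fractional volumes sum to 1: the whole organ is always
accounted for, with unirradiated tissue carried in an explicit zero-dose
bin. This convention matters because the seriality model's organ response is
a *product* over subvolumes — dropping cold volume silently changes the
result. The dose assigned to a bin is its midpoint, which is unbiased for
narrow bins; generated DVHs use 0.1 Gy bins, and readers accept any
contiguous grid since planning systems do not agree on an export width.
Cumulative ("volume receiving at least dose") curves are supported as an
interchange form, with exact first-difference/tail-sum conversions.
Converting a cumulative curve whose final tabulated fraction is not ~0 is an
error rather than a silent volume loss.

Paired organs are treated as single structures (one lung DVH, one combined
breast DVH per patient), matching how cohort risk tables are usually
reported; per-side DVHs should be volume-weighted and summed on input.
`dose_kind` records whether the axis is physical or RBE-weighted dose but is
metadata only: models are applied to the numeric dose as given, which is the
convention for proton plans prescribed in 1.1-scaled (RBE-weighted) Gy.

## Cardiac mortality: relative seriality

The subvolume response is the Poisson sigmoid
`P(D) = 2^(−exp(e·γ·(1 − D/D50)))`; the journal-typeset form of this model
is ambiguous about grouping, but the roles of `D50` (50% response dose) and
`γ` (maximum normalized slope) force this standard reading, and `P(D50) =
1/2` exactly. Organ-level combination uses the relative seriality `s`:

\[ P = \Big[1 - \prod_i \big(1 - P(D_i)^s\big)^{\Delta v_i}\Big]^{1/s}. \]

Defaults (whole heart, cardiac mortality at 15 years): `D50 = 70.3` Gy,
`γ = 0.96`, `s = 1`. Three choices deserve note:

- **No fractionation correction by default.** The model is applied to the
  planned DVH; an EQD2 transform (`eqd2_dvh()`) is provided but off by
  default and requires the caller to supply α/β and fraction number, since
  published parameter fits for this endpoint were made without a stated
  correction.
- **`s = 0` is rejected** (the exponent `1/s` is undefined); any positive
  real is accepted, and for a uniform DVH the organ response equals the
  subvolume response for *every* `s` — a property the tests exercise at
  `s ∈ {0.01, 1, 4}`.
- **Numerics.** The product is evaluated as an exponential of a
  `Δv`-weighted sum of `log(1 − P^s)` terms, with the two-branch `log1mexp`
  guard. The naive `expm1` form loses the result entirely when `P^s`
  underflows relative to 1 (e.g. `s = 4` at low dose); the branch keeps
  full relative precision at both ends.
- **"Excess risk" is the model output itself** (baseline zero); percent
  formatting happens only at reporting. The 15-year horizon is metadata
  fixed by the parameter fit — the model has no time variable.

## Secondary cancer: Schneider modified linear-quadratic / OED

The risk density of tissue at dose `D` is

\[ f(D) = \mu\,\frac{e^{-\alpha' D}}{\alpha' R_f}\Big[1 - 2R_f + R_f^2
   e^{\alpha' D} - (1-R_f)^2 e^{-\frac{\alpha' R_f}{1-R_f}D}\Big], \]

and the organ EAR is the volume-weighted sum over the DVH (equivalently
`μ ·` OED, the organ equivalent dose). Defaults: lung `Rf 0.84`, `α
0.061`/Gy, `μ 2.7`; breast `Rf 0.62`, `α 0.067`/Gy, `μ 4.8` (cases per
10,000 person-years per Gy), with a 30-year reporting horizon as metadata.

- **`α′` is not separately published** for these fits; the package defaults
  to `α′ = α` and exposes an explicit hook
  `α′ = α + β · d_f` for callers who have a quadratic coefficient and dose
  per fraction. This is documented rather than guessed.
- **Low-dose numerics.** The bracket is computed as
  `Rf²·expm1(α′D) − (1−Rf)²·expm1(−α′Rf D/(1−Rf))`, algebraically identical
  to the closed form but exact at `D = 0`. This replaces a truncated Taylor
  branch below a dose threshold: the `expm1` form is uniformly stable, so no
  branch point exists to tune. Consequences verified by tests: `f(0) = 0`
  exactly, and the finite-difference slope at zero recovers `μ` to 0.1% —
  the linear-no-threshold limit, which also gives the low-dose identity
  OED → mean dose.
- Breast EAR is computed only for patients recorded female; male patients
  simply have no breast rows in the risk table.

## Oracle strategy in the tests

Both organ-level models have brute-force voxelwise twins
(`ntcp_voxelwise()`, `ear_voxelwise()`) that evaluate the formulas directly
on a dose list with equal voxel volumes. Binned-vs-voxelwise agreement is
tested at `1e-4` relative on voxel sets drawn on the 0.1-Gy *bin-midpoint
grid*: this isolates the combination formula (log-space product, weighting)
from midpoint discretization, which is a property of the input grid, not of
the implementation. Off-grid voxel sets are additionally tested at `5e-3`
relative — an honest bound, since a ±0.05 Gy midpoint shift alone can move
the heart NTCP by more than `1e-4` relative at Hodgkin dose levels.
Discretization itself is bounded separately: rebinning conserves volume
exactly and moves the mean dose by at most half a bin width.

## The synthetic cohort generator

No patient DVHs accompany published modality-comparison cohorts, so the
generator stands in for them. Each (patient, modality, organ) DVH is a
three-component mixture binned at 0.1 Gy:

1. an **in-field** component, normal around `rbe_factor ×` prescription with
   spread `penumbra_gy`, renormalized within the 108% planning ceiling
   (plans must cover the target at 95% of prescription without exceeding
   108%, so organ hot spots cannot exceed it either);
2. an exponential **low-dose bath** with scale `bath_scale_gy`;
3. the remainder at **zero dose**.

Component weights and the bath scale get per-patient jitter: lognormal for
the scale (σ = 0.15), logit-normal for the fractions (~8% relative) so that
0 and 1 are fixed points — an organ fully inside or outside the field stays
so. Streams are hashed per (patient, modality, organ) from the master seed,
so adding an organ or patient never perturbs other draws, and the caller's
RNG state is untouched.

Default prescriptions emulate an involved-field Hodgkin cohort: 20, 21
(×9), 26.5, 30 (×3), 30.6 (×5), 36 Gy with 9 female / 11 male patients.
The per-modality shape profiles are **calibration constants of the
generator** (shipped in `inst/extdata/modality_profiles.csv`, not published
values), chosen to reproduce the qualitative planning contrasts: helical
tomotherapy trades high-dose organ volume for a much larger low-dose bath
than 3D conformal photons; proton therapy shrinks both; proton doses are
RBE-weighted by 1.1, and the heart profiles are balanced so the RBE penalty
roughly offsets the physical sparing. With these defaults a generated
cohort reproduces the directional findings of published comparisons — lung
and breast EAR ratios HT/3DCRT > 1 and IMPT/3DCRT < 1 for ≥ 90% of patients
across seeds, with no systematic cardiac ordering — and that is *all* a
green cohort test establishes. The generator imitates DVH statistics, not
anatomy, beam physics or optimizer behaviour; inter-patient variability is
a modelling choice (the directional orderings held patient-by-patient in
published cohorts, hence the modest 8% jitter), and absolute synthetic
risks are not calibrated to any clinical table.

## Cohort statistics and sensitivity analyses

The "average risk ratio" between modalities is the arithmetic mean of
per-patient ratios — chosen because the natural companion analysis is a
paired test on patients; the ratio of cohort means is also reported for
transparency. Patients with zero reference risk are excluded from ratios
and counted. The paired t-test is the classical statistic on differences
with `n − 1` degrees of freedom, two-sided (sidedness is a documented
assumption), implemented directly and cross-checked against
`stats::t.test`; the all-zero-differences case returns a flagged
"no difference" with `p = 1` by convention.

Two sensitivity operations mirror the uncertainty discussion of planning
studies: scaling all doses by `1 ± δ` (reporting worst-case absolute change
in percentage points for cardiac risk and relative change for the EARs —
near-linear in the LNT-dominated regime, so a 10% dose error moves EARs by
roughly 10% while cardiac risk moves by well under half a percentage
point), and adding a uniform neutron dose bath of `mSv per treatment Gy ×
prescription` to proton plans (the caller's mSv/Gy figure carries any RBE
weighting, conservatively capped at 20; tens of mSv/Gy leaves cardiac risk
essentially unchanged and adds ~`μ ×` bath dose to the EARs).

## Known limitations

- No confounder modelling (chemotherapy, smoking, hypertension, age at
  exposure), no competing risks, no attained-age modification of EAR.
- Parameter uncertainty is not propagated; `D50`, `γ`, `s`, `Rf`, `α`, `μ`
  enter as point values.
- The midpoint-dose convention and 0.1 Gy default grid are adequate for the
  smooth response curves here but would need revisiting for models with
  sharp thresholds.
- Synthetic cohorts support method validation and directional conclusions
  only.
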