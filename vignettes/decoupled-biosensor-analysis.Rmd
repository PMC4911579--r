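---
title: "Decoupling protein-binding signals in OTFT biosensors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupling protein-binding signals in OTFT biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biotft)
```

## The two-track picture

A p-type organic thin-film transistor with a biotin-binding protein layer
(avidin, streptavidin, neutravidin) under its semiconductor reports a
ligand-binding event through the channel current. `biotft` implements the
analysis that splits that report into two physically distinct channels and
then closes the loop against molecular structure:

* **Device track.** In the saturation regime the gradual-channel law
  $I_{DS} = \frac{W}{2L} C_i \mu_{FET} (V_G - V_T)^2$ holds, so
  $\sqrt{|I_{DS}|}$ is linear in $V_G$; `otft_fit()` extracts the
  threshold voltage $V_T$ (abscissa intercept) and mobility $\mu_{FET}$
  (from the squared slope). The total differential at constant $C_i$,
  $$\frac{\Delta I}{I_0} = \frac{\Delta\mu}{\mu_0}
    - 2\,\frac{\Delta V_T}{V_G - V_{T0}},$$
  decouples the normalized response into a conformational (mobility) and
  an electrostatic (threshold) term; `decompose_response()` solves it in
  any direction and `pair_response()` reports the first-order closure
  residual when all three pieces are measured independently.
* **Structural track.** The per-monomer dipole moment
  $\mathbf{p} = \sum_i q_i(\mathbf{r}_i - \mathbf{r}_{COM})$ (ligand atoms
  included via their monomer label), its trajectory statistics, and
  per-residue RMSF of the binding-pocket loops L3,4 (residues 35–45) and
  L5,6 (70–75) after C$\alpha$ rigid-body alignment.
* **Bridge.** The Helmholtz dipole-layer step
  $\Delta V_T = M_{dip} / (\varepsilon_0 \varepsilon_r A)$ converts a
  layer dipole into a predicted threshold shift; `run_bridge()` scores the
  prediction against a measured shift in units of the measurement SD.

The key assumptions inherited from the physics: the gate capacitance is
dominated by the oxide and does not change upon binding (which is what
licenses the two-term differential); the devices are p-type with the
accumulation branch at $V_G < V_T$; and only the outermost protein
monolayer matters electrostatically, because the dipole/induced-dipole
(Debye, $r^{-6}$) interaction with the semiconductor decays within
nanometers (`debye_cutoff()`).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `W`, `L`, `C_i` | 4e-3, 200e-6, 9e-5 | m, m, F/m² | the study device: 4 mm × 200 µm channel on 300 nm SiO₂ (9 nF/cm²) |
| sweep | +20 → −100 V, step −10 | V | the measured gate window |
| evaluation `v_g` | −100 | V | deepest accumulation point; where responses are quoted |
| `eps_r` | 3 | — | typical relative permittivity of a dry protein layer |
| `area_nm2` | 1.50 | nm² | see below — a back-derived calibration, not a geometry |
| pH | 7.5 | — | the solution condition; Arg/Lys +1, Asp/Glu −1, His neutral |
| His pKa | 6.0 | — | fixed-pKa threshold rule; override via `pka` |
| `trim` | 0.1 | fraction | equilibration discard, mirroring 5 ns of a 50 ns run |
| `frame_spacing_ps` | 10 | ps | the trajectory save interval emulated |
| `alpha` | 0.05 | — | two-sided significance level for group comparisons |

**The footprint area.** The Helmholtz default `area_nm2 = 1.50` is the
one genuinely calibrated constant: it is the per-dipole footprint for
which a 283 D complex dipole at $\varepsilon_r = 3$ reproduces a 23.73 V
layer shift. No independent measurement of the interfacial footprint
backs it, so it is exposed as a parameter and flagged here. Two
alternatives were considered and rejected as defaults: using the
binding-induced dipole *change* (283 − 154 D) instead of the complex
dipole, and a surface-density formulation (`area = 1/density`); neither
reproduces the known shift with the documented permittivity, so both
remain available but not default.

**Debye cutoff criteria.** The screening length is defined by an
interaction threshold. The energy criterion ($|U(r_c)| = k_BT$ at 297 K)
is the default because it needs no extra length scale; a force criterion
(threshold in newtons, $r^{-7}$) is provided for completeness. The
polarizability volume of the semiconductor interface has no literature
value here and is a required input, so the nanometer-scale cutoff is
context, not a validated number.

## The fit-window policy

Manual "linear segment" selection is the classic source of
irreproducibility in $\sqrt{I}$–$V_G$ extraction. The policy in
`otft_fit()`:

1. Keep accumulation-branch points whose current exceeds 3× the
   sub-threshold floor (median magnitude of the off-end quarter of the
   sweep). This drops the noise floor and exact zeros.
2. Optionally drop a configurable fraction of the highest-overdrive
   points (`high_vg_exclude`, default 0).
3. Among all contiguous windows of at least 30% of the kept branch (and
   ≥ 4 points), use the **longest** window with $R^2 \ge 0.995$; if none
   qualifies, fall back to the maximum-$R^2$ window.

Preferring length at sufficient linearity, rather than maximal $R^2$
outright, matters: a pure $R^2$ maximum degenerates to the shortest
allowed window under noise (fewer points are always easier to fit),
inflating the variance of the slope and hence of the mobility. The
longest-sufficient rule keeps noiseless recovery exact (the full branch
wins at $R^2 = 1$) while rejecting windows contaminated by
contact-resistance roll-off, whose compressed slope breaks the linearity
criterion. Ties in length resolve to the higher $R^2$.

Degenerate inputs fail loudly: fewer than four usable points or no
window meeting the criterion raise an extraction-failure error naming the
criterion; positive currents on the fitted branch of a p-type device
raise a data-convention error.

## What the generators emulate — and what they do not

`gen_transfer_curve()` draws the square-law current, multiplies by
lognormal noise (unit mean; device-to-device gain variation dominates in
these transistors), adds a constant leakage floor, and optionally
compresses the current beyond a roll-off onset (retaining a configurable
fraction of the above-onset increment) to mimic contact-resistance
saturation. It does **not** model 1/f noise spectra, hysteresis,
bias-stress drift, or physical contact resistance — the extraction is
only asked to *exclude* roll-off, not to model it.

`gen_bead_tetramer()` builds compact Gaussian bead clusters with balanced
±1 charges plus one corrective charge pair per monomer placed in closed
form so the per-monomer dipole is exact (the monomer is net-neutral, so
its dipole is origin-independent and the correction is linear algebra,
not optimization). Beads carry unit mass so the center of mass is the
centroid. It is a dipole-and-fluctuation stand-in, not a protein: no
secondary structure, no excluded volume, no realistic mass distribution.

`gen_wobble_trajectory()` displaces each bead by an independent isotropic
Gaussian per frame (analytic RMSF $\sigma\sqrt{3}$), with per-loop sigmas
for the open/closed regimes, an optional slowly ramping rigid
rotation+drift to exercise the alignment, and optional per-frame
dipole-magnitude jitter realized by sliding the corrective pair along the
dipole axis. Frames are white, not autocorrelated; that is sufficient for
fluctuation-amplitude and dipole-statistics targets but says nothing
about relaxation times. One numerical consequence worth knowing: the
*magnitude* of a noisy dipole vector is biased upward by transverse
positional noise (the norm of mean-$M$ plus isotropic noise exceeds $M$
on average by roughly $\sigma_\perp^2/M$), which is why dipole-recovery
validation prescribes the fluctuation through the longitudinal jitter
channel with small positional noise, rather than through large bead
noise. Passing these tests therefore demonstrates correct estimators
under known statistics — not that real trajectories are white, harmonic,
or bias-free.

## Numerical choices

* **Superposition.** Kabsch via SVD with a determinant correction;
  reflections are always rejected (proper rotations only) since mirror
  fits are unphysical for proteins. Rank-deficient (collinear) inputs and
  sets of fewer than 3 atoms are errors. Validated against an independent
  quaternion-eigenvector oracle and against `bio3d`.
* **RMSF reference.** Frames are aligned to the first retained frame, the
  time-mean structure is formed, and frames are re-aligned to that mean —
  one iteration, no further re-alignment loop. Per-residue values are the
  C$\alpha$ values by default (`per_residue = "heavy"` averages the
  residue's atoms); whether a published profile used C$\alpha$-only or
  all loop atoms is rarely stated, so the choice is explicit here.
* **Monomer scope.** Published tetramer figures often average "two
  monomers" without naming them; the package default averages **all**
  monomers in scope with a `monomers` argument to restrict, which is the
  symmetric choice and is logged in the results.
* **Responses.** Per-device ratios are formed first and then aggregated
  (mean, SD, RSD) — not ratios of group means. Group comparison uses the
  Welch (unequal-variance) two-sided t-test, from raw values or from
  summary triples (mean, SD, n); plain "t-test" reports rarely specify
  the variance assumption and Welch is the safe default.
* **Signs.** Fits operate on $|I_{DS}|$; reported $V_T$ is signed. The
  bridge compares shift *magnitudes* and reports signs separately,
  because measured shifts are conventionally quoted as positive
  magnitudes while the electrostatic argument fixes a negative
  $\Delta V_T$; the agreement criterion uses the measurement SD only.
* **Constants.** $\varepsilon_0 = 8.8541878128\times10^{-12}$ F/m,
  1 D $= 3.33564\times10^{-30}$ C·m, 1 e·Å $= 4.80320$ D, pinned in one
  internal table.

## Problem sizes used in validation

The test-suite simulations are sized for exactness of the checked
statistic, not realism: 50-seed Monte Carlo batches for figure-of-merit
recovery at 2% noise; 2000-frame wobble runs where a 5% tolerance on
$\sigma\sqrt{3}$ is checked; 300–500 frame runs (10% trim) for dipole
statistics and loop contrasts on 2-monomer, 100-bead-per-monomer models;
100 random 10-atom instances for the superposition oracle.

## Limitations

* Charges are formal integers by rule (or externally supplied per-atom
  sets); there is no pKa prediction, no continuum electrostatics, and no
  induced-polarization self-consistency.
* The trajectory machinery analyses trajectories; it does not generate
  dynamics beyond the white-noise wobble model.
* Contact resistance is excluded, not modelled; sub-threshold slope,
  hysteresis and pulsed-measurement effects are out of scope.
* Reproducing published trajectory-averaged dipoles (≈ 283 D bound,
  ≈ 154 D unbound) and the ≈ 4 Å → 2 Å loop contrast from first
  principles would require the actual tetramer structure and long
  implicit-solvent molecular dynamics; within this package those
  magnitudes serve as generator targets for estimator validation, which
  the bead-model tests recover within their stated tolerances.
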