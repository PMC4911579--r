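# biotft

Decoupled analysis of protein-interlayer organic thin-film transistor
(OTFT) biosensors, for device physicists and computational structural
biologists who want the two halves of one story in one place: what a
transfer curve says about a binding event, and what the protein's
electrostatics and loop dynamics say it *should* have said.

## The problem and the model

A layer of a biotin-binding protein (avidin, streptavidin or neutravidin)
deposited at the dielectric/semiconductor interface of a p-type OTFT turns
the transistor into a label-free biosensor: ligand binding changes the
channel current. The current alone conflates two physically distinct
channels. In the saturation regime

```
I_DS = (W / 2L) · C_i · μ_FET · (V_G − V_T)²
```

so √|I_DS| is linear in V_G, with the threshold voltage `V_T` as abscissa
intercept and the mobility `μ_FET` from the squared slope. Differentiating
at constant capacitance gives, to first order,

```
ΔI/I₀ = Δμ/μ₀ − 2·ΔV_T/(V_G − V_T0)
```

which decouples the normalized response into a **conformational** term
(mobility: binding-induced disorder in the semiconductor above the protein
layer) and an **electrostatic** term (threshold voltage: the protein
layer's dipole moment). The electrostatic term is bridged to structure by
the Helmholtz dipole-layer expression

```
ΔV_T = M_dip / (ε₀ · ε_r · A)
```

with `M_dip` the per-protein dipole moment (debye), `ε_r` the layer
permittivity and `A` the per-dipole footprint. On the structural side the
package computes `M_dip = |Σᵢ qᵢ (rᵢ − r_COM)|` per monomer (ligand
included) from partial charges, its trajectory statistics, and per-residue
RMSF profiles of the binding-pocket loops L3,4 (residues 35–45) and L5,6
(residues 70–75), whose open→closed clamping upon binding is the
conformational signature behind the mobility drop.

Every estimator is validated against seeded synthetic generators with
known ground truth: square-law transfer curves with multiplicative noise,
gate leakage and contact roll-off; bead-model tetramers with exactly
prescribed per-monomer dipoles; harmonic-wobble trajectories with
prescribed per-residue fluctuation amplitudes (analytic RMSF `σ√3`).

## Worked example

Nine synthetic device pairs with an injected threshold-only binding effect
(ΔV_T = −29.04 V on a +7.6 V baseline), extracted and decoupled:

```r
library(biotft)
pairs <- lapply(1:9, function(k)
  gen_paired_curves(7.6, 1e-6, delta_vt = -29.04, noise_rel = 0.02,
                    seed = 100 + k, device_id = paste0("pfc", k)))
run_device_track(pairs, groups = "PFC")
#> Device track: 9 pairs, V_G = -100 V
#> PFC.delta_I_rel: -0.4697 +/- 0.01216 (n = 9, RSD 0.0259)
#> PFC.delta_mu_rel: -0.00428 +/- 0.01346 (n = 9, RSD 3.14)
#> PFC.delta_vt_term: 0.2703 +/- 0.001661 (n = 9, RSD 0.00614)
#> PFC.delta_vt: -29.11 +/- 0.2222 (n = 9, RSD 0.00763)
```

The mobility term is recovered as ≈ 0 and the threshold term as 0.27 —
the injected electrostatic perturbation, cleanly separated from the
conformational channel. The threshold shift itself comes back within
0.3% (−29.11 V vs −29.04 V injected). Bridging a trajectory-averaged
bead-model dipole to that measured shift:

```r
s  <- gen_bead_tetramer(target_dipole = 283, seed = 1)
tr <- gen_wobble_trajectory(s, n_frames = 500, sigma = 0.1,
                            dipole_sigma_D = 33, seed = 2)
st <- trajectory_dipole_stats(tr, trim = 0.1)   # 283.5 +/- 34.0 D
run_bridge(st$mean, measured_shift = 29.04, measured_sd = 5.45)
#> Helmholtz bridge:
#>   predicted |dV_T| = 23.73 V (M = 283.467 D, eps_r = 3, A = 1.5 nm^2)
#>   measured  |dV_T| = 29.04 +/- 5.45 V
#>   agreement: 0.97 SD -> within the 1-SD criterion
```

A 283 D dipole layer predicts a 23.7 V threshold shift — within one
standard deviation of the 29.04 ± 5.45 V measurement it is compared to.

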