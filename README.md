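# flipkinetics

Free-energy profiles and kinetics for base-flipping reaction coordinates
from umbrella-sampling data.

When a damaged base — canonically a cyclobutane pyrimidine dimer (CPD) —
must leave the DNA helix to reach a repair enzyme's active site, the motion
is naturally described by a pseudo-dihedral angle ξ built from four centers
of mass of atom groups. This package takes biased (umbrella-window) time
series along such a 360°-periodic coordinate and computes:

- **F(ξ)**, the potential of mean force, by self-consistent periodic WHAM
  with per-window harmonic biases U_i(ξ) = k_U/2 · Δ(ξ−ξ_i)², including
  gap/coverage validation, segment-wise convergence RMSDs, and optional
  per-window free-energy-perturbation corrections for auxiliary flat-bottom
  restraints (ΔF = −kT ln⟨e^(−ΔU/kT)⟩);
- **D(ξ)**, the local diffusivity, from each window's stationary variance
  and integrated autocorrelation time, D = var(ξ)/τ_int, with τ_int from a
  noise-guarded double-exponential fit of the correlation function;
- **mean first passage times** by the Smoluchowski double integral with a
  reflecting intra-helical and an absorbing extra-helical boundary,

      τ₊ = ∫ᵃᵇ dξ e^{F(ξ)/kT}/D(ξ) ∫ᵃ^ξ dξ′ e^{−F(ξ′)/kT},

  the mirrored τ₋, rates k± = 1/τ±, the kinetic equilibrium constant
  K = τ₋/τ₊ always reported next to its thermodynamic counterpart
  e^{−ΔF/kT}, and a constant-diffusivity variant quantifying how much
  roughness in D(ξ) slows the passage.

A first-class synthetic-data module generates ground-truth systems
(overdamped Langevin dynamics on calibrated periodic double wells,
position-dependent D, harmonic biases, Hamiltonian-replica-exchange
emulation, a brute-force first-passage oracle) so the entire pipeline is
validated end-to-end: campaign → WHAM → diffusivity → MFPT must recover
the model it was fed.

## Worked example

Generate a synthetic campaign on the rough-diffusivity double-well preset
(intra-helical minimum at 30°, extra-helical at −135° lying 2 kcal/mol
lower, 3.5 kcal/mol barrier, D fluctuating tenfold), write it in the
plain-text window dialect, and analyze it from a config file:

```r
library(flipkinetics)
m  <- modelSystem("double-well", dLogAmp = log(10) / 2)
ws <- runUmbrellaCampaign(m, spec = simulationSpec(0.01, 1e5, 10),
                          exchangeEvery = 0, seed = 7)
writeWindowSet(ws, "demo", model = m, seed = 7)
yaml::write_yaml(list(windows = "demo", output_dir = "demo/out",
                      n_segments = 2, label = "synthetic-flip"),
                 "demo/config.yaml")
out <- runAnalysis("demo/config.yaml")
out$report
```

which logs each stage and prints:

```
[coverage] 180 windows, spacing 2 deg, span 358 deg, closure: TRUE
[states] reflecting 34.0 deg, absorbing 224.0 deg
[done] tau+ = 3.003e-07 s, tau- = 7.852e-06 s
KineticsReport [synthetic-flip] (local diffusivity)
  tau+ = 3.003e-07 s   tau- = 7.852e-06 s
  k+   = 3.331e+06 /s  k-   = 1.274e+05 /s
  K_eq(kinetic) = 26.15   K_eq(thermo) = 21.48   dF = -1.829 kcal/mol
  reflecting at 34.0 deg, absorbing at 224.0 deg
```

Reading: flipping out (τ₊) is ~26× faster than flipping back, consistent
with the extra-helical state sitting ≈1.8 kcal/mol below the intra-helical
one on this landscape (e^{1.83/kT} ≈ 21 — the kinetic and thermodynamic
equilibrium constants agree to within the two-state approximation). The
analysis also writes `profile.txt`, `diffusivity.txt`,
`convergence_rmsd.txt` and `kinetics_report.txt` under `demo/out/`. Times
here are desk-scale: the generator's diffusivity is chosen for resolvable
window autocorrelation, not to mimic microsecond flipping.

The full recovery benchmark at production scale (180 windows × 10⁵ stored
samples, 10⁴ oracle walkers, a few minutes on one CPU):

```r
b <- runBenchmark(seed = 1)
b$verdicts
#   pmf diffusivity        mfpt
#  TRUE        TRUE        TRUE
```

A thin command-line wrapper with `analyze`, `simulate`, `benchmark`,
`coverage` and `coordinate` subcommands lives at
`inst/scripts/flipkin.R`.

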