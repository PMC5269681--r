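---
title: "From umbrella windows to flipping kinetics: models and methods"
author: "flipkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From umbrella windows to flipping kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipkinetics)
```

## The problem

A damaged base such as a cyclobutane pyrimidine dimer (CPD) must leave the
DNA double helix — "flip out" — before a repair enzyme like photolyase can
act on it. The natural reaction coordinate for this motion is a
pseudo-dihedral angle $\xi$ built from four centers of mass of atom groups
(opposite-strand nucleotides, remote reference nucleotides, the damaged
nucleotides' backbone, and their bases). Because $\xi$ is an angle, the
landscape is periodic with period $360^\circ$: the base can leave through
the major groove (positive direction) or the minor groove (negative
direction).

The package turns biased simulations along $\xi$ into two quantities:

1. the free-energy profile (potential of mean force) $F(\xi)$, and
2. the kinetics of the flipping transition — mean first passage times
   (MFPTs) $\tau_+$ (intra- to extra-helical) and $\tau_-$ (back), rates
   $k_\pm = 1/\tau_\pm$, and the equilibrium constant.

It also ships a complete synthetic-data generator, so that every stage of
the pipeline can be validated end-to-end against known ground truth — the
generator is first-class, tested code, not a fixture.

## Reaction-coordinate bookkeeping

Window centers conventionally run from $-320^\circ$ to $38^\circ$ in steps
of $2^\circ$: more than one wrap half-period, so all series are *unwrapped*
to the branch of their window center before any statistics
(`unwrapToBranch()`). Signed arcs between states are computed by
`angularPath()`, which fixes the direction explicitly: from an
intra-helical minimum at $29^\circ$ to the extra-helical state at
$-135^\circ \equiv 225^\circ$ the positive (major-groove) arc is
$196^\circ$, from $69^\circ$ it is $156^\circ$, and the negative
(minor-groove) arc from $69^\circ$ is $-204^\circ$. `angularPath()` always
returns the arithmetic value; no printed value is special-cased.

The dihedral itself uses the IUPAC sign convention (clockwise positive
looking from center 2 to center 3). Note that a torsion is *invariant*
under reversing the order of its four points; it changes sign under mirror
reflection. Group membership (which nucleotides form each center) is user
configuration, never hard-coded, because residue numbering differs between
structures; hydrogens are excluded by default ("heavy atoms") with masses
from a standard-atomic-weight table.

## Periodic WHAM

Each umbrella window $i$ carries a harmonic bias
$U_i(\xi) = \tfrac{k_U}{2}\,\Delta(\xi-\xi_i)^2$ with $\Delta$ the periodic
minimal-image difference in radians and $k_U$ in kcal mol$^{-1}$ rad$^{-2}$
(production default 400). `wham()` solves the standard self-consistent
equations on a uniform periodic grid,

$$\rho_b = \frac{\sum_i n_{ib}/g_i}{\sum_i (N_i/g_i)\, e^{(f_i -
U_{ib})/k_BT}}, \qquad f_i = -k_BT \ln \sum_b \rho_b\, e^{-U_{ib}/k_BT},$$

iterated until the window constants move by less than `tol` (default
$10^{-7}$ kcal/mol, cap $10^5$ iterations — both standard practice;
non-convergence is an error that reports the last residual). Optional
statistical inefficiencies $g_i = 2\tau_{\mathrm{int}}/\Delta t + 1$
down-weight correlated samples. Design choices worth knowing:

* **Bin width** defaults to $2^\circ$ (one bin per window at the standard
  spacing); it is a free parameter.
* **Unoccupied bins are undefined (NA), not infinite**, so that downstream
  integrals are restricted to the occupied range instead of silently
  diverging.
* The estimate is gauge-invariant under per-window bias offsets and under
  grid rotation by whole bins; both are covered by tests.

State free-energy differences use Boltzmann-weighted integrals over angular
regions ($\Delta F = F_B - F_A$, `stateDeltaF()`), with regions defaulting
to the basins of attraction delimited by the located barrier tops
(`locateExtrema()`, periodic neighbor logic, optional moving-average
smoothing). Segment-wise convergence is quantified by `convergenceRMSD()`
after re-referencing each segment profile to zero mean on the mutually
occupied bins, mirroring the practice of judging convergence on 2 ns
segments per window.

## Restraint corrections by FEP

Production umbrella runs may carry an auxiliary flat-bottom center-of-mass
restraint (zero in 2.5–6.5 Å, harmonic outside) keeping the two thymines
stacked. Removing its influence is a free-energy perturbation per window:
$\Delta F = -k_BT \ln \langle e^{-\Delta U/k_BT}\rangle$ with
$\Delta U = -U_{\mathrm{restraint}}$ on restrained-ensemble frames,
evaluated with log-sum-exp for overflow safety (`fepDeltaF()`). The
standard error comes from a circular block bootstrap with block length
$2\tau_{\mathrm{int}}$. The estimator obeys the Gibbs–Bogoliubov bound
$\Delta F \le \langle \Delta U\rangle$ exactly; forward/backward hysteresis
is reported by `fepHysteresis()` as a convergence check.
`applyFEPCorrection()` adds the per-window corrections to the profile and
re-references it.

## Diffusivity and mean first passage times

Overdamped motion along $\xi$ follows the Smoluchowski picture with a
position-dependent diffusion coefficient $D(\xi)$. Within one narrow
harmonic window the coordinate is approximately an Ornstein–Uhlenbeck
process, for which

$$D(\xi_i) = \frac{\operatorname{var}(\xi)}{\tau_{\mathrm{int}}}$$

exactly (variance in rad$^2$ from the unwrapped series). The integrated
autocorrelation time comes from a double-exponential fit
$C(t) = A e^{-t/\tau_1} + (1-A) e^{-t/\tau_2}$,
$\tau_{\mathrm{int}} = A\tau_1 + (1-A)\tau_2$, in the spirit of Hess's
block-averaging procedure; the block-averaging standard-error curve is
attached as a plateau diagnostic. The exact symbol-level published form of
the window-diffusivity relation is not reproduced in the available text,
so this package deliberately adopts the variance-over-correlation-time
estimator, which is the construction the umbrella-window diffusivity
literature refers to; this is flagged here prominently.

Two numerical safeguards matter in the fit. First, lags after the
autocorrelation estimate drops below a noise floor (default 0.05) are
excluded: beyond that point the estimate carries correlated noise, not
decay signal. Second, the two-scale model must justify itself against a
single exponential by BIC *and* its slow amplitude must exceed three times
the RMS of $C(t)$ in the pure-noise region beyond twice the fit range —
otherwise the acf noise, which is smooth, is reliably fitted as a spurious
slow mode and $\tau_{\mathrm{int}}$ (hence $D$) can be off by 50% for
individual windows. If every fit fails, the estimate falls back to direct
integration of $C(t)$ and is flagged.

MFPTs are the Smoluchowski double integrals with a reflecting boundary at
the intra-helical minimum and an absorbing boundary at the extra-helical
state (reached along the positive, major-groove arc):

$$\tau_+ = \int_a^b \frac{e^{F(\xi)/k_BT}}{D(\xi)}
\int_a^{\xi} e^{-F(\xi')/k_BT}\, d\xi'\, d\xi,$$

and mirrored for $\tau_-$. Quadrature is trapezoidal with a cumulative
inner integral ($O(n)$ total); for flat $F$ and constant $D$ the quadrature
reproduces $L^2/(2D)$ *exactly*, which the tests exploit. $D$ is
interpolated between window centers linearly in $\ln D$ (it is positive and
can vary over an order of magnitude), clamped at the ends. Reported times
are converted to seconds. `constantDiffusivityVariant()` replaces $D(\xi)$
by the arithmetic mean of the window values — the averaging scheme is a
package choice, since only "one average (constant) diffusion constant" is
specified — and reports how much faster the smooth-D passage is; roughness
in $D$ slows the reaction just as landscape roughness does.

`equilibriumCheck()` always accompanies the kinetic equilibrium constant
$K_{\mathrm{kin}} = \tau_-/\tau_+$ with its thermodynamic counterpart
$K_{\mathrm{thermo}} = e^{-\Delta F/k_BT}$; the two agree in the deep
two-state limit (tested at a 10 $k_BT$ barrier, $|\ln$ ratio$| < 0.2$). The
identity is a two-state approximation: it does not hold for barrierless
profiles, so reports on such landscapes should read the log-ratio as a
regime diagnostic, not an error.

## The synthetic generator

`modelSystem()` defines ground truth: a truncated Fourier PMF on period
$360^\circ$ and a log-cosine diffusivity
$D(\xi) = D_0 e^{A\cos(\xi-\phi)}$. The `double-well` preset is calibrated
(linear solve plus one root find, verified to $0.5^\circ$ and 0.05
kcal/mol) to a landscape shaped like the protein-bound dimer-flipping
profile: intra-helical minimum at $30^\circ$, extra-helical minimum at
$-135^\circ$ lying 2 kcal/mol *below* it, and a 3.5 kcal/mol barrier on the
major-groove path — consistent with a system whose flipped state is
stabilized by the enzyme and whose barriers stay below 5 kcal/mol.
`dLogAmp = log(10)/2` reproduces the one-order-of-magnitude $D$
fluctuation reported for flipping coordinates.

Dynamics are Euler–Maruyama with the Itô spurious-drift term
$D'(\xi)\Delta t$ — required for the correct stationary law once $D$
depends on position. The propagator refuses steps whose deterministic drift
exceeds 0.2 rad. `runUmbrellaCampaign()` propagates one walker per window
in lockstep and optionally emulates Hamiltonian replica exchange: every
`exchangeEvery` ps a random parity of neighbor pairs attempts configuration
swaps with Metropolis acceptance on the bias energies (the landscape term
cancels). At the standard spacing/force constant the realized acceptance is
$\approx 0.5$, comparable to the $\approx 0.4$ of the production protocol.
Exchange provably leaves each window's marginal unchanged (tested by
Kolmogorov–Smirnov against no-exchange runs), but it *interrupts the
window's time correlation*, which the diffusivity estimator needs; the
benchmark therefore propagates its windows without swaps, and exchange
correctness is validated separately.

Reproducibility: a single campaign seed expands into per-window substreams
through a splitmix64 counter scheme, so results do not depend on
scheduling, and identical seeds give bit-identical series.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: biased
diffusive sampling on a periodic landscape, position-dependent $D$,
harmonic umbrella biases, replica exchange, and restrained auxiliary
coordinates for FEP inputs. It does **not** emulate all-atom reality:
no orthogonal slow degrees of freedom (which make apparent $D$
time-scale-dependent), no memory effects, no force-field anharmonicities,
no exchange-induced correlation artifacts beyond the swap itself. Passing
the recovery suite therefore certifies the *estimators*, not the physics
of any particular molecular system.

## Problem sizes and study conditions

The benchmark (`runBenchmark()`, also the heart of the package's acceptance
suite) uses 180 windows at $2^\circ$ spacing, $k_U = 400$ kcal mol$^{-1}$
rad$^{-2}$, $T = 300$ K, and per window $10^6$ steps of 0.01 ps storing
every 10th sample — $10^5$ samples spanning an emulated 10 ns, the
production data-gathering length. $D_0 = 10^{-3}$ rad$^2$/ps is the
package's desk-scale choice: it keeps the window integrated
autocorrelation time ($k_BT/k_U/D_0 \approx 1.5$ ps) resolvable at the 0.1
ps output interval while keeping the first-passage oracle (default $10^4$
walkers at 0.5 ps steps) tractable. Recovery targets: profile RMS within
0.3 kcal/mol of ground truth (zero-mean aligned), mean $D$ within 10%, and
the double-integral $\tau_+$ within 15% of the brute-force oracle. The MFPT
comparison is the most delicate: profile errors enter exponentially, so an
0.05 kcal/mol error in the barrier-well free-energy difference already
moves $\tau_+$ by $\approx 9\%$ at 300 K. The oracle timestep 0.5 ps keeps
its own discretization bias well inside the band on this landscape
(verified against the exact flat-landscape law at finer steps).

## Known limitations

* The MFPT double integral assumes overdamped one-dimensional dynamics on
  the chosen segment; flux through the opposite groove is not summed, by
  construction of the reflecting boundary.
* The window-variance diffusivity estimator assumes stationarity (burn-in
  removed) and near-harmonic confinement; with replica exchange enabled it
  is biased and the package deliberately does not use exchanged series for
  it.
* WHAM re-weighting treats samples as exchangeable within a window;
  inefficiency weighting corrects counts, not the stitching noise between
  windows, which dominates the profile uncertainty at production sampling.
* FEP corrections are per-window exponential averages; strongly active
  restraints (poor reference/target overlap) need staging, which is out of
  scope here.
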