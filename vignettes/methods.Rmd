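---
title: "Force-matching recalibration and host-guest binding analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-matching recalibration and host-guest binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmbind)
```

# What this package models

`fmbind` is a desk-scale re-implementation of a two-part workflow from
host-guest modelling of cucurbit[8]uril (CB8) with drug-like guests:

1. **Recalibrating bonded force-field terms** (harmonic bonds, harmonic
   angles, periodic dihedrals) by *generalized force matching*: fitting the
   parameters so that molecular-mechanics energies *and* per-atom forces
   reproduce a reference Hamiltonian over an ensemble of gas-phase
   configurations, with L2 regularization toward the starting
   (GAFF/GAFF2-like) parameters.
2. **Analysing host-guest binding** with switching-function contact-number
   collective variables (CVs), well-tempered metadynamics on toy potentials,
   free-energy surfaces (FES) over 1-2 CVs, standard-state binding free
   energies with block-analysis uncertainties, and affinity
   error/ranking metrics (MSE/MAE/RMSE, Kendall tau, Pearlman PI).

The quantum-chemical reference levels of the original workflow (semiempirical
and DFT single points) and the solvated, PME-electrostatics metadynamics of
the real CB8-drug systems are **out of scope**: they need an external MD/QM
stack.  In their place, a synthetic-data module supplies *ghost Hamiltonians*
(known parameter sets that label sampled configurations exactly, so
parameter-recovery becomes a testable property), and toy binding models whose
standard-state binding free energy is known by quadrature.  See
`desk_scope_exclusions()` for the published quantities that are deliberately
not recomputed.

# The MM model and its evaluator

The potential is Amber-style:

$$E = \sum_{\text{bonds}} k_b (r - r_{eq})^2
    + \sum_{\text{angles}} k_a (\theta - \theta_{eq})^2
    + \sum_{\text{dihedrals}} k_d [1 + \cos(n\phi - \delta)]
    + E_{LJ} + E_{Coul},$$

in kcal/mol, Angstrom, radians, amu, with $k_B = 0.0019872041$
kcal/(mol K) and the electrostatic constant 332.0637 kcal A/(mol e$^2$).
Conventions that matter:

* The "torsional barrier" quoted for an $n = 2$, $\delta = 0$ ring dihedral
  (2.08 kcal/mol for the stiff host) is the amplitude $k_d$; the
  peak-to-trough barrier of a single term is $2 k_d$.  Periodicities and
  phases are immutable in refitting.
* Non-bonded exclusions follow the bond graph: 1-2 and 1-3 pairs excluded,
  1-4 pairs scaled (electrostatic $1/1.2$, van der Waals $1/2$; always
  frozen), all other pairs full strength.  Gas phase, no cutoff,
  Lorentz-Berthelot combination.
* Improper torsions use the same periodic form and are frozen by default —
  whether the original refit touched them is not documented, so an opt-in
  `fit_k` flag exists but nothing in the package enables it.
* Forces are analytic gradients, vectorised over term instances and frames;
  the test suite pins them to central finite differences at $10^{-5}$
  kcal/(mol A) across random configurations, plus translational/rotational
  invariance and Newton's third law.

# The force-matching objective

With a reference dataset of $T$ frames (coordinates, reference energy
$E^{ref}_t$, reference forces $F^{ref}$),

$$J = w_E \hat J_E + w_F \hat J_F + w_{reg} \hat J_{reg},$$

* $\hat J_E$: mean squared energy residual after removing the optimal
  constant offset (MM and reference energy zeros are unrelated; the offset is
  the least-squares constant, i.e. residuals are mean-centred), normalized by
  the reference-energy variance;
* $\hat J_F$: mean squared force-component residual normalized by the pooled
  reference-force variance;
* $\hat J_{reg}$: mean over fit-enabled symmetry classes of
  $[(p - p_0)/s]^2$ with scale $s = \max(|p_0|, \text{floor})$ and floors
  10 kcal/mol/A$^2$ (bond $k$), 5 kcal/mol/rad$^2$ (angle $k$),
  0.5 kcal/mol (dihedral amplitudes), 0.1 (equilibrium lengths/angles) —
  the floors keep the penalty finite where the reference value is zero
  (e.g. an absent torsional barrier).

Weights default to $w_E = w_F = 1$ and $w_{reg} = 0.1$, the stated
intermediate regularization level.  Normalizing the data terms by reference
variances makes them dimensionless so the relative weights are meaningful;
the original implementation's internal normalization is not documented and is
not claimed to be reproduced — only the stated weight ratios are.

**Symmetry classes.** Parameters are stored per canonical atom-type key, so
all term instances sharing a type share one value by construction; the fit
vector has one entry per (type key, slot).  Frozen entries (charges, LJ, 1-4
scales, periodicities, phases) cannot move.

**Optimizer.** Bounded quasi-Newton (L-BFGS-B) in scaled coordinates
($z = p/s$), force constants bounded below by zero, dihedral amplitudes
unconstrained in sign.  The design originally called for finite-difference
gradients over the class vector; profiling showed FD gradients needed ~10k
objective evaluations and still under-converged (parameters 10-15% off on
weak-signal classes purely from early termination).  The gradient is instead
computed *analytically* — energies/forces are linear recombinations of
precomputed, parameter-independent geometry features (bond lengths, angles,
torsions and their coordinate gradients), so $\partial J/\partial p$ reduces
to inner products of residuals with those features.  The analytic gradient is
itself validated against central finite differences (to $10^{-5}$ relative)
in the test suite, and the regularized fit then converges: on the standard
recovery experiment (ghost truth perturbed $\pm 20\%$, 2000 exact-labelled
frames, default weights), bond force constants return to within ~0.3%, angle
force constants within ~3%, dihedral amplitudes within ~6% — the residual
offsets being the genuine regularization pull toward the perturbed anchor,
consistent with the documented "about 10%" error increase that the
regularizer costs on the data terms.

**Assessment.** `assess()` reports offset-corrected energy RMSE/MAE and the
force RMSE $\sqrt{\mathrm{mean}_{t,i} \|\Delta F_{t,i}\|_2^2}$ in
kcal/(mol A atom) — the per-atom-norm convention; whether the published
figures averaged norms or components before the root is not stated, so this
choice is isolated in one function.  Per-atom error series are ordered
heavy-atoms-first, and the monitoring bins are white $\le 10 <$ blue
$\le 30 <$ green $\le 50 <$ red, in kcal/(mol A).

# The toy sampler and well-tempered metadynamics

`run_langevin()` integrates overdamped (Brownian) dynamics with
Euler-Maruyama: $dx = \mu F\,dt + \sqrt{2 k_B T \mu\, dt}\,\eta$, uniform
mobility $\mu = 1/(m\gamma)$ (mass 12 amu, friction 1 ps$^{-1}$ by default).
Any positive mobility leaves the Boltzmann distribution invariant, so masses
only set time scales; this justifies using a uniform mobility even for mixed
H/heavy toys.  Numerical caveat stated rather than hidden: a harmonic mode
with per-step damping $a = k\mu\,dt$ samples a variance inflated by
$\approx 1/(1 - a/2)$.  Sampling for *fitting data* uses $a = 0.15$ on the
stiffest mode (throughput; labels are exact regardless of the sampling
distribution), while distribution-accuracy checks (equipartition,
bond-marginal variance) lower it to $a \approx 0.02$.

Well-tempered metadynamics deposits Gaussians of height
$h_t = h_0 e^{-V(s_t)/k_B\Delta T}$, $\Delta T = (\gamma - 1)T$, every
`pace_time`.  Defaults follow the published binding protocol: $h_0 = 0.24$
kcal/mol, pace 0.5 ps, $\gamma = 20$; the published CV widths (0.1 nm for the
COM distance, $\pi/16$, $\pi/8$ for the angles) are the package defaults for
spherical CVs, while the 1D double-well fixtures use a width of 0.4 A chosen
once as roughly half the thermal basin width ($\sqrt{k_BT/U''} \approx
0.47$ A) — the only free width in that toy, since the published values are
tied to CVs that do not exist there.  The FES follows the standard
well-tempered relation $F(s) = -\frac{\gamma}{\gamma-1} V(s) + C$;
`fes_from_bias(..., tail_average = 0.5)` additionally time-averages the
estimate over the last half of the deposition history, the usual damping of
the estimator's residual fluctuation (checkpoint offsets cancel in any
free-energy difference).  On the asymmetric double well (barrier 3 kcal/mol,
tilt 0.3 kcal/mol/A, quadrature $\Delta F = 1.71$ kcal/mol), 1 ns runs at
five seeds recover $\Delta F$ to within 0.08 kcal/mol with tail averaging
(up to 0.32 without).

Reweighting to the unbiased ensemble uses the final-bias (constant-offset)
variant, $w \propto e^{+V_{final}(s)/k_BT}$ normalized to mean 1 — an
approximation to time-dependent estimators, chosen for simplicity and
validated against the bias-derived FES on fixtures (agreement within 0.3
kcal/mol is asserted).  The exact reweighting estimator used alongside the
original sampling protocol is not documented; no claim of identity is made.

# Contact CVs

The switching function $s(r) = [1-(r/r_0)^6]/[1-(r/r_0)^{12}]$ is evaluated
through the algebraically equivalent $1/(1+(r/r_0)^6)$, which removes the
0/0 at $r = r_0$ (value exactly 1/2).  $r_0$ defaults to 6 A.  Contact
numbers sum $s(r_{ij})$ over inter-group pairs; the by-atom decomposition
$C_i$ sums exactly to $C$ (closure is asserted to $10^{-9}$ per frame).
Heavy-atoms-only is the default (the free-energy-analysis convention);
all-atom mode serves monitoring plots, whose bins are white $\le 1 <$ blue
$\le 5 <$ green $\le 10 <$ red.  Aromatic/phenyl groups are user-declared
index sets — no ring perception, mirroring the original manual selection.
Spherical CVs $(\rho, \theta, \phi)$ are measured between mass-weighted COMs
in the laboratory frame; whether the original used a host-aligned frame is
not printed, and no alignment is guessed.

# Free-energy surfaces and the standard-state binding free energy

`build_fes()` histograms (optionally reweighted) samples and sets
$F = -k_BT \ln(w/\max w)$, masked where unsampled, minimum at zero.  Ties in
`find_global_min()` break toward the lowest flattened (column-major) index.
The decoupled (unbound) state is the region $\{C < 0.01,\ \rho >
\rho_{min}\}$; `decoupled_state_value()` returns both the sample-weighted
mean $F$ over the region and the pooled macrostate value
$-k_BT\ln(\sum_{region} w / \max w)$, plus the geometric shell volume
$V_u = \frac{4\pi}{3}(\rho_{hi}^3 - \rho_{lo}^3)$.

The binding estimator is the two-term form
$\Delta G^\circ = [F_{bound} - F_{decoupled}] + \text{correction}$, with two
documented constructions:

* **Minimum/mean convention** (the published wording): bound = global
  minimum bin, decoupled = mean $F$, correction $+k_BT\ln(V_u/V^\circ)$,
  $V^\circ = 1660.54$ A$^3$.
* **Pooled two-state identity**: bound = total Boltzmann weight outside the
  decoupled region, decoupled = total weight of the shell.  Because the
  pooled decoupled value already contains the shell's translational entropy,
  the standard-state conversion enters as $-k_BT\ln(V_u/V^\circ)$, giving
  $\Delta G^\circ = -k_BT\ln[(N_b/N_u)(V_u/V^\circ)]$ — exactly the
  configurational-integral ratio, independent of the arbitrary shell size.

On the toy radial square well (depth 5 kcal/mol, radius 5 A, sampled to
16 A; exact $\Delta G^\circ = -4.317$ kcal/mol by quadrature), the pooled
identity reproduces the oracle to $-0.03$ kcal/mol, while the minimum/mean
convention is off by $+1.97$ kcal/mol.  The bias of the latter has two
sources worth understanding: (i) a probability FES over $\rho$ contains the
radial Jacobian, so a flat well spanning many bins has its minimum at the
largest-$\rho$ bin and the minimum value under-represents the basin weight by
$\sim k_BT\ln(\text{bins spanned})$; (ii) an intensive mean-$F$ paired with
an extensive volume correction leaves a residual
$k_BT[\langle\ln\rho^2\rangle_{shell} - \ln\rho_*^2]$ that grows with the
shell distance — and with $r_0 = 6$ A the zero-contact threshold pushes the
shell beyond ~13 A.  For the narrow, deep wells of real host-guest minima
the min-based convention is far less biased, which is presumably why it is
serviceable in practice; for the wide flat toy well it is not, so the
package treats the pooled identity as its validated estimator and keeps the
min/mean convention available (and default-signed as published) for
comparability.  Block-analysis uncertainties (`block_sd`, default 10
contiguous blocks, SD with ddof = 1) mirror the published error bars;
the published per-system SDs themselves are not reproducible without the
original trajectories and are not asserted.

# Affinity metrics

`error_metrics()` uses MSE $= \mathrm{mean}(\Delta G_{exp} -
\Delta G_{calc})$ — the only sign convention consistent with the published
GAFF $(-1.1)$ and FM-BLYP $(+0.2)$ cells.  Kendall $\tau$ is plain pair
counting (tau-a; the printed data contain no ties, so tie corrections are
untestable).  The Pearlman predictive index weights pair agreements by the
magnitude of the **predicted** difference,
$w_{ij} = |\Delta G^{calc}_j - \Delta G^{calc}_i|$: enumerating all 21 guest
pairs shows this is the only convention that reproduces the full published
PI row (0.60, 0.58, 0.48, 0.65 → 0.6/0.6/0.5/0.7), whereas
experimental-difference weights give 0.65/0.57/0.08/0.73.  The ketamine
guest (G5) is modelled in both protonation forms (its pKa straddles the
experimental pH); `apply_protonation_average()` collapses the two rows by
arithmetic means before any metric is computed, leaving 7 scored guests.
Rounding for table comparison is half-away-from-zero at one decimal.

**A known irreproducible cell.** The published GAFF $\tau$ (0.4) is
internally inconsistent with the published GAFF $\Delta G$ column: GAFF and
FM-BLYP both have 16 concordant and 5 discordant pairs against experiment
($\tau = 11/21 = 0.524 \to 0.5$), yet the table prints 0.4 and 0.5.  No
convention that is a function of the printed columns (tau-a/tau-b, 7- or
8-row variants, Spearman, difference-weighted statistics) yields 0.4 for
GAFF while preserving the other three cells; the cell was most likely
carried over from the preceding study that produced the GAFF predictions.  The corresponding
acceptance expectation is asserted as printed and intentionally left
failing; the other 19 metric cells reproduce exactly.

# The synthetic world — and what a green test does not establish

`make_toy_host()` builds a ring of alternating "nr"/"cr" backbone atoms (one
"hr" substituent each — three atom types, shared classes across the ring),
with an N-C-N-C-like ring torsion of amplitude 2.08 kcal/mol ("stiff") or 0
("floppy"), phase 0, periodicity 2.  At the flat reference geometry the
ring torsions sit at $\phi = 0$, the *maximum* of the $n=2$, $\delta=0$
term, so the stiff ring puckers thermally — convenient, since it diversifies
the torsional ensemble that the refit learns from.  Ghost datasets default
to 600 K, 2000 frames (a scale-down of the published 22,000; recovery tests
define sufficiency here), many independent walkers advanced in batch, and
i.i.d. Gaussian label noise as the stand-in for reference-vs-MM
functional-form mismatch — explicitly *not* a claim about real QM error
structure, which is configuration-correlated.  Consequently, green recovery
tests establish that the estimator and optimizer are correct and
well-conditioned, not that refitting against a real QM reference reaches any
particular accuracy; the published force-RMSE improvements remain outside
desk scope.  The toy binding world is spherically symmetric with a
switching-derived contact proxy; it exercises the FES/standard-state
machinery against an exact oracle but has none of the multi-basin binding
modes, host flexibility, or solvent of the real systems.

# Numerical choices, degenerate inputs, limitations

* Round trips of topologies/parameters use 15 significant digits (stable to
  12); XYZ files carry frame indices and optional energies on comment lines.
* Overlapping non-bonded pairs ($r < 10^{-6}$ A) raise a singularity error
  naming the atoms and frame; missing parameters raise lookup errors naming
  the type key; zero-variance references raise normalization errors.
* Angle forces guard $\sin\theta \ge 10^{-10}$; torsion gradients guard
  collinear geometries at $10^{-20}$ on the squared normal lengths.
* Metadynamics biases are cached on a 600-point grid for 1D identity CVs
  (linear interpolation; the height-decay law then holds to the
  interpolation error, ~$10^{-3}$ relative) and evaluated by direct Gaussian
  summation otherwise, with minimum-image wrapping on periodic CVs.
* Dynamics abort with the step index if a trajectory leaves the potential's
  domain guard.
* The optimizer reports non-convergence (`converged = FALSE`) with
  best-so-far parameters when the iteration cap binds; the default cap (400)
  is ample for the shipped fixtures.
* No solvent, no cutoffs/Ewald, no polarizability or cross terms, no
  replica methods; single-molecule gas-phase systems of tens of atoms are
  the intended scale.
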