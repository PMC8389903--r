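---
title: "Evaluating and optimizing aqueous ion force fields with kbff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and optimizing aqueous ion force fields with kbff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbff)
```

# Scope and philosophy

`kbff` implements the analysis layer of a force-field parameterization
workflow for aqueous alkali halides: given particle configurations and
collective time series — normally produced by molecular dynamics — it
computes corrected solvation free energies, Kirkwood–Buff activity
derivatives, self-diffusion and conductivity, and the static dielectric
constant, and drives a staged global search of the ion Lennard-Jones
parameters against experimental activity data.

The package does not run molecular dynamics. Instead, every estimator is
paired with a seeded synthetic generator that produces inputs with exactly
the statistical structure the estimator assumes, with the generating
parameters ("planted truths") stored alongside. The test suite and the
analysis scripts close the loop: generate, estimate, compare with the
planted value at the appropriate statistical tolerance. Passing these tests
demonstrates that the estimators are correct on data satisfying their
assumptions; it does not demonstrate anything about the physical fidelity
of any particular water or ion model, which only real simulations can.

# Units and constants

All public functions use molecular-simulation units: nm, kJ/mol, ps,
elementary charges, Kelvin. `kbff_constants` carries k_B·N_A
(0.008314 kJ/mol/K), the Coulomb prefactor 1/(4πε₀) = 138.935 kJ·nm/mol/e²,
and the SI constants used at I/O boundaries (conductivity in S/m, pressure
in atm). Thermal energy at 300 K is 2.494 kJ/mol; `thermal_energy()` is
self-tested against this value.

# Force-field model

Species carry (σ, ε, q, m); unlike pairs use Lorentz–Berthelot mixing
(arithmetic σ, geometric ε). The Lennard-Jones potential is truncated at
0.9 nm and shifted by its value at the cutoff, so the potential is exactly
zero there; no long-range dispersion correction is applied, because such a
correction would change the meaning of the shift. The bundled table
`table1_ions.csv` carries the optimized ion parameters
(K⁺ 0.283/0.90, Na⁺ 0.231/0.45, Cl⁻ 0.43/0.42, Br⁻ 0.443/0.75; nm and
kJ/mol, charges ±1).

For alchemical coupling the package exposes a soft-core variant
V(r, λ) = λ·V_shifted(r_sc) with r_sc = (α⁶(1−λ)^p + r⁶)^{1/6}, soft-core
radius α = 0.5 nm and power p = 1 by default. Two conventions had to be
fixed here: the exact soft-core functional form (taken as the standard
r⁶-regularized form above, finite at r = 0 for λ < 1, reducing to the plain
shifted potential at λ = 1 and to zero at λ = 0), and whether the cutoff
shift applies along the coupling path — it does, so that the λ = 1 endpoint
is identical to the pair potential used everywhere else.

# Ewald lattice constant

The self-interaction constant ξ of a unit point charge in a cubic periodic
lattice with uniform neutralizing background is evaluated by Ewald
splitting (real-space erfc sum, reciprocal-space Gaussian sum, self and
background terms) in reduced units of the box length. Defaults
(α = 6/L, real-space images |n| ≤ 3, reciprocal shells |m| ≤ 8) converge
the constant to better than 10⁻⁶; both sums are re-evaluated at enlarged
cutoffs and an informative error names the unconverged term otherwise.
The value, −2.837297, is independent of the splitting parameter — asserted
over a factor-of-two sweep in the tests — and is cross-checked against an
independent direct lattice sum with charge-neutral cell grouping. The
direct sum converges to the Ewald value plus the cell second-moment shift
2π/3·M₂ (M₂ = −1/4 for a point charge with cubic background, i.e. +π/6),
which the oracle removes; this shape term is the classic difference between
cell-wise direct summation and tinfoil-boundary Ewald summation.

# Solvation free energies

`ti_integrate()` performs the λ-quadrature of ⟨∂H/∂λ⟩ (trapezoid by
default — exact for integrands linear in λ, monotone, conservative; natural
cubic spline optional) with errors propagated from per-λ standard errors
assuming independence between λ states. The default schedule is 10 uniform
λ states per coupling stage; spacing is a free choice and uniform is the
neutral default.

The TI machinery is validated against a closed-form toy: a particle in a
harmonic well charged against a linear external potential,
H(λ) = k_s x²/2 + λ·qE·x, for which ΔF = −(qE)²/(2k_s) and ⟨∂H/∂λ⟩ is
linear in λ. Each λ state is sampled exactly from its Gaussian ensemble, so
the toy exercises precisely the bookkeeping, quadrature and error model.
Over 20 seeds the 3-SE interval covers the closed form in ≥ 95% of runs
(20/20 in the shipped run).

Two analytic corrections make simulated free energies comparable:

* `finite_size_correction()`:
  F_corr = (f·q²/ε)·[−ξ/(2L) + 2πr²/(3L³)], f = 1/(4πε₀), r = 2^{1/6}σ.
  The first term removes the spurious interaction of the ion with its
  periodic images (screened by the solvent dielectric ε), the second the
  interaction with the homogeneous neutralizing background over the ion
  volume. The correction is quadratic in q and vanishes as L → ∞. At the
  infinite-dilution production settings (L = 2.5 nm, ε = 72, 300 K) the
  correction for a cation + anion pair is ≈ 0.91 k_BT for all four salts —
  about one thermal energy unit. Because single-ion free energies are not
  experimentally separable without extra-thermodynamic assumptions, the
  package reports and tests this correction at the pair level.
* `pressure_correction()`: F_p = k_BT·ln(p₁/p₀) with p₁ = k_BT·n, the work
  of compressing an ideal gas from the 1 atm standard state into a 1 mol/L
  ideal solution: 3.20 k_BT at 300 K. The standard state is taken exactly
  as stated (1 mol/L at the simulation temperature), with no
  temperature-adjusted variant.

`solvation_free_energy()` composes F_total = F_sim + F_corr + F_p and is
additive over the two ions of a salt.

# Structure and activity

`radial_distribution()` is the standard minimum-image histogram estimator
on uniform half-open bins [lo, hi), normalized by the ideal-gas expectation
per spherical shell; self-pairs are excluded and unordered like-species
pairs counted once. The histogram range is truncated to whole bins below
L/2 (minimum-image validity). The estimator is required, in tests, to equal
a naive O(N²)-per-frame double-loop oracle *exactly* — same bins, same
counts — on mixed-species random and Monte Carlo fixtures.

`kb_integral_finite()` integrates h = g − 1 against the geometric weight of
a spherical subvolume of radius R, w(x) = 1 − 3x/2 + x³/2 with x = r/(2R),
over [0, 2R]. The binned g is treated as exactly piecewise constant and the
polynomial weight is integrated analytically within each bin. A midpoint
rule was considered and rejected: per-bin exact integration makes the
quadrature exact for any step-shaped correlation aligned with bin edges
(verified against the closed form to 10⁻¹⁰) while remaining second-order
for smooth g, with no extra cost.

`kb_extrapolate()` fits G^R against 1/R by ordinary least squares and
reports the intercept G^∞ with standard errors (computed in closed form, so
perfect noiseless fits return zero SEs without degenerate-fit warnings).
The default fit window is the full supplied R range; `kb_chain()` samples
R ∈ [L/8, L/4], inside the regime where the finite-volume integral is close
to linear in 1/R for short-ranged h but far from the minimum-image boundary.
Monte-Carlo coverage of the intercept (100 seeds, 3-SE interval, ≥ 95
covered) is part of the suite.

The activity derivative of a symmetric 1:1 electrolyte at constant T and p
is taken as
a_cc = 1 / (1 + n·(G₊₊ + G₊₋ − G₊s − G₋s)),
the binary-solution Kirkwood–Buff result with indistinguishable ions,
assuming G₋₋ = G₊₊ (symmetric-salt reading) and averaging the two
ion–solvent integrals. It reduces to 1 when all integrals vanish (ideal
solution), is smooth away from the singular set
1 + n(...) = 0 (which raises an informative error — physically an osmotic
instability), and is dimensionally invariant (all G in m³ with matching
densities give the same number). The solvent–solvent integral does not
enter this constant-pressure derivative; it is retained in the `kb_set`
container for density consistency checks via
n = 1/(G₊₋ − G₊₊). The solvent is treated as a single site (its center of
mass) in solvent-involving correlations. Molality–density conversion uses
the actual box composition of the trajectory, not experimental densities,
for self-consistency with the simulated ensemble.

`activity_curve()` chains RDF → finite-volume KB → 1/R extrapolation →
a_cc per molality; per-point errors re-run the chain on five contiguous
frame blocks and report the block standard error. Five blocks is the
package-wide error protocol (`block_average_error()`), with the remainder
of a non-divisible series discarded from the end.

# Transport

`mean_squared_displacement()` averages over all time origins and all
particles of a species; it refuses wrapped input (inter-frame jumps above
L/2) and points to `unwrap()`, which reconstructs continuous tracks by
minimum-image folding of successive displacements (and refuses
near-ambiguous jumps beyond 0.45 L). `fit_self_diffusion()` fits
MSD = 6Dτ + c; the offset c absorbs short-time deviations. The default
window spans 10–50% of the largest lag — a neutral reading of "long-time"
— and is always recorded in the result; a coefficient of determination
below 0.9 triggers a non-linearity warning (e.g. ballistic input). For
planted-truth recovery tests the window [30, 600] ps on 3000-frame,
256-particle Brownian fixtures keeps the sampling error of D̂ near 1–2%,
comfortably inside the 5% recovery requirement; these sizes are the
package's chosen desk-scale study conditions.

`finite_size_diffusion_correction()` implements the hydrodynamic
finite-size correction D_self = D_sim − ξ·k_BT/(6πηL) with the same lattice
constant ξ; the solvent viscosity is a required input per water model
(0.729 mPa s is the conventional SPC/E value used in the examples), never a
silent default. `conductivity()` applies κ = n e²(D⁺ + D⁻)/(k_BT) for
monovalent ions and converts to S/m.

# Dielectric response

The static susceptibility of a salt solution is decomposed into water,
cross, and ion terms from the box dipole M(t) and ion current J(t):
χ_ww = ⟨δM²⟩/(3ε₀Vk_BT), χ_wi = 2⟨δM·δM_I⟩/(3ε₀Vk_BT),
χ_ii = ⟨δM_I²⟩/(3ε₀Vk_BT), with M_I(t) = ∫J dt reconstructed by cumulative
summation (the integration constant drops out of the centered moments), and
ε = 1 + Σχ. The zero-frequency limit is taken analytically from these
equilibrium fluctuation formulas rather than by extrapolating a computed
spectrum, because only the static limit is consumed downstream; additivity
against the total-moment fluctuation then holds by construction (asserted
to 10⁻¹⁰ in tests). A stationarity screen compares the first and last
five-block means of |M|² against their within-block (sub-blocked) standard
errors and warns beyond 5 SE. The dielectric decrement is the plain
difference to the pure-solvent constant (72.0 for SPC/E as the bundled
example value).

# Synthetic generators

* `ideal_gas()`: iid uniform positions per frame; g ≡ 1, all KB integrals
  zero, a_cc ≡ 1. The null model for the whole structure chain.
* `mc_fluid()`: single-particle Metropolis sampling of the shifted
  Lennard-Jones fluid (optionally with minimum-image Coulomb — a toy
  treatment without Ewald sums, adequate for small neutral boxes but not
  for long-range dielectric physics). Starts from a randomized lattice;
  logs the acceptance rate (warning outside 5–95%) and applies a
  non-ergodicity screen: first-vs-last five-block energy means beyond 6
  within-block SE raise an error. Equilibrium configurations are all the
  KB estimators need, which is why Monte Carlo can replace dynamics here.
* `brownian()`: Gaussian displacements with variance 2D·dt per component,
  per-species planted D; stored wrapped, exactly unwrappable.
* `dipole_process()`: stationary Ornstein–Uhlenbeck vector processes for
  the water dipole and the integrated ion dipole, with the ion current
  emitted as the exact discrete derivative — so the planted susceptibility
  components are recovered by the estimator's own discrete integration
  without discretization error. Planted components must satisfy the
  Cauchy–Schwarz constraint χ_wi² ≤ 4χ_wwχ_ii.
* `mock_backend()`: an analytic map from ion parameters to pair free
  energies (linear response, sensitivities A = −300 kJ/mol/nm and
  B = 40 per kJ/mol by default) and to activity curves (linear response
  with four linearly independent molality profiles — constant, m/5,
  √(m/5), (m/5)² — one per ion × parameter direction). The activity
  objective is therefore a positive-definite quadratic form with its
  global minimum, value zero, exactly at the planted parameters; with
  observation noise of variance s², the expected objective at the truth is
  s². Linear response was chosen over a quadratic penalty deliberately: a
  quadratic penalty makes the objective quartic — flat — around the
  optimum, which defeats both grid identification and interpolation and
  does not resemble how observables respond to small parameter changes.

All generators are bit-reproducible under a fixed seed, and every
statistical recovery test derives its tolerance from sampling error (block
SEs or analytic null expectations), never from tighter ad-hoc constants.
For the ideal-gas RDF flatness checks the tests use the analytic Poisson
standard error of each bin count under the null rather than an estimated
SE, because a 5-block SE estimate has only 4 degrees of freedom and makes
an every-bin 3-SE assertion unreliable.

# The staged optimizer

`optimize_salt_family()` mirrors the strategy that makes a four-ion global
search tractable: the optimum depends only on the initial chloride
parameters.

1. For each chloride (σ, ε) on the user's grid, Na⁺ and K⁺ are constrained
   to the solvation free-energy isolines of NaCl and KCl:
   `free_energy_isoline()` walks an ε grid and root-finds σ by bisection to
   0.001 nm (the third decimal of the sodium σ matters). The candidate
   minimizing the salt's activity objective is then refined continuously
   along the isoline within one ε grid cell.
2. Holding the cations fixed, Br⁻ is optimized on the bromide salts over
   its own (σ, ε) grid, followed by a sub-grid polish confined to one grid
   cell around the winning node. With a noisy backend the polish is
   accepted only when its unbiased improvement (replicate evaluations at
   both points) exceeds twice the combined noise SE — sampled points win
   unless an improvement is resolvable above the noise floor. The same
   rule governs the landscape: the reported optimum is the best *sampled*
   chloride point, and the cubic-interpolated minimum of the landscape
   (two-pass natural splines on a regular grid) is reported alongside,
   adopted only if its improvement exceeds an explicit `noise_floor`
   argument (default: never).
3. Ties are broken deterministically: smallest k, then smallest σ, then
   smallest ε.

The objective `objective_k()` averages squared deviations per salt over its
molality grid and then averages over salts; each optimization stage uses
the salts that involve the ion being varied (chloride salts in stage 1,
bromide salts in stage 2), while the reported landscape value averages all
four salts at the assembled parameter set. Molalities are restricted to the
open interval (0, 5) mol/kg; the default grid spacing is 0.25 mol/kg.
Reference activity tables are pluggable CSVs
(`molality_molkg, a_cc[, error]`); no experimental data is bundled, and the
backend's synthetic reference curves (a Debye–Hückel-like √m decay with
salt-specific slopes) serve the tests.

End-to-end recovery is tested: a noiseless backend returns the planted
four-ion set exactly (objective ≈ 10⁻¹⁶); with observation noise 0.01 the
set is recovered within grid resolution over five seeds; an off-grid
planted chloride is located by the interpolated minimum an order of
magnitude closer than the best sampled node.

# Trajectory and series I/O

Three plain-text formats are supported, with exact round-trip tests:
multi-frame XYZ (box length and time on the comment line, nm), concatenated
GROMACS-style coordinate frames (nm, fixed-width, 3 decimals), and a long
CSV dialect (`frame, particle, species, x, y, z`) that decouples tests from
any format library. Boxes are cubic only; triclinic input is rejected
loudly. Coordinates are returned exactly as stored — wrapping and
unwrapping are explicit operations, because KB/RDF estimators need wrapped
and MSD needs unwrapped coordinates. Species labels can be resolved against
a force-field table on read, which attaches charges and rejects unknown
labels. Scalar/vector series use two- or four-column CSV
(`time, value` / `time, vx, vy, vz`). No binary or compressed formats are
parsed; none of the installed format libraries in this language handle
these trajectory dialects, so the readers are small hand-validated parsers.

Every analysis script writes a `manifest.json` (stage, configuration, input
hashes, seeds, package version, timestamp) via `write_run_manifest()`, and
identical seeds reproduce byte-identical outputs.

# Problem sizes and runtime

The shipped tests and scripts use desk-scale sizes chosen so the whole
suite runs in about a minute: 20–300 particles, hundreds of frames for
structure; 256 particles × 3000 steps for diffusion recovery; 4 × 10⁴ steps
for the dipole process; Metropolis runs of ≤ 10⁴ sweeps; optimizer grids of
a few tens of chloride nodes. These sizes are statements about statistical
sufficiency for the planted-truth tolerances (5% for D, CI-level for
susceptibilities, grid resolution for the optimizer), not about the scales
a production study would use.

# Known limitations

* The Monte Carlo Coulomb option uses minimum-image interactions without
  Ewald summation; it is a fixture for sign- and association-level tests,
  not a quantitative electrolyte model.
* The activity derivative assumes a symmetric 1:1 salt (G₋₋ = G₊₊);
  asymmetric or multivalent electrolytes would need the full
  multicomponent KB expressions.
* The dielectric estimator returns only the static limit, not χ(ω).
* Synthetic fixtures do not emulate water structure, hydrogen bonding,
  finite-concentration ion correlations, or thermostat/barostat artifacts;
  conclusions about real force fields require real trajectories fed
  through the same interfaces.
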