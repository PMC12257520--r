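---
title: "Methods: path-integral dynamics of water isotopes with q-TIP4P/F"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path-integral dynamics of water isotopes with q-TIP4P/F}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`pimdwater` simulates liquid H2O, HDO, D2O and T2O with the q-TIP4P/F
potential: a flexible four-site water model with

* a **quartic expansion of a Morse potential** for each covalent OX bond,
  $V(r) = D_r\,[\alpha_r^2\Delta^2 - \alpha_r^3\Delta^3 +
  \tfrac{7}{12}\alpha_r^4\Delta^4]$ with $\Delta = r - r_{eq}$,
* a **harmonic bend**, $\tfrac12 k_\theta(\theta - \theta_{eq})^2$,
* a **Lennard-Jones** site on oxygen, and
* point charges on the two covalent sites plus a massless **M site** on the
  HOH bisector, $\mathbf r_M = \gamma\,\mathbf r_O + \tfrac{1-\gamma}{2}
  (\mathbf r_{X_1} + \mathbf r_{X_2})$. Forces acting on M are pushed back
  onto the massive sites with the transposed placement weights.

The numeric constants ship in a versioned JSON file
(`inst/extdata/qtip4pf_constants.json`) in the internal unit system nm /
ps / amu / kJ mol$^{-1}$ / e, in which 1 amu nm$^2$ ps$^{-2}$ equals
1 kJ/mol exactly. The constants are deliberately isotope-independent:
isotope substitution enters **only** through the site masses
(H 1.00783, D 2.01410, T 3.01605, O 15.9949 amu), so all isotope effects in
the output are nuclear quantum effects plus trivial mass scaling, never
re-parameterization. HDO is modelled as 100% singly deuterated molecules.

Electrostatics use the **reaction-field** kernel
$q_iq_j(1/r + k_{rf} r^2 - c_{rf})$ with
$k_{rf} = (\varepsilon_{rf}-1)/[(2\varepsilon_{rf}+1) r_c^3]$,
$\varepsilon_{rf} = 78.3$, cut off at $r_c = 1$ nm together with the LJ
term. Whether the kernel should be shifted to zero at the cutoff is an
open dialect question for this model family; we default to the shifted
form ($c_{rf} = 1/r_c + k_{rf} r_c^2$) because a continuous potential
avoids energy drift in microcanonical checks, and expose `shift_rf` for
the unshifted variant. The LJ term is plainly truncated (no tail
correction, no switching).

# Ring-polymer dynamics

Each atom is a ring polymer of $n_b$ beads with springs
$\omega_n = n_b/(\beta\hbar)$; bead slice $k$ of one molecule interacts
only with slice $k$ of the others. The propagator is the OBABO splitting:

1. half-step **PILE thermostat** in normal-mode space: exact
   Ornstein-Uhlenbeck weights $e^{-\gamma_k\Delta t/2}$, internal-mode
   friction at the critical-damping value $\gamma_k = 2\omega_k$ and a
   small centroid friction $\gamma_0 = 0.1$ ps$^{-1}$,
2. half kick by the physical forces,
3. **exact free-ring-polymer drift** in normal modes,
4. half kick, half thermostat.

With $n_b = 1$ and the thermostat off this is exactly velocity Verlet,
which the tests verify against an independent R implementation. Dynamical
observables (diffusion, spectra) are computed from the same thermostatted
propagator with the small centroid friction kept on, which broadens
vibrational lines somewhat; peak **positions** are the validated quantity.

Constant pressure uses a **Monte Carlo barostat**: isotropic $\ln V$
proposals every 25 steps (auto-tunable width, default 0.02), molecular
*centroid* scaling (all beads of a molecule displaced rigidly, so bead
springs and intramolecular terms are untouched), and a Metropolis weight
$\exp\{-\beta[\Delta\bar U + P\Delta V - (N+1)k_BT\,\Delta\ln V]\}$ built
from the bead-averaged potential, which preserves the quantum Boltzmann
distribution. Whether beads should instead be scaled independently is not
settled; centroid scaling is the default and the proposal code is isolated
behind the ensemble flag.

Estimators recorded per frame: bead-averaged potential $\bar U$, the
**centroid-virial** kinetic estimator
$K_{cv} = \tfrac32 N k_BT - \tfrac{1}{2n_b}\sum (\mathbf r_k - \bar{\mathbf
r})\cdot \mathbf F_k$, the primitive estimator, the virial pressure
$P = (2K_{cv} + \bar W)/3V$, volume and centroid kinetic temperature.
Total quantum energy is $E = K_{cv} + \bar U$ and enthalpy $H = E + PV$.
At $n_b = 1$ both kinetic estimators are the classical kinetic energy.

# Analysis pipelines

**Thermodynamics.** $\rho = NM/(N_A\langle V\rangle)$ with block-averaged
errors (no error bar below 5 blocks); $\kappa_T = \langle\delta
V^2\rangle/(k_BT\langle V\rangle)$ from volume fluctuations (the
fluctuation route was chosen over numerical $\partial V/\partial P$
because it needs a single run; the choice is recorded in the output).
Heat capacities come from a fourth-order polynomial fit of $H(T)$ or
$E(T)$ followed by analytic differentiation, with resampled error bands;
finite-bead heat capacities are bead-convergence limited, and the
function says so in its output. The density-maximum locator fits a
quadratic around the extremum of $\rho(T)$ (or the minimum of $P(T)$ at
constant volume — the two routes agree where both apply) and reports
"none in range" for monotone input.

**Diffusion.** $D$ from the slope of the multiple-origin MSD of the O
ring-polymer centroids, $\mathrm{MSD} = 6Dt$; sub-linear windows
(log-log slope < 0.9) are flagged as not diffusive. $D(T)$ is fitted by
the Arrhenius law $D_0 e^{-E_A/k_BT}$ on the high-temperature branch
($T \ge 300$ K by convention) and by the mode-coupling power law
$D_1 (T - T_{MCT})^{\gamma}$ on 220-300 K, with $T_{MCT}$ bounded below
the fitted window. MCT parameters are sensitive to the window; a
sensitivity harness reports parameter shifts under one-point window
moves, and the crossover temperature is reported as the numerical
intersection of the two branches.

**Spectra.** The VDOS is the Fourier transform of the mass-weighted
centroid velocity autocorrelation — the ring-polymer approximation to the
Kubo-transformed TCF — with a Hann window, ACF length one quarter of the
trajectory and 4x zero padding. The IR spectrum applies the harmonic
quantum-correction prefactor $\omega\tanh(\beta\hbar\omega/2)$ to the
dipole ACF transform; the convention is stored in the object's metadata
since more than one prefactor convention is in circulation. Sampling
below a 4500 cm$^{-1}$ Nyquist frequency is refused because the OH
stretch band would alias.

**Structure.** RDFs are bead-resolved (same-bead pairs) and normalized by
the ideal-gas expectation per counted pair, which makes the ideal-gas
fixture exactly flat. The tetrahedral order parameter
$q = 1 - \tfrac38\sum_{j<k}(\cos\psi_{jk} + \tfrac13)^2$ over the four
nearest O neighbours and the shell-separation metric are computed on
centroids (per-replica variants sit behind a flag). The shell separation
$\langle d_{fs}\rangle$ is implemented as the 5th-minus-4th nearest
neighbour distance; the literature definition lives in references not
reproduced here, so this stand-in is validated only against the
qualitative limits (about 0.1 nm in tetrahedral, about 0 in high-density
environments). Hydrogen bonds use the geometric criterion
$d_{OO} < 3.5$ Å and $\theta_{HOO} < 30°$, evaluated per replica with the
angle at the donor oxygen between the donated O→X bond and the O→O
vector; replica means are averaged afterwards, and HDO statistics are
split by donor species. The HB energy is
$E_{HB} = (E_{pot} - E_0)/n_{HB}$ with $E_0$ from a single-molecule
path-integral run at matched $(T, n_b)$ — a 0 K minimum would miss the
thermal intramolecular energy — and $n_{HB} = 2\,\mathrm{bonds}/N$
(each bond counted for both partners; the alternative convention is a
flag).

**Delocalization.** $R_g^2 = \langle n_b^{-1}\sum_k |\mathbf r_k -
\bar{\mathbf r}|^2\rangle$ per species, decomposed in a molecule-fixed
frame built from centroid geometry each frame: $\hat x$ along the
centroid O→X$_1$ bond, $\hat z$ normal to the molecular plane, $\hat y$
completing the frame. The three components sum to $R_g^2$ to machine
precision by construction. For HDO the frame-defining site X$_1$ is the H
site by convention (configurable).

# Synthetic fixtures

Every pipeline stage is testable without liquid simulations:

* exact normal-mode Gaussian sampling of **free ring polymers**, whose
  3-D gyration radius has the discrete closed form
  $\langle R_g^2\rangle = \tfrac{\beta\hbar^2}{4m}(1 - 1/n_b^2)$ —
  re-derived in the tests by brute-force normal-mode summation with
  frequencies from direct diagonalization of the bead-coupling matrix;
* a diamond-cubic **tetrahedral lattice** ($q = 1$ by construction);
* **dimers** with prescribed $(d_{OO}, \theta_{HOO})$;
* **spectral toys** (superposed cosines packaged as archives, so the
  spectral code cannot tell fixtures from simulations);
* **curve families** (Arrhenius / MCT / quartic) whose fitters are exact
  inverses in the noiseless case.

All fixtures are seed-deterministic and carry their generating spec.

What the fixtures do *not* emulate is liquid-state correlation structure:
passing fixture tests demonstrates the estimators and transforms are
correct, not that a short desk-scale liquid run is converged. The liquid
checks therefore assert robust *orderings* (band red shifts, gyration
mass ordering, anisotropy direction) rather than paper-scale numbers.

# Study conditions and desk profile

The reference study conditions are $N = 512$ molecules, $n_b = 32$,
$dt = 0.25$ fs (0.5 fs classical), $r_c = 1$ nm, $\varepsilon_{rf} =
78.3$, $\gamma_0 = 0.1$ ps$^{-1}$, at constant molar volume
$v = 18.0$ cm$^3$/mol (box edge 2.48 nm; $\rho = 1.0$ g/cm$^3$ for H2O,
200-400 K) or constant $P = 0.1$ MPa (220-400 K), with ns-scale
equilibration and production. These ship as YAML configs under
`inst/configs/` and parse into runnable settings.

The package's **desk profile** — used throughout the tests and the
acceptance script — is 32 molecules, 8 beads, 300 K, 1 ps equilibration
under a temporarily strong centroid friction (5 ps$^{-1}$, so the initial
lattice melts within the run) followed by 3 ps production at
$\gamma_0 = 0.1$ ps$^{-1}$. A 32-molecule box at $v = 18$ cm$^3$/mol has
edge 1.24 nm, so the cutoff is reduced to $L/2$ and the reaction-field
constant recomputed; this is the dominant systematic difference from the
reference conditions and mainly affects absolute pressures. Desk-scale
temperature grids for the fitting pipelines use 5-7 points over
220-400 K. At these sizes every ordering the package asserts (VDOS red
shifts with isotope mass, HDO stretch bimodality,
$R_g$(H) > $R_g$(D) > $R_g$(T) > $R_g$(O), $R_{g,z}^2 \ge R_{g,y}^2 \ge
R_{g,x}^2$ for covalent sites, HDO/H2O transferability) is already
stable; absolute thermodynamic derivatives ($C_P$, $\kappa_T$) are not
converged at desk scale and are exercised on constructed inputs instead.

# Numerical choices and degenerate inputs

* Bond-angle forces guard the $\sin\theta \to 0$ degeneracy; collinear
  molecules are still defined for M-site placement (with a skip counter
  in the gyration frame builder).
* Charged-site overlaps below $10^{-4}$ nm and non-finite coordinates are
  rejected outright; per-step displacements beyond 0.05 nm abort the run
  with a diagnostic rather than propagate a blown-up state.
* The engine never wraps coordinates (molecules stay whole; interactions
  use minimum images), which keeps centroid MSDs valid without
  unwrapping; the MSD code still rejects input with jumps larger than
  $L/2$ in case foreign wrapped trajectories are fed in.
* At large bead numbers the stiffest normal mode makes
  $\gamma_k\,dt$ order one at the default 0.25 fs step; the splitting
  bias in sampled variances scales as $dt^2$, so the 64-bead oscillator
  checks run at 0.05-0.1 fs.
* Fit start values come from log-linear solutions (Arrhenius) or
  bounded heuristics (MCT); MCT non-convergence is reported with
  diagnostics, never silently replaced.
* All random streams (R fixtures and the compiled engine's
  `mt19937_64`) are seed-deterministic; identical seeds give bit-identical
  trajectories.

# Known limitations

* Reaction-field electrostatics only (no Ewald/PME), matching the model
  conventions targeted here.
* Thermostatted ring-polymer dynamics broadens spectral lines; no
  correction is attempted.
* Heat capacities at $n_b = 8$-32 carry a bead-convergence error of order
  several J mol$^{-1}$ K$^{-1}$; treat desk-scale $C_P$/$C_V$ as trends.
* The shell-separation metric is a documented stand-in (see above).
* No bosonic exchange, higher-order Trotter factorization, or
  path-integral Monte Carlo.
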