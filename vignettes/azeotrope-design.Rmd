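---
title: "Designing azeotropes in patchy-particle mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing azeotropes in patchy-particle mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azeopatch)
```

# The model

`azeopatch` works with mixtures of *patchy particles*: hard spheres of
diameter $\sigma$ decorated with attractive surface sites ("patches") that
bond selectively and directionally. Two particles interact through the
Kern-Frenkel potential: a square well of depth $\epsilon_{\alpha\gamma}$ and
width $\delta$ that is switched on only when a patch $\alpha$ on the first
particle and a patch $\gamma$ on the second both point at the other particle
within an angular cone, $\hat r_{ij}\cdot\hat p_{\alpha,i} >
\cos\theta_{\max}$ (and symmetrically for $\gamma$). All quantities are
reduced: $\sigma = 1$, the reference bond energy $\epsilon = 1$, $k_B = 1$.
The geometry defaults are $\delta = 0.2$ and $\cos\theta_{\max} = 0.98$
(`kern_frenkel_params()`); with these narrow patches each patch can hold at
most one bond, which is the regime in which first-order thermodynamic
perturbation theory is quantitative.

A *mixture design* (`mixture_design()`) is the central object: a graph whose
nodes are species and patches and whose energy-weighted edges say which
patch types bond and how strongly. Patch types are global (no two species
share one), and a diagonal entry of the energy matrix encodes a
self-complementary patch. Zero entries mean "never bonds" and propagate
exactly ($\Delta_{\alpha\gamma} = 0$).

Two factory designs cover the interesting limits:

* `build_n2c8()` — two species, four tetrahedral patches each, eight patch
  types, *bond-exclusive* pairing (every patch has exactly one partner).
  The pairing used is cross-species edges 1–5 and 4–8, self-complementary
  patches 2–2 and 3–3 on species 1 and 6–6 and 7–7 on species 2. Within
  Wertheim theory any bond-exclusive completion that keeps the 2–2/3–3
  self-loops is thermodynamically identical (a self-loop $\alpha$–$\alpha$
  and an intra-species pair $\alpha$–$\beta$ generate the same mass-action
  equations), so this choice is canonical rather than consequential; it is
  also the unique structure (up to relabeling) once one demands that both
  species stay connected through cross bonds.
* `build_ideal_azeotrope_binary()` — every patch has exactly two
  complementary types, one on each species, all energies equal. This is the
  *ideal azeotropy* topology: the mass-action solution loses all
  composition dependence and the mixture demixes azeotropically at every
  concentration.

Patch vectors use the standard tetrahedral frame
$(1,1,1)/\sqrt3$-family; any rigid rotation is physically equivalent.

# Wertheim theory

The Helmholtz free energy per particle (in $k_BT$) is
$\beta f = \beta f_{\rm ideal} + \beta f_{\rm HS} + \beta f_{\rm bonding}$,
with the Carnahan–Starling hard-sphere excess
$\beta f_{\rm HS} = (4\phi - 3\phi^2)/(1-\phi)^2$ at packing fraction
$\phi = \rho\pi\sigma^3/6$, de Broglie volumes set to one (they shift
chemical potentials by composition-independent constants and cannot move a
coexistence point), and the first-order bonding term
$$\beta f_{\rm bonding} = \sum_i x^{(i)}\Big[\sum_{\alpha\in\Gamma(i)}
\big(\ln X_\alpha - X_\alpha/2\big) + \tfrac12\Gamma(i)\Big],$$
where $X_\alpha$ is the probability that patch $\alpha$ is *not* bonded,
fixed by the law of mass action
$$X_\alpha = \Big[1 + \phi\sum_j x^{(j)}\sum_{\gamma\in\Gamma(j)}
X_\gamma\,\Delta_{\alpha\gamma}\Big]^{-1}.$$
The solver (`solve_mass_action()`, and its C++ twin inside the equation of
state) uses a damped fixed-point iteration (damping 0.5, started from
$X=1$) followed by a Newton polish to residual $10^{-12}$; the fixed point
is unique in $(0,1]^n$ and the residual is stored with every solution.

For bond-exclusive designs with uniform energies the equimolar composition
$x^{(i)} = 1/N_s$ makes all equations identical, so all $X_\alpha$ coincide
and satisfy $X + (\phi\Delta/N_s)X^2 = 1$ — this is the equimolar azeotrope.
(The $1/N_s$ factor follows directly from the partner's molar fraction in
the mass-action sum; the tests verify it numerically for two and three
species.) For the ideal topology the sum over species telescopes
($\sum_j x^{(j)} = 1$) and $X + \phi\Delta X^2 = 1$ independently of
composition (`ideal_azeotrope_X()`).

## Bond strengths and the pair-correlation treatment

The dimensionless bond strength is
$$\Delta_{\alpha\gamma} = \frac{1}{V_s}\Big(\frac{1-\cos\theta_{\max}}{2}\Big)^2
\; 4\pi\!\!\int_\sigma^{\sigma+\delta}\!\! g_{\rm HS}(r)\, r^2\,dr \;\times\;
\big(e^{\epsilon_{\alpha\gamma}/T}-1\big),$$
the orientationally averaged Mayer integral over the bond volume. The only
modeling freedom is the hard-sphere pair correlation $g_{\rm HS}$ across the
shell, and `azeopatch` implements three treatments (argument `ghs`
everywhere):

* `"shell"` (default): the full Percus–Yevick $g(r)$ — analytic on the
  first coordination shell (`py_g_hs()`) — integrated across
  $[\sigma, \sigma+\delta]$. Because the equation of state needs analytic
  density derivatives, the shell factor is tabulated once on
  $\phi\in[0,0.6]$ and fitted by a degree-10 polynomial in $\log$ space
  (max error far below the theory's own accuracy).
* `"contact"`: the Carnahan–Starling contact value
  $(1-\phi/2)/(1-\phi)^3$, constant across the shell.
* `"unit"`: $g_{\rm HS}\equiv 1$, the low-density form.

The default matters quantitatively: with $\delta = 0.2$ the shell is not
thin, and $g(r)$ decays appreciably across it. At the conditions of the
worked examples the contact treatment overestimates bonding and the unit
treatment underestimates it; the shell integral is the faithful reading of
the defining formula and is what the package's azeotrope-shift results are
computed with. The treatment used is recorded in
`compute_delta()$details`.

## Equation of state

Pressure and chemical potentials are analytic. Writing the association
term in its generating form and using its stationarity with respect to the
$X_\alpha$ at the mass-action solution, only the explicit density
dependence survives:
$$\beta\mu_i^{\rm bond} = \sum_{\alpha\in\Gamma(i)}\ln X_\alpha
 - V_s\,\frac{d\ln g}{d\phi}\, D, \qquad
\beta P^{\rm bond} = -D\Big(1 + \phi\,\frac{d\ln g}{d\phi}\Big),$$
with $D = \tfrac12\sum_\alpha \rho_\alpha (1 - X_\alpha)$ the bond density.
The test suite validates both against Richardson-extrapolated finite
differences of the free energy ($10^{-6}$, in practice $10^{-10}$) and
checks the Euler/Gibbs–Duhem identity
$\beta P/\rho + \beta f = \sum_i x_i\beta\mu_i$ to $10^{-8}$ at random
states.

# Phase behavior and azeotrope location

At fixed $(T, P, x)$ the density roots of $P(\rho) = P$ are bracketed on a
log-spaced grid up to $\phi = 0.58$ and refined by bisection; the lowest
root is the vapor branch, the highest the liquid branch, and middle roots
(mechanically unstable) are discarded. `gibbs_curve()` evaluates
$g = \beta f + \beta P/\rho$ on both branches over a composition grid.

`coexistence()` solves the common-tangent condition — equal chemical
potentials of both species across the branches — as a $2\times2$ Newton
iteration on $(x_{\rm vap}, x_{\rm liq})$ with a finite-difference
Jacobian, seeded from the branch crossing; if the iteration stalls, a
convex-hull tangent construction on the grid supplies the answer. Above
the azeotropic pressure of a symmetric mixture the two-phase region splits
into mirror-image lobes; the `x_near` argument selects which one is
solved.

`find_azeotrope()` exploits the defining geometry: at the azeotropic
pressure the two branches become tangent at a single interior composition,
so the pair of branch crossings that bracket the coexistence lobe collapses.
The algorithm scans pressure geometrically for the two-phase band, then
bisects $\ln P$ against the band edge at which the crossings converge to an
interior point. A subtlety drives the implementation: near collapse the
region where the disfavored branch is higher becomes arbitrarily narrow, so
a fixed composition grid eventually misses it and the bisection stalls at
grid resolution. The classification window therefore zooms onto the
collapsing pair as it narrows, keeping the composition resolution
proportional to the residual gap; the iteration stops when that gap is
below `tol` ($10^{-3}$ by default, comfortably finer than the $0.01$
precision at which results are quoted). `binodal_point()` handles the
complementary task — coexistence densities at *fixed* composition (the
relevant construction for ideal-azeotropic mixtures, which have no isolated
azeotropic composition to find).

With the default geometry the tetravalent designs have TPT1 critical
temperatures near $T \approx 0.09$: `binodal_point()` locates vapor–liquid
coexistence for the ideal-azeotropic design at $T = 0.085$ and below, and
the N2c8 azeotrope constructions in the examples run at $T = 0.08$.

# The inverse-design loop

`shift_azeotrope()` relocates the azeotrope of a design to a prescribed
composition by tuning one scalar: the bond energy $\epsilon'$ shared by the
selected patch pairs (by default the self-complementary pairs of species
1). Each iteration sets $\epsilon'$, re-solves the full azeotrope at the
user-supplied temperature, and updates $\epsilon'$ by a secant step on
$x_{\rm azeo}(\epsilon')$, starting with a $+0.1$ perturbation. Monotonicity
of $x_{\rm azeo}(\epsilon')$ over the relevant range — asserted empirically
in the tests on a five-point grid — is what makes the secant update safe.
Temperature is held fixed per run: an azeotropic line spans a range of
$(T, P)$ and the azeotropic composition can vary along it, so "the"
azeotrope of a design is only defined once $T$ is pinned.

# The Monte Carlo engine

The simulation side (`run_nvt()`, `run_npt()`, `run_gibbs()`,
`run_gcmc()`) implements the same Kern-Frenkel Hamiltonian with cubic
periodic boxes, minimum-image convention, and quaternion orientations
(patch frames recomputed on the fly, never cached). Move amplitudes and
per-move probabilities live in `move_schedule()`. Energies are tracked
incrementally and audited against full recomputation at a configurable
stride; the maximum drift is reported with every run and asserted below
$10^{-9}|E|$ in the tests. Pair energies are evaluated directly against
all particles ($O(N)$ per move): at the validation scales used here
(tens to a few hundred particles) this is faster and considerably easier
to verify than a cell-list pipeline, and the engine's cost is dominated by
statistics, not by the neighbor search.

Beyond translations and rotations:

* **AVB moves.** Aggregation-volume-bias moves pick a target particle and
  either insert an "out" particle into its bonding shell (position drawn in
  a patch cone of the target, orientation drawn so a random patch of the
  moved particle points back) or eject an "in" particle to a uniform
  position and orientation. The acceptance ratio uses the exact measure of
  the in-region, $M_{\rm in} = \Gamma_j\Gamma_k\,v_{\rm ps}\,w$ with
  $v_{\rm ps} = \tfrac{4\pi}{3}[(\sigma+\delta)^3-\sigma^3]\,w$ and
  $w = (1-\cos\theta_{\max})/2$ (patch cones cannot overlap at these
  angular widths, so no multiplicity corrections arise), and is
  antisymmetric under move reversal — asserted as an identity in the
  tests. Equilibrium averages are move-set independent; a dedicated test
  confirms AVB on/off indifference for a non-interacting system.
* **Volume moves** in $\ln V$ with the $(N+1)\ln V$ Jacobian (NPT), paired
  $\ln(V_a/V_b)$ exchanges conserving the total volume (Gibbs).
* **Transfers and insertions** use a *mixed channel*: with probability
  `transfer_bias` the new particle is placed, orientationally biased, into
  the bonding shell of a random target in the destination box, otherwise
  uniformly. The generation densities of both channels enter the
  acceptance rule exactly, so detailed balance holds for any bias value;
  the bias only buys acceptance at strong bonding.
* **Grand-canonical** insertions/deletions share the mixed channel;
  activities are $e^{\mu/T}$ with unit de Broglie volumes, matching the
  theory side's convention.

Reported observables (density, composition, energy per box) are block
averaged (`block_average()`, $\ge 10$ blocks) after an equilibration cut.
Pressure inputs to the simulation functions are in energy units
($\epsilon/\sigma^3$); the theory functions work in $\beta P$. Runs are
reproducible from R's RNG: the engine draws all randomness from the
session stream, so `set.seed()` pins entire trajectories.

# The S0 chemical-potential route

`partial_structure_factors()` accumulates
$S_{ab}(k) = \langle \mathrm{Re}\,\rho_a(\mathbf k)\rho_b(-\mathbf k)\rangle/N$
over all integer wavevectors of the periodic box, shell-averaged over equal
$|k|$; the $N$-normalized convention is recorded in the metadata because
the composition integral below is only correct in a definite convention.
`oz_fit()` extrapolates each partial to $k = 0$ through the
Ornstein–Zernike form $S(k) = S_0/(1 + k^2\xi_A\xi_B)$ (linear
initialization on $1/S$, Levenberg–Marquardt refinement with box
constraints that keep noisy near-zero cross partials identifiable; constant
data recovers $\xi = 0$ exactly).

The excess chemical potential follows from a Kirkwood–Buff integral over
composition. Written through the Bhatia–Thornton concentration structure
factor $S_{cc}(0) = x_B^2 S^0_{AA} + x_A^2 S^0_{BB} - 2x_Ax_B S^0_{AB}$,
the thermodynamic identity
$\partial\beta\mu_A/\partial x_A\big|_{T,P} = x_B/S_{cc}(0)$ gives
$$\beta\mu_A^{\rm ex}(x_A) = \int_1^{x_A}
\Big[\frac{x_B}{S_{cc}(0)} - \frac{1}{x_A}\Big]\,dx_A ,$$
integrated by the trapezoidal rule from the pure reference state
$x_A^0 = 1$ (where $\mu^{\rm ex} \equiv 0$). This reading of the integrand
is pinned down by a hard requirement: for an ideal mixture
($S_{cc} = x_Ax_B$) the integrand must vanish identically, and the package
asserts exactly that. The $x_A = 1$ endpoint is a $0/0$ limit and is
linearly extrapolated from the two nearest interior points; $S_0$ fit
errors are propagated in quadrature through the integral. The total
chemical potential is assembled as
$\mu_A = \mu^0_A + T\ln(x_A/x^0_A) + \mu^{\rm ex}_A$ (`total_mu()`), with
the pure-state reference $\mu^0$ obtained by bisecting the grand-canonical
chemical potential until the sampled density matches the NPT density
(`match_mu0()`). `s0_mu_pipeline()` chains all of this.

# What the generated data emulate — and what they do not

All test inputs are generated in code: factory designs, random overlap-free
gases, bonded dimers, synthetic Ornstein–Zernike tables with known
parameters, and full Monte Carlo trajectories of the model itself. They
exercise every contract of the package — exact limits (ideal gas, hard
spheres, zero bonding), conservation laws, detailed-balance identities,
closed-form mass-action solutions, and statistical agreement between the
simulation and the theory that the package itself implements. What they do
not establish is the fidelity of the *model* to any laboratory system: a
real DNA-origami or colloidal mixture has polydispersity, flexible linkers,
many-body and torsional effects that the Kern-Frenkel coarse-graining
discards. Passing tests certify the thermodynamics of the model, not the
chemistry it abstracts.

# Problem sizes and numerical choices in the shipped tests

The test suite runs simulations at deliberately reduced scale, chosen so
each statistical assertion still has a comfortable margin: hard-sphere NPT
at $N = 128$ (equation-of-state agreement within 2%), Gibbs cross-validation
at $96$ particles per box against the TPT1 binodal of a wider-patch
($\cos\theta_{\max} = 0.90$) tetravalent fluid at $T = 0.13$ — a deliberate
choice of a fluid whose bonds open often enough to equilibrate in tens of
thousands of sweeps — and the S0 pipeline at $N = 160$ with a $0.1$
composition step. Wider patches raise the critical temperature and soften
the bond-breaking barriers without touching any of the code paths being
validated. Theory-side computations run at full precision everywhere
(they cost seconds).

Two acceptance-style simulation checks are asserted at their nominal
temperatures ($T = 0.138$ for the ideal design and $T = 0.098$ for the
tuned N2c8 mixture) where the default-geometry model is supercritical in
both TPT1 and direct simulation (the two agree internally to a few percent
in bonding energy); no vapor–liquid separation exists there, and those two
assertions fail by design rather than being weakened. The subcritical
validations above cover the same machinery where the model does coexist.

# Known limitations

* TPT1 neglects bond-loop correlations; its critical temperatures are
  upper bounds on the simulated ones, so theory–simulation binodal
  comparisons are made a safe distance below $T_c$.
* The azeotrope search assumes a single collapsing coexistence lobe in the
  search window; exotic designs with multiple interior azeotropes would
  need the window narrowed per lobe.
* The engine has no cell lists and is not meant for $N \gg 10^3$; it is a
  validation instrument, not a production sampler.
* Ideal-azeotropic designs have no isolated azeotropic composition, so
  `find_azeotrope()` (correctly) reports failure for them; use
  `binodal_point()` at any composition instead.
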