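---
title: "Modelling competitive biomolecular adsorption on nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling competitive biomolecular adsorption on nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

When a surface or nanoparticle (NP) is exposed to a biological fluid such as
milk, the biomolecules in the fluid compete for the surface and form an
adsorbed layer — the biomolecular corona — whose composition is set jointly
by binding thermodynamics (who sticks hardest), kinetics (who arrives
fastest), and geometry (who blocks how much area). `nanocorona` implements a
three-stage coarse-grained pipeline for predicting that composition:

1. **Rigid-body energy model** (`build_heatmap()` and friends): a molecule is
   a rigid set of one-per-residue beads; its interaction with a spherical NP
   is a pairwise sum of tabulated short-range potentials of mean force
   (PMFs), a screened-Coulomb electrostatic term, and an optional Hamaker
   core term. Sweeping the molecule–surface distance and Boltzmann-averaging
   yields an adsorption energy per orientation — a heatmap over the two
   rigid-body angles.
2. **Rate parameterization** (`build_species_table()`): each orientation
   becomes a potential adsorbate species with a projected footprint area, an
   effective radius, an adsorption rate constant from kinetic collision
   theory, and a desorption rate constant from detailed balance.
3. **Kinetic Monte Carlo** (`run_corona()`): event-driven competitive
   adsorption of hard spherical footprints on the NP sphere, optionally with
   a displacement channel in which strong binders can evict weaker ones, and
   with quasi-equilibrium rate scaling to make fast small adsorbates (e.g.
   lactose) affordable.

This vignette records the model assumptions, the tunable parameters, the
numerical choices, and the design decisions taken where more than one
reasonable reading existed. Everything quantitative shown here is computed
by the package at build-or-test time; nothing is transcribed from elsewhere
except the clearly-labelled bundled reference tables.

## The rigid-body energy model

### Inputs and conventions

Units are fixed throughout: lengths in nm, energies in units of the thermal
energy $k_\mathrm{B}T$ (at the NP's configured temperature, default 300 K),
charges in elementary charges, concentrations in mol/L, times in seconds.
Conversions to SI happen only inside the kinetic-theory rate formulas.

A **PMF table** (`pmf_table()`, `load_pmf()`) gives the free energy of one
bead type versus its surface separation distance (SSD, bead centre to
surface). Interpolation is linear and exact at the nodes. Outside the table
the contract is: below the first node the first segment's slope is continued
and capped at +50 $k_\mathrm{B}T$ (a hard repulsive wall — extrapolating an
attractive slope inward would invent unphysical binding), and above the last
node the energy is exactly zero. Tables with fewer than 10 samples or a tail
more than 0.5 $k_\mathrm{B}T$ from zero load with a warning rather than an
error, because deliberately tiny toy tables are legitimate test inputs.

A **molecule** (`cg_molecule()`, `read_structure()`) is one bead per residue
placed at the side-chain heavy-atom centroid (the C$_\alpha$ for glycine),
typed by the 3-letter residue code, with integer charges at neutral pH
(Arg/Lys +1, Asp/Glu −1, His 0). Lactose is a pair of neutral glucose beads
0.52 nm apart (`lactose_model()`); the separation is configurable because
the equilibrium glycosidic distance is a modelling choice, not a measured
input of the pipeline. Rigidity is a hard assumption: every orientation
operation preserves the pairwise bead distance matrix to 10⁻⁹ nm (enforced
by property tests). For flexible proteins — the caseins prominently —
rigidity biases binding energies; globular proteins are less affected.

### Orientations

The reference state (`canonicalize_orientation()`) aligns the inertia axis
with the smallest moment to $z$ and the second smallest to $y$, then applies
180° flips so the dipole components along $z$ and $y$ are non-negative.
Single beads and point-like degenerate tensors fall back to the identity
with a warning. An orientation $(\phi, \theta)$ is then generated by
rotating $-\phi$ about $z$ followed by $180° - \theta$ about $y$, so
$(0°, 180°)$ is the identity. The default grid is 5° in both angles with
$\phi \in [0°, 355°]$ and $\theta \in [0°, 175°]$ — 72 × 36 cells whose
angles are multiples of 5°. In orientation averages and concentration
weights, a cell at an exact pole receives the sine of its cell midpoint
rather than zero, so coarse grids do not silently drop polar orientations.

### The distance sweep and Boltzmann averaging

For one orientation the molecule hovers above the NP's north pole and the
sweep variable $d$ is the SSD that the lowest bead would have on the axis;
each bead's own SSD follows the sphere convention
$\mathrm{ssd}_b = |\mathbf{r}_b - \mathbf{r}_\mathrm{NP}| - R_\mathrm{NP}$,
which converges to the planar slab geometry of the PMFs for
$R_\mathrm{NP} \gtrsim 50$ nm. The default sweep runs from the innermost
tabulated PMF point to 1.5 nm in 0.005 nm steps, because metal-surface PMFs
have decayed essentially to zero by 1–1.5 nm.

The per-orientation adsorption energy is the thermally weighted mean energy

$$E_\mathrm{ads} = \frac{\int U(d)\, e^{-U(d)}\, \mathrm{d}d}
                        {\int e^{-U(d)}\, \mathrm{d}d},$$

by trapezoidal quadrature with the integrand shifted by $\min U$ before
exponentiation (wells of hundreds of $k_\mathrm{B}T$ would otherwise
overflow). An alternative reading — the $-\ln Z$ free energy of the swept
coordinate — was considered and rejected in favour of the weighted mean
energy; for the deep wells that dominate corona formation the two agree to
within the well depth's thermal width, and the mean-energy form is the one
the upstream tooling convention describes. `r_min` is the location of the
global minimum of $U(d)$. The test suite pins this operator to closed forms
(constant curves, a two-piece square well, the deep-well dominance limit)
and to independent adaptive quadrature on smooth curves at 10⁻³
$k_\mathrm{B}T$.

### Term closures

The electrostatic closure is the linearized Poisson–Boltzmann interaction
of a point bead charge with a uniformly charged sphere held at the zeta
potential:

$$U^{el}(r) = q\,\zeta\,\frac{R_\mathrm{NP}}{r}\,
              e^{-(r - R_\mathrm{NP})/\lambda_D},$$

with the Debye length defaulting to 0.78 nm (150 mM 1:1 salt near room
temperature, the ionic strength of milk). The "screened Coulomb" term is
named but not printed in the methodology this package follows, so this
standard closure is a documented design decision rather than an extraction.

The long-range core van der Waals term uses the two-sphere Hamaker
expression with the bead as a small sphere of its library radius. A point
bead has no volume to integrate, so "sphere–point" is necessarily realized
as sphere–small-sphere. The gap is clamped at 0.05 nm to avoid the contact
divergence — the short-range regime belongs to the PMF, which already
contains the vdW repulsion and solvation structure. The Hamaker constant is
configurable and **off by default** (0 J): no aluminium–water constant is
bundled, and small beads (the glucose bead) skip the term entirely via the
`small` flag in `bead_library()`.

## Rate parameterization

The footprint of an orientation (`footprint_area()`) projects each bead,
as a disc of its bead radius, radially onto the NP surface and takes the
convex hull (polygonized discs, 90 boundary points each, `grDevices::chull`
in the tangent plane). For footprints subtending more than ~10° of arc a
spherical-cap correction replaces the planar area so 2 nm particles degrade
gracefully; at the 80 nm scale of the bundled system the planar hull is
exact to well under a percent. The effective radius (`effective_radius()`)
inverts the cap projection of a sphere resting on the NP and reduces to
$\sqrt{A/\pi}$ in the planar limit; round-tripping a single bead recovers
its radius within 5% for $R_\mathrm{NP} \ge 40$ nm (a property test).

Adsorption rates use kinetic collision theory for two spheres in solution,

$$k_a = \frac{A_i}{4\pi R_\mathrm{NP}^2}\,
        \bigl[4\pi D N_A (R_\mathrm{NP} + R_i)\bigr] \times 1000,$$

in L mol⁻¹ s⁻¹, with the pair diffusion coefficient
$D = \frac{k_\mathrm{B}T}{6\pi\eta}(R_\mathrm{NP}^{-1} + R_i^{-1})$ and
$\eta = 8.9\times10^{-4}$ Pa s. The $6\pi\eta$ form is the standard
Stokes–Einstein pair expression; a printed version of this formula omits
the $\pi$ typographically, and the dimensional check (and the derived value
$D \approx 1.27\times10^{-10}$ m² s⁻¹ for an 80 nm particle and a 2 nm
adsorbate) confirms the $6\pi\eta$ reading. The number of binding sites
$N_\mathrm{sites} = 4\pi R_\mathrm{NP}^2 / A_i$ is kept as a real number —
rates, not lattice sites, drive the simulation.

Desorption follows detailed balance with a reference concentration of
1 mol/L: $k_d = k_a c_0 e^{E_\mathrm{ads}}$, so
$k_a / k_d = e^{-E_\mathrm{ads}}$ L/mol. The defining equation is lost to a
typesetting artefact in the source methodology, so the $c_0 = 1$ M
convention — the standard one, and the only one that gives $k_d$ units of
s⁻¹ — is adopted and documented here.

A molecule's bulk concentration is distributed over its orientations in
proportion to $\sin\theta$ (solid-angle abundance), normalized so the total
is reproduced exactly (`orientation_concentrations()`).

## The kinetic Monte Carlo simulator

`run_corona()` advances an event-driven (Gillespie direct method)
simulation: the total rate is the sum of per-species arrival rates
$k_a C N_\mathrm{sites}$ and the desorption rates of everything adsorbed;
waiting times are exponential; arrivals land uniformly at random on the
sphere. Adsorbates are hard spherical caps: two overlap when the
great-circle separation of their anchors is less than the sum of their
footprint cap half-angles, with the half-angle derived from the footprint
area via $\cos\alpha = 1 - A_i / (2\pi R_\mathrm{NP}^2)$. This is exactly
the arc-projected effective-radius rule for cap-shaped footprints, and it
extends cleanly to the single-site scenario ($A_i = 4\pi R_\mathrm{NP}^2
\Rightarrow \alpha = \pi$: any two adsorbates overlap) with no special
casing. All comparisons are done on cosines, so the hot loop contains no
inverse trigonometry.

In **hard-sphere mode** an arrival overlapping anything is rejected (time
still advances). In **displacement mode** the arrival is accepted with the
logistic probability

$$p(\Delta E) = \frac{e^{-\Delta E}}{1 + e^{-\Delta E}}, \qquad
  \Delta E = E_\mathrm{ads} - \sum_{j \in \mathrm{overlaps}} E_j,$$

and on acceptance all overlapped adsorbates are evicted. With no overlaps
the sum is empty and $\Delta E = E_\mathrm{ads}$ — the arrival displaces
implicit water, whose affinity defines the zero of the energy scale; water
is never an explicit adsorbate. Because acceptance onto bare surface then
multiplies the effective adsorption rate by $p(E_\mathrm{ads})$, the
desorption rate is multiplied by the same factor
(`displacement_desorption_correction()`), preserving every equilibrium
constant; the correction only matters for binders weaker than about
−3 $k_\mathrm{B}T$. The displacement channel is deliberately asymmetric —
one molecule may evict many, never the converse — which breaks detailed
balance; the justification adopted is that the reverse event (multiple
simultaneous arrivals on one target) is essentially never sampled anyway.

### Quasi-equilibrium acceleration

A small, weakly binding, highly concentrated species (lactose) can consume
nearly all events while contributing nothing but an equilibrated monolayer.
The accelerator (`accel = TRUE`) watches a sliding window (default 10⁴
events): any species whose adsorb and desorb counts both exceed `n_eq`
(default 100) and whose net flux is below 10% of its event total is deemed
quasi-equilibrated, and its $k_a$ and $k_d$ are scaled by a common factor
$\alpha < 1$ — the equilibrium constant, and therefore its steady-state
coverage, is untouched — chosen so the scaled species contributes at most
10× the fastest non-equilibrated rate. The scaling reverts whenever a
non-equilibrated event class fires, and the window restarts. The window,
`n_eq`, flux tolerance and headroom are all configurable; the defaults are
conventional order-of-magnitude choices, since the cited acceleration
methodology does not fix them. An acceptance test verifies that steady-state
compositions with the accelerator on and off agree within three combined
standard errors on a lactose-like benchmark while the slow species' event
counts improve.

### Summaries, reproducibility, bookkeeping

Summaries average the adsorbed count of each parent molecule over the
post-burn-in window (default: the second half of the horizon; the averaging
window is a choice, so it is configurable) and report number densities per
nm² and mass abundances
$M_{\mathrm{ab},i} = 100\, N_i \mathrm{MW}_i / \sum_j N_j \mathrm{MW}_j$.
Standard errors come from 10 block averages. Every stochastic draw flows
from one `set.seed(seed)` call, so a seed plus inputs reproduces the event
stream bit-for-bit; summary and event-log writers emit full-precision text,
and the run manifest records the parameters, seed and a content hash.
Bulk concentrations are held constant (no depletion). The event loop is
compiled (Rcpp); overlap candidates come from a uniform 3D cell grid over
the unit sphere whose cell edge is at least the largest overlap chord
between any species pair, so a 27-cell neighbourhood scan is exact — an
engineering acceleration only, with no effect on which events occur. The
integrity audit (`audit_overlaps = TRUE`) deliberately bypasses the grid
and re-checks all pairs, so it doubles as the grid's correctness oracle.
Coronas of ~10⁵ adsorbates run at roughly 10⁵ events per second.

## The bundled milk system and the synthetic generator

`milk_fixture()` packages a simplified milk model — the six most abundant
cow-milk proteins plus lactose — against aluminium surfaces (an 80 nm
particle at −5 mV). Three kinds of content are bundled, with provenance
tags:

- **Reference tables** (`milk_characteristics()`, `milk_binding_minima()`,
  `milk_corona_reference()`): molecular weights, charges, concentrations,
  radii of gyration; per-protein binding minima with preferred orientations
  on Al(100)/(110)/(111); and reference corona compositions. These are
  transcribed reference values guarded digit-for-digit by checksum tests.
  The Al(111) reference column contains an internal inconsistency (its
  AS2C number density implies a mass abundance ~8× the printed one;
  back-calculation suggests the density should read ~0.30×10⁻³ nm⁻²), so
  that column is flagged and excluded from numeric cross-checks.
- **Single-orientation protein species**: the full orientation heatmaps
  behind the reference minima are not reconstructible from printed data, so
  each protein enters the bundled species table once, at its minimum, with
  footprint $\pi R_g^2$ — a clearly-labelled synthetic assumption suitable
  for qualitative ranking work, not for reproducing absolute densities.
- **Synthetic PMFs** (`synthetic_pmf()`): a smooth quadratic wall plus
  Gaussian well with the global minimum exactly at the requested depth and
  position (default 0.23 nm, within the 0.21–0.25 nm range typical of
  metal-surface minima), zero beyond 1.5 nm. The glucose default depth of
  −6 $k_\mathrm{B}T$ is a plausible weak-binder scale chosen once for the
  fixture; the real glucose profile is machine-learning-derived upstream
  and not bundled. Shape, not provenance, is what the synthetic curves
  emulate: they exercise every numerical path (wall extrapolation,
  interpolation, averaging) without claiming chemical accuracy.

What passing tests on these fixtures show — and what they do not: the
simulator is validated against exact two-state closed forms, equilibrium
ratios, hard-sphere integrity audits and its own brute-force re-evaluation;
the energy model against closed-form integrals and independent quadrature.
None of that certifies the *chemistry* of a real protein–aluminium system,
which enters entirely through the PMF tables and structures the user
supplies.

## Problem sizes and numerical choices, collected

- Distance sweep 0.005 nm; orientation grid 5° (72 × 36); trapezoidal
  quadrature; min-shifted exponentials everywhere an $e^{-E}$ appears.
- Footprint discs polygonized at 90 points (single-disc area exact to
  0.3%); planar hulls with a cap correction beyond 10° of arc.
- Wall cap +50 $k_\mathrm{B}T$; Hamaker gap clamp 0.05 nm; detailed-balance
  exponent capped at +700 with a warning.
- Simulation benchmarks in the test suite use 10⁴–3×10⁵ events on 4–20 nm
  particles, sized to give 3σ discrimination for the properties under test;
  the acceptance checks use 10⁵ post-burn-in events for the two-state
  comparison.
- Ties and degeneracies: first altLoc wins in PDB input; degenerate inertia
  tensors fall back to identity with a warning; zero dipole components
  leave the canonical frame unflipped; `r_min` reports the first grid
  argmin on exactly flat curves.

## Known limitations

Rigid molecules; single-bead-per-residue resolution; point-charge
electrostatics against a uniform zeta-potential sphere (no charge
regulation, no pH dependence); no bulk depletion; no adsorbate
conformational change or surface diffusion; the displacement channel's
deliberate detailed-balance violation; and reference-table protein species
that carry a synthetic footprint assumption. Extending to a new material or
molecule needs only PMF tables for its bead types and a structure — the
pipeline itself is material-agnostic.
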