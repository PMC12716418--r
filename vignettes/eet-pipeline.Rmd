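---
title: "Modeling excitation energy transfer in chlorophyll a/c antenna supercomplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling excitation energy transfer in chlorophyll a/c antenna supercomplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eetscape)
```

eetscape turns an atomic model of a pigment–protein supercomplex — here, a
photosystem I (PSI) core wrapped in layers of fucoxanthin–chlorophyll a/c
antenna proteins, as in coccolithophores and other red-lineage algae — into
a quantitative picture of how absorbed excitation energy migrates to the
photochemical trap, and fits the time-resolved spectra that measure the
same process. This vignette is the package's own account of the models, the
tunable parameters, the numerical choices, and the limits of what the
synthetic tests demonstrate.

## The transfer model

**Pigments as two-level sites.** Each chlorophyll contributes one Qy
excitation. The transition dipole is placed at the central Mg with its
direction along the NB→ND nitrogen axis — the standard geometric proxy for
the chlorin Qy transition moment — and a per-species magnitude (defaults:
4.0 D for Chl a, 3.4 D for Chl c; literature-scale values, freely
configurable since no absolute rate claim rests on them). Site energies
default to 663.5 nm (Chl a) and 633.5 nm (Chl c), converted internally as
E = 10^7/λ to 15071.6 and 15785.3 cm⁻¹; per-pigment overrides are keyed by
pigment id. Carotenoids are parsed and counted but excluded from the
transfer network: the kinetic model here is chlorophyll-only. The
chlorophyll c2–MGDG adduct is treated as one Chl c chromophore with an
ignored lipid tail.

**Pairwise Förster rates.** For two pigments the electronic coupling in
the ideal point-dipole approximation is

    V = s · 5034 · κ · μ₁μ₂ / R³   [cm⁻¹; μ in D, R in Å]

with κ = û₁·û₂ − 3(û₁·R̂)(û₂·R̂) and `s` a multiplicative screening factor
(default 1, vacuum; a 1/n² preset is one parameter away). An
extended-dipole scheme (±q charges separated by 8.7 Å along the Qy axis)
is available for close pairs; the scheme in force is recorded in all
output metadata. The golden-rule rate is

    k = 1.18 · V² · J   [ps⁻¹; V in cm⁻¹, J in cm]

where 1.18 is 2π/ħ expressed in these units (numerically 4π²c with c in
cm/ps — the test suite re-derives both constants from independent CGS/SI
unit analyses). J is the overlap of the area-normalized donor *emission*
and acceptor *absorption* lineshapes: Gaussians of 250 cm⁻¹ FWHM, the
emission red-shifted by a 100 cm⁻¹ Stokes shift. Both width and shift are
explicit parameters; they are not printed in typical experimental reports,
and all headline checks in this package are ratio- or recovery-based so
that these choices are exposed rather than hidden.

**Generalized Förster between subunits.** Within each subunit the
chlorophylls are strongly coupled, so inter-subunit transfer is computed
between *exciton clusters*: the intra-subunit Hamiltonian (site energies
on the diagonal, dipole couplings off-diagonal) is diagonalized, donor
states are Boltzmann-weighted at 295 K (instantaneous intra-cluster
equilibration, the standard generalized-Förster assumption), and

    k(D→A) = Σ_α P_α Σ_β 1.18 |V_αβ|² J_αβ,   V_αβ = Σ_ij c^D_αi c^A_βj V_ij

with J_αβ the Gaussian overlap of donor-state emission (ε_α − Stokes) and
acceptor-state absorption (ε_β), both reusing the site lineshape width (no
exchange narrowing — a simplification, kept configurable through the
width parameter). The entire PSI-core chlorophyll set is pooled into one
acceptor cluster by default, because antenna→core arrows, not per-core-
subunit arrows, are the quantity of interest; `core_as_one = FALSE` splits
it.

## Kinetics, trapping, and routes

The directed cluster rate table feeds a master equation dp/dt = K p with
an explicit absorbing trap fed from the core cluster at 1 ps⁻¹ by default
(photochemistry is much faster than antenna transfer; the rate is a
parameter). Columns of K sum to zero exactly, so total probability
(transient + absorbed) is conserved identically. `solve_kinetics()`
eigen-decomposes K (falling back to numerical propagation with a warning
if the eigenbasis is ill-conditioned), `mfpt_to_trap()` solves the linear
system tᵀA = −1 over transient states. Because the trap is explicit,
mean first-passage times include the final trapping step.

Two different summaries of "how long does energy take from subunit X to
the core" are computed side by side, because the field's figures label
per-arrow time constants while kinetic theory favors first-passage times:

* the **route constant** — the minimum, over directed paths using only
  steps with τ ≤ 25 ps (the map-rendering admissibility rule), of the sum
  of stepwise time constants; ties are broken lexicographically on subunit
  names so results are deterministic;
* the **MFPT**, which accounts for re-crossings and parallel flux.

For irreversible chains the two coincide (tested); in reversible networks
the MFPT is generally larger. `layer_average_route_time()` reports both
means over all subunits of the requested layers and lists any source
without an admissible route rather than silently dropping it.

Rate maps follow the conventional display classes: time-constant intervals
(0,1], (1,10], (10,20] ps, with slower pairs omitted from the *map* (never
from the network), and routing restricted to steps of at most 25 ps.
Interval boundaries are half-open (a, b] — τ = 20 ps is still drawn, τ =
20.01 ps is not.

## Global DAS fitting

Time-resolved cubes (delay × wavelength) are fitted as a parallel sum of
exponentials sharing lifetimes across wavelengths,
signal(t, λ) = Σ_k DAS_k(λ) · c_k(t), with c_k the analytic
exponential ⊗ Gaussian-IRF kernel (erfcx-stabilized, so a 5 ns component
evaluated 1 ps before time zero underflows to zero instead of overflowing).
The fit is separable: lifetimes (in log-space, since they span 0.16 ps to
5 ns) are optimized by Levenberg–Marquardt while the per-wavelength
amplitudes are solved linearly at each iterate. The IRF width is fixed to
the instrument value stored with the cube (70 fs for the default
simulation) and can optionally be freed, as can time zero. Lifetimes
closer than a factor 1.2 trigger a degeneracy warning. This is DAS
analysis by construction — sequential/target models are out of scope.

## What the synthetic generators emulate

* `make_dimer()` builds the three textbook two-pigment geometries with
  closed-form κ (1, −2, 0) attached as metadata — the unit tests' anchor.
* `make_layered_antenna()` emulates the fiber-like, layered architecture:
  radial fibers of antenna subunits, one per layer, facing each other
  across a 22 Å inter-layer gap; fibers separated by arc gaps that grow
  with radius; and a three-dimensional core pigment block only 16 Å from
  the innermost layer. The contact-distance ordering (core gap <
  inter-layer gap < inter-fiber gap) is the load-bearing design choice:
  it reproduces the qualitative transfer structure of the real
  supercomplex — innermost-layer→core is the fastest step (single
  picoseconds), consecutive-layer steps are a few ps, cross-fiber steps
  are slow or inadmissible — so optimal routes run along fibers and
  outer-layer route constants land in the tens of picoseconds. An early
  planar-disc core inverted that ordering (antenna→core became the
  bottleneck), which contradicts the architecture being emulated; the 3D
  block corrected it.
* `make_inventory_fixture()` reproduces the pigment census of the
  35-subunit antenna (291 Chl a, 121 Chl c of which 9 are the c2–MGDG
  adduct, 224 carotenoids with hexanoyloxyfucoxanthin confined to
  Lhcq-type subunits, 4–7 Chl c in every Lhcq/Lhcf subunit, 95 Chl a +
  23 carotenoids in the 12-subunit core, one linker chlorophyll; 755
  pigments among 790 het groups). Its coordinates are placeholder lattice
  positions: it guarantees census statistics and layer topology, not
  geometry, and it self-audits every total at construction.
* `make_ta_cube()` builds four-component cubes whose defaults mirror the
  measured antenna cascade — 0.16 ps, 2.8 ps, 62 ps and 5 ns components
  with the corresponding sign structures — on a 120-delay (−1 to 3000 ps,
  log-spaced after 1 ps) × 64-wavelength (660–710 nm) grid, 70 fs IRF,
  and additive noise scaled to the signal maximum.

What passing tests therefore show: the mathematics (couplings, overlaps,
exciton algebra, kinetics, separable fitting) is correct against
independent oracles, and the pipeline reproduces the *designed* transfer
structure of the emulation. What they do not show: agreement with a real
deposited structure, which uses quantum-chemically derived couplings,
heterogeneous site energies and non-Gaussian lineshapes. Rates from the
dipole proxies should be read at order-of-magnitude precision.

## Numerical choices

* Spectral overlaps go through a 6001-node trapezoid rule on a grid
  spanning ±6σ of both lineshapes (for Gaussians this is accurate to well
  below 1e-10 relative; a user-supplied grid that fails to cover both
  shapes is an error, never a silent truncation). Inside the exciton-state
  double sums the closed Gaussian-product form is used for speed; the two
  agree to quadrature precision and tests enforce it.
* Couplings below a 2 Å center-center contact floor are refused — the
  dipole approximation is meaningless there. Pair enumeration stops at
  40 Å Mg–Mg (configurable); beyond it, point-dipole rates are far slower
  than any reporting cutoff in use.
* Cluster Hamiltonians are symmetrized before `eigen(symmetric = TRUE)`;
  Boltzmann weights shift energies by their minimum before
  exponentiation.
* Degenerate-input policy: zero antenna subunits make inventory averages
  `NA` (not zero); an all-zero rate matrix propagates constant
  occupancies; unreachable traps give infinite MFPT; a source with no
  admissible route is reported explicitly.

## Problem sizes used by the test-suite and acceptance runs

Oracle-equivalence tests run on ≤ 50-pigment lattices (brute-force double
loops), 2×2-cluster toy systems, 4–6-state kinetic models (against
numerical integration and a 10⁵-walker Gillespie simulation), and the
full 6-layer × 5-fiber default lattice (340 pigments, 31 clusters) for the
end-to-end route analysis. DAS recovery statistics use 20 independent
noise seeds per setting. These sizes were chosen as the smallest at which
each property is non-trivial.

## Known limitations

Dipole-proxy couplings (no transition densities or TrEsp charges); fixed
species-level site energies (the real system's conformational spread of
energies is representable only through per-pigment overrides); Gaussian
lineshapes without vibronic structure, so Chl c→a overlap — which in
reality rides on vibronic sidebands — is underestimated at the default
width; chlorophyll-only networks (no carotenoid donors); incoherent rate
kinetics only (no Redfield-type coherent corrections); DAS rather than
target analysis; no chirp or coherent-artifact handling in the fitting.
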