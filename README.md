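# eetscape

Structure-based analysis of **excitation energy transfer (EET)** in
pigment–protein supercomplexes — built for the giant photosystem I (PSI)
antenna systems of red-lineage algae such as coccolithophores, where a
monomeric PSI core is wrapped in dozens of fucoxanthin–chlorophyll a/c
proteins arranged in concentric, fiber-like layers. It is aimed at
photosynthesis researchers who have an atomic model (mmCIF/PDB) and/or
time-resolved spectra and want the standard chain of calculations between
them, with every step testable and every parameter explicit.

The package covers:

* **Pigment extraction and census** — parse coordinates, classify
  chlorophyll a / chlorophyll c / carotenoid cofactors from het-codes,
  annotate subunits with LHC family and concentric layer, and tabulate
  per-subunit inventories.
* **Förster rates between chlorophyll pairs** — point-dipole (or
  extended-dipole) couplings `V = s·5034·κ·μ₁μ₂/R³` (cm⁻¹) and
  golden-rule rates `k = 1.18·V²·J` (ps⁻¹), with `J` the overlap of
  area-normalized Gaussian donor-emission and acceptor-absorption
  lineshapes (site energies default to 663.5 / 633.5 nm for Chl a / c).
* **Generalized Förster rates between subunits** — per-subunit exciton
  Hamiltonians, Boltzmann-weighted donor states, and
  `k = Σ_α P_α Σ_β 1.18 |V_αβ|² J_αβ` between pigment clusters, with the
  whole PSI core as one acceptor cluster.
* **Kinetics and pathways** — a trapping master equation (eigen-lifetimes,
  occupancies, mean first-passage times) and antenna→core route analysis
  (minimal path-sum routes using only steps ≤ 25 ps, layer-averaged route
  constants, with MFPTs always co-reported).
* **Global DAS fitting** — separable (variable-projection) fitting of
  delay × wavelength cubes with shared lifetimes, analytic
  exponential⊗Gaussian-IRF kernels, and decay-associated spectra.
* **Synthetic generators** — seeded dimers, layered fiber lattices, a
  census-matched 48-subunit inventory fixture, and four-component
  transient-absorption cubes with known truth, used throughout the tests.

Everything is tibble-in / tibble-out with `tidy()`, `glance()`,
`augment()` and `autoplot()` methods on the result objects.

## Worked example

```r
library(eetscape)

# pigment census of the packaged antenna fixture
inventory(make_inventory_fixture())
#> <eet_inventory> 755 pigments (790 het groups)
#> # A tibble: 1 × 4
#>   n_antenna_subunits mean_chl_a mean_chl_c mean_carotenoid
#>                <int>      <dbl>      <dbl>           <dbl>
#> 1                 35       8.31       3.46             6.4

# a six-layer, five-fiber synthetic antenna around a 40-chlorophyll core
m   <- make_layered_antenna(seed = 17)
m
#> <eet_structure> 31 subunits (30 antenna), 340 pigments, 340 EET nodes
tab <- cluster_network(m)              # generalized Förster rate table
layer_average_route_time(tab, layers = c(5, 6))
#> <eet_route_summary> 10 sources; mean route 18.26 ps; mean MFPT 71.12 ps

# global DAS fit of a simulated four-component TA cube (70 fs IRF, 1% noise)
fit <- fit_global(make_ta_cube(seed = 1), 4, init = c(0.2, 3, 60, 5000))
tidy(fit)
#> # A tibble: 4 × 5
#>   component lifetime_ps peak_nm peak_amplitude label
#>       <int>       <dbl>   <dbl>          <dbl> <chr>
#> 1         1       0.159    681.          1.03  decay
#> 2         2       2.82     688.          0.953 decay
#> 3         3      61.9      684.          1.21  decay
#> 4         4    5019.       676.         -0.406 long-lived/uncoupled
```

Reading the numbers: the census means are the per-antenna-subunit pigment
averages (121 Chl c and 224 carotenoids over 35 subunits give exactly 3.46
and 6.4). In the lattice, routes from the two outermost layers reach the
core along their own fibers with a mean summed time constant of ~18 ps
(the co-reported mean first-passage time, ~71 ps, additionally counts
re-crossings and trapping); innermost-layer subunits transfer directly to
the core in a few ps. The DAS fit recovers the four generating lifetimes
(0.16 ps, 2.8 ps, 62 ps, 5 ns) from the noisy cube, flagging the
nanosecond component with its blue-shifted negative spectrum as
long-lived/uncoupled chlorophyll.

See `vignette("eet-pipeline")` for the model definitions, parameter
defaults, and the limits of what the synthetic emulation demonstrates.

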