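# reflmem

Specular neutron reflectometry (NR) modelling and co-refinement for
silicon-supported lipid bilayers carrying membrane-embedded and
surface-adsorbed proteins — the experimental geometry used to study how
anti-apoptotic Bcl-2, sitting inside a mitochondrial-outer-membrane
mimic, sequesters pro-apoptotic Bax in oligomer layers on the bilayer
surface instead of letting it porate the membrane.

The package is for NR practitioners and membrane biophysicists who want
a scriptable, testable alternative to GUI fitting programs for this
class of system, plus a synthetic-data generator for method validation.

## What it computes

**Scattering length densities.** Each component (lipid fragments,
proteins per mean residue, substrate materials) has
$\rho = \sum_i b_i / V$, with labile hydrogens exchanging against the
solvent ($b_H(1-xf) + b_D xf$ per site at D2O fraction $x$, exchange
fraction $f$) and biosynthetic deuteration on non-labile sites. The
H2O/D2O mixture matching silicon's SLD comes out at 38% D2O (Si-matched
water).

**Reflectivity.** Exact slab-model $R(Q)$ by the Abeles optical-matrix
method (compiled), Névot–Croce roughness, automatic error-function
micro-slicing when roughness rivals layer thickness, and Gaussian
$dQ/Q$ resolution smearing by Gauss–Hermite quadrature. An independent
pure-R Parratt recursion cross-checks the kernel to 1e-8.

**Structure.** One `membrane_structure` (Si / oxide / water gap /
bilayer with embedded Bcl-2 / up to two Bax surface layers / solvent)
maps deterministically to per-contrast slab stacks — geometry shared,
SLDs contrast-dependent — and to component volume-fraction profiles
$\phi(z)$ that sum to one with solvent.

**Co-refinement.** `fit()` minimizes the pooled
$\chi^2 = \sum ((R_\mathrm{model} - R)/\sigma_R)^2$ over all contrasts
at once (differential evolution + derivative-free polish,
deterministic by seed), `confidence_intervals()` gives
residual-bootstrap 95% intervals, and `structure_report()` prints the
conventional table: Bcl-2 coverage, proximal/distal Bax layer
thicknesses and coverages, total surface-layer thickness.

**Kinetics.** One- and two-component exponential association
$y(t) = y_0 + \sum A_i(1-e^{-t/\tau_i})$ for ATR-FTIR amide-I traces
and for surface-protein volume series extracted from time-resolved NR
fits, with AICc-gated component selection.

## Worked example

```r
library(reflmem)

s <- mom_fixture(3)         # high-Bcl-2 POPC reference system
structure_report(s)
#>   Bcl-2 volume coverage in bilayer/%            39.9
#>   Bax proximal distribution thickness/A         55.0
#>   Bax proximal distribution coverage/%          26.2
#>   Bax distal distribution thickness/A           52.7
#>   Bax distal distribution coverage/%            4.5
#>   total membrane-bound Bax layer thickness/A    107.7

# simulate the four solvent contrasts and recover the structure
ds <- simulate_contrast_set(s, seed = 11)
free <- list(bcl2_fraction = c(0.05, 0.6),
             surface1_thickness = c(20, 120), surface1_coverage = c(0.02, 0.6),
             surface2_thickness = c(20, 120), surface2_coverage = c(0.001, 0.3))
p <- fit_problem(s, ds, free, free_backgrounds = FALSE)
fit(p, seed = 42, control = list(maxiter = 60, de_tol = 1e-5))
#> <nr_fit> chi2/N = 1.139 (raw 683.5 over 600 points)
#>   bcl2_fraction          0.39797
#>   surface1_thickness     54.979
#>   surface1_coverage      0.26131
#>   surface2_thickness     52.681
#>   surface2_coverage      0.045354
```

The recovered parameters sit on the generating truth (39.9% embedded
Bcl-2; 55 Å proximal Bax layer at 26.2%; 52.7 Å distal layer at 4.5%)
and χ²/N ≈ 1 says the fit explains the data at the simulated noise
level. A 50 Å Bax layer over a 25 Å monomer reads as a two-unit stack:

```r
oligomer_units(50, 25)
#> [1] 2        (bracket: 2 2)
```

Two-stage binding kinetics at ATR-FTIR sampling:

```r
tr <- simulate_kinetics(c(1, 1.5), c(9, 148), t_end = 720, dt = 4/3,
                        noise_rel = 0.02, seed = 11)
fit_association(tr, 2)
#> <kinetic_fit> 2 component(s)
#>   A1 = 1.007 +/- 0.044, tau1 = 9.193 +/- 0.71 min
#>   A2 = 1.512 +/- 0.016, tau2 = 146.9 +/- 2.7 min
```

A thin CLI over the same functions is in `inst/cli/reflmem.R`
(`simulate`, `fit`, `profile`, `kinetics` subcommands).

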