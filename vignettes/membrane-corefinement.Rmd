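---
title: "Co-refining neutron reflectometry of protein-laden supported bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-refining neutron reflectometry of protein-laden supported bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Anti-apoptotic Bcl-2 resides inside the mitochondrial outer membrane (MOM)
and neutralizes the pore-forming, pro-apoptotic Bax. Specular neutron
reflectometry (NR) on silicon-supported lipid bilayers can resolve where
each protein sits relative to the bilayer: Bcl-2 embedded inside the
membrane, Bax accumulating in one or two diffuse layers stacked on the
outer surface. `reflmem` implements the full quantitative chain of such an
experiment: scattering-length-density (SLD) bookkeeping with H/D isotopes,
exact slab-model reflectivity, simultaneous fitting of several solvent
contrasts to one structure, volume-fraction profiling, and the
exponential-association kinetics of Bax accumulation. Because beamline
data are not bundled, a synthetic-data module generates reflectivity and
kinetic datasets with the statistical structure the analysis assumes, and
every claim the package makes about itself is demonstrated by recovering
known ground truths from such data.

## Scattering length densities

Each chemical component (lipid headgroup, acyl chains, a protein on a
per-mean-residue basis, substrate materials) carries a formula, a
molecular volume $V$ and a count of labile hydrogens. Its SLD is
$\rho = \sum_i b_i / V$ with bound coherent scattering lengths $b_i$.
Hydrogen appears in three guises:

* non-labile H, a fraction $d$ of which may be biosynthetically replaced
  by deuterium (the deuteration level; 0.9 by default for the deuterated
  Bax entry, reflecting the >90% level such preparations reach);
* labile H, which exchanges with the solvent: each contributes
  $b_H (1 - x f) + b_D x f$, where $x$ is the solvent D2O volume fraction
  and $f$ the exchange fraction;
* explicit D written in the formula (tail-deuterated chains).

The exchange fraction defaults to 0.9 for folded proteins and 1.0 for
lipid exchangeables. These are field conventions, not measured values,
so they live in the editable component table
(`inst/extdata/components.tsv`) together with the fragment volumes, and
both are surfaced as arguments rather than constants. The solvent SLD is
the linear mix of pure H2O and D2O computed from the same element table
and a 30.0 Å³ water molecular volume; inverting it reproduces the
classic silicon-matched water at 38% D2O.

## Reflectivity kernel

Reflectivity of a slab stack is computed with the Abeles optical-matrix
method (compiled, in `src/`), with interface roughness entering as
Névot–Croce damping of each Fresnel coefficient. A pure-R Parratt
recursion provides a mathematically independent cross-check; the test
suite holds the two to better than $10^{-8}$ relative agreement on
random stacks.

Névot–Croce factors are only accurate while roughness is small compared
with the adjacent layer thicknesses. The bilayer models here contain a
thin (defaults to 4 Å) water gap between oxide and headgroups whose
interfaces carry ~3 Å roughness, so the forward model re-expresses such
stacks as their error-function SLD profile cut into slices of at most
min(2 Å, roughness/3), with zero roughness. Runs of adjacent slices whose
SLD varies by less than 0.001 (units of $10^{-6}\,\text{Å}^{-2}$) are
merged into one slab of their thickness-weighted mean SLD — slabs of
identical SLD and zero roughness are exactly equivalent to one thicker
slab, and at this tolerance the approximation error stays below 0.1%
of R, two orders of magnitude under the simulated noise. This roughly
halves the slab count and dominates the fitting cost.

Instrument resolution is applied as a Gaussian convolution in $Q$ of
FWHM $(dQ/Q)\,Q$, evaluated with 17-point Gauss–Hermite quadrature. For
model fitting the slab model is evaluated exactly at every
quadrature-shifted $Q$, so no interpolation error enters. The kernel
shape of the actual beamline reductions is not published; Gaussian is
assumed and recorded here. Constant $dQ/Q$ (3.5% default, 7% preset) is
used unless a dataset supplies a per-point $\sigma_Q$ column.

## The membrane model

One `membrane_structure` holds the physical parameterization:
Si / native oxide (12 Å, 8% hydrated) / water gap (4 Å) / inner heads
(8 Å) / chains (28 Å) / outer heads / up to two uniform protein surface
layers / bulk solvent. Conventions worth stating:

* $z = 0$ at the Si/oxide boundary, increasing toward bulk solvent.
* The embedded protein occupies all three bilayer sub-layers at a single
  volume fraction, displacing lipid within the covered area; the
  reported "volume coverage in bilayer" is that fraction directly. A
  per-sub-layer option was considered and rejected: the tabulated
  quantity being recovered is a single number, and extra fractions are
  poorly identifiable at these noise levels.
* Surface protein distributions are uniform-coverage slabs (proximal +
  optional distal), matching how such systems are tabulated, not
  functional-form decays.
* One global roughness is shared by bilayer and protein interfaces
  (substrate roughness separate) to limit parameter count.

`to_slabs()` maps a structure to one slab stack per solvent contrast;
thicknesses, roughnesses and fractions are identical across contrasts —
only SLDs change. This is the co-refinement constraint that makes the
inverse problem well-posed. `volume_fraction_profile()` produces
$\phi(z)$ per component with error-function interfaces; the profile sums
to 1 with solvent everywhere, conserves each layer's volume per unit
area independent of grid spacing, and the SLD profile assembled from it
agrees with the one assembled from the slab stack to $10^{-9}$ — two
construction paths over the same geometry.

The bilayer template values (oxide 12 Å, gap 4 Å, heads 8 Å, tails 28 Å,
roughness 3 Å, coverage 0.95, head hydration 0.2) are documented
defaults in the tradition of supported-POPC work, not claims about any
particular dataset.

## Co-refinement

`chi_squared()` is $\sum ((R_\mathrm{model}\cdot s + b - R)/\sigma_R)^2$
over all datasets. It is reported both raw and divided by the total
point count; published $\chi^2$ values for such fits rarely state their
normalization, so both are kept and the per-point form is used
internally.

`fit()` runs a differential-evolution global search (rand/1/bin,
population 15 per free parameter, up to 2000 generations, stopping when
the population's relative cost spread falls below `de_tol`) followed by
a derivative-free polish (Nelder–Mead, or Brent for one parameter).
Everything is deterministic given the seed. No differential-evolution
package is a dependency; the ~40-line implementation is part of the
package and tested through its recoveries. Scale is fixed at 1 and a
background per dataset is free (0 to 1e-5) by default; in the bundled
recovery experiments the backgrounds are fixed at the generator's
floor, since they are known there and the five structural parameters
are the scientific point.

Confidence intervals are residual-bootstrap: Gaussian noise of width
$\sigma_R$ is resampled about the best-fit curves, each resample is
refit locally (Levenberg–Marquardt on the weighted residuals, started
from the optimum — the global landscape has already been searched), and
the central 95% of each parameter's distribution is taken, widened if
necessary to contain the point estimate. The confidence level is a
choice, not a reproduction of the original analysis, whose interval
method is unpublished.

When the data may or may not resolve a second (distal) surface layer,
`select_surface_layers()` fits both models and keeps the two-layer one
only if it lowers per-point $\chi^2$ by more than 5% *and* puts more
than 3% coverage in the distal layer — the resolvability bar below
which a distal distribution is reported as n/a.

## Kinetics

Binding time series follow
$y(t) = y_0 + \sum_i A_i (1 - e^{-t/\tau_i})$ with one or two
components. Fitting is Levenberg–Marquardt over a deterministic
log-spaced multi-start grid of time constants (plus seeded jitter),
parameterized in $\log\tau$ to keep $\tau > 0$; components are returned
fast-to-slow and uncertainties are 1σ, from the parameter covariance —
they are labelled as such since conventions differ. The second
component must earn its place: `select_components()` demands an AICc
improvement greater than 10, a conservative strong-evidence threshold
chosen against overfitting slow drifts. Time zero is protein injection;
pre-injection points are the caller's to discard.

`series_to_trace()` converts time-stamped structural fits into the
kinetic observable for time-resolved NR: surface-layer protein volume
per unit area (coverage × thickness summed over layers) against
mid-acquisition time, with the acquisition span as the x-uncertainty.
A ~15-minute acquisition window cannot resolve a ~9-minute process, so
single-component fits are the default reading of such series; the fast
phase is accessible only to the 80-second ATR-FTIR sampling.

## Synthetic data: what it does and does not emulate

`simulate_contrast_set()` produces the four standard contrasts (D2O,
80% D2O, Si-matched water, H2O) on 150 log-spaced points over
0.01–0.3 Å⁻¹ at $dQ/Q$ = 3.5%, with Gaussian noise of
$\sigma = 0.02\,R + 10^{-7}$ — a relative-noise model whose scale is
chosen to resemble published error bars of such experiments, not
asserted as any instrument's true counting statistics (the tests stress
it at 1–5%). `mom_fixture(1:5)` provides the five reference systems
(three POPC, two 9:1 POPC:CL) whose protein parameters are set to the
tabulated central values; they are the ground truths of the recovery
experiments. `simulate_timeresolved_nr()` emulates staged structural
evolution (monomer layer, doubling, coverage growth) with an
exponential approach between anchors.

Passing recovery tests on these data shows the estimator is consistent
and well-calibrated *under its own assumptions*: Gaussian uncorrelated
noise, exact slab-model physics, known backgrounds, known component
volumes. Real data add footprint and alignment artifacts, Q-dependent
backgrounds, imperfect absolute scaling, correlated reduction errors
and uncertain molecular volumes; none of these are simulated, and
recovery here does not bound their effects.

## Problem sizes and numerical choices

The bundled recovery experiments use: 150 points × 4 contrasts, five
free structural parameters, DE population 75 with a 70-generation
budget before the polish, and 20–30 bootstrap resamples; the kinetics
recoveries use 200 noisy replicates (two-component, 80 s sampling) and
50 replicates (one-component, 15 min sampling). These sizes are the
package's desk-scale defaults for demonstrating recovery; the optimizer
accepts larger budgets through `control`. Degenerate inputs are refused
early (flat kinetic traces, fractions outside [0, 1], material volume
over 1, non-increasing Q), and fits that stop on budget rather than
tolerance are flagged in `convergence`, never silently returned.

## Known limitations

* Imaginary SLD is ignored; strongly absorbing systems are out of scope.
* Uniform slabs cannot represent genuinely decaying surface
  distributions; the two-slab parameterization is the chosen, tabulated
  compromise.
* Bootstrap intervals assume the noise model that generated
  $\sigma_R$; they are not a posterior.
* Component volumes and exchange fractions are literature conventions;
  systematic errors in them propagate directly into coverage fractions.
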