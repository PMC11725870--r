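---
title: "Reversible aggregation analysis of membrane-protein cluster size distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversible aggregation analysis of membrane-protein cluster size distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hots)
```

## The scientific problem

Many membrane proteins — receptors, channels, enzymes — are not uniformly
dispersed in the plasma membrane but occur as small clusters whose size
distribution decreases monotonically: monomers are the most common species,
dimers rarer, trimers rarer still, with no preferred cluster size. We call
such clusters higher-order transient structures (HOTS). Two classes of
mechanism could produce membrane clusters:

* **Attractors**: external membrane regions (scaffolds, lipid rafts,
  curvature or thickness patches) that concentrate proteins. Because an
  attractor collects a Poisson-like number of proteins, attractor mechanisms
  predict *peaked* size distributions once the attracted protein is
  abundant.
* **Self-assembly**: proteins weakly and reversibly bind copies of
  themselves. The cluster size distribution is then an emergent property of
  the protein itself, and reversible-aggregation theory — developed
  originally for surfactant micellization — predicts its exact shape.

This package implements the quantitative machinery to state both predictions,
fit the self-assembly model to measured cluster-size tables, simulate a toy
lattice version of sticky diffusion, analyze label coordinates on membrane
sheets, and generate synthetic data with known ground truth.

## The reversible-aggregation model

The membrane is idealized as a two-dimensional lattice of unit area $A_0$
(µm²), the *configurational unit area*: $1/A_0$ plays the role that the 1 M
standard-state concentration plays in solution chemistry. Two parameters
govern everything:

* $\Delta G^0_{\mathrm{mon\to bulk}}$ (written `dG_bulk`, in RT units): the
  standard free energy of transferring one monomer into an infinite
  close-packed "bulk phase" of identical proteins. Negative = cohesive.
* $A_0$ (`A0`, µm²).

A compact two-dimensional $n$-mer has a perimeter deficit — its edge
proteins are missing neighbor bonds — so the monomer-to-$n$-mer free energy
follows from a thermodynamic cycle through the bulk phase:

$$\Delta G^0_{\mathrm{mon}\to n\mathrm{mer}} = (n - n^{\alpha})\,
\Delta G^0_{\mathrm{mon\to bulk}},$$

with boundary exponent $\alpha = 1/2$ for compact clusters (perimeter
$\propto \sqrt{\text{area}}$). The equilibrium density of $n$-mers at
monomer density $c_{\mathrm{mon}}$ is then

$$c_n = A_0^{-1} (A_0 c_{\mathrm{mon}})^n
\exp\!\left[(n^{\alpha} - n)\,\Delta G^0/RT\right],$$

implemented by `nmer_density()`. Three consequences, all exposed as
functions:

1. **Critical monomer concentration** (`critical_monomer_concentration()`):
   $c^{\mathrm{crit}}_{\mathrm{mon}} = A_0^{-1} e^{\Delta G^0/RT}$, the
   monomer density in equilibrium with bulk phase.
2. **Critical distribution** (`critical_distribution()`): at criticality
   $c_n = A_0^{-1} e^{n^{\alpha} \Delta G^0/RT}$, the largest monotone
   distribution the model supports.
3. **Phase transition** (`critical_total_concentration()`): the total
   protein in the critical distribution,
   $A_0^{-1}\sum_n n\, e^{n^{\alpha}\Delta G^0/RT}$, is finite exactly when
   $\Delta G^0 < 0$ and $\alpha > 0$. Protein beyond this density condenses
   into bulk-phase sheets. Linear aggregates (polymer chains) have a
   boundary energy that does not grow with $n$ ($\alpha = 0$) and therefore
   never undergo the transition; `is_phase_transition_capable()` flags this.

Below criticality the distribution is strictly monotonically decreasing —
the model can *never* produce a peaked distribution, which is what makes the
HOTS-versus-attractor comparison decisive.

```{r core}
p <- aggregation_params(dG_bulk = -1.24, A0 = 0.58)
critical_monomer_concentration(p)
critical_total_concentration(p)
nmer_density(p, cmon = 0.45, n = 1:5)
```

The generalized exponent $\alpha \in [0, 1)$ is deliberately a single scalar
(`boundary_exponent`); arbitrary boundary-energy functions $g(n)$ are out of
scope because every qualitative regime of interest (compact clusters,
chains) is reached through $\alpha$ alone.

### Units

Energies are dimensionless multiples of RT throughout; areas are µm²,
densities µm⁻², coordinates nm. Conversions happen only at I/O boundaries,
never inside the model.

## Fitting measured distributions

Experiments measure $c_n$ for $n = 1 \ldots n_{\max}$ by counting labels
over a known membrane area. The fit imposes the mass constraint

$$c_{\mathrm{tot}} = \sum_{n=1}^{n_{\max}} n\, c_n,$$

so the fitted curve holds exactly the measured total density. Because both
$c_{\mathrm{mon}}$ (the monomer bin) and $c_{\mathrm{tot}}$ are measured,
fixing the cohesion energy determines $A_0$ through the constraint and vice
versa. `fit_single()` therefore performs a deterministic one-dimensional
profile search: for each candidate `dG_bulk` the observed monomer density
pins $c_{\mathrm{mon}}$, a monotone bisection resolves the unique $A_0$
satisfying the constraint, and the resulting curve is scored against the
data. `fit_global()` shares one `dG_bulk` across several datasets — an
expression series — while each dataset's $A_0$ is resolved from its own
totals; the objective is the summed per-dataset loss. The two parameters
remain separately identifiable because they enter the law through distinct
powers of $n$.

Design choices a user should know:

* **Loss.** The default (`loss = "auto"`) uses inverse-variance weighted
  least squares on densities when the data carry standard errors (the
  pipeline attaches Poisson errors $\sqrt{\text{count}}/\text{area}$ to
  counted tables), and otherwise unweighted least squares on
  $\log(c_n + 10^{-6})$, which balances the many-decade dynamic range of
  the tails. For simulation-derived panels, where every size bin is a time
  average over the same number of samples and the interest is in the
  mass-carrying low-$n$ bins, we fit plain least squares on densities
  (`loss = "density", weights = "none"`).
* **Zero bins.** Sizes inside $1..n_{\max}$ with no observed clusters are
  retained at density 0 rather than dropped; dropping them would bias the
  tail. The $10^{-6}$ µm⁻² floor applies only inside the logarithm.
* **nmax.** By default the largest size with a nonzero observation, per
  dataset.
* **Search.** A fixed 81-point grid over `dG_bounds` (default
  $[-10, -10^{-3}]$ RT) seeds a golden-section refinement — deterministic,
  no random restarts; a boundary minimum is reported with
  `converged = FALSE`, never silently.
* **Uncertainty.** A seed-controlled nonparametric bootstrap resamples
  *clusters* (not labels), refitting each replicate
  (`fit_config(n_bootstrap = ...)`).

`fit_shared_A0()` answers a complementary question: with the cohesion
energy fixed (say, at a global estimate), is one configurational area
consistent with a whole panel? It matches the low-$n$ cluster densities
($n = 1..6$ by default) as functions of total density, resolving each
dataset's $c_{\mathrm{mon}}$ from the constraint.

```{r fit-demo}
set.seed(1)
panel <- make_distribution_panel(-1.82, 0.08, ctots = c(1, 2, 4, 8),
                                 area = 2500)
fit <- fit_global(panel)
fit
```

## The attractor model

`attractor_distribution()` implements a grand-canonical Poisson-occupancy
attractor: regions at density `mtot` bind proteins independently with
association constant `Ka` (µm², occupancy per unit free-protein density), so
occupancy is Poisson with mean $\lambda = K_a c_{\mathrm{free}}$ and the
mass balance $c_{\mathrm{tot}} = c_{\mathrm{free}} + m_{\mathrm{tot}}
\lambda$ closes the model. Observable clusters are attractors carrying at
least one protein; free monomers are reported in the $n = 1$ bin because
the experiment cannot distinguish a bound singleton from a free monomer.
This specific functional form is our own documented variant — chosen as the
simplest non-saturable attractor with the mechanism's defining behaviors:
Poisson-like occupancy, *peaked* at high protein density, monotone at low
density (`is_peaked()` classifies). `fit_attractor()` and
`discriminate_models()` fit both mechanisms to one table with a common loss
and report the better-supported one.

## The lattice simulation

`lattice_run()` is a deliberately minimal kinetic toy — not a
statistical-thermodynamic model — showing that transient clusters emerge
from nothing but sticky random walks with excluded volume. Particles on a
100×100 grid (site length 0.1 µm, so 0.01 µm² per site and 100 µm² total)
each draw one of {stay, up, down, left, right} per sweep with weights
{$w$, 1, 1, 1, 1}, where $w$ = `pwait_bound` (default 50) if at least one
4-neighbor site is occupied and `pwait_free` (default 1) otherwise.
Numerical choices:

* a draw into an occupied or out-of-bounds site becomes a stay (the
  simplest rule preserving the five-outcome weighting);
* particles update sequentially in a freshly shuffled order each sweep,
  which avoids the collision conflicts of parallel updates;
* binding and cluster binning both use 4-connectivity;
* boundaries reflect by default (`boundary = "periodic"` is available);
* burn-in defaults to ten sweeps per grid site, far beyond the observed
  relaxation of the cluster-size histogram, and sampling thins to every
  tenth sweep.

`density_sweep()` runs a seeded trajectory per requested density and
converts time-averaged 4-connected cluster histograms to µm⁻². In the
bundled analysis (tests and `scripts/acceptance.R`) we simulate densities
2, 4, 10 and 20 µm⁻² (200–2000 particles) for 2×10⁵ sweeps each, discarding
the first 10⁵ — sizes chosen so the per-bin Monte-Carlo error is well below
the fitted-parameter tolerances while a full panel runs in about a minute.
Fitting those four curves with one global cohesion energy yields
ΔG⁰ ≈ −0.62 RT with per-density areas rising from ≈0.15 to ≈0.24 µm², and a
shared-area refit gives ≈0.21 µm² — an order of magnitude above the 0.01 µm²
grid site, as expected, since the simulation encodes no $n$-mer energy, runs
far from infinite dilution, and its clusters occupy multiple sites rather
than points.

## Point-pattern analytics

`point_pattern()` holds label coordinates (nm) inside a membrane-region
polygon; membership uses the even-odd rule with boundary points counted
inside, and areas come from the shoelace formula. The operational cluster
definition is single linkage with a distance cutoff
(`link_clusters()`): components of the graph joining all pairs within the
cutoff, ties linking. The cutoff is a first-class parameter recorded in
every output — a sensible default is about three label diameters (larger
for 18 nm than for 6 nm gold) — because linking behavior is the one place
where an analysis choice directly reshapes the size distribution.
Downstream:

* `cluster_size_distribution()` tabulates per-size cluster densities with
  Poisson errors;
* `subtract_background()` removes a no-expression control per size bin,
  clamping at zero (clamped bins are recorded and warned about);
* `nnd_centroids()` and `csr_null()` test whether cluster *centroids* are
  randomly placed: the Monte-Carlo null matches the closed-form 2D Poisson
  nearest-neighbor law $2\pi\lambda r e^{-\pi\lambda r^2}$ on large
  regions;
* `pairwise_distance_histogram()` plus `fit_gaussian_peak()` estimate the
  intra-cluster packing distance (≈ the protein diameter for close-packed
  clusters);
* `thin_labels()` applies binomial thinning, the standard model of
  sub-unity labeling efficiency.

Distances are Euclidean in the sheet plane; no tilt correction is applied
(observed clusters are approximately planar).

## The synthetic-data generator

`synth_config()` + `simulate_point_pattern()` produce label patterns with
known ground truth, emulating the statistical structure of immunogold
membrane-sheet data:

* cluster sizes are independent Poisson counts around the generating
  model's expected densities (the grand-canonical independence picture);
  supercritical requests error out, naming the critical total density;
* centroids are uniform in the region (CSR), matching the observed
  randomness of real cluster centroids;
* each cluster is a hexagonal packing at 5.2 nm nearest-neighbor spacing
  (the measured most-probable intra-cluster distance) with small Gaussian
  jitter, randomly rotated;
* the observation model applies binomial thinning and superimposes uniform
  background, with a ground-truth channel that `blind = TRUE` strips.

The default region is a 50 × 50 µm rectangle, the scale of an EM montage of
one unroofed membrane; at HOTS-like densities this yields on the order of
10⁴ labels, matching real single-membrane datasets. What the generator does
*not* emulate: micrograph pixel data, stain texture, protein-rich islands,
antibody-linker geometry, or spatially structured nonspecific background
(assumed uniform for lack of a measured characterization). Passing
recovery tests on synthetic data therefore validates the pipeline's
statistics, not those imaging-layer effects.

## Numerical notes

* `nmer_density()` evaluates in log space, so extreme sizes underflow to 0
  instead of overflowing.
* The phase-transition series is summed with an analytic incomplete-gamma
  integral bound on the tail, guaranteeing the requested relative
  tolerance without a fixed cutoff.
* All mass-balance inversions are monotone bisection solves, robust to the
  overflow of supercritical trial values; round trips hold to 10⁻⁹
  relative tolerance.
* `is_peaked()` takes the first maximum on exact ties, so a flat
  distribution is "not peaked".
* Every stochastic operation accepts an integer seed, and identical
  configurations plus seeds reproduce identical outputs.

## Limitations

The theory is the dilute limit: finite-occupancy corrections when the
membrane is crowded are not implemented. Fitted values of `dG_bulk` and
`A0` depend on the idealized boundary-energy model and should be read as
effective parameters — the cohesion scale and the configurational-entropy
scale — rather than microscopic constants. Bulk-phase outliers beyond the
critical density are deliberately outside the fitted law: the model
accounts for the HOTS distribution up to criticality, and systematic excess
in the large-$n$ tail is itself evidence of near-critical expression. The
attractor implementation is one representative non-saturable variant;
saturable scaffolds with cooperative binding are not modeled.
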