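# hots

Quantitative analysis of **higher-order transient structures (HOTS)** — the
small, reversible self-clusters that many membrane proteins (receptors,
channels, enzymes) form in the plasma membrane. Across cell types and
expression levels these clusters show a *monotonically decreasing* size
distribution: monomers outnumber dimers, dimers outnumber trimers, with no
preferred size. This package provides the reversible-aggregation theory that
predicts this shape, the machinery to fit it to measured cluster-size
tables, a competing "attractor" (scaffold/raft) model for discrimination, a
lattice Monte-Carlo simulator of sticky diffusion, point-pattern statistics
for label coordinates on membrane sheets, and a synthetic-data generator
with known ground truth.

It is aimed at quantitative membrane biophysicists working with
immunogold/EM or super-resolution label coordinates, and at modelers who
want a tested reference implementation of 2D reversible aggregation.

## The model

A protein that binds copies of itself with standard free energy
`ΔG⁰_mon→bulk` (RT units; negative = cohesive), on a membrane with
configurational unit area `A₀` (µm²), forms n-mers at equilibrium densities

    cₙ = A₀⁻¹ (A₀ c_mon)ⁿ exp[(n^α − n) ΔG⁰/RT],   α = 1/2,

where the boundary term `n^α ΔG⁰` is the perimeter bonding deficit of a
compact 2D cluster. Consequences, each a package function:

* critical monomer concentration `c_crit = A₀⁻¹ exp(ΔG⁰/RT)` —
  `critical_monomer_concentration()`;
* critical distribution `cₙ = A₀⁻¹ exp(n^α ΔG⁰/RT)` —
  `critical_distribution()`;
* a true 2D phase transition: the critical total density
  `A₀⁻¹ Σ n exp(n^α ΔG⁰/RT)` is finite iff `ΔG⁰ < 0` and `α > 0`
  (`critical_total_concentration()`); excess protein condenses into
  bulk-phase sheets. Linear aggregates (`α = 0`) never condense.

Fitting (`fit_single()`, `fit_global()`) imposes the mass constraint
`Σ n·cₙ = c_tot`, so with the monomer density pinned by the data each
candidate `ΔG⁰` determines `A₀` and the fit is a deterministic 1D profile
search; `fit_global()` shares one `ΔG⁰` across an expression series. The
attractor alternative (`attractor_distribution()`) predicts *peaked*
distributions at high protein density and is fitted and compared with
`discriminate_models()`.

## Worked example

Generate one synthetic membrane sheet (50 × 50 µm) from known parameters,
then analyze it blind — cluster, tabulate, fit:

```r
library(hots)
p <- aggregation_params(dG_bulk = -1.24, A0 = 0.58)
critical_monomer_concentration(p)
#> [1] 0.4989383
critical_total_concentration(p)
#> [1] 8.658551

cfg <- synth_config("hots", p, ctot = 4.3)   # 4.3 proteins per um^2
pp  <- simulate_point_pattern(cfg, seed = 1)
pp
#> Point pattern: 10758 points in a 2500 um^2 region (4.303 um^-2)

cl <- link_clusters(pp, cutoff = 20)         # single linkage, 20 nm
cl
#> Cluster set: 10758 points -> 3211 clusters (cutoff 20 nm)

d <- cluster_size_distribution(cl)
head(as.data.frame(d), 3)
#>   n density counts          se
#> 1 1  0.4536   1134 0.013469967
#> 2 2  0.2696    674 0.010384604
#> 3 3  0.1700    425 0.008246211

fit_single(d)
#> Mass-constrained reversible-aggregation fit
#>   datasets: 1   converged: TRUE
#>   dG_bulk (global): -1.145 RT
#>   A0 per dataset (um^2): 0.639
#>   cmon per dataset (um^-2): 0.454
#>   objective: 15.839
```

The fitted cohesion energy (−1.15 RT) and configurational area (0.64 µm²)
recover the planted values (−1.24 RT, 0.58 µm²) to within the sampling
error of a single ~10⁴-label sheet; the observed monomer density
(0.454 µm⁻²) sits at 91% of the critical concentration, i.e. this membrane
is expressed close to the phase boundary. Fitting a multi-density panel
with `fit_global()` tightens the estimate considerably (see the vignette in
`vignettes/reversible-aggregation.Rmd`).

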