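# scavnet

Spatial-use networks from scavenger GPS telemetry: dynamic Brownian bridge
home ranges, trajectory-to-graph network construction, node fidelity and
resource characterization, status contrasts and node regressions, and
random-vs-targeted node-removal perturbation experiments.

## The problem

Avian scavengers such as the Egyptian vulture increasingly forage on
predictable anthropogenic food subsidies (PAFS) — landfills, intensive
farms, supplementary feeding stations ("vulture restaurants") — and
European waste policy is set to close many landfills. To anticipate how
foraging movements reorganize when central resources disappear, movement
ecologists model space use as a network: the polygons of the population's
50% utilization-distribution contour are nodes, and between-node movement
paths are weighted links. Network metrics (diameter, density, degree,
betweenness) then describe foraging strategies, and simulated node removal
— uniformly random versus targeted at a resource type — probes robustness.

`scavnet` implements that entire chain for R users, from raw timestamped
fixes to perturbation tables, plus a synthetic trajectory generator with
ground-truth visit logs, so the pipeline can be developed and validated
without access to sensitive tracking data on endangered species.

## The core model

For consecutive fixes $z_a, z_b$ at $t_a, t_b$, the Brownian bridge places
the animal at time fraction $\alpha$ at
$\mathcal{N}\big(z_a + \alpha(z_b - z_a),\;
\alpha(1-\alpha)(t_b-t_a)\sigma^2_m + (1-\alpha)^2\varepsilon_a^2 +
\alpha^2\varepsilon_b^2\big)$ per axis. The motion variance $\sigma^2_m$
(m²/s) is estimated dynamically in sliding windows by leave-out maximum
likelihood with BIC change-point detection; bridge densities integrated
over time and rasterized on a metric grid give the utilization
distribution. Betweenness of node $v$ is
$\sum_{s \ne t \ne v} \sigma_{st}(v) / \sigma_{st}$ over unordered pairs,
with $\sigma_{st}$ the number of unweighted shortest paths.

## Worked example

The numbered scripts under `analysis/` run the full study workflow on the
default synthetic population (16 birds, 30-min fixes, two 150-day summer
seasons) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # trajectories, sites, land cover
Rscript analysis/02_homerange.R     # dBBMM UDs, population 50% contour
Rscript analysis/03_network.R       # labels, paths, status networks
Rscript analysis/04_features.R      # land cover, resources, fidelity
Rscript analysis/05_stats.R         # ANOVA, PCA, node regressions
Rscript analysis/06_perturbation.R  # removal experiments, paired T-tests
```

With the shipped defaults (seed 1) the run prints, among other things:

```
simulated 153600 fixes for 16 individuals (56 sites)
32 individual-year UDs; population 50% contour has 24 polygons (mass 0.501)
non_breeder: 19 nodes, 75 links, diameter 3
breeder: 11 nodes, 23 links, diameter 2
mean nodes per bird-year: non-breeders 17.8, breeders 3.5
non_breeder top resource after landfill removal: extensive_livestock
breeder top resource after landfill removal: extensive_livestock
```

Read: the population's core range splits into 24 polygons; non-breeders
use strictly more nodes and links than breeders, both pooled and per
bird-year (17.8 vs 3.5 node means; the ANOVA table in
`results/anova_contrasts.csv` makes the contrast formal); and once every
landfill node is deleted, extensive livestock holds the highest mean
betweenness of the remaining resource groups in both networks — the
foraging network reorganizes around livestock carcasses.

The same chain is available as one call:

```r
library(scavnet)
pl <- run_pipeline(seed = 1, n_runs = 1000)
pl$metrics$non_breeder$network   # nodes, links, diameter, density measures
pl$perturbation$non_breeder$comparison  # per-step paired T-tests
```

## Layout

- `R/`, `src/` — the package: simulation, dBBMM, contours, networks,
  features, statistics, perturbation (Rcpp for the numerical cores)
- `analysis/` — the numbered workflow scripts shown above
- `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles
- `vignettes/spatial-use-networks.Rmd` — models, assumptions, parameter
  rationale, limitations
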