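# migsem

Phylogenetic piecewise structural equation models for the annual cycle
of migratory birds.

## What it is for

Tracking studies have described the full annual schedule — departure
from the non-breeding site, arrival at the breeding site, departure
from the breeding site, arrival at the non-breeding site — for
hundreds of bird species. `migsem` is for analysts who compile such
records across studies and want to ask, at macro scale, what drives the
timing: the latitudes of the seasonal ranges, the migration distance
they imply, and body mass, the key intrinsic trait. The package takes a
tracking table (one row per tracked individual or population), a
species trait table of minimum body masses, and a dated phylogeny, and
runs the whole analysis: validation and derivation of durations,
day-of-year indices and great-circle distances; a piecewise SEM over a
hypothesized causal DAG; decomposition of standardized direct, indirect
and total effects; and a d-separation test of the causal structure.

## The model

Each endogenous node *y* of the DAG (latitudes, distance, and the four
timings, which carry over within a cycle) is fitted as a Gaussian mixed
model on z-scored variables:

    y = Xβ + u_phylo + u_species + u_paper(species) + u_year + ε
    u_phylo ~ N(0, σ²_phylo · C),   others i.i.d.

where `C` is the Brownian-motion correlation matrix of shared branch
lengths from the phylogeny. Fitting is either Bayesian (blocked Gibbs
sampler; 4 chains × 10,000 iterations, burn-in 1000, split-R̂ < 1.1;
Normal(0, 2.5²) priors on coefficients, half-t(3, 0, 2.5) on SDs) or
REML (fast, for simulation studies). An edge's standardized coefficient
enters path tracing only if its 95% interval excludes zero; indirect
effects are sums over directed paths of products of gated edge weights,
and total = direct + indirect. The DAG's testable independence claims
combine into Fisher's C = −2 Σ log p ~ χ²(2k). Marginal/conditional R²
follow Nakagawa–Schielzeth.

A first-class synthetic-data generator (`simulate_bundle()`) draws
tree, traits and records from this structural model with known ground
truth — by default at the compiled-study scale (186 species, ~1700
records nested in papers and species, phylogenetic signal in mass) — so
every stage is testable without downloads.

## Worked example

```r
library(migsem)

bundle <- simulate_bundle(n_species = 60, mean_records = 9, seed = 1)
dir <- file.path(tempdir(), "demo"); write_bundle(bundle, dir)

records <- read_tracking_table(file.path(dir, "tracking.csv"))
traits  <- read_trait_table(file.path(dir, "traits.csv"))
tree    <- read_newick(file.path(dir, "tree.nwk"))

derived <- derive_cycle(records, traits)
summarize_timing(derived)
#> Timing summary across 60 species
#>   dep_nb_doy             mean    86.7  sd    9.4  (28 March)
#>   arr_b_doy              mean   121.4  sd    9.0  (01 May)
#>   dep_b_doy              mean   235.1  sd   12.4  (23 August)
#>   arr_nb_doy             mean   286.2  sd   12.8  (13 October)
#>   spring_duration        mean    34.7  sd   10.1  (9.5% of cycle)
#>   breeding_duration      mean   113.7  sd   15.2  (31.1% of cycle)
#>   autumn_duration        mean    51.2  sd   11.5  (14.0% of cycle)
#>   nonbreeding_duration   mean   165.7  sd   15.8  (45.4% of cycle)
```

The mean dates are the two-stage means (within species, then across
species) of the four events; the durations partition the annual cycle.
Autumn migration is longer than spring here
(`paired_t_autumn_vs_spring(derived)`: t = 16.86, df = 565,
p < 2e-16), as the generator's anchors imply.

```r
phylo <- vcv_from_tree(prune_to_species(tree, unique(derived$species)))
sem <- fit_sem(derived, build_default_dag(), phylo,
               sem_control(backend = "reml"))
sem$fits$dep_nb
#> Equation: dep_nb ~ body_mass + breed_lat + nb_lat_abs + mig_dist + flight_mode
#>   backend: reml (converged)
#>   body_mass     -0.396  [ -0.554,  -0.239] *
#>   breed_lat      0.215  [  0.110,   0.320] *
#>   nb_lat_abs     0.026  [ -0.112,   0.165]
#>   mig_dist       0.093  [ -0.023,   0.209]
#>   flight_mode    0.049  [ -0.255,   0.354]
#>   R2m = 0.194, R2c = 0.432
```

Heavier species leave the non-breeding grounds earlier (the generating
truth for this edge is −0.33), higher-latitude breeders later (truth
0.29); starred rows are effects whose 95% interval excludes zero. The
decomposition and the structure test:

```r
effects <- decompose_effects(build_default_dag(), sem)
render_effect_table(effects)
#>                 body_mass breed_lat nb_lat_abs mig_dist dep_nb arr_b dep_b
#> arr_nb direct   0.29      -         -          -        -      0.19  0.43
#> arr_nb indirect 0.11      0.09      -0.03      0.05     0.06   -     -
#> arr_nb total    0.40      0.09      -0.03      0.05     0.06   0.19  0.43
#> ...

dsep_test(derived, build_default_dag(), phylo)
#> Fisher's C = 3.00, df = 6, p = 0.808
```

Body mass delays arrival at the non-breeding site both directly (0.29)
and through the carry-over chain (0.11 indirect); the non-significant
global Fisher's C (p = 0.81) says the simulated data are consistent
with the DAG that generated them.

The same run, driven by a YAML config, is available from the command
line (`inst/cli/migsem.R simulate|run`) and as `run_pipeline()`, which
writes per-stage CSV/JSON artifacts and a manifest.

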