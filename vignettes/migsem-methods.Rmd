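---
title: "Methods: phylogenetic piecewise SEM for annual-cycle timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic piecewise SEM for annual-cycle timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Migratory birds run their year on a tight schedule: departure from the
non-breeding site, arrival at the breeding site, departure from the
breeding site, arrival back at the non-breeding site. The timing of
these four events is shaped jointly by where a species breeds and
winters (latitude sets local phenology), by how far it must fly, and by
intrinsic traits — above all body mass, which scales the time needed
for breeding and the speed of powered flight. `migsem` implements a
macro-scale analysis of these drivers: given a table of annual-cycle
tracking records (one row per tracked individual, or a population
average used as a proxy), a species trait table of minimum (lean) body
masses, and a dated phylogeny, it fits a *piecewise* structural
equation model — one mixed-effects regression per endogenous variable
of a hypothesized causal DAG — and decomposes standardized direct,
indirect and total effects by path tracing.

## The causal graph

`build_default_dag()` encodes the hypothesized structure:

* body mass → breeding latitude and (absolute) non-breeding latitude
  (Bergmann's rule acting on the wintering distribution);
* body mass, both latitudes and flight mode → migration distance;
* each timing depends on mass, the latitudes, distance, flight mode,
  and **all earlier timings of the same annual cycle** (carry-over
  effects). There are no edges from one cycle into the next: timing is
  assumed to be reset during the non-breeding period.

The non-breeding latitude enters as an absolute value. Southern-
hemisphere wintering latitudes are strongly collinear with migration
distance when signed; folding the hemisphere removes that
collinearity while preserving the distance-to-the-equator meaning. The
variance-inflation factors of every equation are reported
(`vif()`); the expectation for conforming data is VIF < 2.

## The structural equations

Every endogenous node *y* is fit as a Gaussian mixed model on z-scored
variables:

y = Xβ + u_phylo + u_species + u_paper(species) + u_year + ε,

with u_phylo ~ N(0, σ²_phylo · C) across species, where C is the
Brownian-motion correlation matrix derived from shared branch lengths
of the phylogeny (λ fixed at 1; no signal parameter is estimated), and
the species, paper-within-species ("paper" is the source study a record
was compiled from) and year intercepts i.i.d. Species enters twice — a
phylogenetically structured term and a free term — so that trait
similarity beyond phylogeny is not forced through the tree.

Two backends satisfy the same contract:

* **`backend = "bayes"`** (default): a blocked Gibbs sampler, 4 chains
  × 10,000 iterations with the first 1000 discarded per chain,
  equal-tailed 95% credible intervals, split-R̂ convergence checks with
  the 1.1 threshold. Priors are weakly informative: Normal(0, 2.5²) on
  standardized coefficients and half-Student-t(3, 0, 2.5) on every SD,
  the latter implemented exactly through the Huang–Wand inverse-gamma
  mixture so that all full conditionals stay conjugate.
* **`backend = "reml"`**: restricted maximum likelihood with the
  variance ratios optimized on the log scale through a Woodbury
  identity on the q×q random-effect inner matrix, and Wald intervals
  (t quantile, df = n − p) from the plug-in covariance. This backend
  exists because simulation studies (50 replicates × 7 equations) are
  infeasible with full MCMC; its interval calibration is itself
  verified by the parameter-recovery acceptance test.

**Response scaling.** Explanatory variables are z-scored as a matter of
course; the response is z-scored too (default `scale_response = TRUE`),
so coefficients are *fully* standardized and multiply along paths —
without this, path products are not comparable across equations. A
raw-response mode is available.

**Scaling convention.** z-scoring uses the population SD (denominator
n). Binary covariates (flight mode, coded flapping = 0 / soaring = 1;
sex, male = 0 / female = 1) stay on their 0/1 scale. Body mass is
log10-transformed before scaling: masses spanning 8.7–7600 g would
otherwise put essentially all variance on a few heavy species.

**Missing data** are removed listwise per equation with a logged count.
Records of unknown sex are only dropped when sex is in the model.

## Effect decomposition

After fitting, each DAG edge gets the standardized coefficient of its
equation as a weight — **gated by significance**: an edge whose 95%
interval covers zero contributes exactly 0 to every path. The direct
effect of i on j is the weight of the edge i→j; the indirect effect is
the sum over all directed paths of length ≥ 2 of the product of edge
weights (exact enumeration; the graph is small); total = direct +
indirect. Gating is the convention under which the published indirect
and total cells are reproducible as products of the published
significant direct coefficients; the ungated decomposition is available
with `gate = FALSE`. Tables render with half-away-from-zero rounding to
2 decimals, preserving the sign of a negative value that rounds to zero
("-0.00"), and "-" for absent/non-significant effects.

## d-separation

The DAG's testable content is its basis set: for every non-adjacent
ordered pair (i, j), i earlier in topological order, the claim
"i ⟂ j | parents(j) ∪ parents(i)". Pairs of two exogenous variables are
excluded — no structural equation constrains their association. Each
claim is tested by regressing j on its conditioning set plus i with the
same mixed-model machinery, and the claim p-values combine into
Fisher's C = −2 Σ log p, referred to χ² with 2k degrees of freedom.

Claim tests need more care than the equation fits, because several
claim variables (flight mode, the latitudes) are effectively replicated
at the species level only: a plug-in Wald test against residual df
rejects a true conditional independence at roughly 2–3× the nominal
rate in calibration simulations at a few dozen species. Two corrections
are applied: the claim coefficient's posterior (short Gibbs chains) is
used rather than the plug-in REML SE, because the posterior SD
marginalizes over variance-component uncertainty; and its z-score is
referred to a t distribution with *containment* (between-within)
degrees of freedom — a predictor constant within species is tested
against (number of species − species-level terms) df, a record-level
predictor against residual df, the same rule the package's REML Wald
p-values use. Null-DAG calibration of the resulting Fisher's C is part
of the acceptance suite. The d-separation test is reported as a
structure-evaluation aid, not as a gate on the effect decomposition.

## Distances and dates

Migration distances are great-circle (haversine) distances on the IUGG
mean-radius sphere (6371.0088 km, configurable). The choice of
great-circle convention is immaterial for the SEM because distances are
z-scored before fitting. The spring leg runs from the *last*
non-breeding site to the breeding site, the autumn leg from the
breeding site to the *first* non-breeding site; the single distance
node in the DAG is the mean of the two legs (identical whenever one
non-breeding site is used). The non-breeding latitude used in the model
is likewise the mean absolute latitude of the two sites.

Event dates map to a continuous day index: days since Jan 1 of the
tracking year (the calendar year containing the departure from the
non-breeding site), continuing past 365 for events after Dec 31. Means
are linear, not circular: indexed this way the events cluster far from
the wrap point. Durations use true calendar arithmetic, so the four
periods sum to 365 or 366 exactly; the non-breeding period runs from
arrival at the first non-breeding site to departure from the last
(operationally, to the same calendar day one year after the recorded
departure). Population-level rows are treated identically to
individual rows, unweighted. Rows violating an invariant (southern-
hemisphere breeding, event order, unparseable dates, coordinate range)
are rejected with a per-row reason, never silently dropped.

## The synthetic world

`simulate_bundle()` generates tree, traits and tracking records from
the structural model with known ground truth, emulating the compiled
study's statistical structure: 186 species by default, records per
species from a zero-truncated negative binomial with mean ≈ 9 (≈1700
records, heavily skewed), papers nested in species (mean ≈ 1.6 per
species), tracking years 1995–2021, 37% of records of unknown sex,
phylogenetic signal (h² = 0.5) in log mass on a unit-depth Yule tree.
Default path coefficients are set to magnitudes consistent with the
published standardized effects (e.g. 0.35 for the spring carry-over,
−0.33 for mass on spring departure); they are *defaults of a synthetic
world*, not estimates of the real data. Variance components follow the
reported pattern: species and paper variance dominate, phylogeny and
year are small.

Endogenous variables are generated on the standardized scale in
topological order; each node's residual variance is set so the node has
unit variance, and every generated column is re-standardized
empirically before downstream use so the generating coefficients are
exactly the standardized effects the pipeline estimates. Natural units
are then layered on: masses of 10^(2.2 ± 0.65) g split ±5% by sex;
breeding latitudes 55 ± 8°N; non-breeding latitudes 20 ± 10° absolute,
wintering south of the equator exactly when the drawn distance exceeds
the northern-geometry maximum; distances 6500 ± 1800 km; event dates
around the anchors 27 March, 2 May, 26 August, 16 October with SDs
14/14/18/18 days. The anchor gaps are several times these SDs, which is
what keeps the event-order invariant satisfiable.

Two feasibility guards distort the truth for a small fraction of
records, and their counts are recorded in the truth file: distances are
clamped into the great-circle band attainable for the record's
latitudes (a few percent of records), and records violating event order
redraw their timing residuals (rare; a final 1-day separation is forced
if integer rounding collapses a gap). Non-breeding coordinates are
back-computed by inverting the spherical law of cosines, so the written
coordinates reproduce the generated distance to numerical precision.

What the generator does **not** emulate: real geography (flyways, land
masks, longitudinal structure of routes), age classes, intraspecific
latitude–timing clines, sex differences (sex is assigned at random and
carries no effect unless a truth coefficient is supplied), observation
error in digitized dates, or non-Gaussian tails. A green recovery test
therefore establishes that the estimator recovers the stated generative
process at the stated scale — not that the model is correct for real
tracking data.

## Numerical choices

* REML optimization: Nelder–Mead on log variance ratios (Brent when a
  single component), start log(0.1), ratios clamped to e^±[−12, 8];
  convergence failures are flagged and block downstream decomposition
  unless forced.
* Cholesky factorizations ridge the phylogenetic correlation by 1e−8.
* Ties/degeneracies: a zero-variance predictor is an error naming the
  column; perfect collinearity reports an infinite VIF; a paired t test
  with zero-variance differences returns t = 0 when centred; R̂ of
  constant identical chains is 1 by convention.
* Intervals are equal-tailed (2.5%, 97.5%) in both backends.
* All stochastic steps (simulation, MCMC) are seeded explicitly;
  chains use seed + chain index.

## Known limitations

* Wald intervals from the REML backend ignore variance-component
  uncertainty; coverage is verified empirically at the simulation scale
  used in the acceptance tests, not guaranteed at very small n.
* The phylogenetic and free species intercepts are weakly separated in
  short MCMC runs (their sum is well identified); split-R̂ flags this,
  and the full-length default settings are recommended for reported
  variance partitions.
* Indirect effects are reported as point decompositions of the gated
  coefficient estimates; no posterior intervals on path products are
  propagated.
* Fisher's C claim p-values come from the likelihood machinery even
  when the SEM itself is fitted by MCMC; the test is reported for
  structure evaluation, not used as a gate.
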