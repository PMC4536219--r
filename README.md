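# riverEMS

Regional river surveys yield a site-by-taxon table, an environmental table,
and three questions: does the fauna organise into one of the idealised
metacommunity structures along a latent gradient; how do alpha and beta
diversity differ between headwaters, mid-sized streams and large rivers; and
which environmental or spatial variables best predict richness and the
composition gradient? `riverEMS` is an R package for community ecologists
that answers all three for incidence/abundance matrices of the kind produced
by benthic invertebrate monitoring (the machinery transfers unchanged to any
site-by-OTU incidence table).

Three method families are implemented:

* **Elements of Metacommunity Structure (EMS).** The incidence matrix is
  arranged by reciprocal averaging (correspondence analysis); coherence is
  tested by the number of embedded absences `Abs`, species turnover by the
  number of replacements `Re` on the range-filled matrix, and boundary
  clumping by Morisita's index `MI` with a chi-square test. `Abs` and `Re`
  are judged against a fixed-incidence proportional ("r1") null ensemble —
  each null matrix preserves every site's richness exactly and draws taxa
  with probability proportional to their incidence — via
  `z = (null mean − observed) / null SD` with two-tailed p. The outcome
  pattern maps deterministically onto 14 idealised/quasi structures
  (Checkerboard, Random, Evenly spaced / Gleasonian / Clementsian, three
  Nested species-loss variants, and their Quasi- counterparts).
* **Diversity across river sections.** Sites are split by catchment size
  (headwaters < 20 km², mid-sized [20, 100), large ≥ 100); richness,
  Hurlbert rarefied richness (per 100 individuals) and Simpson's index are
  compared by one-way ANOVA with Tukey HSD letters, and beta diversity as
  Bray–Curtis dispersion (distance to group centroid) with an F test.
* **Boosted regression trees.** Stage-wise boosting of five-split regression
  trees (Poisson loss for richness, Gaussian for the primary ordination
  axis; learning rate 0.001, bag fraction 0.5), with 10-fold
  cross-validation selecting the number of trees, percent deviance explained
  `100·(null − residual)/null`, and gbm-style relative influence per
  predictor and per category (physical, land use, chemical, spatial).

A seeded synthetic generator (`simulateMetacommunity()`,
`simulateEnvironment()`, `simulateAbundance()`) produces metacommunities
with known idealised structure, an environmental driver carrying the latent
gradient, and conditional abundances, so the whole pipeline is testable
without survey data.

## A worked example

```r
library(riverEMS)

cfg <- syntheticConfig("clementsian", nSites = 168, nTaxa = 160, seed = 1)
sim <- simulateMetacommunity(cfg)
env <- simulateEnvironment(sim$gradient, cfg)
ab  <- simulateAbundance(sim$incidence, cfg)

res <- runPipeline(ab, env, nSim = 200, seed = 1,
                   learningRate = 0.005, maxTrees = 1000)

res$ems$table[1, c("Abs_z", "Re_z", "MI", "structure")]
#>         Abs_z      Re_z       MI   structure
#> all1 238.4428 -516.0148 8.317712 Clementsian
```

All eight analyses (four site sets × two ordination axes) classify as the
Clementsian family here: strong positive coherence (fewer embedded absences
than the nulls, z = 238.4), strong positive turnover (more replacements,
z = −516.0), and clumped range boundaries (MI = 8.32, p < 0.05) — distinct
communities replacing one another as groups along the gradient, which is
exactly the structure the generator built.

```r
res$brt$all_composition$influence[1:2, ]
#>         variable influence category
#> 1  chem_chloride 84.274588 chemical
#> 2 chem_nuisance2  3.671371 chemical
```

The boosted trees attribute the composition gradient to `chem_chloride` —
the variable the generator used as the driver — with 84.3% relative
influence, and explain 53.6% of cross-validated deviance; richness, which
the generator does not tie to the environment, stays near 0% (0.02%).
`reportBundle(res, "out/")` exports the EMS table, diversity tables,
BRT evaluations and influences as CSV plus a JSON run manifest.

For real data, `readAbundance("counts.csv")` (sites in rows, taxa in
columns) and `readSiteTable("sites.csv")` replace the simulation calls.

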