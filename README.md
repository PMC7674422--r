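# fossilcal

Fossil-calibrated clade-age priors and Bayesian node dating on fixed
topologies, for molecular-clock studies that must confront ambiguous fossil
assignments.

## The problem

Divergence-time estimation hinges on translating fossil first occurrences
into prior densities for clade ages. A fossil gives a hard minimum age, but
how much older the clade may be depends on how completely the fossil record
samples it. fossilcal derives that prior mechanistically: a clade
originating *t* Myr before its first record diversifies as a birth–death
process (net diversification *d* = λ − μ, turnover ε = μ/λ) and leaves
fossils along every lineage at sampling rate ψ per lineage per Myr. The
calibration density is

    f(t) = E[ ψ N exp(−ψ S(t)) | N ≥ 1 ],

with *N* the number of lineages alive at fossilisation and *S*(*t*) the
clade's total accumulated lineage duration — both stochastic outcomes of
the diversification process, estimated here by exact-event Monte Carlo.

When **two** fossils compete for the status of first record — a younger one
securely assigned, an older one questionably so — fossilcal builds a
weighted mixture prior: below the older fossil's age only the younger
component contributes (weight p_younger), above it both do
(p_younger f_younger + p_older f_older, weights summing to 1). The mixture
can be uni- or bimodal depending on the rates and the age gap.

On top of the priors, the package provides:

* a Metropolis–Hastings sampler over node ages on a fixed rooted topology
  (birth–death node-age prior × calibration densities, optional
  strict-clock GTR+Γ pruning likelihood in C++),
* trace summaries: effective sample size and 95% HPD intervals,
* a bimodality/convergence experiment with simulated fossil pairs,
* the deterministic marker-filter cascade used to select clock-like
  phylogenomic genes from precomputed ortholog metrics (relative bitscore,
  dN/dS, missing data, codon masking, GC heterogeneity, gene structure,
  and the permissive/strict gene-set thresholds),
* Newick/NEXUS tree I/O, YAML/JSON constraint files, TSV densities and
  traces, and a thin command-line wrapper (`inst/cli/fossilcal.R`).

## Worked example

The pufferfish order Tetraodontiformes has two candidate first records:
†Cretatriacanthus (89.8–83.0 Ma) and †Plectocretacicus (100.3–98.0 Ma),
with the younger considered twice as credible (weights 2/3 vs 1/3).

```r
library(fossilcal)
cfg  <- readConstraints(system.file("extdata", "tetraodontiformes.yaml",
                                    package = "fossilcal"))
cc   <- cfg$constraints[[1]]
dens <- mixtureCalibrationDensity(cc@fossils[[1]], cc@fossils[[2]],
                                  cfg$bd, nReps = 1e5, seed = 1)
dens
#> CalibrationDensity on [83.00, 347.82] Ma (1000 grid points), two-fossil mixture
#>   median 115.90 Ma, 95% equal-tail [89.00, 166.94] Ma

tr    <- timeTree(ape::read.tree(text = "(takifugu:100,mola:100);"))
cal   <- list(list(label = cc@cladeLabel, node = 3L, density = dens))
trace <- samplePrior(tr, cal, cfg$bd,
                     MCMCConfig(iterations = 1e5, thinning = 10, seed = 2))
traceSummary(trace)[, c("parameter", "mean", "hpdLow", "hpdHigh", "ess")]
#>      parameter    mean hpdLow hpdHigh  ess
#> 1 logPosterior  -4.363  -5.91  -3.824 4628
#> 2      rootAge 119.186  84.85 158.601 4757
#> 3    age_node3 119.186  84.85 158.601 4757
```

The prior density starts at the younger fossil's minimum age (83 Ma),
integrates to 1, and the prior-only MCMC on the calibrated node reproduces
it (the sampled mean of ~119 Ma and 95% HPD of roughly 85–159 Ma restate
the density through the chain). The vignette
(`vignettes/fossil-calibration.Rmd`) documents the model, the estimator,
and every tunable parameter.

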