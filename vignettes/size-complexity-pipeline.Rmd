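---
title: "Testing the size–complexity hypothesis with phylogenetic comparative methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the size-complexity hypothesis with phylogenetic comparative methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Ant colonies are superorganisms: reproduction is monopolized by queens while
workers perform the colony's tasks, and in some species the workers are
themselves divided into discrete physical castes (minors, majors, soldiers).
The *size–complexity hypothesis* proposes that larger colonies favour the
evolution of this division of labour, in analogy with the relationship
between body size and cell-type number in multicellular organisms. The
competing *genetic-variability* explanation proposes instead that higher
within-colony genetic diversity — from queens mating with several males
(polyandry) or colonies housing several queens (polygyny) — is what enables
caste polymorphism.

`antphylo` implements a complete, testable pipeline for distinguishing these
explanations with species-level comparative data: trait curation, Bayesian
phylogenetic mixed models (BPMMs), phylogenetic path analysis, correlated
evolution of paired binary traits by continuous-time Markov chain (CTMC)
models, and hidden-rate-model ancestral reconstruction — together with a
synthetic-data simulator whose known causal structure lets every stage be
validated by parameter recovery.

# Trait curation

One row per species is derived from literature-style observation rows:

* **Queen mating frequency** is aggregated by the *harmonic* mean. At low
  mating frequencies an extra mate changes within-colony relatedness much
  more than at high frequencies; the harmonic mean weights small values
  accordingly.
* **Colony size** is the arithmetic mean weighted by the number of colonies
  behind each estimate; estimates lacking a sample size contribute with unit
  weight rather than being discarded.
* **Worker size variation** is the coefficient of variation (CV) of worker
  head width: sd/mean, unit-free and scale-invariant. We use the sample
  (n−1) standard deviation; the convention is configurable
  (`worker_size_cv(..., sample_sd = FALSE)`).
* **Caste number** follows the morphometric coding rules: limited size
  variation or monophasic allometry imply one caste; distinct non-allometric
  scaling relationships are counted; otherwise the literature count is used.
* Species with derived life histories (supercolonies, social parasitism
  other than temporary social parasitism, thelytoky, gamergate reproduction,
  hybrid caste determination) are excluded as secondary reorganizations of
  the ancestral superorganismal state.

Colony size, mating frequency and queen number are log10-transformed; the
head-width CV is square-root transformed. Binary codings split colony size
at the median of the species entering the analysis (ties to "small"; 40th
and 60th percentile variants for sensitivity) and mating frequency at two
effective mates — the value at which mean worker relatedness is halfway
between its single-queen extremes. Every analysis uses the maximal
complete-case subset for its own variables rather than one globally complete
table.

# Correlated evolution of paired binary traits

Two binary traits (small/large colonies, single/multiple castes) evolve on
the tree as a 4-state CTMC over (0,0), (0,1), (1,0), (1,1). Double
transitions are forbidden. The *independent* model has 4 rates (each
trait's gain and loss); the *dependent* model has 8, conditioning each
single-trait rate on the other trait's current state. The likelihood is
computed by Felsenstein's pruning algorithm in C++; branch transition
matrices come from one eigendecomposition of the generator reused across
edges, with scaling-and-squaring as fallback for defective generators.
Ambiguous tips (one trait missing) enter with likelihood one over their
compatible states. The root uses a uniform prior over the four states by
default (configurable to the stationary distribution); tree rescaling by a
constant is exactly offset by inverse rate rescaling, which is why the
conventional ×0.001 branch rescaling for time-calibrated trees changes
nothing but the numeric range of the rates.

Rates carry an exponential prior whose mean is itself uniform on (0, 100)
— a hyper-prior that avoids committing to a rate scale — with a gamma
(shape 2) variant for prior-sensitivity checks. Two samplers target this
model:

* **Reversible-jump MCMC** adds per-rate on/off indicators so a transition
  can be *exactly* zero; proposing the reinstated rate from its prior makes
  the acceptance ratio collapse to the likelihood ratio. The fraction of
  visited models with a rate at zero estimates the posterior probability
  that the transition does not occur.
* **Stepping-stone sampling** estimates each model's log marginal
  likelihood along the power-posterior path with powers (k/K)^{1/0.4},
  which concentrates stones near the prior where the integrand changes
  fastest. The chain anneals from the posterior *down* to the prior: the
  hard direction (finding a concentrated data mode from a diffuse prior)
  never has to happen, which empirically cuts the estimator's variance by
  several fold at equal cost. Each stone mixes a full per-coordinate
  Metropolis sweep with occasional independence refreshes from the prior.

Support is summarized as BF = 2(log ml_dependent − log ml_independent),
with BF > 2 positive, > 5 strong and > 10 very strong evidence.

# Bayesian phylogenetic mixed models

The BPMM is y = Xb + a + e with a ~ N(0, V_A A), where A is the Brownian
covariance of the tree (shared root-to-ancestor path lengths), and
e ~ N(0, V_R I). Phylogenetic heritability is V_A/(V_A+V_R)×100. The
Gaussian family uses a blocked Gibbs sampler: fixed and random effects are
drawn jointly from their multivariate normal conditional, the variances
from conjugate inverse-Wishart (equivalently inverse-gamma) updates with
the (V = 1, ν = 0.002) default prior. Parameter-expanded variants
(Fisher: ν = 1, α.V = 1000; χ²: ν = 1000, α.V = 1) re-draw a working scale
parameter for the phylogenetic term and help poorly mixing
discrete-response chains. The Poisson log-link family augments a latent
log-rate per species updated by Metropolis-within-Gibbs; its
observation-level residual acts as additive overdispersion on the log
scale. Multi-tree uncertainty is handled by fitting per tree and pooling
the posterior draws before estimation; marginal R² is computed per draw as
var(Xb)/(var(Xb)+V_A+V_R) and reported as the median of per-tree medians
(per-tree values are also exposed). Point estimates are kernel-density
posterior modes with 95% highest-density intervals; pMCMC for a contrast is
the smaller one-sided proportion of paired draws. Sampler correctness is
pinned by closed-form GLS agreement at known variances and by the exact OLS
limit under an identity covariance; convergence is monitored with
autocorrelation-time effective sample sizes (warning below 300) and the
Gelman–Rubin statistic across independent chains.

# Phylogenetic path analysis

Four candidate causal models relate complexity (binary castes, or the
worker-size CV), colony size, mating frequency and queen number; all four
include queen_number → mating_frequency and colony_size →
mating_frequency. They differ in what drives complexity: (1) colony size
only; (2) complexity drives colony size; (3) both size and mating
frequency; (4) mating frequency only. Each model's d-separation basis set
has one claim per non-adjacent vertex pair, conditioned on the union of
both vertices' parent sets. The regression response is the topologically
deeper vertex (ties to the lexicographically later name); continuous
responses use our PGLS with Pagel's λ profiled by maximum likelihood on
[0, 1] (validated to machine precision against `nlme::gls` +
`ape::corPagel`), and binary-castes responses use a Laplace-approximated
logistic regression with a phylogenetic random effect whose variance is
profiled (at zero variance it is exactly ordinary logistic regression;
separation triggers a flagged ridge-penalized fit). Fisher's
C = −2Σ ln p is referred to χ² with 2k degrees of freedom;
CICc = C + 2qn/(n−1−q) with q the number of edges; weights
ω ∝ exp(−ΔCICc/2); models within 2 CICc of the best are the supported set.
Averaged path coefficients renormalize ω over the supported set, with
absent paths contributing coefficient and variance zero, and normal
approximation CIs from the averaged variances. Continuous variables are
z-scored first so coefficients are comparable across edges.

**An identifiability caveat that matters for interpretation**: candidate
models 1 and 2 share the same skeleton and the same single collider
(size → mating ← queens), so they are Markov equivalent — no test built
from conditional-independence claims can distinguish them, and on data
generated under model 1 the two models receive statistically equal support.
Model 4 (and to a lesser degree the over-parameterized model 3) is reliably
rejected. Distinguishing 1 from 2 requires information beyond conditional
independence — temporal order, interventions, or distributional asymmetries
— which the d-sep machinery does not use. The structure-recovery experiment
in the test suite documents this honestly: the size-driven model wins only
as often as its equivalence class allows.

# Hidden rate models and ancestral reconstruction

Caste evolution may speed up or slow down across the tree, so the binary
(or 1–4 count) character is modelled with hidden rate classes: the expanded
state is (observed state, rate class), observed transitions get per-class
rates under equal-rates, symmetric or all-rates-different structures, and
class switches preserve the observed state. We use a single shared
class-switch rate — a deliberate simplification that keeps the parameter
count low at the tree sizes we target. Models with 1–3 classes are fitted
by multi-start maximum likelihood on the expanded pruning likelihood and
compared by AICc per tree; across a tree sample the winner is the candidate
with the lowest AICc on the largest fraction of trees, ties toward fewer
parameters. Marginal ancestral probabilities come from the standard
up-pass/down-pass algorithm with hidden classes summed out; each node is
assigned its argmax state (an exact 0.5 tie goes to the single-caste state,
with a warning), and every internal node is classified: (1) single with all
descendants single, (2) single with at least one multiple descendant,
(3) multiple with all descendants multiple, (4) multiple with at least one
single descendant. An origin is an edge from a single-state parent to a
multiple-state child; the count is reported as a lower-bound-style summary
on the argmax assignments.

For the ancestral-value contrast (what was colony size just before
multiple castes evolved?), we fit the Gaussian BPMM to the tip values and,
at every retained iteration, draw the ancestral field at the internal nodes
from its exact conditional given the sampled tip-level effects, using the
node-inclusive phylogenetic covariance. Per iteration the node values are
regressed (intercept-free) on the four node categories, so the category
means carry the between-node scatter, and the category-1 vs category-2
contrast is summarized by pMCMC. We chose this construction over a fixed
category factor on latent node responses because the latter is not
identified: a category containing no tips contributes nothing to the
likelihood once its latent responses are integrated out, and its "estimate"
is prior noise. The calibration cost of our choice is modest and
quantified in the tests: with categories assigned at random to nodes of a
homogeneous Brownian trait, the contrast stays non-significant in roughly
80–90% of replicates (the residual anti-conservatism comes from
phylogenetic correlation among node values, which the per-draw regression
treats as independent scatter). Estimates are reported on the measurement
scale by back-transforming posterior summaries from log10.

# The synthetic-data generator

`generate_species_table()` produces a Yule tree (rescaled to unit height)
and a species table with a recorded truth object. The `paper_like` preset
emulates the empirical marginals: log-normal-like colony sizes anchored at
a median of 300 (the realized location is re-centred after simulation
because the phylogenetic mean itself drifts between tree realizations),
mating frequencies ≥ 1 with a point mass at single mating, queen numbers
with a point mass at one queen, and caste counts dominated by a single
caste. The causal presets (`size_complexity_true`, `mating_frequency_true`,
`null`) generate Gaussian log-scale traits with the stated effect structure
— queen number and colony size both drive mating frequency (effects 0.5 and
0.35) — and derive the binary castes trait from a tip-level logistic
liability on the driver (slope 1.6 on the z-scale, intercept −1.0, about
30% multiple-caste species). The transition-rate and ancestral-state
recovery experiments instead plant a conditioned gain process directly on
the tree: gains of the second trait are only possible while the lineage is
in the large class (gain 1.2–2.0, loss 0.15–0.8 per unit tree height,
mirroring the inferred transition diagram in which polymorphism arises only
in large-colony lineages and large size is rarely lost once polymorphic).

What the generator does *not* emulate: real taxon sampling and taxonomy,
the empirical tree's shape, measurement error in literature-derived traits,
and correlated missingness. Passing recovery tests therefore demonstrates
the estimators work under their assumptions at these problem sizes; they do
not certify the biological conclusions on real data.

# Numerical choices and test scale

Likelihood work is done in C++ (RcppArmadillo); optimization uses
multi-start Nelder–Mead on log rates (Brent for one-parameter models) with
rates below 1e−7 reported as boundary zeros. Covariance factorizations add
a 1e−8-scale ridge; zero-length branches yield identity transition
matrices; polytomies are handled natively by the pruning pass. Default
chain settings in code are test-scale (thousands of iterations); the
long-chain settings appropriate for real data (1.1M/11M iterations, burn-in
100k/1M, thinning 1000/5000, 32+ stones, 400 trees) are reachable through
the same arguments. The test and validation experiments use 60–300-tip
trees with 10–20 replicates per experiment and fixed seeds, sized so the
whole suite runs in minutes on one CPU; the acceptance script reruns the
full pipeline at n = 300–400 species from a single seed.

# Known limitations

* Models 1 and 2 of the candidate set are Markov equivalent (above); path
  analysis alone cannot orient the size–complexity edge.
* The d-sep logistic claims lose power when the binary trait is strongly
  phylogenetically clustered: the random effect can absorb a threshold-like
  signal (phylogenetic separation), which makes the test conservative.
* The stepping-stone estimate at desk-scale settings carries Monte-Carlo
  noise of a few BF units; borderline BFs near 2 should be re-run with more
  stones and iterations.
* The node-category contrast is mildly anti-conservative under random
  categories (phylogenetic correlation among node values), and hidden-rate
  classes are marginalized with a single shared switch rate.
* Tree samples are assumed rooted and time-calibrated; no attempt is made
  to infer, date or summarize trees.
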