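---
title: "Models and methods for quantifying cytoplasmic incompatibility from brood counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantifying cytoplasmic incompatibility from brood counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biological problem

Wolbachia and related endosymbionts spread through arthropod populations by
cytoplasmic incompatibility (CI): sperm from an infected male carries a
modification that derails early embryogenesis unless the egg is infected
too. In haplodiploid hosts such as the spider mite *Tetranychus urticae* —
where unfertilized (haploid) eggs develop into males and fertilized
(diploid) eggs into females — an incompatible fertilization has two possible
outcomes: the embryo dies (female-mortality CI, FM-CI) or it sheds the
paternal genome and develops into a viable haploid male (male-development
CI, MD-CI). A brood from an incompatible cross therefore shows fewer adult
daughters, and the deficit is split between dead eggs and surplus sons.

`cibrood` implements the statistical machinery for dissecting host
modulation of CI with a full diallel cross design: every female genotype
crossed to every male genotype, each pair measured once with an infected
male (incompatible cross) and once with an uninfected male (its compatible
control). Three per-brood proportions are modelled:

* `F` — adult females / eggs,
* `MD` — adult males / eggs,
* `FM` — eggs that produced no adult mite / eggs that did not become adult
  males.

# The binomial regression model

Each numerator is modelled as a binomial draw from its denominator with a
logit-linear predictor over the male infection state (`inf`), male genotype
(`mgeno`), female genotype (`fgeno`) and their interactions, plus a
zero-mean random intercept for the day cohort on which a replicate was set
up:

$$y_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
\mathrm{logit}(p_i) = \mathbf{x}_i^\top\beta + u_{day[i]}, \qquad
u_j \sim \mathcal{N}(0, \sigma_{day}^2).$$

Priors are weakly informative on the logit scale: $\mathcal{N}(0, 3)$ for
the intercept, $\mathcal{N}(0, 1.5)$ for all other coefficients, and
half-$\mathcal{N}(0, 1)$ for $\sigma_{day}$. A unit step on the logit scale
is a large effect for proportions, so these priors regularize without
constraining any plausible effect; the exact choice matters little at the
replication levels of a diallel experiment. Sampling uses JAGS (two chains
of 5,000 iterations, the first 1,000 discarded as warmup, by default), and
every fit reports rank-normalized split-$\widehat{R}$ and bulk effective
sample size per parameter, flagging the fit when any parameter exceeds
$\widehat{R} > 1.01$ or falls below ESS 400. Rows with a zero denominator
for the modelled response carry no likelihood information and are dropped
from that fit only.

# Corrected indexes

Raw proportions confound CI with nuclear background, fertilization rate and
day effects. The corrected indexes therefore compare each incompatible
cross with the compatible control of the *same* genotype pair, using the
model's population-level predictions (day intercepts excluded):

$$CI_{corr} = 1 - F_{obs}/F_c, \qquad
MD_{corr} = \frac{MD_{obs} - MD_c}{1 - MD_c}, \qquad
FM_{corr} = \frac{FM_{obs}(1 - MD_{corr}) - FM_c}{1 - FM_c}.$$

All three are computed per posterior draw and only then summarized (mean
and the 9/50/91 posterior percentiles); ratios of posterior summaries would
understate the uncertainty. Values outside $[0, 1]$ are reported unclipped —
a negative $CI_{corr}$ is evidence that the incompatible cross outperformed
its control, not an error. Because `MD` and `FM` are fitted in separate
models, the $MD_{corr}$ draws enter the $FM_{corr}$ formula by sample
position; absent a joint model this positional coupling is the only
coherent way to propagate their dependence, and it is exact whenever the
two posteriors are (approximately) independent.

# What the simulator generates — and what it omits

`simulate_diallel()` draws brood counts from an explicit generative chain:
egg counts are negative-binomial (leaf-disc totals overdisperse relative to
Poisson); each egg is fertilized with probability `fert` (default 0.7, a
typical daughter fraction for mated *T. urticae* females); a fertilized egg
in an incompatible cross is CI-affected with probability `theta` and an
affected egg becomes a candidate male with probability `phi` (the MD route)
or dies (the FM route); every candidate survives to adulthood with
probability `1 - base_mort` (default 0.05). Day effects shift fertilization
and survival on the logit scale with standard deviation `day_sd` (default
0.3, a mild cohort effect); defaults of 8–11 replicates per cross and a
mean of 80 eggs per replicate mirror a five-female leaf disc scored over
five days. Rescue crosses (infected females) behave as compatible: the
modification is ablated.

In the zero-mortality limit the generative expectations are
$F_{obs} = f(1-\theta)$, $F_c = f$, $MD_{obs} = (1-f) + f\theta\phi$,
$MD_c = 1-f$, $FM_{obs} = \theta(1-\phi)/(1-\theta\phi)$, $FM_c = 0$.
Substituting them into the index formulas makes the fertilization rate
cancel and yields

$$CI_{corr} = \theta, \qquad MD_{corr} = \theta\phi, \qquad
FM_{corr} = \theta(1-\phi),$$

so $CI_{corr} = MD_{corr} + FM_{corr}$ exactly. `closed_form_indexes()`
performs this substitution numerically and anchors the recovery tests: on
large simulated designs both the plug-in (pooled-count) and posterior-mean
indexes converge to $(\theta, \theta\phi, \theta(1-\phi))$.

The simulator is deliberately simpler than reality: no within-host
Wolbachia density dynamics, perfect maternal transmission, no
sex-differential mortality, no multi-generation dynamics, and day effects
that act symmetrically on fertilization and survival. Passing recovery
tests therefore show that the estimation pipeline is faithful to this
generative model, not that the model captures every feature of real brood
data (e.g. brood-level overdispersion beyond the day structure would make
the plain-binomial models overconfident).

# Model comparison and variance attribution

Four fixed-effect variants — `inf`, `inf*mgeno`, `inf*fgeno`,
`inf*mgeno*fgeno`, all with day intercepts — are compared by WAIC computed
from pointwise posterior log-likelihoods with the log-sum-exp
stabilization; the standard error of a WAIC difference uses the pointwise
contrasts against the best model. To rank the explanatory variables on a
common scale, `finite_population_sd()` reconstructs, per posterior draw and
per model term, the complete vector of per-level effects (reference cells
are exact zeros under treatment coding), centers it, and takes the standard
deviation with denominator $J - 1$ over the $J$ level combinations of the
term; the day group uses the sampled day intercepts. This finite-population
summary asks how much the *realized* levels differ, which is the relevant
question for a designed panel of genotypes, and is invariant to the choice
of reference level.

# Segregation analysis of a maternal modifier

The inheritance experiment asks whether the maternal modifier that switches
the CI phenotype from FM to MD is a single recessive locus. Heterozygous F1
females (reciprocal crosses between the modifier line and a non-modifier
line) are backcrossed to modifier-line males; each F2 female is then
homozygous at each modifier locus independently with probability 1/2. Under
`k` unlinked recessive loci that are all required, the expected fraction of
F2 females expressing the extreme MD phenotype is $0.5^k$ — 0.5 for a
monogenic trait. `simulate_inheritance()` generates this design (single
female broods, ~40 eggs over seven days, no day structure, because single
pairings cannot separate a day effect from the female).

The per-brood male counts of the incompatible F2 crosses are fitted with an
ordered two-component binomial mixture,

$$y_i \sim w\,\mathrm{Bin}(n_i, p_{hi}) + (1-w)\,\mathrm{Bin}(n_i, p_{lo}),$$

with $w \sim \mathrm{Uniform}(0,1)$ and the component probabilities built
from a base logit and a strictly positive increment (both with
$\mathcal{N}(0, 1.5)$ priors on the unconstrained scale), so
$p_{lo} < p_{hi}$ holds in every draw by construction and $w$ always refers
to the high-MD component — label switching is impossible rather than
corrected post hoc. `test_monogenic()` summarizes the posterior of $w$,
reports whether 0.5 lies inside the 9–91 percentile interval, and ranks the
candidate expectations $0.5^k$. The mixture is fitted separately by
maternal origin and pooled, since the modifier segregates only through one
parental line.

One honest caveat: when the data contain a single cluster (no modifier
segregating, or `phi_high = phi_low`), the likelihood cannot decide which
component carries the data, and the posterior of $w$ becomes diffuse rather
than collapsing to 0. The ordering constraint prevents label switching but
cannot identify an empty component. The weight is therefore interpretable
only when both components are populated; the convergence flags and the
width of the 9–91 interval of $w$ are the practical guards, and
`test_monogenic()` declines to rank hypotheses when every brood has exactly
the same MD value.

# Numerical and design choices

* **Sampler.** JAGS with the `glm` module (block updates for
  binomial-logit GLMs). The convergence contract — $\widehat{R}$, ESS,
  flags — is sampler-agnostic.
* **Coding.** Treatment contrasts with the alphabetically first level as
  reference; indexes depend only on predicted proportions and are
  coding-invariant, and the finite-population SDs include reference cells
  as zeros so they are too.
* **Degenerate draws.** A compatible-cross prediction of exactly 0 (for
  `F`) or 1 (for `MD`/`FM`) would make an index undefined; these raise
  errors naming the cross rather than producing silent infinities. On the
  logit scale such draws do not occur unless the data are themselves
  degenerate.
* **Zero-egg broods.** Retained in data files (they document effort) but
  excluded from every likelihood: a binomial with zero draws carries no
  information.
* **Problem sizes in the test suite.** Recovery and comparison tests run
  on designs of 2–5 genotypes with 6–60 replicates per cross and shortened
  chains (700–3,000 iterations); these sizes were chosen so that each
  check's tolerance sits at 3 standard errors or more of its Monte-Carlo
  noise. The package defaults remain the full experimental scale.

# Reading the outputs

`estimate_ci_indexes()` returns per-pair posterior summaries with the mean
and the 9/50/91 percentiles used throughout (`autoplot()` draws them as
point-ranges ordered by CI strength, colored by male genotype, echoing the
field's standard presentation). `compare_ci_models()` returns the WAIC
table with differences and difference-SEs against the best model, and
`finite_population_sd()` the per-term variance attribution.
`pipeline_all()` runs the whole chain from a YAML config and writes
manifests sufficient to reproduce every command from the config and seed
alone.
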