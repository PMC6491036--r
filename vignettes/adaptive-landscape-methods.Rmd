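---
title: "Adaptive-landscape analysis of foot proportions: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-landscape analysis of foot proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pedapt)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, the numerical choices,
and — importantly — what the synthetic-data tests do and do not establish
about real data.

## The question and the data

Linear proportions of the foot skeleton (tarsal, metatarsal, and phalangeal
lengths) covary with locomotor behavior across anthropoid primates:
terrestrial quadrupeds, heel-strike plantigrade apes, suspensory and
climbing specialists, and bipedal humans occupy different parts of shape
space. The package implements the full chain of inference that turns a
per-individual measurement table, a time-calibrated phylogeny, and a set of
verbal locomotor hypotheses into (i) a morphospace, (ii) a ranked family of
adaptive-landscape models, and (iii) credibility intervals for ancestral
morphologies such as the *Homo–Pan* last common ancestor. A fossil tip
participates as data throughout: it is grafted into the tree at its known
age (a stem lineage with a 1.4-Myr terminal branch ending 4.4 Ma in the
packaged configuration) and all covariances use its true, non-contemporaneous
depth rather than forcing ultrametricity.

## Morphometrics

Six variables enter every analysis: talar trochlea length, talar *neck*
length (maximum talar articular length minus trochlea length — the
subtraction is the only derived measurement), cuboid, MT1, MT5, and PP4
lengths. Each individual's six values are divided by their geometric mean,
so the product of the standardized values is exactly 1 per individual and
the representation is invariant to overall size. PCA is computed on the
*covariance* matrix of the standardized variables (their variances are
informative and on a common dimensionless scale; correlation-based PCA
would discard the relative-variance structure). Loading columns are signed
so that each column's largest-magnitude entry is positive, which fixes the
reflection ambiguity reproducibly. The PCA is fitted at the individual
level, fossil included; per-taxon mean scores feed all phylogenetic stages.
UPGMA clustering uses Euclidean distances between per-taxon mean
standardized variables, with ties broken by lowest pair index (the
`stats::hclust` convention), and the cophenetic correlation measures how
faithfully the dendrogram represents the underlying distances.

## The Hansen model and its implementation

Trait change along a branch painted with regime $k$ follows
$dX = \alpha(\theta_k - X)\,dt + \sigma\,dB$. Conditional on the root
state, tip means are $W(\alpha)\,\theta$ where $W$ integrates
$\alpha e^{-\alpha (T_i - t)}$ over each lineage's regime history (the
residual weight $e^{-\alpha T_i}$ is assigned to the root regime's column:
the *root-at-optimum* convention, standard in OUCH-style fits, avoiding an
extra unidentifiable root parameter). Tip covariances are
$\frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}(1 - e^{-2\alpha s_{ij}})$ with
$s_{ij}$ the shared time and $d_{ij}$ the patristic separation; the
$\alpha \to 0$ limit is Brownian motion. Traits (the first three PCs) are
fitted as independent univariate processes sharing one painting, with
log-likelihoods summed — the multivariate-\(\alpha\) Hansen model is out of
scope, and the independent-axes treatment keeps all hypotheses comparable
on the same parameter-counting convention.

**Profiling instead of joint optimization.** For fixed $\alpha$, the
optima $\theta$ are a GLS estimate and $\sigma^2$ has a closed-form ML
value, so the entire fit reduces to a deterministic one-dimensional search
over $\alpha$: an 18-point log-spaced grid on $[10^{-4}, 50]\,\mathrm{Myr}^{-1}$
followed by local refinement (`stats::optimize`, tolerance $10^{-6}$ on
$\log\alpha$). This is exactly the ML solution a 2-D quasi-Newton search
over $(\log\alpha, \log\sigma^2)$ would find, with no convergence or
multi-start concerns; determinism matters because the parametric-bootstrap
power analysis refits models thousands of times and must be bit-reproducible
under a seed. The upper bound $\alpha \le 50/\mathrm{Myr}$ excludes
degenerate white-noise fits (half-life < 0.014 Myr on a 40-Myr-deep tree);
a regime whose discounted weight underflows at large $\alpha$ is dropped
from the GLS solve and reported with a warning as unidentifiable.

**Parameter counting.** Per trait: 2 ($\alpha$, $\sigma^2$) + K optima for
a Hansen model, 2 (rate, root) for Brownian motion; counts are summed over
traits and AICc uses $n$ = number of taxa. Both conventions are explicit
choices (`infoCriteria()`), since several defensible alternatives exist.

**The hypothesis family.** `buildHypotheses()` encodes six nested
hypotheses: H1 Brownian motion; H2 one global optimum; H3 adds advanced
bipedalism (*Homo*) and terrestrial quadrupedalism (*Pan*, *Gorilla*,
*Papio*, *Theropithecus*, *Erythrocebus*, *Chlorocebus*) against an
arboreal background; H4 splits terrestrial into heel-strike plantigrady
(*Pan*, *Gorilla*) versus semiplantigrady (the terrestrial
cercopithecines); H5 adds a climbing/hindlimb-suspension regime (*Pongo*,
*Ateles*, *Alouatta*, *Lagothrix*); H6 separates active climbing
(hylobatids, *Alouatta*, *Lagothrix*) from suspension (*Pongo*, *Ateles*).
Three genuinely open details are resolved as explicit, switchable settings:
the fossil's regime in H3–H6 defaults to the African-ape regime of each
hypothesis (`fossil_regime`); *Lagothrix* defaults to the climbing regime
in H6; hylobatids other than *Hylobates* and *Symphalangus* (i.e.
*Hoolock*) travel with the hylobatid clade. A clade's regime includes its
stem branch, so a shift happens at the origin of the clade. The *Homo*
terminal branch may be shortened (default 0.1 Myr in the pipeline) so the
single-taxon bipedal optimum is pinned by *Homo*'s trait value rather than
being nearly unidentifiable at the end of an 8-Myr branch; the tree used
for pGLS and ancestral estimation keeps the original branch.

## Stepwise regime discovery

`surfaceForward()` starts from a single optimum and tries a shift at the
origin of every branch, scoring candidates by AICc on a shared 12-point
$\alpha$ grid (covariances and whitened data are cached per $\alpha$, so a
full sweep is one matrix solve per candidate) and refining the best
candidate with the full search before accepting. Any AICc improvement
accepts (threshold configurable); ties go to the branch closest to the
root, then to branch index. `surfaceBackward()` greedily merges regime
pairs (including back into the basal regime) while AICc improves, and
reports convergent evolution when independent shifts collapse onto one
optimum ($k' < k$). The known tendency of this family of algorithms to
overfit on low-dimensional data is real: with a single trait the AICc cost
of one extra optimum (~2–3 units) is routinely exceeded by the maximum of
dozens of candidate-branch likelihood gains even on structureless data.
With the study's three trait axes each shift costs three optima and the
small-sample AICc correction grows quickly, which is what keeps the
false-positive rate low; the package's null-behavior tests therefore run at
the study's dimensionality (three traits), and simulation-based corrections
beyond AICc are deliberately out of scope.

## Monte-Carlo power analysis

`powerCompare()` fits two candidate models to the data, simulates
`n_sims` datasets from each fitted model (exact Gaussian draws — mean from
the weight matrix, covariance from the OU form — never an Euler scheme),
refits both models to every dataset, and forms two distributions of
$\delta = -2(\log L_0 - \log L_1)$. Power is the fraction of the
B-generated distribution exceeding the 95th percentile of the A-generated
(null) distribution; the empirical $\delta$'s position indicates which
model the data support. The study-scale default is 1000 replicates per
model; tests run at 100. Because refits use the same deterministic
profiled optimizer as the original fits, $\delta$ distributions are exactly
reproducible under a seed — with one corollary worth stating plainly:
comparing a model specification *against itself* yields bitwise-equal
log-likelihoods, so every replicate's $\delta$ is exactly zero and the
reported power is 0, not the nominal 5% that would arise if $\delta$ had a
continuous distribution. The nominal-level property that is actually
meaningful — the empirical $\delta$ of data generated under model A falls
below the null 95th percentile in ≈95% of meta-replicates — is what the
calibration tests exercise.

## Ancestral states

`bmAncestral()` conditions the joint Gaussian of all node states on the
tips, with the root state and rate estimated by ML and the conditional
variance inflated by the root-estimate uncertainty (universal-kriging
form); intervals are Gaussian. `stableMcmc()` replaces Gaussian increments
with symmetric alpha-stable increments: the change along a branch of
length $t$ is stable with index $a \in (1, 2]$ and scale $c\,t^{1/a}$, so
$a = 2$ recovers Brownian motion with rate $2c^2$ and smaller $a$ gives
heavy tails that let a single lineage absorb an exceptional divergence
instead of inflating the global rate — damping the "averaging effect" that
pulls Brownian estimates toward phenotypically derived tips. This
parameterization (location 0, scale $\propto t^{1/a}$, one global $c$ and
$a$ per trait) is the package's own documented choice; it is validated in
its Gaussian limit against the closed-form Brownian solution rather than
against any external executable.

The sampler is Metropolis-within-Gibbs: internal nodes are two-colored by
depth parity and each color class is proposed and accepted per-node in
vectorized sweeps (no two nodes in a class share a branch); the scale
moves on the log axis under a log-uniform prior on $[10^{-6}, 10^3]$
(bounded away from zero so rates cannot collapse); the index moves by a
reflecting random walk under a uniform prior on $(1, 2]$. Proposal scales
adapt toward 20–40% acceptance during the first third of iterations only,
preserving detailed balance afterwards. The alpha-stable density is
evaluated from a precomputed inversion-integral table (trapezoid rule on
$f(z) = \pi^{-1}\int_0^\infty \cos(tz)e^{-t^a}dt$, bilinear interpolation
in $(a, z)$, Pareto-tail continuation beyond $z = 30$, closed forms at the
Cauchy and Gaussian endpoints). Node estimates are posterior *medians*
with per-axis 2.5/97.5% quantiles pooled across chains after burn-in —
the credibility "box" around a focal node is the product of per-axis
marginal intervals, not a joint region. Convergence is summarized by the
Gelman–Rubin PSRF per monitored parameter, floored at 1 so identical
chains report exactly 1; runs with any PSRF > 1.2 are flagged (and still
returned). Model comparison uses a DIC-family predictive criterion with a
doubled effective-parameter penalty,
$\mathrm{BPIC} = -2\,\overline{\log L} + 2 p_D$ with
$p_D = 2(\log L(\bar\theta) - \overline{\log L})$ evaluated at posterior
means and summed over traits; lower is preferred, and differences below 2
are reported as ties.

The study-scale protocol is 2,000,000 iterations, thinning 200, burn-in
600,000, two chains; the test suite runs 20,000/20/6,000 (and
4,000/10/1,200 inside the 100-replicate coverage study). These test scales
are the package's documented test conditions: long enough for PSRF < 1.1
and stable quantiles on 45-taxon problems, short enough to iterate on.

## What the synthetic generator does and does not emulate

`studyFixture()` regenerates, bit-identically from (scenario, seed): the
packaged 45-taxon tree (44 extant anthropoids with plausible divergence
times and clade structure mirroring hominoids, cercopithecoids, and
platyrrhines — an explicitly synthetic stand-in, *not* the published
molecular consensus), the H1–H6 paintings, three latent trait axes
simulated under the chosen generating hypothesis (defaults: $\alpha = 2$,
$\sigma^2 = 1$, optima separated by several stationary standard deviations
$\sqrt{\sigma^2/2\alpha} = 0.5$ — a strong but not caricatural adaptive
signal), per-taxon body masses from Brownian motion on the log scale
(root 8 kg, rate 0.04/Myr, spanning roughly 0.5–100 kg), and individual
measurements built as mass$^{b_v}$-scaled shape components times lognormal
noise (sd 0.06; exponents 1/3 for the trochlea and 0.30 elsewhere, giving
the slight negative allometry seen in comparative scaling data). The
fossil's traits are generated from the African-ape regime, so the fixture
reproduces the qualitative headline — the fossil clusters with the
terrestrial-plantigrade taxa — as a smoke test of the machinery, not as a
scientific claim.

What passing tests on this fixture establish: the estimators recover known
generating parameters, the model-selection machinery identifies generating
regimes at documented effect sizes, the credibility intervals have nominal
coverage, and every file-format boundary round-trips. What they do not
establish: anything about real measurement error structure, intraspecific
covariance, topological uncertainty, or the actual values of anthropoid
foot proportions — the generator matches statistical structure, not
millimeters.

## Numerical choices and degenerate inputs

- OU covariances use `expm1` so the $\alpha \to 0$ limit is smooth; below
  $\alpha = 10^{-9}$ the Brownian form is used directly.
- Pagel's λ is applied in covariance space (off-diagonal scaling), keeping
  fossil-tip variances exact; λ > 1 is admitted only while the matrix
  stays positive definite.
- Zero-length branches (from polytomy resolution) are floored at
  $10^{-8}$ Myr inside the MCMC so increment scales stay positive.
- Duplicate taxa in UPGMA merge at height 0 with a warning; a distance
  matrix with zero spread flags the cophenetic correlation as undefined.
- The pGLS excludes tips lacking data (e.g. a fossil without a literature
  body mass) with a warning naming them; p-values use $t_{n-2}$,
  two-tailed, and λ boundary flags come from likelihood-ratio tests
  against $\chi^2_1$.

## Known limitations

Single-rate, independent-axes OU models only (no multivariate $\alpha$ or
$\sigma$ matrices, no measurement-error variance per species, no moving
optima); SURFACE inherits the stepwise family's overfitting tendencies on
low-dimensional data; the stable model treats traits independently and
estimates one scale and one index per trait; BPIC is a plug-in predictive
estimator, not a marginal-likelihood method.
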