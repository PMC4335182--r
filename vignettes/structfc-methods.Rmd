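---
title: "Jointly modeling functional and structural brain connectivity with StructFC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jointly modeling functional and structural brain connectivity with StructFC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StructFC)
```

## The model

StructFC infers functional connectivity (FC) between pairs of brain regions
from fMRI joint-activation counts, using structural connectivity (SC) from
probabilistic diffusion tractography as prior information. The premise is
empirical: region pairs with strong white-matter linkage tend to show higher
functional coherence, but SC is a static property while FC is task-dependent,
so the structural information should inform — not dictate — the functional
estimate.

For each region pair, each subject's activity series are dichotomized into
elevated / non-elevated states (`dichotomize()`: state 1 when the
mean-adjusted signal exceeds $c\,\hat\sigma$, default $c = 0.01$), and the
two indicator series are cross-tabulated into 4-category counts
$Z = (Z_1, \ldots, Z_4)$: both active, first only, second only, neither
(`jointActivationCounts()`). Counts are rescaled to a common unit of
$T = 100$ scans by largest-remainder allocation so they stay integers summing
to $T$. Tractography gives each pair a success count $S$ out of $M = 1000$
scaled trials.

The hierarchy is

$$Z_n \mid \theta \sim \mathrm{Multinomial}(T, \theta), \qquad
  S_n \mid \pi \sim \mathrm{Binomial}(M, \pi),$$
$$\pi \sim \mathrm{Beta}(\alpha_0, \beta_0), \qquad
  \theta \mid \pi \sim \mathrm{Dirichlet}\!\big(\alpha(\pi) + \alpha_1,\;
  \alpha_2,\; \alpha_3,\; \alpha_4\big),$$

independently across the $n = 1, \ldots, N$ subjects. The structure–function
coupling lives entirely in the link $\alpha(\pi)$, an increasing function
placing extra prior weight on joint activation ($\theta_1$) when the
structural connection probability is high. The default is
$\alpha(\pi) = C\,(10^\pi - 1)$ with $C = 10 / (9/\ln 10 - 1) \approx
3.438026$, fixed by two constraints: the average of $\alpha(\pi)$ over
$[0,1]$ is 10 (so the total prior mass matches the $\alpha_i$ scale of the
defaults $\alpha_1 = 5$, $\alpha_2 = \alpha_3 = \alpha_4 = 10$), and at
$\pi = 1$ the prior mean of $\theta_1$,
$(\alpha(\pi)+\alpha_1)/(\alpha(\pi)+\sum_i \alpha_i)$, is about $0.5$ —
roughly the largest plausible maximum-likelihood value of $\theta_1$:

```{r link}
lk <- linkFunction()
alphaLink(c(0, 0.5, 1), lk)
integrate(function(p) alphaLink(p, lk), 0, 1)$value
priorMeanTheta1(c(0, 1))
```

Setting the link to a constant severs the coupling and makes the posterior a
product of conjugate Beta and Dirichlet distributions — the basis for the
closed-form sampler checks below, and for the functional-only comparator
(`fcOnlyPosterior()`), which replaces $\alpha(\pi)$ by its average
$\bar\alpha = 10$ so both methods carry equal total prior mass.

## Coherence and ascendancy

Functional coherence is a chance-corrected agreement statistic in the spirit
of Cohen's kappa:

$$\kappa = \frac{\theta_1 + \theta_4 - E}{1 - E}
  \;\text{ if } \theta_1\theta_4 > \theta_2\theta_3, \text{ else } 0,
  \qquad
  E = (\theta_1+\theta_2)(\theta_1+\theta_3) +
      (\theta_3+\theta_4)(\theta_2+\theta_4),$$

restricted to $[0, 1]$ ($\kappa = 0$ whenever agreement does not exceed
chance, i.e. the odds ratio is at most 1). Ascendancy compares the marginal
activation odds of the two regions,

$$\tau_{ab} = \frac{(\theta_1+\theta_2)/(\theta_3+\theta_4)}
                   {(\theta_1+\theta_3)/(\theta_2+\theta_4)},$$

with $\tau_{ab} > 1$ meaning region $a$ is ascendant (more readily active)
— the basis for edge direction. Swapping the regions swaps $\theta_2
\leftrightarrow \theta_3$, leaving $\kappa$ unchanged and inverting $\tau$.
Both statistics are evaluated per retained posterior draw of $\theta$ and
then summarized; they are never computed from the posterior-mean $\theta$,
which would understate their posterior uncertainty.

## Posterior sampling

`runPairChain()` runs a Gibbs sampler with an embedded Metropolis step:
$\theta$ is drawn exactly from its Dirichlet full conditional
(`conditionalThetaParams()`), and $\pi$ is updated by a Normal random-walk
proposal accepted by the ratio of full conditional densities
(`logConditionalPi()`, evaluated in log space with `lgamma`; proposals
outside $(0,1)$ have zero density and are rejected). Defaults are 10000
iterations after 2000 burn-in, thinned by 10; the simulation studies use
2000 + 500. The proposal scale starts at $2.4$ times the approximate
conjugate posterior standard deviation of $\pi$ and is adapted in batches of
50 during burn-in only (vanishing adaptation toward 25% acceptance), then
frozen so the retained chain has the correct stationary distribution.
Initialization: $\pi^0$ at its approximate conjugate posterior mean,
$\theta^0$ from its full conditional. The inner loop is compiled (Rcpp) and
uses R's RNG, so results are bit-reproducible under a seed; `fitAllPairs()`
derives each pair's seed from the base seed and pair index, making
whole-brain runs independent of processing order.

Sampler correctness is tested two ways: with a constant link the chain's
moments must match the conjugate Beta/Dirichlet closed forms within three
autocorrelation-aware Monte-Carlo standard errors, and under the default
link simulation-based calibration over 200 prior-predictive replicates must
give uniform ranks of the true $(\pi, \theta_1)$ within their posterior
samples ($\chi^2$ test at $\alpha = 0.01$).

## Edge calls and networks

A pair is *connected* when $P(\kappa > e_\kappa \mid Z, S) > p_\kappa$ with
$e_\kappa = 0.4$ (moderate agreement) and $p_\kappa = 0.5$. Given
connection, the pair is *directed* when $P(\tau > e_\tau \mid Z, S) >
p_\tau = 0.5$, evaluated on the orientation whose posterior-mean $\tau$ is
at least 1. No external standard exists for $e_\tau$; by default it is the
median of the orientation-normalized posterior-mean $\tau$,
$\max(\bar\tau, 1/\bar\tau)$, over the connected pairs. Pooling over
connected pairs (rather than all pairs) was chosen because ascendancy is
only defined for functionally connected pairs; normalizing the orientation
makes the threshold independent of which region of a pair was stored first.
Exceedance uses a strict inequality — immaterial for continuous samples,
fixed for determinism.

`buildBrainNetwork()` turns edge calls into undirected (connection) or
directed (ascendancy) graphs, and `networkMetrics()` computes the clustering
coefficient $C$, characteristic path length $L$, a degree-matched random
null, the small-world index $\sigma = (C/C_{\mathrm{random}}) /
(L/L_{\mathrm{random}})$, and hubs. Conventions where the formulas leave
room:

* directed clustering uses $C_i = E_i / k_i(k_i-1)$ with $k_i$ the size of
  the union of in- and out-neighborhoods and $E_i$ the number of directed
  links among those neighbors, each counted once — this keeps $C_i \le 1$
  and gives a directed 3-cycle $C = 1/2$; nodes with fewer than two
  neighbors contribute $C_i = 0$;
* $L$ averages shortest-path lengths over ordered reachable pairs,
  excluding unreachable pairs;
* the null preserves the exact degree sequence via double edge swaps
  (10 successful swaps per edge, self-loops and multi-edges rejected;
  in/out degrees preserved when directed), with 1000 realizations by
  default;
* hubs are nodes whose (total / out- / in-) degree strictly exceeds the
  network mean plus one population standard deviation, so a regular network
  has none.

## What the synthetic-data generator does and does not emulate

`simulatePairDataset()` draws from the hierarchy exactly as written:
$\pi$ from its Beta prior, $\theta$ from the linked Dirichlet, then
multinomial and binomial counts. This is the model's own data-generating
process, so the simulation studies measure estimator behavior *when the
model is true*. Real fMRI/DTI data depart from it in ways the generator
does not emulate: temporal autocorrelation surviving pre-whitening,
between-subject heterogeneity in $\theta$ and $\pi$ (the model pools one
$\theta$ per pair), distance- and geometry-dependent tractography biases,
and the upstream choices of parcellation and voxel summarization. Passing
tests therefore establish internal correctness and the value of the
structural prior under the stated hierarchy, not robustness to those
departures.

The correlation-correspondence study (`kappaRhoStudy()`) is the partial
exception: it generates bivariate-normal activity series (variances 0.2,
matching what regional fMRI profiles typically show after standardization)
whose implied cell probabilities equal a target $\theta$, exercising the
full dichotomize–count–fit pipeline on continuous data.
`solveBivariateParams()` inverts the thresholds from the marginal
probabilities and finds the correlation by monotone root finding on the
bivariate-normal orthant probability (conditional-Gaussian quadrature,
tolerance $10^{-8}$).

## Simulation-study designs and replication

The bias study (`runBiasStudy()`) follows the published grid of structural
priors $(\alpha_0, \beta_0) \in \{(1,100), (2,18), (2,5), (2,2), (5,2),
(18,2)\}$ and sample sizes $N \in \{15, 30, 100\}$, reporting the mean
absolute deviation of the posterior mean from the truth. The package default
is a scaled-down replication — 10 draws of $\pi$, 5 of $\theta$ per $\pi$,
20 datasets per $\theta$, chains of 2000 + 500 — which resolves the
published cells to within a few percent while a cell runs in seconds; the
full design (10 × 10 × 100, chains 7000 + 2000) is a parameter change away.
Because datasets are nested within $(\pi, \theta)$ draws, the Monte-Carlo
standard error of a cell mean is computed across the $\pi$ clusters, not
across datasets; the flat SE would understate the error several-fold. Sample
sizes share common random numbers (nested subject subsets of the same
datasets), so comparisons across $N$ are paired.

The sensitivity study (`runSensitivityStudy()`) generates from one link and
fits with others, over the four families $g(10)$, $f(1.5)$, $f(0.5)$,
$g(0.01)$ — exponential $g(b)(\pi) = C_b(b^\pi - 1)$ and power
$f(p)(\pi) = 10(p+1)\pi^p$, all normalized to integral 10 so the prior mass
of the coupling is held fixed. Its bias metric is the sum over components of
the absolute *mean signed* bias of the posterior-mean $\theta_i$ across
datasets, per $\theta$ draw: with matched generate/fit links the signed bias
averages toward zero, so this statistic isolates the systematic distortion a
wrong link would introduce. It is replication-dependent by construction
(noise-dominated when links match); the defaults — 10 $\theta$ draws, 100
datasets each, $N = 30$ subjects — mirror the bias study's per-$\theta$
replication, with $N$ set to the middle of the study's sample sizes.

## Numerical choices and degenerate inputs

* All densities are computed in log space; $\theta_i = 0$ against a positive
  count yields $-\infty$, not an error.
* Rescaled multinomial counts use largest-remainder rounding (ties to the
  lowest cell index) so they are integers summing exactly to $T$; averaged
  structural counts are rounded to the nearest integer and clamped to
  $[0, M]$ for the binomial likelihood.
* Constant (zero-variance) regional profiles become all-zero indicator
  series flagged as degenerate, keeping pair bookkeeping rectangular
  instead of dropping regions mid-pipeline.
* The regional summary `extractDominantProfile()` returns the first
  singular vector in the time domain, sign-aligned with the voxel-mean
  signal (or a supplied reference), since singular vectors are defined only
  up to sign.
* Quantiles of voxel-level tractography counts use linear interpolation
  between order statistics (the common default in scientific software).
* Pairs with no structural data can either error or fall back to a flat
  Beta prior on $\pi$ with a constant link — a logged, explicit choice, not
  a silent default.

## Known limitations

Tractography itself, parcellation, task-involved-voxel selection and image
preprocessing are upstream of this package: inputs are regional profiles
(or voxel matrices already subset to a region) and region-level tract-count
matrices. The distance adjustment of tractography counts sometimes applied
upstream (e.g. zero-inflated Poisson regression on inter-region distance)
is not implemented — its output feeds in as pre-adjusted matrices. One
$\theta$ per pair is shared across subjects; subject-level random effects
are outside the current model. Alternative chance-corrected agreement
statistics (Scott's $\pi$, Fleiss' kappa) and centrality/community metrics
are deliberately out of scope.
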