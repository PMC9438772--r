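---
title: "Modelling amplification bias in multi-template PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling amplification bias in multi-template PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrbias)
```

## The problem

An amplicon library is the end product of 20–30 PCR cycles applied to a
mixture of templates that differ in primer-binding energetics, GC
content and secondary structure. If each template is copied with its
own constant efficiency, relative abundances drift every cycle; and
because sequencing observes only a composition (an arbitrary per-library
scale factor separates reads from molecules), that drift is entangled
with closure effects: one taxon's gain is every other taxon's apparent
loss. `pcrbias` implements a compositional model of this process and
the machinery to estimate it from a calibration experiment in which one
sample is amplified to several consecutive cycle numbers in replicate.

## Deterministic kinetics

For one template with initial amount $z$, template efficiency
$\theta \in (0,1]$ and product efficiency $\lambda \in (0,1]$, product
counts satisfy $c(t) = \theta z + (\lambda + 1)\,c(t-1)$ with
$c(1) = \theta z$, whose closed form is

$$c(t) = \frac{\theta z}{\lambda}\left((\lambda+1)^t - 1\right)
  \;\approx\; \frac{\theta z}{\lambda}(\lambda+1)^t ,$$

the approximation dropping a term whose relative size is exactly
$(\lambda+1)^{-t}$ — below $10^{-3}$ for $\lambda \ge 0.37$ at $t = 22$,
the earliest cycle in the reference design. `counts_recurrence()` is
kept as the brute-force oracle for `counts_closed_form()` and
`counts_approx()`; the tests verify their equivalence over $10^4$
random parameter draws at relative tolerance $10^{-9}$.

$\theta$ and $z$ appear only as a product: a single-tube experiment can
never separate an abundant, poorly amplified template from a rare,
efficiently amplified one. The package therefore stores `theta_z` and
works with its ILR image $a$.

## Compositions, balances and the contrast basis

Given a rooted, strictly binary phylogeny of the $n$ templates, each
internal node defines a contrast between its left and right subclades.
The sign matrix $\Phi$ encodes membership ($-1$ left, $+1$ right, $0$
non-descendant) and the contrast matrix $\Psi$ rescales each row by
$k_i/n_{i-}$ and $k_i/n_{i+}$ with
$k_i = \sqrt{n_{i-}n_{i+}/(n_{i-}+n_{i+})}$, making the rows orthonormal
with zero sums. Balances are $b = \log(x)\,\Psi^\top$ and the inverse
transform is $x = \mathcal{C}(\exp(b\,\Psi))$ with $\mathcal{C}$ the
closure. Two consequences carry the whole method:

* zero row sums annihilate constant vectors, so the per-library scale
  factor $A$ cancels exactly — no library-size normalisation is needed
  or wanted;
* substituting the geometric approximation into the transform makes
  balances **linear in cycle number**,
  $b(t) = t\log(\lambda+1)\Psi^\top - \log\lambda\,\Psi^\top + a$,
  with homogeneous efficiencies giving slope zero (the no-bias null).

Orientation of each contrast (which child is "left") is not defined by
the mathematics; the package fixes it as *first child in Newick order =
left = $-1$*, with rows ordered by preorder traversal from the root.
All downstream inferences are invariant to this convention, but a fixed
convention makes every artifact bit-reproducible. Multifurcating trees
are rejected rather than silently resolved, because an arbitrary
resolution would change the basis.

## Preprocessing

The pipeline applies, in order: optional rarefaction to a common depth
(sampling without replacement, seeded), the prevalence filter, and
Bayesian-multiplicative zero replacement.

* **Prevalence filter.** A template is kept iff its count is strictly
  greater than `min_count = 10` in at least `min_fraction = 0.5` of the
  libraries — a literal reading of "over 10 times in at least 50%".
  The boundary case (counts exactly 10 everywhere) is removed.
* **Zero replacement.** For a library with total $N$ and Dirichlet
  strengths $s_j$ (default Bayes–Laplace, $s_j = 1/n$), a zero becomes
  the posterior-expected pseudo-count $N s_j/(N + T)$ with
  $T = \sum_j s_j$, and non-zero counts are multiplicatively shrunk so
  the library total is preserved. Jeffreys ($s_j = 1/2$) and uniform
  ($s_j = 1$) strengths, or explicit vectors, are selectable; the
  method reference names only the family, so the prior strength is an
  exposed choice rather than a constant.

The filter is not cosmetic. Templates whose expected counts fall below
roughly ten reads at the sequencing depth carry almost no log-scale
information: their log-counts are biased (Jensen) and their zeros are
imputed, which biases the corresponding balances coherently across
replicates. In calibration simulations, credible intervals for $a$
cover at the nominal 95% for well-resolved templates but degrade for
sub-resolution ones; running the filter first — as the pipeline
prescribes — restores nominal coverage on the retained subcomposition.
Subcompositional coherence of the model makes this well-defined: the
retained templates follow the same model with the same efficiencies.

## The hierarchical model and its priors

Observed balances of replicate $j$ at cycle $t$ are modelled as
$b^{(t,j)} \sim \mathcal{N}(b(t), \Sigma)$ with
$\Sigma = \mathrm{diag}(\sigma_i^2)$ — noise is diagonal in balance
space and shared across cycles. Priors: $\lambda_i \sim
\mathrm{Beta}(4,1)$ (mean 0.8, mass towards efficient amplification),
$a_i \sim \mathcal{N}(0, \mathrm{sd} = 2)$ i.i.d., and $\sigma_i \sim
\mathcal{N}_+(0, 1)$. The scale notation for the $a$ prior is read as a
standard deviation of 2 (the convention of the probabilistic-programming
stack this model family is usually written in); the value is exposed in
`pcr_priors()` in any case. Identifiability needs at least two distinct
cycles — the slope and level of a line cannot be separated from one
support point — and `fit_pcr_model()` refuses single-cycle designs.

## Sampling

The model is fitted by a No-U-Turn sampler written for this package
(dynamic Hamiltonian Monte Carlo with slice-based tree sampling,
dual-averaging step size, and a dense mass matrix). Three
implementation choices matter and are worth recording:

1. **Efficiency parameterisation.** The prior has positive density at
   the $\lambda = 1$ boundary, so any smooth map to the real line
   leaves a tail there. A logit map leaves an *exponential* tail that
   no fixed mass matrix can whiten (the tail direction rotates as it
   stretches), which caps the effective sample size well below what the
   rest of the posterior allows. The sampler instead uses
   $\lambda = 1 - e^{-w^2/2}$, whose pushforward tail is Gaussian; the
   boundary pile-up becomes an ordinary shoulder.
2. **Metric.** The mass matrix is initialised from a Laplace
   approximation (L-BFGS mode, Hessian by central differences of the
   analytic gradient) and refined once from a long warmup window,
   shrinking the sample covariance towards the previous metric. The
   trajectory is parameterised with centred cycles internally, removing
   the slope–intercept ridge that raw cycle numbers (22–26) would
   induce; $a$ is recovered deterministically per draw.
3. **Common-scale move.** The data identify only the $n-1$ contrasts of
   $\log(\lambda + 1)$; the remaining direction (a common shift) is
   constrained by the prior alone and is curved in the unconstrained
   coordinates. Each NUTS transition is composed with a
   generalized-Gibbs slice move along that orbit (with the group-action
   Jacobian in the slice density), which traverses the prior-identified
   direction natively.

Together these give, at the default desk-scale budget of 500 warmup +
1000 kept draws on each of 2 chains, minimum effective sample sizes of
roughly 800–1000 and split-chain R-hat around 1.005 on the reference
recovery problem; the full-scale configuration (5000 + 20000 on 4
chains) is available via `sampler_control(full_scale = TRUE)`. The
default target acceptance is 0.85, which removed the occasional
divergent transitions seen at 0.8 without a measurable speed cost.
Analytic gradients are verified against finite differences in the test
suite, and the full posterior is cross-checked against an independent
MCMC engine (JAGS) on a small configuration where single-site sampling
mixes reliably.

Convergence reporting (`diagnostics()`) uses split-chain R-hat (each
chain halved, so within-chain drift registers) and effective sample
sizes from `coda`, with thresholds 1.01 and 400 by default. With fewer
than two chains R-hat is reported as `NA` and flagged.

## The synthetic generator

`simulate_tree()`, `simulate_params()`, `synthetic_truth()` and
`simulate_experiment()` produce fully specified calibration experiments
with ground truth. Defaults mirror the reference design: cycles 22–26,
12 replicates per cycle (60 libraries), 9988 reads per library.
Efficiencies are drawn from the model's own Beta(4, 1) prior,
initial-profile balances from $\mathcal{N}(0, 2)$, and the per-balance
noise scale defaults to $\sigma = 0.05$, the reference noise level used
throughout the recovery studies. Per-library scale factors are
log-normal (sdlog 0.25, a modest library-size spread typical of a
single MiSeq run); they model the unobservable molecule-to-read scaling
and are annihilated by the ILR — the tests verify that changing them
does not change a single simulated count. Counts are multinomial at
fixed depth, the natural emulation of reads rarefied to a common depth.

Noise is injected in balance space, matching the inference model's
observation layer; an optional `noise = "lambda_jitter"` mode instead
perturbs the efficiencies per replicate (2% CV), a deliberately
misspecified generator for robustness studies. What the generator does
**not** emulate: PCR errors and chimeras (removed upstream by denoising
in real pipelines), cycle-dependent efficiencies, substrate competition
and plateau effects, taxonomic structure in the tree, or read-level
artefacts. Passing recovery tests therefore demonstrates correctness of
the inference under the model's own assumptions plus multinomial
sequencing — not robustness to every real-world violation.

For covariate studies, `simulate_sequences()` draws template sequences
with controlled GC and a synthetic "secondary-structure energy"
covariate generated as a stated linear function of GC plus Gaussian
noise; the default GC slope is zero so that energy and GC are
independent unless a confounded design is requested. The positive
control used in the tests generates
$\log\lambda = -0.22 + 0.015\,(E + 30) + \varepsilon$,
$\varepsilon \sim \mathcal{N}(0, 0.05)$, with $E \sim \mathcal{N}(-30,
4)$ kcal/mol over 20 templates — an effect detected by the Huber
regression in ≈98% of repeats while the null GC covariate stays at its
nominal type-I error.

## Covariate analyses

* `efficiency_mantel()` correlates pairwise Levenshtein distances
  between template sequences with pairwise differences in posterior log
  efficiency (absolute difference by default, squared optional — the
  method reference does not state which; absolute is the conventional
  metric choice). P-values use the add-one permutation convention
  $(1 + \#\{r^\ast \ge r\})/(1 + n_\mathrm{perm})$ and a one-sided
  alternative by default, with a two-sided option.
* `robust_lm()` fits $\log\lambda \sim \mathrm{GC} + E$ by Huber
  M-estimation (tuning 1.345, IRLS to $10^{-8}$; Tukey bisquare
  selectable) with $t$-based p-values on $n - 3$ degrees of freedom.
  The efficiency summary fed in is the posterior mean of
  $\log\lambda$ by default (median selectable); energies are used as
  provided, negative meaning more stable, with no transform.

## Numerical conventions and degenerate inputs

* All logarithms are natural.
* "Cycle 0" denotes the approximated initial profile
  $\mathcal{C}(\mathrm{ilr}^{-1}(a))$; the closed-form count expression
  is identically zero at $t = 0$, so this convention is what the model
  can meaningfully report there. Reconstructions at $t \ge 1$ use the
  exact closed form, while posterior-predictive means use the linear
  trajectory (the model's own observation mean); the two differ by the
  geometric residual $(\lambda+1)^{-t}$, negligible in the log-linear
  phase.
* $\lambda$ is validated against $(0, 1]$, never clamped; sampling is
  on the open interval, with the boundary approachable to floating-point
  resolution.
* Compositional tolerances: closure sums to 1 within $10^{-12}$;
  round-trip ILR within $10^{-10}$; basis orthonormality within
  $10^{-10}$.
* Degenerate fits: a single distinct cycle raises an identifiability
  error; fitting interpolation-exact data (one replicate at two cycles)
  leaves the noise scale's posterior improper, so the prior-recovery
  test uses two replicates at two cycles of pure noise — the smallest
  proper design in which $\lambda$ remains essentially prior-driven.

## Problem sizes used by the tests

The recovery and coverage studies run at the reference design (10
templates, 5 cycles × 12 replicates, depth 9988, $\sigma = 0.05$) with
500 + 1000 × 2 sampling for the headline fit and 300 + 500 × 2 across
20 coverage repeats; Mantel calibration uses 1000 null simulations of
15 × 15 matrices with 999 permutations; regression controls use 200
repeats of 20 templates. These sizes were chosen as the smallest at
which the binomial/Monte-Carlo tolerances of the checks are meaningful;
the same studies scale up unchanged.

## Known limitations

Constant efficiencies restrict the model to the log-linear phase;
substrate competition, self-annealing and plateau effects at late
cycles are outside it, as are cycle-dependent efficiencies and the
"rare biosphere" frequency-dependent effects reported for early cycles.
The Gaussian observation layer is light-tailed; a multivariate-$t$
layer is a natural extension point but is not implemented. Efficiencies
of templates discarded by the prevalence filter are not estimated at
all — the method is silent, not unbiased, about sub-resolution taxa.
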