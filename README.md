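# pcrbias

Multi-template PCR — the amplification step behind every 16S/ITS amplicon
library — copies each template with its own efficiency. Over 20–30 cycles
even small efficiency differences compound into large distortions of the
relative abundances a sequencer finally reports, and because those
abundances are compositional (only ratios are observable), the distortion
is nonlinear and propagates between taxa. `pcrbias` models this process,
estimates per-template amplification efficiencies from a replicated
multi-cycle calibration experiment, reconstructs the community at any
cycle (including the approximated initial profile at "cycle 0"), and
tests what drives the efficiency differences. It is aimed at microbiome
researchers who want to quantify or correct amplification bias, and at
method developers who need a fully specified synthetic test bed.

## The model

Let `z_i` be the initial amount of template `i`, `θ_i` its amplification
efficiency and `λ_i ∈ (0, 1]` the efficiency of its PCR product. The
product count after `t` cycles solves a linear recurrence in closed form:

    c_i(t) = (θ_i z_i / λ_i) ((λ_i + 1)^t − 1) ≈ (θ_i z_i / λ_i) (λ_i + 1)^t ,

the approximation holding in the log-linear phase. Absolute counts are
unobservable; compositions are analysed in isometric log-ratio (ILR)
coordinates defined by a rooted binary phylogeny of the templates. With
contrast matrix `Ψ` ((n−1) × n, orthonormal, zero row sums), balances of
the amplifying community are **linear in cycle number**:

    b(t) = t · log(λ + 1) Ψᵀ − log(λ) Ψᵀ + a ,   a = ilr(θz) ,

and the unknown per-library scale factor cancels exactly in the
transform. Replicated observations at several cycles are modelled
hierarchically:

    b^(t,j) ~ Normal(b(t), diag(σ²)),  λ ~ Beta(4, 1),
    a ~ Normal(0, 2),  σ ~ half-Normal(0, 1),

fitted with a built-in No-U-Turn sampler (dense mass matrix seeded by a
Laplace approximation, plus a slice move along the prior-identified
common efficiency scale). `θz` is identifiable only through `a`; `λ` is
identified by the slope of the balance trajectory.

## Worked example

Simulate a calibration experiment in the reference design (5 cycles
22–26, 12 replicates, 9988 reads per library), preprocess it the way the
method prescribes, and fit:

```r
library(pcrbias)

basis  <- simulate_tree(8, seed = 11)
p0     <- simulate_params(basis, seed = 12)
params <- pcr_params(lambda = p0$lambda, a = p0$a, sigma = 0.05,
                     basis = basis)
truth  <- synthetic_truth(basis, params, seed = 13)
experiment <- simulate_experiment(truth)        # 8 templates x 60 samples

filtered <- prevalence_filter(experiment)       # ">10 reads in >=50%"
pseudo   <- zero_replace(filtered)              # Bayesian-multiplicative
fbasis   <- contrast_basis(ape::keep.tip(basis$tree,
                                         rownames(filtered$counts)))
obs  <- build_observations(filtered, fbasis, counts = pseudo)
post <- fit_pcr_model(obs, fbasis, seed = 14)

head(posterior_summary(post), 8)
#>     parameter   mean    sd median   q2.5 q97.5
#> 1 lambda[T01]  0.966 0.033  0.977  0.874 0.999
#> 2 lambda[T03]  0.709 0.035  0.713  0.625 0.764
#> 3 lambda[T04]  0.696 0.034  0.701  0.613 0.750
#> 4 lambda[T05]  0.554 0.040  0.556  0.470 0.627
#> 5 lambda[T06]  0.753 0.036  0.758  0.667 0.810
#> 6 lambda[T07]  0.873 0.039  0.879  0.777 0.935
#> 7 lambda[T08]  0.514 0.034  0.517  0.435 0.571
#> 8    a[node1] -0.170 0.144 -0.170 -0.448 0.116
```

One template (T02) was discarded by the prevalence filter, so seven
efficiencies are estimated. They track the generating truth closely:

```r
round(params$lambda[fbasis$leaf_order], 3)   # truth
#> 0.985 0.721 0.707 0.590 0.771 0.888 0.527
round(unname(posterior_params(post)$lambda), 3)
#> 0.966 0.709 0.696 0.554 0.753 0.873 0.514
```

`bias_summary()` quantifies the distortion accumulated between two
cycles as per-template log-ratios of reconstructed relative abundances
(here cycles 22 → 26; positive = over-amplified):

```r
bias_summary(post, t1 = 22, t2 = 26, n_draws = 500, seed = 15)
#>   template   mean median    q25    q75
#> 1      T01  0.181  0.181  0.171  0.190
#> 2      T03 -0.378 -0.377 -0.405 -0.348
#> 3      T04 -0.407 -0.406 -0.432 -0.382
#> 4      T05 -0.757 -0.762 -0.809 -0.706
#> 5      T06 -0.277 -0.279 -0.302 -0.252
#> 6      T07 -0.012 -0.013 -0.041  0.016
#> 7      T08 -0.865 -0.867 -0.900 -0.828
```

The fastest template (T01, λ ≈ 0.97) gains ~20% in relative abundance
over four cycles while the slowest (T08) loses ~58% — without any change
in the underlying community. `reconstruct_composition()` extrapolates
the fitted model to any cycle, and `posterior_predictive_compositions()`
adds the observation noise back for posterior-predictive checks.
Convergence is monitored with split-chain R-hat and effective sample
sizes via `diagnostics(post)`.

File-based front ends cover the same pipeline end to end:
`run_simulate()` writes a complete synthetic dataset (counts, metadata,
Newick tree, FASTA, energies, truth JSON), `run_fit()` goes from files
to posterior artifacts, and `run_associate()` runs the covariate
analyses (Mantel test of Levenshtein distance against efficiency
differences; Huber regression of log efficiency on GC content and
secondary-structure free energy).

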