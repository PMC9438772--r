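#' Random template phylogeny and its ILR basis
#'
#' Draws a random rooted, strictly binary tree on `n` uniquely named
#' leaves (`T01`, `T02`, ...) and derives its sign and contrast matrices.
#'
#' @param n Number of templates (>= 2).
#' @param seed Optional integer seed (caller's RNG state restored).
#' @return A [contrast_basis()].
#' @export
simulate_tree <- function(n, seed = NULL) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  tr <- with_seed(seed, ape::rtree(n, rooted = TRUE))
  tr$tip.label <- sprintf("T%02d", seq_len(n))
  contrast_basis(tr)
}

#' Random generating parameters for a synthetic experiment
#'
#' Draws efficiencies, initial-profile balances and noise scales from the
#' model's own priors (efficiencies Beta(4, 1) by default) so that
#' synthetic truths look like communities the inference model considers
#' plausible. The noise scale defaults to sigma = 0.05 per balance, the
#' reference calibration-noise level used throughout the package's
#' recovery studies.
#'
#' @param basis A [contrast_basis()] (e.g. from [simulate_tree()]).
#' @param seed Optional integer seed.
#' @param lambda_shape1,lambda_shape2 Beta shapes for the efficiencies.
#' @param a_scale SD of the Normal draw for the initial-profile balances.
#'   `0` gives a uniform initial composition.
#' @param sigma_scale Scale of the half-Normal draw for the per-balance
#'   noise.
#' @return A [pcr_params()].
#' @export
simulate_params <- function(basis, seed = NULL, lambda_shape1 = 4,
                            lambda_shape2 = 1, a_scale = 2,
                            sigma_scale = 0.05) {
  check_basis(basis)
  stopifnot(lambda_shape1 > 0, lambda_shape2 > 0, a_scale >= 0,
            sigma_scale > 0)
  n <- n_templates(basis)
  with_seed(seed, {
    lambda <- stats::rbeta(n, lambda_shape1, lambda_shape2)
    a <- stats::rnorm(n - 1L, 0, a_scale)
    sigma <- pmax(abs(stats::rnorm(n - 1L, 0, sigma_scale)), 1e-6)
    pcr_params(lambda = lambda, a = a, sigma = sigma, basis = basis)
  })
}

#' Ground truth of a synthetic calibration experiment
#'
#' Bundles everything needed to regenerate a synthetic dataset
#' bit-for-bit: the generating parameters and basis, the cycle/replicate
#' design, sequencing depth, per-sample scale factors and the seed. The
#' defaults mirror the reference calibration design: cycles 22-26, 12
#' replicates per cycle (60 libraries) and 9988 reads per library.
#' Per-sample scale factors A are log-normal (sdlog 0.25) unless supplied;
#' they model library-size variation and provably never reach the
#' balances.
#'
#' @param basis A [contrast_basis()].
#' @param params A matching [pcr_params()].
#' @param cycles Integer vector of distinct cycle numbers.
#' @param replicates Replicates per cycle.
#' @param depth Multinomial sequencing depth per library.
#' @param scale_factors Optional positive vector, one per library
#'   (cycle-major order); drawn log-normally when `NULL`.
#' @param seed Integer seed governing noise, scale factors and sequencing.
#' @param noise `"balance"` injects Gaussian noise in balance space
#'   (matching the inference model); `"lambda_jitter"` instead perturbs
#'   the efficiencies per replicate (multiplicatively, 2% CV) — a
#'   deliberately misspecified mode for robustness studies.
#' @return An object of class `synthetic_truth`; also stores the
#'   noiseless balance trajectory at the design cycles.
#' @export
synthetic_truth <- function(basis, params, cycles = 22:26,
                            replicates = 12, depth = 9988,
                            scale_factors = NULL, seed = 1,
                            noise = c("balance", "lambda_jitter")) {
  check_basis(basis)
  noise <- match.arg(noise)
  cycles <- as.integer(cycles)
  stopifnot(length(cycles) >= 1, all(cycles >= 1), replicates >= 1,
            depth >= 1)
  n_samples <- length(cycles) * replicates
  if (depth < n_templates(basis)) {
    warning("sequencing depth below the number of templates; ",
            "expect very sparse counts", call. = FALSE)
  }
  if (is.null(scale_factors)) {
    scale_factors <- with_seed(seed,
      stats::rlnorm(n_samples, meanlog = 0, sdlog = 0.25))
  }
  stopifnot(length(scale_factors) == n_samples, all(scale_factors > 0))
  traj <- balance_trajectory(params, basis)
  structure(
    list(basis = basis, params = params, cycles = cycles,
         replicates = as.integer(replicates), depth = as.integer(depth),
         scale_factors = scale_factors, seed = as.integer(seed),
         noise = noise, trajectory = traj,
         noiseless_balances = balance_at(traj, cycles)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", n_templates(x$basis), " templates; cycles ",
      paste(range(x$cycles), collapse = "-"), " x ", x$replicates,
      " replicates; depth ", x$depth, "\n", sep = "")
  invisible(x)
}

#' Simulate a replicated multi-cycle amplicon experiment
#'
#' For every (cycle, replicate) pair: evaluates the closed-form product
#' counts, adds diagonal Gaussian noise to their balances (or jitters the
#' efficiencies in the misspecified mode), maps back to the simplex,
#' applies the per-sample scale factor and draws multinomial counts at
#' the configured depth. Reproducible from the truth's seed.
#'
#' @param truth A [synthetic_truth()].
#' @return A [count_experiment()] with sample names `c<cycle>_r<rep>`.
#' @export
simulate_experiment <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  basis <- truth$basis
  params <- truth$params
  n <- n_templates(basis)
  K <- n - 1L
  design <- expand.grid(rep = seq_len(truth$replicates),
                        cycle = truth$cycles)[, c("cycle", "rep")]
  design <- design[order(design$cycle, design$rep), ]
  S <- nrow(design)
  with_seed(truth$seed + 1L, {
    counts <- matrix(0L, nrow = n, ncol = S,
                     dimnames = list(basis$leaf_order,
                                     sprintf("c%d_r%02d", design$cycle,
                                             design$rep)))
    for (s in seq_len(S)) {
      tt <- design$cycle[s]
      if (truth$noise == "balance") {
        # exact closed-form kinetics; Gaussian noise enters in balance
        # space, matching the inference model's observation layer
        b <- ilr(counts_closed_form(params$theta_z, params$lambda, tt),
                 basis) + stats::rnorm(K, 0, params$sigma)
        x <- ilr_inverse(b, basis)
      } else {
        lam <- pmin(params$lambda *
                      exp(stats::rnorm(n, 0, 0.02) - 0.5 * 0.02^2), 1)
        x <- closure(counts_approx(params$theta_z, lam, tt))
      }
      # absolute scale (A * depth) never reaches the balances; the
      # multinomial probabilities only see the composition
      expected <- truth$scale_factors[s] * truth$depth * x
      counts[, s] <- stats::rmultinom(1L, truth$depth,
                                      expected / sum(expected))
    }
    count_experiment(counts, cycles = design$cycle,
                     replicates = design$rep)
  })
}

#' Random template sequences with controlled GC content
#'
#' Draws one DNA sequence per template whose realised GC fraction is
#' within 0.02 of its target, together with a synthetic
#' secondary-structure "free energy" covariate generated as a stated
#' linear function of GC plus Gaussian noise (coefficients are recorded,
#' and the GC slope defaults to 0 so energy and GC are independent unless
#' asked otherwise).
#'
#' @param n Number of sequences.
#' @param length Sequence length in bases (>= 50 recommended; the
#'   rounding error of the GC target must stay below 0.02).
#' @param gc_targets Vector of target GC fractions in \[0, 1\] (recycled).
#' @param seed Optional integer seed.
#' @param energy_intercept,energy_gc_slope,energy_sd Coefficients of the
#'   synthetic energy model E = intercept + slope * GC + N(0, sd), in
#'   kcal/mol (more negative = more stable).
#' @return List of class `synthetic_sequences` with elements `sequences`
#'   (named character), `gc` (realised fractions), `energy` and
#'   `energy_coefficients`.
#' @export
simulate_sequences <- function(n, length = 250,
                               gc_targets = 0.5, seed = NULL,
                               energy_intercept = -30,
                               energy_gc_slope = 0, energy_sd = 4) {
  stopifnot(n >= 1, length >= 1)
  gc_targets <- rep_len(gc_targets, n)
  if (any(gc_targets < 0) || any(gc_targets > 1)) {
    stop("`gc_targets` must lie in [0, 1]", call. = FALSE)
  }
  n_gc <- round(gc_targets * length)
  if (any(abs(n_gc / length - gc_targets) > 0.02)) {
    stop("sequence length too short to realise the GC targets within 0.02",
         call. = FALSE)
  }
  ids <- sprintf("T%02d", seq_len(n))
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      bases <- c(sample(c("G", "C"), n_gc[i], replace = TRUE),
                 sample(c("A", "T"), length - n_gc[i], replace = TRUE))
      paste(bases[sample.int(length)], collapse = "")
    }, character(1))
    names(seqs) <- ids
    gc <- n_gc / length
    energy <- energy_intercept + energy_gc_slope * gc +
      stats::rnorm(n, 0, energy_sd)
    structure(
      list(sequences = seqs,
           gc = stats::setNames(gc, ids),
           energy = stats::setNames(energy, ids),
           energy_coefficients = c(intercept = energy_intercept,
                                   gc_slope = energy_gc_slope,
                                   sd = energy_sd)),
      class = "synthetic_sequences"
    )
  })
}
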