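# Shared fixtures and brute-force oracles, built in code at test time.

basis2 <- function() contrast_basis(ape::read.tree(text = "(A,B);"))

basis3 <- function() contrast_basis(ape::read.tree(text = "((A,B),C);"))

random_basis <- function(n, seed) simulate_tree(n, seed = seed)

toy_experiment <- function(counts, cycles = NULL, replicates = NULL) {
  if (is.null(cycles)) cycles <- rep(22L, ncol(counts))
  if (is.null(replicates)) replicates <- seq_len(ncol(counts))
  count_experiment(counts, cycles, replicates)
}

# classic dynamic-programming edit distance, the oracle for levenshtein()
dp_levenshtein <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  m <- length(a); n <- length(b)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  D[1L, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L,
                               D[i, j] + (a[i] != b[j]))
    }
  }
  D[m + 1L, n + 1L]
}

# a degenerate posterior whose draws are all equal to the given
# parameters; used to test reporting operations deterministically
constant_posterior <- function(basis, lambda, a, sigma, iter = 100,
                               chains = 2) {
  n <- length(basis$leaf_order)
  row <- c(lambda, a, rep_len(sigma, n - 1L))
  m <- matrix(rep(row, each = iter), nrow = iter)
  colnames(m) <- c(paste0("lambda[", basis$leaf_order, "]"),
                   paste0("a[", rownames(basis$contrast), "]"),
                   paste0("sigma[", rownames(basis$contrast), "]"))
  structure(
    list(chains = replicate(chains, m, simplify = FALSE),
         template_ids = basis$leaf_order,
         balance_ids = rownames(basis$contrast),
         basis = basis,
         priors = pcr_priors(),
         control = sampler_control(),
         seed = 1L,
         divergences = rep(0L, chains),
         max_depth_hit = rep(0L, chains)),
    class = "pcr_posterior"
  )
}

# posterior stub from explicit per-chain draw matrices (diagnostics tests)
chains_posterior <- function(chains, basis) {
  structure(
    list(chains = chains,
         template_ids = basis$leaf_order,
         balance_ids = rownames(basis$contrast),
         basis = basis,
         priors = pcr_priors(),
         control = sampler_control(),
         seed = 1L,
         divergences = rep(0L, length(chains)),
         max_depth_hit = rep(0L, length(chains))),
    class = "pcr_posterior"
  )
}

# one small synthetic calibration experiment reused by slower tests
small_synthetic <- function(n = 6, seed = 77, sigma = 0.05,
                            replicates = 12, depth = 9988,
                            cycles = 22:26) {
  basis <- simulate_tree(n, seed = seed)
  p0 <- simulate_params(basis, seed = seed + 1L)
  params <- pcr_params(lambda = p0$lambda, a = p0$a, sigma = sigma,
                       basis = basis)
  truth <- synthetic_truth(basis, params, cycles = cycles,
                           replicates = replicates, depth = depth,
                           seed = seed + 2L)
  list(basis = basis, params = params, truth = truth,
       experiment = simulate_experiment(truth))
}
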