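test_that("balance observations are scale-invariant and match the oracle", {
  b <- random_basis(5, seed = 21)
  set.seed(22)
  m <- matrix(rpois(10 * 5, 40) + 1L, 5, 2,
              dimnames = list(b$leaf_order, c("s1", "s2")))
  m[, 2] <- m[, 1] * 10L  # same composition, 10x library size
  exp <- count_experiment(m, cycles = c(22, 22), replicates = 1:2)
  obs <- build_observations(exp, b)
  expect_equal(obs$balances[, 1], obs$balances[, 2], tolerance = 1e-12)

  uni <- count_experiment(
    matrix(7L, 5, 1, dimnames = list(b$leaf_order, "u")), 22, 1)
  expect_equal(unname(build_observations(uni, b)$balances[, 1]),
               rep(0, 4))

  # independent matrix-product oracle
  x <- runif(5, 0.5, 4)
  exp1 <- count_experiment(
    matrix(round(1000 * x), 5, 1, dimnames = list(b$leaf_order, "s")),
    23, 1)
  expect_equal(unname(build_observations(exp1, b)$balances[, 1]),
               unname(drop(b$contrast %*% log(round(1000 * x)))),
               tolerance = 1e-12)
})

test_that("build_observations rejects zeros and mismatched names", {
  b <- random_basis(3, seed = 23)
  m <- matrix(c(0L, 5L, 5L), 3, 1, dimnames = list(b$leaf_order, "s"))
  exp <- count_experiment(m, 22, 1)
  expect_error(build_observations(exp, b), "zero_replace")
  rownames(exp$counts) <- c("X1", b$leaf_order[2:3])
  expect_error(build_observations(exp, b), "X1")
})

test_that("the likelihood is exchangeable over sample order", {
  sim <- small_synthetic(n = 4, seed = 401, replicates = 3)
  obs <- build_observations(sim$experiment, sim$basis,
                            counts = zero_replace(sim$experiment))
  B <- t(obs$balances); tv <- as.numeric(obs$cycles)
  lp1 <- pcrbias:::make_model_logp(B, tv, sim$basis$contrast, pcr_priors())
  set.seed(77)
  perm <- sample(nrow(B))
  lp2 <- pcrbias:::make_model_logp(B[perm, ], tv[perm],
                                   sim$basis$contrast, pcr_priors())
  for (i in 1:5) {
    q <- c(runif(4, 0.8, 2.4), rnorm(3), rnorm(3, -2, 0.3))
    expect_equal(lp1(q)$value, lp2(q)$value, tolerance = 1e-10)
  }
})

test_that("fit requires at least two distinct cycles", {
  sim <- small_synthetic(n = 4, seed = 402, replicates = 4, cycles = 22)
  obs <- build_observations(sim$experiment, sim$basis,
                            counts = zero_replace(sim$experiment))
  expect_error(fit_pcr_model(obs, sim$basis), "single cycle")
})

test_that("near-noiseless data recover the efficiencies within 3 sd", {
  basis <- simulate_tree(5, seed = 403)
  params <- pcr_params(lambda = c(0.95, 0.8, 0.7, 0.85, 0.6),
                       a = c(0.5, -0.3, 0.2, -0.1), sigma = 1e-3,
                       basis = basis)
  truth <- synthetic_truth(basis, params, replicates = 6, depth = 1e6,
                           seed = 404)
  exp <- simulate_experiment(truth)
  obs <- build_observations(exp, basis, counts = zero_replace(exp))
  post <- suppressWarnings(
    fit_pcr_model(obs, basis,
                  control = sampler_control(warmup = 300, iter = 600),
                  seed = 11))
  s <- posterior_summary(post)
  li <- grep("^lambda", s$parameter)
  z <- abs(log1p(s$mean[li]) - log1p(params$lambda)) /
    pmax(s$sd[li] / (1 + s$mean[li]), 1e-6)
  expect_true(all(z < 3 | abs(s$mean[li] - params$lambda) < 0.02))
  ai <- grep("^a", s$parameter)
  expect_equal(unname(s$mean[ai]), unname(params$a), tolerance = 0.05)
})

test_that("with almost no data the efficiency posterior returns the prior", {
  # two cycles x two replicates of pure noise: the trajectory soaks up
  # the cycle means and lambda stays essentially prior-distributed
  basis <- simulate_tree(4, seed = 405)
  set.seed(406)
  m <- matrix(rpois(16, 500) + 1L, 4, 4,
              dimnames = list(basis$leaf_order, paste0("s", 1:4)))
  exp <- count_experiment(m, cycles = c(22, 22, 23, 23),
                          replicates = c(1, 2, 1, 2))
  obs <- build_observations(exp, basis)
  post <- suppressWarnings(
    fit_pcr_model(obs, basis,
                  control = sampler_control(warmup = 400, iter = 1500),
                  seed = 12))
  lam_mean <- mean(pcrbias:::pooled_draws(post)[, 1:4])
  expect_lt(abs(lam_mean - 0.8), 0.1)   # Beta(4,1) mean
})

test_that("shifting all cycle labels is absorbed into the intercept", {
  basis <- simulate_tree(5, seed = 407)
  params <- pcr_params(lambda = c(0.9, 0.75, 0.8, 0.65, 0.7),
                       a = c(0.2, -0.4, 0.3, 0.1), sigma = 0.01,
                       basis = basis)
  truth0 <- synthetic_truth(basis, params, cycles = 22:26,
                            replicates = 6, depth = 1e5, seed = 408)
  exp0 <- simulate_experiment(truth0)
  obs0 <- build_observations(exp0, basis, counts = zero_replace(exp0))
  # same balances, cycle labels shifted by -22
  obs1 <- obs0
  obs1$cycles <- obs0$cycles - 22L
  ctl <- sampler_control(warmup = 300, iter = 600)
  post0 <- suppressWarnings(fit_pcr_model(obs0, basis, control = ctl,
                                          seed = 13))
  post1 <- suppressWarnings(fit_pcr_model(obs1, basis, control = ctl,
                                          seed = 13))
  s0 <- posterior_summary(post0); s1 <- posterior_summary(post1)
  li <- grep("^lambda", s0$parameter)
  expect_equal(s0$mean[li], s1$mean[li], tolerance = 0.05)
  est0 <- posterior_params(post0); est1 <- posterior_params(post1)
  slope1 <- balance_trajectory(est1, basis)$slope
  expect_equal(unname(est1$a), unname(est0$a + 22 * slope1),
               tolerance = 0.05)
})

test_that("diagnostics pass healthy chains and flag pathological ones", {
  b <- random_basis(3, seed = 31)
  nm <- c(paste0("lambda[", b$leaf_order, "]"),
          paste0("a[", rownames(b$contrast), "]"),
          paste0("sigma[", rownames(b$contrast), "]"))
  set.seed(32)
  good <- lapply(1:2, function(i) {
    m <- matrix(rnorm(2000 * 7), 2000, 7); colnames(m) <- nm; m
  })
  dg <- diagnostics(chains_posterior(good, b))
  expect_true(all(dg$rhat < 1.01))
  expect_true(all(dg$ok))
  # iid chain ESS is close to the number of draws
  expect_true(all(dg$ess > 0.6 * 4000) && all(dg$ess < 1.6 * 4000))

  bad <- list(good[[1]], good[[2]] + 5)  # disjoint supports
  db <- diagnostics(chains_posterior(bad, b))
  expect_true(all(db$rhat > 1.1))
  expect_false(any(db$ok))

  # textbook split-R-hat oracle for the first parameter; coda applies an
  # additional degrees-of-freedom correction, so agreement is coarse
  x1 <- bad[[1]][, 1]; x2 <- bad[[2]][, 1]
  halves <- list(x1[1:1000], x1[1001:2000], x2[1:1000], x2[1001:2000])
  W <- mean(vapply(halves, var, numeric(1)))
  Bv <- 1000 * var(vapply(halves, mean, numeric(1)))
  rhat_oracle <- sqrt((999 / 1000 * W + Bv / 1000) / W)
  expect_gt(rhat_oracle, 1.1)
  expect_equal(db$rhat[1], rhat_oracle, tolerance = 0.5)

  single <- chains_posterior(good[1], b)
  expect_warning(ds <- diagnostics(single), "2 chains")
  expect_true(all(is.na(ds$rhat)))
  expect_false(any(ds$ok))
})

test_that("posterior predictive draws are compositions on the fitted line", {
  b <- random_basis(4, seed = 41)
  lam <- c(1, 0.6, 0.6, 0.6)
  post <- constant_posterior(b, lambda = lam, a = c(0.2, -0.1, 0.3),
                             sigma = 1e-8)
  pp <- posterior_predictive_compositions(post, cycles = c(0, 22, 35),
                                          n_draws = 30, seed = 2)
  sums <- tapply(pp$proportion, interaction(pp$cycle, pp$draw), sum)
  expect_equal(unname(as.numeric(sums)), rep(1, length(sums)),
               tolerance = 1e-9)
  # sigma -> 0 collapses onto the deterministic reconstruction (up to
  # the geometric-growth residual, negligible in the log-linear phase)
  est <- posterior_params(post)
  for (tt in c(0, 22, 35)) {
    got <- pp$proportion[pp$cycle == tt & pp$draw == 1]
    expect_equal(got, unname(reconstruct_composition(est, b, tt)),
                 tolerance = 1e-4)
  }
})

test_that("bias summary centres on zero without bias and splits by sign", {
  b <- random_basis(4, seed = 51)
  post_null <- constant_posterior(b, lambda = rep(0.8, 4),
                                  a = c(0.5, -0.5, 0.2), sigma = 0.05)
  bs <- bias_summary(post_null, t1 = 22, t2 = 26, n_draws = 50, seed = 3)
  expect_lt(max(abs(bs$median)), 1e-10)
  bs_same <- bias_summary(post_null, t1 = 26, t2 = 26, n_draws = 20,
                          seed = 3)
  expect_true(all(bs_same$median == 0 & bs_same$q25 == 0 &
                    bs_same$q75 == 0))

  # one fast template gains, the closure pushes the others down
  post_fast <- constant_posterior(b, lambda = c(1, 0.6, 0.6, 0.6),
                                  a = c(0, 0, 0), sigma = 0.05)
  bf <- bias_summary(post_fast, t1 = 22, t2 = 26, n_draws = 50, seed = 4)
  expect_gt(bf$median[1], 0)
  expect_true(all(bf$median[-1] < 0))
})
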