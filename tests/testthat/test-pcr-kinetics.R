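test_that("recurrence matches hand-iterated product counts", {
  expect_equal(counts_recurrence(1, 1, 3), 7)        # 1, 3, 7
  expect_equal(counts_recurrence(2, 0.5, 2), 5)      # 2 + 1.5 * 2
  expect_equal(counts_recurrence(3.7, 0.42, 1), 3.7) # initial condition
  expect_error(counts_recurrence(1, 1, 0), "integer >= 1")
  expect_error(counts_recurrence(-1, 1, 2), "positive")
  expect_error(counts_recurrence(1, 1.5, 2), "0, 1")
})

test_that("closed form equals the recurrence oracle", {
  expect_equal(counts_closed_form(1, 1, 10), 1023)   # 2^10 - 1
  set.seed(21)
  for (i in 1:200) {
    tz <- runif(1, 0.01, 100)
    lam <- runif(1, 0.02, 1)
    tt <- sample(1:30, 1)
    expect_equal(counts_closed_form(tz, lam, tt),
                 counts_recurrence(tz, lam, tt),
                 tolerance = 1e-9)
  }
})

test_that("small-lambda limit is linear amplification", {
  for (lam in c(1e-6, 1e-5)) {
    expect_equal(counts_closed_form(2, lam, 10), 2 * 10,
                 tolerance = 1e-4)
  }
})

test_that("theta = lambda collapses to the monoparametric count z(1+lambda)^t", {
  # closed form counts products only; adding back the original z gives
  # the textbook geometric count
  z <- 3; lam <- 0.7; tt <- 12
  expect_equal(counts_closed_form(lam * z, lam, tt) + z,
               z * (1 + lam)^tt, tolerance = 1e-10)
})

test_that("approximation error is exactly the geometric factor", {
  for (lam in c(0.2, 0.5, 1)) {
    for (tt in c(1, 5, 10, 25)) {
      exact <- counts_closed_form(2.5, lam, tt)
      approx <- counts_approx(2.5, lam, tt)
      rel <- (approx - exact) / approx
      expect_equal(rel, (1 / (lam + 1))^tt, tolerance = 1e-12)
    }
  }
  expect_equal((counts_approx(1, 1, 10) - counts_closed_form(1, 1, 10)) /
                 counts_approx(1, 1, 10), 2^-10, tolerance = 1e-12)
  expect_equal((counts_approx(1, 1, 1) - counts_closed_form(1, 1, 1)) /
                 counts_approx(1, 1, 1), 0.5, tolerance = 1e-12)
  # monotone decreasing in t
  errs <- (1 / (0.6 + 1))^(1:20)
  expect_true(all(diff(errs) < 0))
})

test_that("pcr_params keeps a and theta_z consistent through the basis", {
  b <- random_basis(5, seed = 2)
  set.seed(3)
  tz <- runif(5, 0.1, 2)
  p <- pcr_params(lambda = rep(0.8, 5), theta_z = tz, sigma = 0.1,
                  basis = b)
  expect_equal(p$a, ilr(tz, b), tolerance = 1e-10)
  expect_equal(unname(p$theta_z), unname(closure(tz)), tolerance = 1e-10)
  # scaling theta_z leaves the identified quantity a unchanged
  p10 <- pcr_params(lambda = rep(0.8, 5), theta_z = 10 * tz, sigma = 0.1,
                    basis = b)
  expect_equal(p10$a, p$a, tolerance = 1e-12)
  expect_error(pcr_params(lambda = rep(1.2, 5), theta_z = tz,
                          sigma = 0.1, basis = b), "0, 1")
  expect_error(pcr_params(lambda = rep(0.5, 4), theta_z = tz[1:4],
                          sigma = 0.1, basis = b), "per template")
})

test_that("balances of approximated counts are exactly linear in cycle", {
  b <- random_basis(7, seed = 4)
  p <- simulate_params(b, seed = 5)
  traj <- balance_trajectory(p, b)
  ts <- 1:30
  bal <- vapply(ts, function(tt)
    ilr(counts_approx(p$theta_z, p$lambda, tt), b),
    numeric(6))
  pred <- balance_at(traj, ts)
  expect_equal(bal, pred, tolerance = 1e-9)
  # second differences vanish: exact linearity
  expect_lt(max(abs(bal[, -(1:2)] - 2 * bal[, -c(1, 30)] +
                      bal[, -(29:30)])), 1e-9)
  # one-cycle increment is the slope, for any t
  expect_equal(bal[, 10] - bal[, 9], traj$slope, tolerance = 1e-9)
})

test_that("homogeneous efficiencies give zero slope (no bias null)", {
  b <- random_basis(6, seed = 6)
  p <- pcr_params(lambda = rep(0.85, 6), a = rnorm(5), sigma = 0.1,
                  basis = b)
  traj <- balance_trajectory(p, b)
  expect_lt(max(abs(traj$slope)), 1e-12)
  for (tt in c(1, 7, 31)) {
    expect_equal(unname(reconstruct_composition(p, b, tt)),
                 unname(ilr_inverse(p$a, b)), tolerance = 1e-10)
    expect_lt(max(abs(logratio_change(p, b, 1, tt))), 1e-10)
  }
})

test_that("two-template slope matches the hand-derived value", {
  b <- basis2()
  p <- pcr_params(lambda = c(1, 0.5), a = 0, sigma = 0.1, basis = b)
  traj <- balance_trajectory(p, b)
  expect_equal(unname(traj$slope), log(1.5 / 2) / sqrt(2),
               tolerance = 1e-8)
  expect_equal(unname(traj$slope), -0.20341, tolerance = 1e-4)
})

test_that("reconstruction matches the worked two-template example", {
  b <- basis2()
  p <- pcr_params(lambda = c(1, 0.5), theta_z = c(0.5, 0.5), sigma = 0.1,
                  basis = b)
  got <- reconstruct_composition(p, b, 5)
  # unnormalised (31 * 0.5, (1.5^5 - 1) * 0.5/0.5)
  expect_equal(unname(got), unname(closure(c(15.5, 6.59375))),
               tolerance = 1e-8)
  expect_equal(unname(got), c(0.70158, 0.29842), tolerance = 1e-4)

  expect_equal(reconstruct_composition(p, b, 0),
               ilr_inverse(p$a, b), tolerance = 1e-12)
  expect_error(reconstruct_composition(p, b, -1), ">= 0")
})

test_that("reconstruction is invariant to rescaling theta_z", {
  b <- random_basis(5, seed = 11)
  set.seed(12)
  tz <- runif(5, 0.2, 3)
  lam <- runif(5, 0.4, 1)
  p1 <- pcr_params(lambda = lam, theta_z = tz, sigma = 0.1, basis = b)
  p2 <- pcr_params(lambda = lam, theta_z = 250 * tz, sigma = 0.1,
                   basis = b)
  for (tt in c(0, 3, 20)) {
    expect_equal(reconstruct_composition(p1, b, tt),
                 reconstruct_composition(p2, b, tt), tolerance = 1e-10)
  }
})

test_that("log-ratio change behaves as a bias summary", {
  b <- random_basis(4, seed = 13)
  p <- simulate_params(b, seed = 14)
  expect_equal(unname(logratio_change(p, b, 8, 8)), rep(0, 4))
  lr <- logratio_change(p, b, 22, 26)
  expect_equal(lr, log(reconstruct_composition(p, b, 26) /
                         reconstruct_composition(p, b, 22)))
})

test_that("non-monotone relative-abundance trajectories exist", {
  # a template with intermediate efficiency and moderate initial share
  # first gains on the slow grower, then loses to the fast one
  b <- basis3()
  p <- pcr_params(lambda = c(1.0, 0.7, 0.3),
                  theta_z = c(0.001, 0.05, 0.949), sigma = 0.1, basis = b)
  prop2 <- vapply(0:35, function(tt)
    reconstruct_composition(p, b, tt)[2], numeric(1))
  peak <- which.max(prop2)
  expect_gt(peak, 1)
  expect_lt(peak, 36)
  expect_gt(prop2[peak], prop2[1])
  expect_gt(prop2[peak], prop2[36])
})
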