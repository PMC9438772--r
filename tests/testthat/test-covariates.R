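test_that("gc_content counts G/C and excludes N from the denominator", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ANGC"), 2 / 3)
  expect_equal(gc_content("atgc"), 0.5)
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("NNN"), "only N")
  expect_error(gc_content("AXGC"), "unexpected")
})

test_that("levenshtein matches the dynamic-programming oracle", {
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  set.seed(61)
  alphabet <- c("A", "C", "G", "T")
  for (i in 1:40) {
    s1 <- paste(sample(alphabet, sample(1:12, 1), TRUE), collapse = "")
    s2 <- paste(sample(alphabet, sample(1:12, 1), TRUE), collapse = "")
    d <- levenshtein(s1, s2)
    expect_equal(d, dp_levenshtein(s1, s2))
    expect_equal(d, levenshtein(s2, s1))            # symmetry
    s3 <- paste(sample(alphabet, sample(1:12, 1), TRUE), collapse = "")
    expect_lte(levenshtein(s1, s3),
               d + levenshtein(s2, s3))             # triangle
  }
  m <- levenshtein_matrix(c(a = "ACGT", b = "AGGT", c = "TTTT"))
  expect_equal(diag(m), c(a = 0L, b = 0L, c = 0L))
  expect_equal(m["a", "b"], 1L)
})

test_that("mantel test statistic and p-value follow the conventions", {
  set.seed(62)
  n <- 12
  d1 <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  r_self <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(r_self$statistic, 1)
  expect_equal(r_self$p_value, 1 / 100)

  # identical relabelling of both matrices leaves the test invariant
  d2 <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  t0 <- mantel_test(d1, d2, n_perm = 199, seed = 7)
  p <- sample(n)
  t1 <- mantel_test(d1[p, p], d2[p, p], n_perm = 199, seed = 7)
  expect_equal(t0$statistic, t1$statistic, tolerance = 1e-12)

  expect_error(mantel_test(d1, matrix(0, n, n)), "constant")
  expect_error(mantel_test(d1, d2[1:6, 1:6]), "same dimension")
  asym <- d1; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mantel_test(asym, d2), "symmetric")
})

test_that("mantel statistic agrees with the vegan implementation", {
  set.seed(63)
  n <- 15
  d1 <- as.matrix(dist(matrix(rnorm(n * 4), n)))
  d2 <- as.matrix(dist(matrix(rnorm(n * 4), n) +
                         0.5 * matrix(rnorm(n * 4), n)))
  mine <- mantel_test(d1, d2, n_perm = 999, seed = 3)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  # permutation p-values agree up to Monte-Carlo noise
  expect_lt(abs(mine$p_value - ref$signif), 0.08)
})

test_that("mantel p-values are calibrated under the null", {
  set.seed(64)
  pv <- vapply(1:300, function(i) {
    n <- 12
    d1 <- as.matrix(dist(rnorm(n)))
    d2 <- as.matrix(dist(rnorm(n)))
    mantel_test(d1, d2, n_perm = 199, seed = i)$p_value
  }, numeric(1))
  ks <- stats::ks.test(pv, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.04)
})

test_that("efficiency_mantel wires sequences to efficiency distances", {
  seqs <- c(T1 = "ACGTACGT", T2 = "ACGTACGA", T3 = "TTGGCCAA")
  ll <- c(T1 = -0.1, T2 = -0.5, T3 = -0.9)
  res <- efficiency_mantel(seqs, ll, n_perm = 99, seed = 1)
  expect_s3_class(res, "mantel_test")
  d_eff <- abs(outer(ll, ll, "-"))
  ref <- mantel_test(levenshtein_matrix(seqs), d_eff, n_perm = 99,
                     seed = 1)
  expect_equal(res$statistic, ref$statistic)
  expect_error(efficiency_mantel(seqs, ll[1:2]), "names")
})

test_that("robust regression recovers exact and contaminated fits", {
  set.seed(65)
  n <- 30
  gc <- runif(n, 0.3, 0.7)
  energy <- rnorm(n, -30, 4)
  tab <- covariate_table(sprintf("T%02d", 1:n), gc, energy,
                         1 + 2 * gc + 0.5 * energy)
  fit <- robust_lm(tab)
  expect_equal(fit$estimate, c(1, 2, 0.5), tolerance = 1e-6)

  # with symmetric Gaussian noise the estimates track OLS
  tab$log_lambda <- 1 + 2 * gc + 0.5 * energy + rnorm(n, 0, 0.1)
  fit_h <- robust_lm(tab)
  ols <- coef(lm(log_lambda ~ gc + energy, data = tab))
  expect_equal(fit_h$estimate, unname(ols), tolerance = 0.05)

  # a single gross outlier moves Huber far less than OLS
  dirty <- tab
  dirty$log_lambda[1] <- dirty$log_lambda[1] + 50
  fit_dirty <- robust_lm(dirty)
  ols_dirty <- coef(lm(log_lambda ~ gc + energy, data = dirty))
  shift_huber <- abs(fit_dirty$estimate[3] - fit_h$estimate[3])
  shift_ols <- abs(ols_dirty[["energy"]] - ols[["energy"]])
  expect_lt(shift_huber, 0.2 * shift_ols)

  coll <- tab
  coll$energy <- 2 * coll$gc
  expect_error(robust_lm(coll), "rank deficient|collinear")
  expect_error(robust_lm(tab[1:3, ]), "4 complete rows")
  expect_error(robust_lm(data.frame(gc = 1:5)), "columns")
})

test_that("bisquare psi is available as an alternative", {
  set.seed(66)
  n <- 25
  gc <- runif(n); energy <- rnorm(n, -30, 4)
  tab <- covariate_table(sprintf("T%02d", 1:n), gc, energy,
                         -1 + 0.02 * energy + rnorm(n, 0, 0.05))
  f1 <- robust_lm(tab, psi = "bisquare")
  expect_lt(abs(f1$estimate[3] - 0.02), 0.01)
})
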