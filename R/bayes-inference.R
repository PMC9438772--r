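#' Balance observations for model fitting
#'
#' Converts a (zero-replaced) count experiment into per-sample ILR balance
#' vectors. Unknown per-library scale factors cancel in the transform, so
#' no library-size normalisation is needed (or meaningful) beforehand.
#'
#' @param exp A [count_experiment()] carrying cycle and replicate labels.
#' @param basis A [contrast_basis()] whose leaves match the experiment's
#'   templates (any row order).
#' @param counts Optional strictly positive matrix overriding
#'   `exp$counts`, typically the output of [zero_replace()]. Must share
#'   `exp`'s dimnames.
#' @return An object of class `observation_set` with elements `balances`
#'   ((n-1) x samples), `cycles`, `replicates` and `template_ids`.
#' @export
build_observations <- function(exp, basis, counts = NULL) {
  check_experiment(exp)
  check_basis(basis)
  m <- if (is.null(counts)) exp$counts else as.matrix(counts)
  missing_tpl <- setdiff(basis$leaf_order, rownames(m))
  extra_tpl <- setdiff(rownames(m), basis$leaf_order)
  if (length(missing_tpl) || length(extra_tpl)) {
    stop("templates do not match the basis leaves; missing: [",
         paste(missing_tpl, collapse = ", "), "], extra: [",
         paste(extra_tpl, collapse = ", "), "]", call. = FALSE)
  }
  m <- m[basis$leaf_order, , drop = FALSE]
  if (any(m <= 0)) {
    stop("counts contain zeros; run zero_replace() first", call. = FALSE)
  }
  structure(
    list(balances = ilr(m, basis),
         cycles = exp$cycles,
         replicates = exp$replicates,
         template_ids = basis$leaf_order),
    class = "observation_set"
  )
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set> ", nrow(x$balances), " balances x ",
      ncol(x$balances), " samples\n", sep = "")
  invisible(x)
}

#' Prior hyperparameters of the hierarchical model
#'
#' Defaults: lambda ~ Beta(4, 1) on (0, 1); a ~ Normal(0, sd = 2) i.i.d.
#' across balances; sigma ~ half-Normal(0, sd = 1).
#'
#' @param lambda_shape1,lambda_shape2 Beta shape parameters for the
#'   product-amplification efficiencies.
#' @param a_sd Prior standard deviation of the initial-profile balances.
#' @param sigma_sd Scale of the half-Normal prior on the per-balance noise.
#' @return A list of class `pcr_priors`.
#' @export
pcr_priors <- function(lambda_shape1 = 4, lambda_shape2 = 1,
                       a_sd = 2, sigma_sd = 1) {
  stopifnot(lambda_shape1 > 0, lambda_shape2 > 0, a_sd > 0, sigma_sd > 0)
  structure(list(lambda_shape1 = lambda_shape1,
                 lambda_shape2 = lambda_shape2,
                 a_sd = a_sd, sigma_sd = sigma_sd),
            class = "pcr_priors")
}

#' Sampler settings
#'
#' The default is a desk-scale configuration (500 warmup + 1000 kept draws
#' on each of 2 chains), ample for this low-dimensional, near-Gaussian
#' posterior. `full_scale = TRUE` switches to 5000 warmup + 20000 draws
#' on 4 chains.
#'
#' @param warmup Adaptation iterations per chain (discarded).
#' @param iter Kept draws per chain.
#' @param chains Number of chains.
#' @param max_treedepth Maximum NUTS doubling depth.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param divergence_warn Warn if the divergent-transition fraction
#'   exceeds this value.
#' @param dense_mass Adapt a dense (full-covariance) mass matrix instead
#'   of a diagonal one. The default is dense: the efficiency block of
#'   this posterior is strongly correlated through its prior-constrained
#'   common scale, which a diagonal metric cannot whiten.
#' @param full_scale Use the full-scale settings.
#' @return A list of class `sampler_control`.
#' @export
sampler_control <- function(warmup = 500, iter = 1000, chains = 2,
                            max_treedepth = 10, target_accept = 0.85,
                            divergence_warn = 0.01, dense_mass = TRUE,
                            full_scale = FALSE) {
  if (full_scale) {
    warmup <- 5000; iter <- 20000; chains <- 4
  }
  stopifnot(warmup >= 20, iter >= 10, chains >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(warmup = as.integer(warmup), iter = as.integer(iter),
                 chains = as.integer(chains),
                 max_treedepth = as.integer(max_treedepth),
                 target_accept = target_accept,
                 divergence_warn = divergence_warn,
                 dense_mass = isTRUE(dense_mass)),
            class = "sampler_control")
}

# Unconstrained parameterisation of the efficiencies: lambda = 1 -
# exp(-w^2 / 2). Because the prior has positive density at the lambda = 1
# boundary, any map to the real line leaves a tail there; this one makes
# the pushforward tail Gaussian (a logit would leave an exponential tail
# that no fixed mass matrix can whiten).
lambda_from_w <- function(w) -expm1(-w^2 / 2)

w_from_lambda <- function(lam) sqrt(-2 * log1p(-lam))

# Log posterior and gradient on the unconstrained scale.
# q = (w [n], level c [K], log sigma [K]); the trajectory is
# parameterised with centred cycles, mu = tc * slope + c, which removes
# the slope/intercept ridge the raw cycle numbers (22-26) would induce;
# a = c - tbar * slope - icpt0 is recovered deterministically.
make_model_logp <- function(B, t, psi, priors) {
  S <- nrow(B); K <- ncol(B); n <- ncol(psi)
  tbar <- mean(t); tc <- t - tbar
  a1 <- priors$lambda_shape1; b1 <- priors$lambda_shape2
  a_var <- priors$a_sd^2; s_var <- priors$sigma_sd^2
  psi_t <- t(psi)
  function(q) {
    w <- q[seq_len(n)]
    cv <- q[n + seq_len(K)]
    r <- q[n + K + seq_len(K)]
    lam <- lambda_from_w(w)
    if (any(lam <= 0)) return(list(value = -Inf, grad = 0 * q))
    u1 <- log1p(lam); u0 <- log(lam)
    slope <- drop(psi %*% u1)
    icpt0 <- drop(-psi %*% u0)
    a <- cv - tbar * slope - icpt0
    sig2 <- exp(2 * r)
    mu <- outer(tc, slope) + matrix(cv, S, K, byrow = TRUE)
    resid <- B - mu
    ss <- colSums(resid^2)
    # Beta prior density plus the |dlambda/dw| = |w| (1 - lambda) Jacobian
    val <- -0.5 * sum(ss / sig2) - S * sum(r) +
      sum((a1 - 1) * u0 + b1 * log1p(-lam) + log(abs(w))) -
      sum(a^2) / (2 * a_var) -
      sum(exp(2 * r)) / (2 * s_var) + sum(r)
    g_mu <- sweep(resid, 2L, sig2, "/")
    ga <- -a / a_var
    g_c <- colSums(g_mu) + ga
    g_slope <- drop(crossprod(tc, g_mu)) - tbar * ga
    gu1 <- drop(psi_t %*% g_slope)
    gu0 <- drop(psi_t %*% ga)
    g_lam <- gu1 / (1 + lam) + gu0 / lam + (a1 - 1) / lam -
      b1 / (1 - lam)
    g_w <- g_lam * w * (1 - lam) + 1 / w
    g_r <- ss / sig2 - S - exp(2 * r) / s_var + 1
    list(value = val, grad = c(g_w, g_c, g_r))
  }
}

# Generalised-Gibbs move along the efficiency common-shift orbit
# u1 -> u1 + delta, u1 = log(1 + lambda): the direction the data never
# identify (zero-sum contrast rows annihilate it) and the prior bounds.
# The orbit is curved in the sampler's unconstrained coordinates, so it
# is traversed natively by 1-D slice sampling (stepping out + shrinkage)
# with the group-action Jacobian included in the slice density.
make_shift_move <- function(lp_fun, n, w = 0.05, max_step_out = 20L) {
  function(q) {
    wq <- q[seq_len(n)]
    lam <- lambda_from_w(wq)
    u1 <- log1p(lam)
    d_lo <- -min(u1) + 1e-9
    d_hi <- log(2) - max(u1) - 1e-9
    eval_delta <- function(delta) {
      lamp <- expm1(u1 + delta)
      wp <- sign(wq) * w_from_lambda(lamp)
      qp <- q
      qp[seq_len(n)] <- wp
      lpv <- lp_fun(qp)
      list(q = qp, lp = lpv,
           g = lpv$value +
             sum(log1p(lamp) - log(abs(wp)) - log1p(-lamp)))
    }
    cur <- eval_delta(0)
    y <- cur$g - stats::rexp(1)
    u <- stats::runif(1, 0, w)
    lo <- max(-u, d_lo); hi <- min(w - u, d_hi)
    k <- max_step_out
    while (k > 0L && lo > d_lo && eval_delta(lo)$g > y) {
      lo <- max(lo - w, d_lo); k <- k - 1L
    }
    k <- max_step_out
    while (k > 0L && hi < d_hi && eval_delta(hi)$g > y) {
      hi <- min(hi + w, d_hi); k <- k - 1L
    }
    repeat {
      delta <- stats::runif(1, lo, hi)
      cand <- eval_delta(delta)
      if (cand$g > y) {
        return(list(q = cand$q, lp = cand$lp$value, grad = cand$lp$grad))
      }
      if (delta < 0) lo <- delta else hi <- delta
      if (hi - lo < 1e-12) {
        return(list(q = cur$q, lp = cur$lp$value, grad = cur$lp$grad))
      }
    }
  }
}

model_inits_det <- function(B, t, n) {
  K <- ncol(B)
  tc <- t - mean(t)
  slope_hat <- drop(crossprod(tc, B)) / sum(tc^2)
  c_hat <- colMeans(B)
  resid <- B - outer(tc, slope_hat) -
    matrix(c_hat, nrow(B), K, byrow = TRUE)
  sd_hat <- pmax(sqrt(colMeans(resid^2)), 1e-3)
  c(rep(w_from_lambda(0.8), n), c_hat, log(sd_hat))
}

model_inits <- function(B, t, n) {
  K <- ncol(B)
  det <- model_inits_det(B, t, n)
  det + c(stats::rnorm(n, 0, 0.3), stats::rnorm(K, 0, 0.05),
          stats::rnorm(K, 0, 0.1))
}

#' Fit the hierarchical PCR-bias model
#'
#' Estimates per-template product efficiencies `lambda`, the
#' efficiency-biased initial balances `a` and per-balance noise `sigma`
#' from replicated multi-cycle balance observations. Observed balances are
#' modelled as diagonal Gaussians centred on the linear trajectory
#' b(t) = t log(lambda + 1) Psi^T - log(lambda) Psi^T + a, with priors
#' lambda ~ Beta(4, 1), a ~ N(0, 2), sigma ~ half-N(0, 1) by default.
#' Sampling uses the built-in No-U-Turn sampler.
#'
#' @param obs An [build_observations()] result spanning at least two
#'   distinct cycles.
#' @param basis The matching [contrast_basis()].
#' @param priors A [pcr_priors()] list.
#' @param control A [sampler_control()] list.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @return An object of class `pcr_posterior` holding per-chain draw
#'   matrices (columns `lambda[...]`, `a[...]`, `sigma[...]`), sampler
#'   metadata and the basis.
#' @export
fit_pcr_model <- function(obs, basis, priors = pcr_priors(),
                          control = sampler_control(), seed = 1) {
  if (!inherits(obs, "observation_set")) {
    stop("`obs` must be an observation_set", call. = FALSE)
  }
  check_basis(basis)
  if (!identical(obs$template_ids, basis$leaf_order)) {
    stop("observation templates do not match the basis", call. = FALSE)
  }
  t_vec <- as.numeric(obs$cycles)
  if (length(unique(t_vec)) < 2L) {
    stop("observations span a single cycle; the slope and intercept of ",
         "the balance trajectory are not jointly identifiable",
         call. = FALSE)
  }
  B <- t(obs$balances)                     # samples x balances
  psi <- basis$contrast
  n <- ncol(psi); K <- nrow(psi)
  lp_fun <- make_model_logp(B, t_vec, psi, priors)
  tbar <- mean(t_vec)

  lambda_names <- paste0("lambda[", basis$leaf_order, "]")
  a_names <- paste0("a[", rownames(psi), "]")
  sigma_names <- paste0("sigma[", rownames(psi), "]")

  # Laplace approximation at the posterior mode supplies a fixed dense
  # metric shared by all chains (falls back to within-chain adaptation if
  # the mode is degenerate); chains start overdispersed around the mode.
  lap <- if (control$dense_mass) {
    lap0 <- laplace_metric(lp_fun, model_inits_det(B, t_vec, n))
    if (!is.null(lap0)) lap0 else NULL
  } else NULL

  chains <- vector("list", control$chains)
  divergences <- integer(control$chains)
  max_depth_hit <- integer(control$chains)
  for (ch in seq_len(control$chains)) {
    res <- with_seed(as.integer(seed) + ch - 1L, {
      shift <- make_shift_move(lp_fun, n)
      if (is.null(lap)) {
        init <- model_inits(B, t_vec, n)
        nuts_chain(lp_fun, init, control$warmup, control$iter,
                   control$max_treedepth, control$target_accept,
                   control$dense_mass, shift_move = shift)
      } else {
        sds <- sqrt(diag(lap$metric$S))
        init <- lap$mode + stats::rnorm(length(lap$mode)) * sds
        nuts_chain(lp_fun, init, control$warmup, control$iter,
                   control$max_treedepth, control$target_accept,
                   control$dense_mass, metric0 = lap$metric,
                   shift_move = shift)
      }
    })
    M <- res$draws
    lam <- lambda_from_w(M[, seq_len(n), drop = FALSE])
    slope <- log1p(lam) %*% t(psi)
    icpt0 <- -log(lam) %*% t(psi)
    a <- M[, n + seq_len(K), drop = FALSE] - tbar * slope - icpt0
    sig <- exp(M[, n + K + seq_len(K), drop = FALSE])
    out <- cbind(lam, a, sig)
    colnames(out) <- c(lambda_names, a_names, sigma_names)
    chains[[ch]] <- out
    divergences[ch] <- res$divergences
    max_depth_hit[ch] <- sum(res$treedepth >= control$max_treedepth)
  }
  div_frac <- sum(divergences) / (control$chains * control$iter)
  if (div_frac > control$divergence_warn) {
    warning(sprintf("%.1f%% divergent transitions; estimates may be biased",
                    100 * div_frac), call. = FALSE)
  }
  structure(
    list(chains = chains,
         template_ids = basis$leaf_order,
         balance_ids = rownames(psi),
         basis = basis,
         priors = priors,
         control = control,
         seed = as.integer(seed),
         divergences = divergences,
         max_depth_hit = max_depth_hit),
    class = "pcr_posterior"
  )
}

#' @export
print.pcr_posterior <- function(x, ...) {
  cat("<pcr_posterior> ", length(x$template_ids), " templates; ",
      length(x$chains), " chains x ", nrow(x$chains[[1]]),
      " draws; ", sum(x$divergences), " divergences\n", sep = "")
  invisible(x)
}

#' Pooled draw matrix of a fitted posterior
#'
#' @param post A [fit_pcr_model()] result.
#' @return Matrix with all chains stacked and `chain` / `draw` prepended
#'   as columns.
#' @export
posterior_matrix <- function(post) {
  stopifnot(inherits(post, "pcr_posterior"))
  out <- do.call(rbind, post$chains)
  iter <- nrow(post$chains[[1]])
  cbind(chain = rep(seq_along(post$chains), each = iter),
        draw = rep(seq_len(iter), times = length(post$chains)),
        out)
}

#' Convergence diagnostics
#'
#' Per-parameter split-chain Gelman-Rubin statistic (each chain is split
#' in half, so within-chain drift also registers) and effective sample
#' size, with a pass/fail summary at configurable thresholds.
#'
#' @param post A [fit_pcr_model()] result with at least 2 chains (R-hat is
#'   reported as `NA` and flagged for a single chain).
#' @param rhat_threshold Largest acceptable R-hat (default 1.01).
#' @param ess_threshold Smallest acceptable effective sample size
#'   (default 400 across chains).
#' @return Data frame with columns `parameter`, `rhat`, `ess`, `ok`, plus
#'   an attribute `pass` (all parameters ok).
#' @export
diagnostics <- function(post, rhat_threshold = 1.01, ess_threshold = 400) {
  stopifnot(inherits(post, "pcr_posterior"))
  split_half <- function(m) {
    h <- floor(nrow(m) / 2)
    list(m[seq_len(h), , drop = FALSE],
         m[h + seq_len(h), , drop = FALSE])
  }
  halves <- unlist(lapply(post$chains, split_half), recursive = FALSE)
  ml_split <- coda::mcmc.list(lapply(halves, coda::mcmc))
  ml_full <- coda::mcmc.list(lapply(post$chains, coda::mcmc))
  params <- colnames(post$chains[[1]])
  single <- length(post$chains) < 2L
  rhat <- if (single) {
    rep(NA_real_, length(params))
  } else {
    gd <- coda::gelman.diag(ml_split, autoburnin = FALSE,
                            multivariate = FALSE)
    gd$psrf[, 1L]
  }
  ess <- as.numeric(coda::effectiveSize(ml_full))
  ok <- (!single & !is.na(rhat) & rhat < rhat_threshold) &
    ess >= ess_threshold
  if (single) {
    warning("R-hat requires at least 2 chains; flagged as not ok",
            call. = FALSE)
  }
  out <- data.frame(parameter = params, rhat = as.numeric(rhat),
                    ess = ess, ok = ok, row.names = NULL)
  attr(out, "pass") <- all(out$ok)
  out
}

sample_draw_rows <- function(post, n_draws) {
  total <- sum(vapply(post$chains, nrow, integer(1)))
  sample.int(total, size = n_draws, replace = n_draws > total)
}

pooled_draws <- function(post) do.call(rbind, post$chains)

draw_params <- function(post, row, pooled = pooled_draws(post)) {
  m <- pooled[row, ]
  n <- length(post$template_ids); K <- length(post$balance_ids)
  list(lambda = unname(m[seq_len(n)]),
       a = unname(m[n + seq_len(K)]),
       sigma = unname(m[n + K + seq_len(K)]))
}

#' Posterior summary as a parameter set
#'
#' Collapses a posterior into a single [pcr_params()] at the posterior
#' means (or medians) of lambda, a and sigma, e.g. for reconstruction or
#' covariate analysis.
#'
#' @param post A [fit_pcr_model()] result.
#' @param basis Basis to attach (defaults to the one stored in the fit).
#' @param summary `"mean"` or `"median"`.
#' @return A [pcr_params()].
#' @export
posterior_params <- function(post, basis = post$basis,
                             summary = c("mean", "median")) {
  summary <- match.arg(summary)
  m <- pooled_draws(post)
  f <- if (summary == "mean") colMeans else
    function(x) apply(x, 2, stats::median)
  v <- f(m)
  n <- length(post$template_ids); K <- length(post$balance_ids)
  pcr_params(lambda = pmin(unname(v[seq_len(n)]), 1),
             a = unname(v[n + seq_len(K)]),
             sigma = unname(v[n + K + seq_len(K)]),
             basis = basis)
}

#' Posterior summary of log efficiencies
#'
#' Per-template posterior mean (or median) of log(lambda), the summary fed
#' to the covariate analyses.
#'
#' @inheritParams posterior_params
#' @return Named numeric vector, one entry per template.
#' @export
posterior_log_lambda <- function(post, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  n <- length(post$template_ids)
  lam <- pooled_draws(post)[, seq_len(n), drop = FALSE]
  v <- if (summary == "mean") colMeans(log(lam)) else
    apply(log(lam), 2, stats::median)
  stats::setNames(as.numeric(v), post$template_ids)
}

#' Posterior-predictive community compositions
#'
#' For each requested cycle and each sampled posterior draw, draws a
#' balance vector from Normal(b(t), diag(sigma^2)) and maps it back to the
#' simplex. Cycle 0 uses the approximated initial profile, b(0) = a, per
#' the package's cycle-0 convention.
#'
#' @param post A [fit_pcr_model()] result.
#' @param basis Basis (defaults to the fit's).
#' @param cycles Integer vector of cycles >= 0.
#' @param n_draws Number of posterior draws to use (default 500).
#' @param seed Optional seed.
#' @return Data frame with columns `cycle`, `draw`, `template`,
#'   `proportion`; proportions sum to 1 within each (cycle, draw).
#' @export
posterior_predictive_compositions <- function(post, basis = post$basis,
                                              cycles, n_draws = 500,
                                              seed = NULL) {
  stopifnot(inherits(post, "pcr_posterior"), all(cycles >= 0))
  check_basis(basis)
  psi <- basis$contrast
  K <- nrow(psi)
  with_seed(seed, {
    rows <- sample_draw_rows(post, n_draws)
    pooled <- pooled_draws(post)
    res <- vector("list", length(cycles) * n_draws)
    k <- 1L
    for (i in seq_along(rows)) {
      par <- draw_params(post, rows[i], pooled)
      slope <- drop(psi %*% log1p(par$lambda))
      icpt <- drop(-psi %*% log(par$lambda)) + par$a
      for (tt in cycles) {
        mu <- if (tt == 0) par$a else slope * tt + icpt
        b <- stats::rnorm(K, mu, par$sigma)
        x <- ilr_inverse(b, basis)
        res[[k]] <- data.frame(cycle = tt, draw = i,
                               template = basis$leaf_order,
                               proportion = as.numeric(x))
        k <- k + 1L
      }
    }
    do.call(rbind, res)
  })
}

#' Posterior distribution of between-cycle log-ratio changes
#'
#' For each posterior draw, reconstructs the noise-free community at
#' cycles `t1` and `t2` and records the per-template log-ratio of relative
#' abundances; returns per-template quantiles (the numbers behind a
#' box-plot of amplification bias between two cycles).
#'
#' @inheritParams posterior_predictive_compositions
#' @param t1,t2 Cycles (>= 0) to compare, `t2` against `t1`.
#' @return Data frame with columns `template`, `mean`, `median`, `q25`,
#'   `q75`.
#' @export
bias_summary <- function(post, basis = post$basis, t1, t2,
                         n_draws = 500, seed = NULL) {
  stopifnot(inherits(post, "pcr_posterior"))
  check_basis(basis)
  with_seed(seed, {
    rows <- sample_draw_rows(post, n_draws)
    pooled <- pooled_draws(post)
    lr <- vapply(rows, function(row) {
      par <- draw_params(post, row, pooled)
      p <- pcr_params(lambda = par$lambda, a = par$a, sigma = par$sigma,
                      basis = basis)
      logratio_change(p, basis, t1, t2)
    }, numeric(length(post$template_ids)))
    data.frame(
      template = post$template_ids,
      mean = rowMeans(lr),
      median = apply(lr, 1, stats::median),
      q25 = apply(lr, 1, stats::quantile, 0.25),
      q75 = apply(lr, 1, stats::quantile, 0.75),
      row.names = NULL
    )
  })
}
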