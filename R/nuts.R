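# No-U-Turn sampler (dynamic Hamiltonian Monte Carlo) with dual-averaging
# step-size adaptation and mass-matrix estimation during warmup.
# `lp_fun(q)` must return list(value = log posterior, grad = gradient).
# The metric is the estimated posterior covariance (diagonal or dense);
# momenta are Gaussian with the inverse of that covariance, so the
# kinetic energy is 0.5 * p' Sigma p and the position update moves along
# the velocity Sigma p.

metric_diag <- function(v) list(type = "diag", v = v)

metric_dense <- function(S) {
  R <- chol(S)                           # S = R'R, R upper triangular
  list(type = "dense", S = S, R = R)
}

met_velocity <- function(metric, p) {
  if (metric$type == "diag") metric$v * p else drop(metric$S %*% p)
}

met_sample <- function(metric, d) {
  z <- stats::rnorm(d)
  if (metric$type == "diag") z / sqrt(metric$v) else
    drop(backsolve(metric$R, z))
}

met_kinetic <- function(metric, p) 0.5 * sum(p * met_velocity(metric, p))

nuts_leapfrog <- function(lp_fun, q, p, grad, eps, metric) {
  p_half <- p + 0.5 * eps * grad
  q_new <- q + eps * met_velocity(metric, p_half)
  lp <- lp_fun(q_new)
  p_new <- p_half + 0.5 * eps * lp$grad
  list(q = q_new, p = p_new, lp = lp$value, grad = lp$grad)
}

nuts_joint <- function(lp, p, metric) lp - met_kinetic(metric, p)

# Heuristic initial step size: double/halve until the acceptance
# probability of a single leapfrog step crosses 0.5.
nuts_find_epsilon <- function(lp_fun, q, metric) {
  eps <- 1
  lp0 <- lp_fun(q)
  p <- met_sample(metric, length(q))
  h0 <- nuts_joint(lp0$value, p, metric)
  step <- nuts_leapfrog(lp_fun, q, p, lp0$grad, eps, metric)
  h1 <- nuts_joint(step$lp, step$p, metric)
  while (!is.finite(h1) && eps > 1e-10) {
    eps <- eps / 2
    step <- nuts_leapfrog(lp_fun, q, p, lp0$grad, eps, metric)
    h1 <- nuts_joint(step$lp, step$p, metric)
  }
  dir <- if (h1 - h0 > log(0.5)) 1 else -1
  while (dir * (h1 - h0) > -dir * log(2) && eps < 1e6 && eps > 1e-10) {
    eps <- eps * 2^dir
    step <- nuts_leapfrog(lp_fun, q, p, lp0$grad, eps, metric)
    h1 <- nuts_joint(step$lp, step$p, metric)
    if (!is.finite(h1)) h1 <- -Inf
  }
  eps
}

nuts_stop_ok <- function(q_minus, q_plus, p_minus, p_plus, metric) {
  dq <- q_plus - q_minus
  (sum(dq * met_velocity(metric, p_minus)) >= 0) &&
    (sum(dq * met_velocity(metric, p_plus)) >= 0)
}

nuts_build_tree <- function(lp_fun, q, p, grad, logu, dir, depth, eps,
                            h0, metric) {
  if (depth == 0L) {
    step <- nuts_leapfrog(lp_fun, q, p, grad, dir * eps, metric)
    joint <- nuts_joint(step$lp, step$p, metric)
    if (!is.finite(joint)) joint <- -Inf
    n_keep <- as.integer(logu <= joint)
    ok <- logu < joint + 1000          # divergence guard
    list(q_minus = step$q, p_minus = step$p, grad_minus = step$grad,
         q_plus = step$q, p_plus = step$p, grad_plus = step$grad,
         q_prop = step$q, lp_prop = step$lp, grad_prop = step$grad,
         n = n_keep, ok = ok,
         alpha = min(1, exp(joint - h0)), n_alpha = 1L,
         divergent = !ok)
  } else {
    t1 <- nuts_build_tree(lp_fun, q, p, grad, logu, dir, depth - 1L, eps,
                          h0, metric)
    if (t1$ok) {
      if (dir == -1) {
        t2 <- nuts_build_tree(lp_fun, t1$q_minus, t1$p_minus,
                              t1$grad_minus, logu, dir, depth - 1L, eps,
                              h0, metric)
        t1$q_minus <- t2$q_minus; t1$p_minus <- t2$p_minus
        t1$grad_minus <- t2$grad_minus
      } else {
        t2 <- nuts_build_tree(lp_fun, t1$q_plus, t1$p_plus,
                              t1$grad_plus, logu, dir, depth - 1L, eps,
                              h0, metric)
        t1$q_plus <- t2$q_plus; t1$p_plus <- t2$p_plus
        t1$grad_plus <- t2$grad_plus
      }
      if (t2$n > 0L &&
          stats::runif(1) < t2$n / max(t1$n + t2$n, 1L)) {
        t1$q_prop <- t2$q_prop
        t1$lp_prop <- t2$lp_prop
        t1$grad_prop <- t2$grad_prop
      }
      t1$n <- t1$n + t2$n
      t1$alpha <- t1$alpha + t2$alpha
      t1$n_alpha <- t1$n_alpha + t2$n_alpha
      t1$divergent <- t1$divergent || t2$divergent
      t1$ok <- t2$ok &&
        nuts_stop_ok(t1$q_minus, t1$q_plus, t1$p_minus, t1$p_plus, metric)
    }
    t1
  }
}

nuts_transition <- function(lp_fun, q, lp, grad, eps, metric, max_depth) {
  p0 <- met_sample(metric, length(q))
  h0 <- nuts_joint(lp, p0, metric)
  logu <- h0 - stats::rexp(1)
  q_minus <- q; q_plus <- q
  p_minus <- p0; p_plus <- p0
  grad_minus <- grad; grad_plus <- grad
  q_new <- q; lp_new <- lp; grad_new <- grad
  n <- 1L; depth <- 0L; ok <- TRUE
  alpha <- 0; n_alpha <- 0L; divergent <- FALSE
  while (ok && depth < max_depth) {
    dir <- if (stats::runif(1) < 0.5) -1 else 1
    if (dir == -1) {
      tr <- nuts_build_tree(lp_fun, q_minus, p_minus, grad_minus, logu,
                            dir, depth, eps, h0, metric)
      q_minus <- tr$q_minus; p_minus <- tr$p_minus
      grad_minus <- tr$grad_minus
    } else {
      tr <- nuts_build_tree(lp_fun, q_plus, p_plus, grad_plus, logu,
                            dir, depth, eps, h0, metric)
      q_plus <- tr$q_plus; p_plus <- tr$p_plus
      grad_plus <- tr$grad_plus
    }
    if (tr$ok && tr$n > 0L && stats::runif(1) < tr$n / n) {
      q_new <- tr$q_prop
      lp_new <- tr$lp_prop
      grad_new <- tr$grad_prop
    }
    n <- n + tr$n
    alpha <- tr$alpha; n_alpha <- tr$n_alpha
    divergent <- divergent || tr$divergent
    ok <- tr$ok &&
      nuts_stop_ok(q_minus, q_plus, p_minus, p_plus, metric)
    depth <- depth + 1L
  }
  list(q = q_new, lp = lp_new, grad = grad_new,
       accept_stat = if (n_alpha > 0L) alpha / n_alpha else 0,
       depth = depth, divergent = divergent)
}

# Regularised covariance estimate from warmup draws, shrunk towards the
# previous metric (or a small multiple of the identity when starting
# cold, as in Stan's windowed adaptation).
estimate_metric <- function(draws, dense, prev = NULL) {
  nw <- nrow(draws)
  shrink <- nw / (nw + 5)
  if (!dense) {
    v <- apply(draws, 2, stats::var)
    v_prev <- if (is.null(prev)) 1e-3 else prev$v
    metric_diag(v * shrink + v_prev * (1 - shrink))
  } else {
    S_prev <- if (is.null(prev)) {
      diag(1e-3, ncol(draws))
    } else if (prev$type == "dense") {
      prev$S
    } else {
      diag(prev$v)
    }
    S <- stats::cov(draws) * shrink + S_prev * (1 - shrink)
    metric_dense((S + t(S)) / 2)
  }
}

# Laplace-approximation metric: posterior covariance estimated as the
# inverse negative Hessian of the log posterior at its mode, with the
# Hessian taken by central differences of the analytic gradient. For a
# near-Gaussian posterior this whitens the dynamics far more accurately
# than a sample covariance from a few hundred warmup draws.
laplace_metric <- function(lp_fun, init) {
  opt <- stats::optim(init,
                      fn = function(q) -lp_fun(q)$value,
                      gr = function(q) -lp_fun(q)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
  q0 <- opt$par
  d <- length(q0)
  H <- matrix(0, d, d)
  for (j in seq_len(d)) {
    h <- 1e-5 * max(1, abs(q0[j]))
    qp <- q0; qp[j] <- qp[j] + h
    qm <- q0; qm[j] <- qm[j] - h
    H[, j] <- (lp_fun(qp)$grad - lp_fun(qm)$grad) / (2 * h)
  }
  H <- (H + t(H)) / 2
  eg <- eigen(-H, symmetric = TRUE)
  if (any(eg$values <= 0)) return(NULL)   # mode degenerate; caller adapts
  S <- eg$vectors %*% (t(eg$vectors) / eg$values)
  S <- (S + t(S)) / 2
  list(mode = q0, metric = metric_dense(S))
}

# One chain: `warmup` adaptation iterations (discarded), `iter` kept
# draws. `dense_mass` uses a full-covariance metric (appropriate here:
# the efficiency block is strongly correlated through its
# prior-constrained common scale). A fixed `metric0` (e.g. from
# [laplace_metric()]) skips covariance re-estimation; only the step size
# is then adapted.
# Optional extra 1-D slice-sampling move along a model-supplied curve
# (`shift_move(q)` returns list(q, lp, grad)), composed with every NUTS
# transition. Used to traverse directions that are identified only by the
# prior and curve away from any fixed metric.
nuts_chain <- function(lp_fun, init, warmup, iter, max_depth = 10L,
                       target_accept = 0.8, dense_mass = TRUE,
                       metric0 = NULL, adapt_mass = TRUE,
                       shift_move = NULL) {
  d <- length(init)
  metric <- if (is.null(metric0)) metric_diag(rep(1, d)) else metric0
  q <- init
  lp0 <- lp_fun(q)
  if (!is.finite(lp0$value)) {
    stop("initial value has non-finite log posterior", call. = FALSE)
  }
  lp <- lp0$value; grad <- lp0$grad

  eps <- nuts_find_epsilon(lp_fun, q, metric)
  # dual averaging state (Hoffman & Gelman 2014)
  mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75; da_iter <- 0L

  # mass-estimation windows within warmup; starting from a supplied
  # metric (Laplace approximation) one long window suffices, while a cold
  # start uses two expanding windows so the second is estimated from
  # draws that already mix under the first metric
  if (!is.null(metric0)) {
    windows <- list(c(max(floor(0.1 * warmup), 1L), floor(0.9 * warmup)))
  } else if (warmup >= 100L) {
    windows <- list(c(max(floor(0.15 * warmup), 1L), floor(0.45 * warmup)),
                    c(floor(0.45 * warmup) + 1L, floor(0.85 * warmup)))
  } else {
    windows <- list(c(max(floor(0.25 * warmup), 1L),
                      max(floor(0.75 * warmup), floor(0.25 * warmup) + 1L)))
  }
  window <- matrix(NA_real_, nrow = warmup, ncol = d)

  draws <- matrix(NA_real_, nrow = iter, ncol = d)
  divergences <- 0L
  depths <- integer(iter)
  accept <- numeric(iter)

  for (m in seq_len(warmup + iter)) {
    tr <- nuts_transition(lp_fun, q, lp, grad, eps, metric, max_depth)
    q <- tr$q; lp <- tr$lp; grad <- tr$grad
    if (!is.null(shift_move)) {
      for (rep in 1:2) {
        mv <- shift_move(q)
        q <- mv$q; lp <- mv$lp; grad <- mv$grad
      }
    }
    if (m <= warmup) {
      da_iter <- da_iter + 1L
      frac <- 1 / (da_iter + t0)
      h_bar <- (1 - frac) * h_bar + frac * (target_accept - tr$accept_stat)
      log_eps <- mu - sqrt(da_iter) / gamma * h_bar
      w <- da_iter^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      window[m, ] <- q
      if (adapt_mass) for (win in windows) {
        if (m == win[2L] && win[2L] > win[1L]) {
          metric <- estimate_metric(
            window[win[1L]:win[2L], , drop = FALSE], dense_mass,
            prev = if (is.null(metric0)) NULL else metric)
          # restart step-size adaptation under the new metric
          eps <- nuts_find_epsilon(lp_fun, q, metric)
          mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
          da_iter <- 0L
        }
      }
      if (m == warmup) eps <- exp(log_eps_bar)
    } else {
      k <- m - warmup
      draws[k, ] <- q
      depths[k] <- tr$depth
      accept[k] <- tr$accept_stat
      if (tr$divergent) divergences <- divergences + 1L
    }
  }
  list(draws = draws, eps = eps, metric = metric,
       divergences = divergences, treedepth = depths,
       accept_stat = accept)
}
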