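#' Per-template PCR parameters
#'
#' Parameters of the amplification model for n templates: product
#' efficiencies `lambda` in (0, 1], the efficiency-biased initial amounts
#' `theta_z` (the product of template efficiency theta and initial amount
#' z, which are never separately identifiable), their ILR image `a`, and
#' the per-balance noise scale `sigma`. Only one of `theta_z` / `a` needs
#' to be supplied; the other is derived through the basis. Because only
#' relative information survives amplification, `theta_z` is stored
#' closure-normalised.
#'
#' @param lambda Numeric vector of n product-amplification efficiencies in
#'   (0, 1].
#' @param theta_z Optional strictly positive vector of length n.
#' @param a Optional balance vector of length n - 1.
#' @param sigma Positive noise scales, length n - 1 (recycled from a
#'   scalar).
#' @param basis A [contrast_basis()] on n templates.
#' @return An object of class `pcr_params` with elements `lambda`,
#'   `theta_z` (closed), `a` and `sigma`.
#' @export
pcr_params <- function(lambda, theta_z = NULL, a = NULL, sigma, basis) {
  check_basis(basis)
  n <- n_templates(basis)
  lambda <- as.numeric(lambda)
  if (length(lambda) != n) {
    stop("`lambda` must have one entry per template", call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda <= 0) || any(lambda > 1)) {
    stop("`lambda` must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(theta_z) && is.null(a)) {
    stop("supply `theta_z` or `a`", call. = FALSE)
  }
  if (is.null(a)) {
    if (any(theta_z <= 0)) stop("`theta_z` must be positive", call. = FALSE)
    a <- ilr(as.numeric(theta_z), basis)
  }
  a <- as.numeric(a)
  if (length(a) != n - 1L || any(!is.finite(a))) {
    stop("`a` must be a finite vector of length n - 1", call. = FALSE)
  }
  theta_z <- ilr_inverse(a, basis)
  sigma <- rep_len(as.numeric(sigma), n - 1L)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be strictly positive", call. = FALSE)
  }
  names(lambda) <- basis$leaf_order
  names(a) <- rownames(basis$contrast)
  names(sigma) <- rownames(basis$contrast)
  structure(list(lambda = lambda, theta_z = theta_z, a = a, sigma = sigma),
            class = "pcr_params")
}

#' @export
print.pcr_params <- function(x, ...) {
  cat("<pcr_params> ", length(x$lambda), " templates; lambda in [",
      signif(min(x$lambda), 3), ", ", signif(max(x$lambda), 3), "]\n",
      sep = "")
  invisible(x)
}

#' PCR product count by direct recurrence
#'
#' Iterates the cycle-by-cycle recurrence c(t) = theta*z + (lambda + 1)
#' c(t - 1) from c(1) = theta*z. Serves as the brute-force reference for
#' [counts_closed_form()].
#'
#' @param theta_z Positive scalar, the product of template efficiency and
#'   initial amount.
#' @param lambda Product amplification efficiency in (0, 1].
#' @param t Integer cycle number >= 1.
#' @return Product count at cycle `t`.
#' @export
counts_recurrence <- function(theta_z, lambda, t) {
  stopifnot(length(theta_z) == 1L, length(lambda) == 1L, length(t) == 1L)
  if (!is.finite(t) || t < 1 || t != round(t)) {
    stop("`t` must be an integer >= 1", call. = FALSE)
  }
  if (theta_z <= 0) stop("`theta_z` must be positive", call. = FALSE)
  if (lambda <= 0 || lambda > 1) stop("`lambda` must be in (0, 1]",
                                      call. = FALSE)
  c_t <- theta_z
  for (tau in seq_len(t - 1L)) c_t <- theta_z + (lambda + 1) * c_t
  c_t
}

#' PCR product count, closed form
#'
#' Solves the amplification recurrence in closed form:
#' c(t) = (theta*z / lambda) ((lambda + 1)^t - 1).
#'
#' @inheritParams counts_recurrence
#' @param theta_z Positive vector (recycled).
#' @param lambda Efficiencies in (0, 1] (recycled).
#' @param t Integer cycles >= 1 (recycled).
#' @return Product counts, vectorised over the inputs.
#' @export
counts_closed_form <- function(theta_z, lambda, t) {
  if (any(theta_z <= 0)) stop("`theta_z` must be positive", call. = FALSE)
  if (any(lambda <= 0) || any(lambda > 1)) {
    stop("`lambda` must be in (0, 1]", call. = FALSE)
  }
  if (any(t < 1)) stop("`t` must be >= 1", call. = FALSE)
  theta_z / lambda * ((lambda + 1)^t - 1)
}

#' Geometric-growth approximation of the product count
#'
#' Drops the -1 term of the closed form, c(t) ~ (theta*z / lambda)
#' (lambda + 1)^t, the approximation under which balances become exactly
#' linear in cycle number. Its relative error against the closed form is
#' exactly (1 / (lambda + 1))^t, negligible past the first few cycles.
#'
#' @inheritParams counts_closed_form
#' @return Approximate product counts.
#' @export
counts_approx <- function(theta_z, lambda, t) {
  if (any(theta_z <= 0)) stop("`theta_z` must be positive", call. = FALSE)
  if (any(lambda <= 0) || any(lambda > 1)) {
    stop("`lambda` must be in (0, 1]", call. = FALSE)
  }
  if (any(t < 1)) stop("`t` must be >= 1", call. = FALSE)
  theta_z / lambda * (lambda + 1)^t
}

#' Linear balance trajectory of an amplifying community
#'
#' Under the geometric-growth approximation the balances of the product
#' composition are linear in cycle number:
#' b(t) = t log(lambda + 1) Psi^T - log(lambda) Psi^T + a.
#'
#' @param params A [pcr_params()].
#' @param basis The [contrast_basis()] the parameters refer to.
#' @return An object of class `balance_trajectory` with `slope` and
#'   `intercept` vectors of length n - 1.
#' @export
balance_trajectory <- function(params, basis) {
  check_basis(basis)
  if (length(params$lambda) != n_templates(basis)) {
    stop("parameter dimension does not match the basis", call. = FALSE)
  }
  psi <- basis$contrast
  slope <- drop(psi %*% log1p(params$lambda))
  intercept <- drop(-psi %*% log(params$lambda)) + params$a
  structure(list(slope = slope, intercept = intercept),
            class = "balance_trajectory")
}

#' Evaluate a balance trajectory at given cycles
#'
#' @param trajectory A [balance_trajectory()].
#' @param t Numeric vector of cycle numbers.
#' @return Matrix of balances, (n-1) x length(t).
#' @export
balance_at <- function(trajectory, t) {
  vapply(t, function(tt) trajectory$slope * tt + trajectory$intercept,
         numeric(length(trajectory$slope)))
}

#' Reconstruct the community composition at a cycle
#'
#' Evaluates the fitted amplification model at cycle `t`:
#' closure over templates of (z_i / lambda_i)((lambda_i + 1)^t - 1), with
#' z = ilr^-1(a). For `t = 0` the efficiency-biased initial profile
#' closure(ilr^-1(a)) is returned, the model's "cycle 0" community.
#'
#' @param params A [pcr_params()].
#' @param basis The matching [contrast_basis()].
#' @param t Integer cycle >= 0.
#' @return Named composition vector summing to 1.
#' @export
reconstruct_composition <- function(params, basis, t) {
  check_basis(basis)
  if (length(t) != 1L || !is.finite(t) || t < 0 || t != round(t)) {
    stop("`t` must be a single integer >= 0", call. = FALSE)
  }
  z_hat <- ilr_inverse(params$a, basis)
  if (t == 0) return(z_hat)
  closure(counts_closed_form(z_hat, params$lambda, t))
}

#' Per-template log-ratio change between two cycles
#'
#' Natural log of the ratio of reconstructed relative abundances at cycle
#' `t2` versus cycle `t1`; the per-template summary of amplification bias
#' accumulated between the two cycles.
#'
#' @inheritParams reconstruct_composition
#' @param t1,t2 Integer cycles >= 0.
#' @return Named numeric vector of length n.
#' @export
logratio_change <- function(params, basis, t1, t2) {
  log(reconstruct_composition(params, basis, t2) /
        reconstruct_composition(params, basis, t1))
}
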