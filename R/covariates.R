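#' GC content of a DNA sequence
#'
#' Fraction of G/C bases; ambiguous `N` bases are excluded from both the
#' numerator and the denominator.
#'
#' @param seq A DNA string over \{A, C, G, T, N\} (case-insensitive).
#' @return GC fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("unexpected characters in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  denom <- sum(chars != "N")
  if (denom == 0L) stop("sequence contains only N bases", call. = FALSE)
  sum(chars %in% c("G", "C")) / denom
}

#' Levenshtein edit distance
#'
#' Minimal number of single-character substitutions, insertions and
#' deletions turning `s1` into `s2` (unit costs).
#'
#' @param s1,s2 Non-empty strings.
#' @return Non-negative integer.
#' @export
levenshtein <- function(s1, s2) {
  stopifnot(nzchar(s1), nzchar(s2))
  as.integer(utils::adist(s1, s2))
}

#' Pairwise Levenshtein distance matrix
#'
#' @param seqs Named character vector of sequences.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
levenshtein_matrix <- function(seqs) {
  d <- utils::adist(seqs)
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

check_dist_matrix <- function(d, name) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d))) ||
      any(diag(d) != 0)) {
    stop("`", name, "` must be a square symmetric matrix with zero ",
         "diagonal", call. = FALSE)
  }
  d
}

#' Mantel permutation test
#'
#' Pearson correlation between the off-diagonal entries of two distance
#' matrices, with significance assessed by jointly permuting the rows and
#' columns of `d2`. The p-value uses the add-one convention
#' (1 + exceedances) / (1 + permutations), so it can never be exactly
#' zero.
#'
#' @param d1,d2 Square symmetric distance matrices of equal dimension
#'   with zero diagonals.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (classic one-sided Mantel) or
#'   `"two.sided"` (on |r|).
#' @return List of class `mantel_test` with elements `statistic` (r),
#'   `p_value`, `n_perm` and `alternative`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d1 <- check_dist_matrix(d1, "d1")
  d2 <- check_dist_matrix(d2, "d2")
  if (!all(dim(d1) == dim(d2))) {
    stop("distance matrices must have the same dimension", call. = FALSE)
  }
  n <- nrow(d1)
  lower <- lower.tri(d1)
  v1 <- d1[lower]
  if (stats::sd(v1) == 0 || stats::sd(d2[lower]) == 0) {
    stop("constant distance matrix: the Mantel statistic is undefined",
         call. = FALSE)
  }
  r_obs <- stats::cor(v1, d2[lower])
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(v1, d2[p, p][lower])
  }, numeric(1)))
  exceed <- if (alternative == "greater") {
    sum(r_perm >= r_obs)
  } else {
    sum(abs(r_perm) >= abs(r_obs))
  }
  structure(list(statistic = r_obs,
                 p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm,
                 alternative = alternative),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("Mantel test: r = ", signif(x$statistic, 4), ", p = ",
      signif(x$p_value, 4), " (", x$n_perm, " permutations, ",
      x$alternative, ")\n", sep = "")
  invisible(x)
}

#' Mantel test of sequence similarity against efficiency differences
#'
#' Convenience wrapper: pairwise Levenshtein distances between template
#' sequences versus pairwise differences in posterior log efficiencies
#' (absolute difference by default, squared optionally).
#'
#' @param seqs Named character vector of template sequences.
#' @param log_lambda Named numeric vector of log efficiencies (same
#'   names).
#' @param efficiency_distance `"absolute"` or `"squared"`.
#' @inheritParams mantel_test
#' @return A [mantel_test()] result.
#' @export
efficiency_mantel <- function(seqs, log_lambda, n_perm = 999, seed = NULL,
                              alternative = c("greater", "two.sided"),
                              efficiency_distance = c("absolute",
                                                      "squared")) {
  efficiency_distance <- match.arg(efficiency_distance)
  ids <- names(seqs)
  if (!setequal(ids, names(log_lambda))) {
    stop("sequence and efficiency names do not match", call. = FALSE)
  }
  log_lambda <- log_lambda[ids]
  d_seq <- levenshtein_matrix(seqs)
  d_eff <- abs(outer(log_lambda, log_lambda, "-"))
  if (efficiency_distance == "squared") d_eff <- d_eff^2
  mantel_test(d_seq, d_eff, n_perm = n_perm, seed = seed,
              alternative = alternative)
}

#' Covariate table for efficiency regression
#'
#' One row per template: GC content, secondary-structure free energy
#' (kcal/mol, an external input) and the posterior summary of
#' log(lambda).
#'
#' @param template_id Character vector of template identifiers.
#' @param gc GC fractions in \[0, 1\].
#' @param energy Free energies (used as provided; negative = more
#'   stable).
#' @param log_lambda Posterior log-efficiency summaries.
#' @return Data frame of class `covariate_table`.
#' @export
covariate_table <- function(template_id, gc, energy, log_lambda) {
  out <- data.frame(template_id = as.character(template_id),
                    gc = as.numeric(gc), energy = as.numeric(energy),
                    log_lambda = as.numeric(log_lambda))
  if (anyDuplicated(out$template_id)) {
    stop("duplicate template identifiers", call. = FALSE)
  }
  if (anyNA(out)) stop("missing values in covariate table", call. = FALSE)
  if (any(out$gc < 0) || any(out$gc > 1)) {
    stop("`gc` must lie in [0, 1]", call. = FALSE)
  }
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Robust regression of log efficiency on GC and energy
#'
#' Fits log(lambda) ~ GC + E by M-estimation (Huber loss, tuning constant
#' 1.345, iteratively reweighted least squares; Tukey bisquare optional)
#' and reports per-coefficient estimates, standard errors and t-based
#' p-values (df = n - 3).
#'
#' @param table A [covariate_table()] with at least 4 complete rows.
#' @param psi `"huber"` (default) or `"bisquare"`.
#' @return Data frame with columns `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`; the `MASS::rlm` fit is attached as attribute
#'   `fit`.
#' @export
robust_lm <- function(table, psi = c("huber", "bisquare")) {
  psi <- match.arg(psi)
  if (!is.data.frame(table) ||
      !all(c("gc", "energy", "log_lambda") %in% names(table))) {
    stop("`table` must contain gc, energy and log_lambda columns",
         call. = FALSE)
  }
  tab <- table[stats::complete.cases(
    table[, c("gc", "energy", "log_lambda")]), ]
  if (nrow(tab) < 4L) {
    stop("need at least 4 complete rows", call. = FALSE)
  }
  X <- stats::model.matrix(~ gc + energy, data = tab)
  if (qr(X)$rank < ncol(X)) {
    stop("collinear design: gc/energy columns are rank deficient",
         call. = FALSE)
  }
  psi_fun <- if (psi == "huber") MASS::psi.huber else MASS::psi.bisquare
  fit <- MASS::rlm(log_lambda ~ gc + energy, data = tab,
                   psi = psi_fun, maxit = 500, acc = 1e-8)
  cf <- summary(fit)$coefficients
  df <- nrow(tab) - nrow(cf)
  out <- data.frame(term = rownames(cf),
                    estimate = cf[, "Value"],
                    std_error = cf[, "Std. Error"],
                    statistic = cf[, "t value"],
                    p_value = 2 * stats::pt(-abs(cf[, "t value"]), df),
                    row.names = NULL)
  attr(out, "fit") <- fit
  out
}
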