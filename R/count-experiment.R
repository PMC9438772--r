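#' Replicated multi-cycle amplicon count experiment
#'
#' Container for an amplicon calibration experiment: an integer count
#' matrix (templates x samples) together with the PCR cycle number and
#' replicate label of every sample.
#'
#' @param counts Non-negative integer matrix, templates in rows (row names
#'   are template identifiers), samples in columns (column names are
#'   sample identifiers).
#' @param cycles Integer vector of per-sample cycle numbers (>= 1), one
#'   per column of `counts`.
#' @param replicates Vector of per-sample replicate labels, one per column.
#' @return An object of class `count_experiment`.
#' @export
count_experiment <- function(counts, cycles, replicates) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("`counts` must have template identifiers as row names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("template identifiers must be unique", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  }
  if (any(counts < 0) || any(!is.finite(counts)) ||
      any(counts != round(counts))) {
    stop("`counts` must be a non-negative integer matrix", call. = FALSE)
  }
  if (any(colSums(counts) == 0)) {
    stop("samples with zero total counts are not allowed: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  }
  if (length(cycles) != ncol(counts) || length(replicates) != ncol(counts)) {
    stop("`cycles` and `replicates` must have one entry per sample",
         call. = FALSE)
  }
  cycles <- as.integer(cycles)
  if (any(is.na(cycles)) || any(cycles < 1L)) {
    stop("`cycles` must be integers >= 1", call. = FALSE)
  }
  structure(
    list(counts = counts,
         cycles = stats::setNames(cycles, colnames(counts)),
         replicates = stats::setNames(as.character(replicates),
                                      colnames(counts))),
    class = "count_experiment"
  )
}

#' @export
print.count_experiment <- function(x, ...) {
  cat("<count_experiment> ", nrow(x$counts), " templates x ",
      ncol(x$counts), " samples; cycles ",
      paste(sort(unique(x$cycles)), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_experiment <- function(x) dim(x$counts)

check_experiment <- function(exp) {
  if (!inherits(exp, "count_experiment")) {
    stop("expected a `count_experiment` object", call. = FALSE)
  }
  exp
}

#' Prevalence filter for rare templates
#'
#' Keeps a template only if its count exceeds `min_count` in at least
#' `min_fraction` of the libraries: the screen applied before modelling to
#' reduce zero-replacement artefacts and the uncertainty attached to rare
#' sequence variants. The inequality on counts is strict (`> min_count`);
#' the library fraction is inclusive (`>=`).
#'
#' @param exp A [count_experiment()].
#' @param min_count Count a template must exceed to be "observed"
#'   (default 10).
#' @param min_fraction Minimum fraction of libraries in which the template
#'   must be observed (default 0.5).
#' @return A [count_experiment()] with the surviving templates; the sample
#'   set is unchanged.
#' @export
prevalence_filter <- function(exp, min_count = 10, min_fraction = 0.5) {
  check_experiment(exp)
  n_obs <- rowSums(exp$counts > min_count)
  keep <- n_obs >= min_fraction * ncol(exp$counts)
  if (!any(keep)) {
    stop("prevalence filter removed every template", call. = FALSE)
  }
  count_experiment(exp$counts[keep, , drop = FALSE],
                   exp$cycles, exp$replicates)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Rarefy libraries to a common depth
#'
#' Subsamples each library without replacement (multivariate
#' hypergeometric) down to exactly `depth` reads, equalising sequencing
#' effort across samples. Reproducible for a fixed `seed`.
#'
#' @param exp A [count_experiment()].
#' @param depth Target reads per sample; every library total must be at
#'   least `depth`.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A [count_experiment()] in which every column sums to `depth`.
#' @export
rarefy <- function(exp, depth, seed = NULL) {
  check_experiment(exp)
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 1L) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  totals <- colSums(exp$counts)
  short <- totals < depth
  if (any(short)) {
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(names(totals)[short], collapse = ", "), call. = FALSE)
  }
  # totals and integrality are validated above; rrarefy's heuristic
  # "observed counts" warning misfires on small toy matrices
  rare <- with_seed(seed,
                    suppressWarnings(vegan::rrarefy(t(exp$counts), depth)))
  count_experiment(t(rare), exp$cycles, exp$replicates)
}

resolve_zero_prior <- function(prior, n) {
  if (is.character(prior)) {
    prior <- match.arg(prior, c("bayes_laplace", "jeffreys", "uniform"))
    s <- switch(prior,
                bayes_laplace = rep(1 / n, n),
                jeffreys = rep(0.5, n),
                uniform = rep(1, n))
    return(s)
  }
  if (is.numeric(prior) && all(prior > 0)) {
    if (length(prior) == 1L) return(rep(prior, n))
    if (length(prior) == n) return(as.numeric(prior))
  }
  stop("`prior` must be a prior name or positive strength(s)", call. = FALSE)
}

#' Bayesian-multiplicative zero replacement
#'
#' Replaces zero counts by their posterior-expected pseudo-counts under a
#' Dirichlet prior and multiplicatively shrinks the observed counts so
#' that each library total is preserved. For a library with total N,
#' Dirichlet strengths s_j and T = sum(s), a zero in component j becomes
#' N s_j / (N + T) and every non-zero count x becomes
#' x (1 - sum(replaced) / N). Libraries without zeros are returned
#' unchanged. The default prior is Bayes-Laplace, s_j = 1/n.
#'
#' @param exp A [count_experiment()] or a non-negative count matrix
#'   (templates x samples) with no all-zero column.
#' @param prior Prior name (`"bayes_laplace"`, `"jeffreys"`, `"uniform"`)
#'   or a positive numeric scalar/vector of Dirichlet strengths.
#' @return Strictly positive real matrix of pseudo-counts with the input's
#'   dimnames; column sums equal the input column sums.
#' @export
zero_replace <- function(exp, prior = "bayes_laplace") {
  counts <- if (inherits(exp, "count_experiment")) exp$counts else
    as.matrix(exp)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (any(colSums(counts) == 0)) {
    stop("all-zero samples cannot be zero-replaced", call. = FALSE)
  }
  n <- nrow(counts)
  s <- resolve_zero_prior(prior, n)
  total_s <- sum(s)
  out <- counts * 1.0
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]
    z <- x == 0
    if (!any(z)) next
    N <- sum(x)
    repl <- N * s[z] / (N + total_s)
    out[z, j] <- repl
    out[!z, j] <- x[!z] * (1 - sum(repl) / N)
  }
  out
}
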