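#' Posterior summary table
#'
#' @param post A [fit_pcr_model()] result.
#' @return Data frame with per-parameter posterior mean, sd, median and
#'   central 95% interval.
#' @export
posterior_summary <- function(post) {
  m <- pooled_draws(post)
  data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    median = apply(m, 2, stats::median),
    q2.5 = apply(m, 2, stats::quantile, 0.025),
    q97.5 = apply(m, 2, stats::quantile, 0.975),
    row.names = NULL
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

record_config <- function(config, outdir, name) {
  jsonlite::write_json(config, file.path(outdir, name),
                       auto_unbox = TRUE, digits = NA)
}

#' Generate a synthetic calibration experiment on disk
#'
#' Simulates a template phylogeny, generating parameters, a replicated
#' multi-cycle count experiment, template sequences and a synthetic
#' energy covariate, and writes counts.tsv, metadata.tsv, tree.nwk,
#' sequences.fasta, energy.tsv, truth.json and the resolved
#' simulate_config.json (with the seed) to `outdir`. The default design
#' is 5 cycles (22-26) x 12 replicates at depth 9988.
#'
#' @param outdir Output directory (created if needed).
#' @param n_templates Number of templates.
#' @param cycles,replicates,depth Experimental design.
#' @param sigma_scale Half-Normal scale of the per-balance noise draw.
#' @param sequence_length Length of the synthetic template sequences.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
run_simulate <- function(outdir, n_templates = 10, cycles = 22:26,
                         replicates = 12, depth = 9988,
                         sigma_scale = 0.05, sequence_length = 250,
                         seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  basis <- simulate_tree(n_templates, seed = seed)
  params <- simulate_params(basis, seed = seed + 1L,
                            sigma_scale = sigma_scale)
  truth <- synthetic_truth(basis, params, cycles = cycles,
                           replicates = replicates, depth = depth,
                           seed = seed + 2L)
  exp <- simulate_experiment(truth)
  seqs <- simulate_sequences(n_templates, length = sequence_length,
                             gc_targets = seq(0.35, 0.65,
                                              length.out = n_templates),
                             seed = seed + 3L)
  names(seqs$sequences) <- basis$leaf_order
  paths <- list(
    counts = file.path(outdir, "counts.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    tree = file.path(outdir, "tree.nwk"),
    fasta = file.path(outdir, "sequences.fasta"),
    energy = file.path(outdir, "energy.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_experiment(exp, paths$counts, paths$metadata)
  ape::write.tree(basis$tree, paths$tree)
  write_fasta(seqs$sequences, paths$fasta)
  write_tsv(data.frame(template_id = basis$leaf_order,
                       energy = unname(seqs$energy)), paths$energy)
  write_truth(truth, paths$truth)
  record_config(list(command = "simulate", n_templates = n_templates,
                     cycles = cycles, replicates = replicates,
                     depth = depth, sigma_scale = sigma_scale,
                     sequence_length = sequence_length, seed = seed),
                outdir, "simulate_config.json")
  invisible(list(basis = basis, params = params, truth = truth,
                 experiment = exp, sequences = seqs, paths = paths))
}

#' Fit the amplification-bias model from files on disk
#'
#' Full preprocessing and inference pipeline: read counts/metadata/tree,
#' optionally rarefy, prevalence-filter, zero-replace, transform to
#' balances, fit the hierarchical model, run convergence diagnostics and
#' write posterior draws, posterior summary, diagnostics and
#' reconstructed compositions at the requested cycles. The tree is pruned
#' to the templates surviving the filter.
#'
#' @param counts_path,metadata_path,tree_path Input files (see
#'   [read_experiment()]; Newick tree).
#' @param outdir Output directory.
#' @param rarefy_depth Optional depth; when given, libraries are rarefied
#'   before filtering.
#' @param min_count,min_fraction Prevalence-filter thresholds.
#' @param zero_prior Dirichlet prior for [zero_replace()].
#' @param priors,control Model priors and sampler settings.
#' @param reconstruct_cycles Cycles at which to export model
#'   reconstructions.
#' @param seed Integer seed.
#' @return Invisibly, a list with the fitted posterior, diagnostics table
#'   and output paths.
#' @export
run_fit <- function(counts_path, metadata_path, tree_path, outdir,
                    rarefy_depth = NULL, min_count = 10,
                    min_fraction = 0.5, zero_prior = "bayes_laplace",
                    priors = pcr_priors(), control = sampler_control(),
                    reconstruct_cycles = c(0, 22:26, 35), seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  exp <- read_experiment(counts_path, metadata_path)
  tree <- ape::read.tree(tree_path)
  if (!is.null(rarefy_depth)) {
    exp <- rarefy(exp, rarefy_depth, seed = seed)
  }
  exp <- prevalence_filter(exp, min_count = min_count,
                           min_fraction = min_fraction)
  missing_leaves <- setdiff(rownames(exp$counts), tree$tip.label)
  if (length(missing_leaves)) {
    stop("templates absent from the tree: ",
         paste(missing_leaves, collapse = ", "), call. = FALSE)
  }
  tree <- ape::keep.tip(tree, rownames(exp$counts))
  basis <- contrast_basis(tree)
  pseudo <- zero_replace(exp, prior = zero_prior)
  obs <- build_observations(exp, basis, counts = pseudo)
  post <- fit_pcr_model(obs, basis, priors = priors, control = control,
                        seed = seed + 1L)
  diag_tab <- diagnostics(post)
  if (!isTRUE(attr(diag_tab, "pass"))) {
    warning("convergence diagnostics flagged ",
            sum(!diag_tab$ok), " parameter(s); inspect diagnostics.tsv",
            call. = FALSE)
  }
  est <- posterior_params(post)
  recon <- do.call(rbind, lapply(reconstruct_cycles, function(tt) {
    data.frame(cycle = tt, template = basis$leaf_order,
               proportion = as.numeric(
                 reconstruct_composition(est, basis, tt)))
  }))
  paths <- list(
    posterior = file.path(outdir, "posterior.csv"),
    summary = file.path(outdir, "posterior_summary.tsv"),
    diagnostics = file.path(outdir, "diagnostics.tsv"),
    reconstruction = file.path(outdir, "reconstruction.tsv"),
    log_lambda = file.path(outdir, "log_lambda.tsv")
  )
  write_posterior(post, paths$posterior)
  write_tsv(posterior_summary(post), paths$summary)
  write_tsv(diag_tab, paths$diagnostics)
  write_tsv(recon, paths$reconstruction)
  write_tsv(data.frame(template_id = post$template_ids,
                       log_lambda = unname(posterior_log_lambda(post))),
            paths$log_lambda)
  record_config(list(command = "fit", counts = counts_path,
                     metadata = metadata_path, tree = tree_path,
                     rarefy_depth = rarefy_depth, min_count = min_count,
                     min_fraction = min_fraction,
                     zero_prior = as.character(zero_prior),
                     priors = unclass(priors),
                     control = unclass(control), seed = seed),
                outdir, "fit_config.json")
  invisible(list(posterior = post, diagnostics = diag_tab,
                 reconstruction = recon, basis = basis, paths = paths))
}

#' Covariate analysis of amplification efficiencies
#'
#' Reads template sequences (FASTA), per-template secondary-structure
#' energies (TSV: template_id, energy) and a per-template log-efficiency
#' table (TSV: template_id, log_lambda, as written by [run_fit()]); runs
#' the Mantel test of Levenshtein distance against efficiency differences
#' and the robust regression log(lambda) ~ GC + E; writes mantel.tsv and
#' coefficients.tsv.
#'
#' @param fasta_path,energy_path,log_lambda_path Input files.
#' @param outdir Output directory.
#' @param n_perm Mantel permutations.
#' @param seed Integer seed.
#' @return Invisibly, a list with the Mantel result, coefficient table
#'   and paths.
#' @export
run_associate <- function(fasta_path, energy_path, log_lambda_path,
                          outdir, n_perm = 999, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  seqs <- read_fasta(fasta_path)
  energy <- utils::read.delim(energy_path)
  ll <- utils::read.delim(log_lambda_path)
  ids <- ll$template_id
  if (!all(ids %in% names(seqs)) || !all(ids %in% energy$template_id)) {
    stop("template identifiers do not match across inputs", call. = FALSE)
  }
  log_lambda <- stats::setNames(ll$log_lambda, ids)
  mant <- efficiency_mantel(seqs[ids], log_lambda, n_perm = n_perm,
                            seed = seed)
  tab <- covariate_table(
    template_id = ids,
    gc = vapply(seqs[ids], gc_content, numeric(1)),
    energy = energy$energy[match(ids, energy$template_id)],
    log_lambda = log_lambda
  )
  coefs <- robust_lm(tab)
  paths <- list(mantel = file.path(outdir, "mantel.tsv"),
                coefficients = file.path(outdir, "coefficients.tsv"))
  write_tsv(data.frame(statistic = mant$statistic,
                       p_value = mant$p_value, n_perm = mant$n_perm,
                       alternative = mant$alternative), paths$mantel)
  write_tsv(coefs, paths$coefficients)
  record_config(list(command = "associate", fasta = fasta_path,
                     energy = energy_path,
                     log_lambda = log_lambda_path, n_perm = n_perm,
                     seed = seed),
                outdir, "associate_config.json")
  invisible(list(mantel = mant, coefficients = coefs,
                 covariates = tab, paths = paths))
}
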