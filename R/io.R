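# Readers/writers for the package's plain-text interchange formats:
# tab-separated count tables (templates x samples), sample-metadata TSV
# (sample_id, cycle, replicate), Newick trees, FASTA, parameter TSVs and
# truth JSON.

#' Write a count experiment to TSV
#'
#' @param exp A [count_experiment()].
#' @param counts_path Path for the count table (template IDs as row
#'   names, sample IDs as columns).
#' @param metadata_path Path for the sample metadata
#'   (`sample_id`, `cycle`, `replicate`).
#' @return Invisibly, the two paths.
#' @export
write_experiment <- function(exp, counts_path, metadata_path) {
  check_experiment(exp)
  tab <- data.frame(template_id = rownames(exp$counts), exp$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = colnames(exp$counts),
                     cycle = unname(exp$cycles),
                     replicate = unname(exp$replicates))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_path, metadata = metadata_path))
}

#' Read a count experiment from TSV
#'
#' @param counts_path Count table written by [write_experiment()] (first
#'   column `template_id`).
#' @param metadata_path Sample metadata TSV with columns `sample_id`,
#'   `cycle`, `replicate`.
#' @return A [count_experiment()].
#' @export
read_experiment <- function(counts_path, metadata_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  meta <- utils::read.delim(metadata_path)
  need <- c("sample_id", "cycle", "replicate")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns sample_id, cycle, replicate",
         call. = FALSE)
  }
  missing_s <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing_s)) {
    stop("samples missing from metadata: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  count_experiment(counts, cycles = meta$cycle,
                   replicates = meta$replicate)
}

#' Write / read sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path FASTA file path.
#' @return `write_fasta()` the path invisibly; `read_fasta()` a named
#'   character vector (upper case).
#' @export
write_fasta <- function(seqs, path) {
  dna <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  names(dna) <- names(seqs)
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  out <- vapply(as.character(dna),
                function(x) toupper(paste(x, collapse = "")), character(1))
  stats::setNames(out, names(dna))
}

#' Write / read per-template PCR parameters as TSV
#'
#' Columns: `template_id`, `lambda`, `theta_z` (closure-normalised).
#'
#' @param params A [pcr_params()].
#' @param path TSV path.
#' @param basis Basis used to rebuild `a` when reading.
#' @param sigma Noise scales to attach when reading (the TSV stores only
#'   per-template quantities).
#' @return `write_params()` the path invisibly; `read_params()` a
#'   [pcr_params()].
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pcr_params"))
  utils::write.table(
    data.frame(template_id = names(params$lambda),
               lambda = unname(params$lambda),
               theta_z = unname(params$theta_z)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path, basis, sigma = 0.05) {
  tab <- utils::read.delim(path)
  ord <- match(basis$leaf_order, tab$template_id)
  if (anyNA(ord)) {
    stop("parameter table does not cover the basis leaves", call. = FALSE)
  }
  pcr_params(lambda = tab$lambda[ord], theta_z = tab$theta_z[ord],
             sigma = sigma, basis = basis)
}

#' Serialise a synthetic truth to JSON
#'
#' Records the Newick tree, generating parameters, design, per-sample
#' scale factors and seed: everything needed to regenerate the dataset.
#'
#' @param truth A [synthetic_truth()].
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- list(
    newick = ape::write.tree(truth$basis$tree),
    leaf_order = truth$basis$leaf_order,
    lambda = unname(truth$params$lambda),
    a = unname(truth$params$a),
    theta_z = unname(truth$params$theta_z),
    sigma = unname(truth$params$sigma),
    cycles = truth$cycles,
    replicates = truth$replicates,
    depth = truth$depth,
    scale_factors = truth$scale_factors,
    seed = truth$seed,
    noise = truth$noise
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a synthetic truth from its JSON record
#'
#' @param path JSON written by [write_truth()].
#' @return A [synthetic_truth()].
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- contrast_basis(ape::read.tree(text = obj$newick),
                          obj$leaf_order)
  params <- pcr_params(lambda = obj$lambda, a = obj$a,
                       sigma = obj$sigma, basis = basis)
  synthetic_truth(basis, params, cycles = obj$cycles,
                  replicates = obj$replicates, depth = obj$depth,
                  scale_factors = obj$scale_factors, seed = obj$seed,
                  noise = obj$noise)
}

#' Export posterior draws as CSV
#'
#' One row per draw with `chain` and `draw` indices.
#'
#' @param post A [fit_pcr_model()] result.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_posterior <- function(post, path) {
  utils::write.csv(as.data.frame(posterior_matrix(post)), path,
                   row.names = FALSE)
  invisible(path)
}
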