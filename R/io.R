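# TSV round-tripping for datasets, test results and evaluation summaries.
# Plain TSV is the canonical on-disk format: counts with samples in rows
# and taxa in columns, a sample metadata table, a per-taxon truth sidecar,
# and a YAML manifest echoing the configuration and seed.

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_tsv_ <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to a directory
#'
#' Writes `counts.tsv` (first column `sample_id`, then one integer column
#' per taxon), `metadata.tsv` (`sample_id`, `trait`, `confounder`,
#' `library_size`), `truth.tsv` (`taxon_id`, `is_causal`,
#' `is_confounder_associated`, `gamma`, `beta1`, `beta2`, `pi_bar`) and
#' `manifest.yaml` (configuration echo plus the replicate seed).
#'
#' @param dataset A `sim_dataset` from [simulate_replicate()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- data.frame(sample_id = rownames(dataset$counts),
                       dataset$counts, check.names = FALSE)
  write_tsv_(counts, file.path(dir, "counts.tsv"))
  meta <- data.frame(sample_id = rownames(dataset$counts),
                     trait = dataset$trait,
                     confounder = dataset$confounder %||%
                       rep(NA_integer_, length(dataset$trait)),
                     library_size = dataset$library_sizes)
  write_tsv_(meta, file.path(dir, "metadata.tsv"))
  J <- ncol(dataset$counts)
  truth <- data.frame(taxon_id = colnames(dataset$counts),
                      is_causal = as.integer(dataset$beta1 != 0),
                      is_confounder_associated =
                        as.integer(dataset$beta2 != 0),
                      gamma = dataset$gamma, beta1 = dataset$beta1,
                      beta2 = dataset$beta2, pi_bar = dataset$pi_bar)
  write_tsv_(truth, file.path(dir, "truth.tsv"))
  manifest <- unclass(dataset$config)
  manifest$pi_bar <- NULL  # recoverable from truth.tsv
  manifest <- Filter(Negate(is.null), manifest)
  yaml::write_yaml(list(replicate_seed = dataset$replicate_seed,
                        config = manifest),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a simulated dataset from a directory
#'
#' Reconstructs the count matrix, covariates, truth annotations and seed
#' written by [write_dataset()]. The abundance matrices (`Pi0`, `Pi`, `P`,
#' `eta`) are not serialized; regenerate the replicate from its manifest
#' seed if they are needed.
#'
#' @param dir Directory written by [write_dataset()].
#' @return A `sim_dataset` (without the abundance matrices).
#' @export
read_dataset <- function(dir) {
  counts_df <- read_tsv_(file.path(dir, "counts.tsv"))
  counts <- as.matrix(counts_df[, -1L, drop = FALSE])
  rownames(counts) <- counts_df[[1L]]
  storage.mode(counts) <- "integer"
  meta <- read_tsv_(file.path(dir, "metadata.tsv"))
  truth <- read_tsv_(file.path(dir, "truth.tsv"))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  confounder <- meta$confounder
  if (all(is.na(confounder))) confounder <- NULL
  structure(list(counts = counts, Pi0 = NULL, Pi = NULL, P = NULL,
                 log_norm = NULL, eta = NULL,
                 library_sizes = meta$library_size,
                 trait = meta$trait, confounder = confounder,
                 causal_set = which(truth$is_causal == 1L),
                 confounder_set =
                   which(truth$is_confounder_associated == 1L),
                 gamma = truth$gamma, beta1 = truth$beta1,
                 beta2 = truth$beta2, pi_bar = truth$pi_bar,
                 half_set = NULL,
                 replicate_seed = manifest$replicate_seed,
                 config = manifest$config),
            class = "sim_dataset")
}

#' Write a test result to TSV
#'
#' One row per tested taxon: `taxon_id`, `p_value`, `q_value`, `detected`,
#' `method`, `level`.
#'
#' @param result A [da_result()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(result, path) {
  stopifnot(inherits(result, "da_result"))
  df <- data.frame(taxon_id = result$taxon_ids,
                   p_value = result$p_values,
                   q_value = result$q_values,
                   detected = as.integer(result$taxon_ids %in%
                                           result$detected),
                   method = result$method_name,
                   level = result$level)
  write_tsv_(df, path)
  invisible(path)
}

#' Write / read an evaluation summary
#'
#' @param summary An `eval_summary` from [run_grid()].
#' @param path TSV file path.
#' @return `path` (write) or a `data.frame` (read).
#' @export
write_eval_summary <- function(summary, path) {
  write_tsv_(summarize_to_table(summary), path)
  invisible(path)
}

#' @rdname write_eval_summary
#' @export
read_eval_summary <- function(path) read_tsv_(path)
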