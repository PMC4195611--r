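#' Serialize an experiment configuration to JSON
#'
#' Stores every field of an [experiment_config()] (profiles as
#' cluster -> variant -> probability maps) so a simulation can be
#' re-run from file. Requires the `jsonlite` package.
#'
#' @param config An `experiment_config`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to serialize experiment configs")
  enc_prof <- function(p) lapply(p, as.list)
  obj <- list(n_reads = config$n_reads,
              mode = config$mode,
              profile_control = enc_prof(config$profile_control),
              profile_treated = enc_prof(config$profile_treated),
              fold_changes = as.list(config$fold_changes),
              error_rates = as.list(config$error_rates),
              barcodes = as.list(config$barcodes),
              strand_random = config$strand_random,
              profile_jitter_sd = config$profile_jitter_sd,
              seed = config$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_experiment_config
#' @param path JSON path written by [write_experiment_config()].
#' @param lib The `exon_library` the profiles refer to (for
#'   validation).
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path, lib) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read experiment configs")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_prof <- function(p) usage_profile(lib, lapply(p, unlist))
  experiment_config(
    n_reads = obj$n_reads,
    profile_control = dec_prof(obj$profile_control),
    mode = obj$mode,
    profile_treated = dec_prof(obj$profile_treated),
    fold_changes = if (length(obj$fold_changes))
      unlist(obj$fold_changes) else NULL,
    error_rates = unlist(obj$error_rates),
    barcodes = unlist(obj$barcodes),
    strand_random = obj$strand_random,
    profile_jitter_sd = obj$profile_jitter_sd,
    seed = obj$seed)
}
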