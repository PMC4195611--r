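revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assemble barcoded amplicon sequences for isoforms
#'
#' An amplicon spans the constitutive exon 3--10 region: 5' barcode,
#' exon 3, the chosen cluster-4 variant, exon 5, the cluster-6 variant,
#' exons 7 and 8, the cluster-9 variant, exon 10, and the reverse
#' complement of the barcode at the 3' end (both primers carry the 7-bp
#' barcode). Deterministic in its inputs.
#'
#' @param lib An `exon_library`.
#' @param isoforms A data.frame with columns `v4`, `v6`, `v9` (as from
#'   [sample_isoforms()]), or a single named vector/list for
#'   [build_amplicon()].
#' @param barcode 7-nt barcode over `{A,C,G,T}` (recycled across rows).
#' @return Character vector of amplicon sequences.
#' @export
build_amplicons <- function(lib, isoforms, barcode) {
  stopifnot(all(grepl("^[ACGT]+$", barcode)), all(nchar(barcode) == 7))
  seqs <- setNames(
    unlist(lapply(lib$clusters, `[[`, "sequence")),
    unlist(lapply(lib$clusters, `[[`, "variant_id")))
  cs <- setNames(lib$constitutive$sequence, lib$constitutive$exon_id)
  for (cl in names(lib$clusters)) {
    col <- paste0("v", cl)
    if (is.null(isoforms[[col]]))
      stop("isoforms must provide a '", col, "' column")
    unknown <- setdiff(unique(isoforms[[col]]), names(seqs))
    if (length(unknown))
      stop("unknown variant id(s): ", paste(unknown, collapse = ", "))
  }
  paste0(barcode,
         cs[["3"]], seqs[isoforms$v4],
         cs[["5"]], seqs[isoforms$v6],
         cs[["7"]], cs[["8"]], seqs[isoforms$v9],
         cs[["10"]], revcomp_chr(barcode))
}

#' @rdname build_amplicons
#' @export
build_amplicon <- function(lib, isoforms, barcode) {
  iso <- as.list(unlist(isoforms))
  names(iso) <- paste0("v", sub("^v", "", names(iso)))
  iso <- as.data.frame(iso, stringsAsFactors = FALSE, check.names = FALSE)
  build_amplicons(lib, iso, barcode)[1]
}

#' Apply a per-base error model to amplicon sequences
#'
#' Independent per-base substitution, insertion and deletion events
#' emulating circular-consensus-like residual errors. Event counts are
#' recorded per read for auditing. Deterministic for a fixed seed.
#'
#' @param sequences Character vector of template sequences.
#' @param error_rates Named numeric vector with elements `sub`, `ins`,
#'   `del`, each in `[0, 0.2]`. Default 0.5% each.
#' @param seed Integer seed.
#' @return A data.frame with `sequence`, `n_sub`, `n_ins`, `n_del`.
#' @export
simulate_reads <- function(sequences,
                           error_rates = c(sub = 0.005, ins = 0.005,
                                           del = 0.005),
                           seed = 1L) {
  er <- error_rates[c("sub", "ins", "del")]
  if (anyNA(er)) stop("error_rates must name sub, ins and del")
  if (any(er < 0) || any(er > 0.2))
    stop("error rates must lie in [0, 0.2]")
  if (all(er == 0)) {
    n <- length(sequences)
    return(data.frame(sequence = as.character(sequences),
                      n_sub = integer(n), n_ins = integer(n),
                      n_del = integer(n), stringsAsFactors = FALSE))
  }
  set.seed(as.integer(seed))
  res <- mx_mutate_reads(as.character(sequences), er[["sub"]],
                         er[["ins"]], er[["del"]])
  data.frame(sequence = as.character(res$sequence),
             n_sub = res$n_sub, n_ins = res$n_ins, n_del = res$n_del,
             stringsAsFactors = FALSE)
}

#' @rdname simulate_reads
#' @param sequence A single template sequence.
#' @export
simulate_read <- function(sequence, error_rates = c(sub = 0.005,
                                                    ins = 0.005,
                                                    del = 0.005),
                          seed = 1L) {
  simulate_reads(sequence, error_rates, seed)
}

#' Configuration for a two-condition amplicon sequencing experiment
#'
#' In `null` mode the control and treated conditions share one generating
#' profile (no splicing change); in `effect` mode the treated profile is
#' the control profile with `fold_changes` applied via
#' [apply_fold_change()]. `profile_jitter_sd`, when positive, adds
#' log-normal biological noise to each condition's profile before
#' sampling (the default 0 reflects a pooled library per condition).
#'
#' @param n_reads Reads per condition.
#' @param profile_control A `usage_profile`.
#' @param mode `"null"` or `"effect"`.
#' @param fold_changes Named numeric vector variant_id -> fold change
#'   (effect mode only).
#' @param profile_treated Optional explicit treated profile; in null mode
#'   it must equal the control profile.
#' @param error_rates Per-base error rates (see [simulate_reads()]).
#' @param barcodes Named character vector condition -> 7-nt barcode.
#' @param strand_random Emit each read on a random strand?
#' @param profile_jitter_sd Log-normal sd of biological profile noise.
#' @param seed Integer seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_reads,
                              profile_control,
                              mode = c("null", "effect"),
                              fold_changes = NULL,
                              profile_treated = NULL,
                              error_rates = c(sub = 0.005, ins = 0.005,
                                              del = 0.005),
                              barcodes = setNames(default_barcodes()[1:2],
                                                  c("control", "treated")),
                              strand_random = TRUE,
                              profile_jitter_sd = 0,
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_reads >= 0, length(barcodes) == 2, !is.null(names(barcodes)))
  er <- error_rates[c("sub", "ins", "del")]
  if (anyNA(er) || any(er < 0) || any(er > 0.2))
    stop("error rates must lie in [0, 0.2]")
  if (mode == "null") {
    if (!is.null(profile_treated) &&
        !isTRUE(all.equal(profile_treated, profile_control)))
      stop("null mode requires identical control and treated profiles")
    profile_treated <- profile_control
    if (!is.null(fold_changes))
      stop("fold_changes are not allowed in null mode")
  } else if (is.null(profile_treated)) {
    if (is.null(fold_changes))
      stop("effect mode needs fold_changes or an explicit treated profile")
    profile_treated <- profile_control
    for (v in names(fold_changes))
      profile_treated <- apply_fold_change(profile_treated, v,
                                           fold_changes[[v]])
  }
  structure(list(n_reads = as.integer(n_reads),
                 profile_control = profile_control,
                 profile_treated = profile_treated,
                 mode = mode, fold_changes = fold_changes,
                 error_rates = er, barcodes = barcodes,
                 strand_random = isTRUE(strand_random),
                 profile_jitter_sd = profile_jitter_sd,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

jitter_profile <- function(profile, sd) {
  if (sd <= 0) return(profile)
  for (cl in names(profile)) {
    p <- profile[[cl]]
    pos <- p > 0
    p[pos] <- p[pos] * exp(rnorm(sum(pos), 0, sd))
    profile[[cl]] <- p / sum(p)
  }
  profile
}

#' Simulate a two-condition barcoded amplicon sequencing experiment
#'
#' Draws isoforms per condition from the configured profiles, assembles
#' barcoded amplicons, optionally flips strands, applies the per-base
#' error model, and (when `dir` is given) writes one FASTQ per condition
#' (Sanger Phred+33 with a constant placeholder quality) plus a
#' `truth.tsv` mapping every read to its sample barcode and generating
#' isoform. The truth table is complete: every emitted read appears
#' exactly once.
#'
#' @param config An [experiment_config()].
#' @param lib An `exon_library`.
#' @param dir Optional output directory (created if needed).
#' @return Invisibly, a list with `reads` (data.frame: `read_id`,
#'   `condition`, `sequence`, plus audit columns) and `truth` (data.frame:
#'   `read_id`, `condition`, `barcode`, `v4`, `v6`, `v9`, `strand`).
#' @export
simulate_experiment <- function(config, lib, dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  conditions <- names(config$barcodes)
  profs <- list(config$profile_control, config$profile_treated)
  all_reads <- list()
  all_truth <- list()
  for (k in seq_along(conditions)) {
    cond <- conditions[k]
    prof <- jitter_profile(profs[[k]], config$profile_jitter_sd)
    n <- config$n_reads
    iso <- sample_isoforms(lib, prof, n, seed = sample.int(2^31 - 1, 1))
    ids <- if (n > 0) sprintf("%s_%06d", cond, seq_len(n)) else character(0)
    amps <- if (n > 0) build_amplicons(lib, iso, config$barcodes[[cond]])
            else character(0)
    strand <- rep("+", n)
    if (config$strand_random && n > 0) {
      flip <- runif(n) < 0.5
      amps[flip] <- revcomp_chr(amps[flip])
      strand[flip] <- "-"
    }
    rr <- simulate_reads(amps, config$error_rates,
                         seed = sample.int(2^31 - 1, 1))
    all_reads[[cond]] <- data.frame(
      read_id = ids, condition = rep(cond, n), sequence = rr$sequence,
      n_sub = rr$n_sub, n_ins = rr$n_ins, n_del = rr$n_del,
      stringsAsFactors = FALSE)
    all_truth[[cond]] <- data.frame(
      read_id = ids, condition = rep(cond, n),
      barcode = rep(config$barcodes[[cond]], n),
      v4 = iso$v4, v6 = iso$v6, v9 = iso$v9, strand = strand,
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, c(all_reads, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(all_truth, list(make.row.names = FALSE)))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (cond in conditions) {
      d <- reads[reads$condition == cond, , drop = FALSE]
      path <- file.path(dir, paste0(cond, ".fastq"))
      write_fastq(setNames(d$sequence, d$read_id), path)
      message(sprintf("wrote %d reads to %s", nrow(d), path))
    }
    tpath <- file.path(dir, "truth.tsv")
    write.table(truth, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("wrote %d truth records to %s", nrow(truth), tpath))
  }
  invisible(list(reads = reads, truth = truth))
}

#' Write/read FASTQ with constant placeholder qualities
#'
#' Thin wrappers over Biostrings for Sanger Phred+33 FASTQ. Written
#' qualities are a constant placeholder (`"I"`, Q40), since the
#' downstream aligner is not quality-aware.
#'
#' @param sequences Named character vector (names become read ids).
#' @param path FASTQ path.
#' @return `write_fastq`: the path, invisibly. `read_fastq`: a named
#'   character vector of sequences.
#' @export
write_fastq <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(unname(as.character(sequences)))
  names(x) <- names(sequences)
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
    paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
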