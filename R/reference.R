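#' Build a combinatorial mutually-exclusive exon reference library
#'
#' Constructs a synthetic exon library with the architecture of the
#' *Dscam1* exon 3--10 amplicon: five constitutive exons (3, 5, 7, 8, 10)
#' and three clusters of mutually exclusive variable exons (clusters 4, 6
#' and 9; by default 12, 48 and 33 variants). Exactly one variant per
#' cluster is spliced into each mature transcript, so the default library
#' spans 12 x 48 x 33 = 19,008 possible isoforms. Variant sequences within
#' a cluster are generated by mutating a shared per-cluster ancestor and
#' are rejection-sampled until every pair is at least
#' `min_intervariant_divergence` diverged, which guarantees that variants
#' are distinguishable by alignment.
#'
#' The two variants of the intracellular cluster 17 lie outside the
#' sequenced exon 3--10 amplicon; they are carried as metadata counts only
#' (see [n_variable_exons()]) and have no sequence in the library.
#'
#' @param cluster_sizes Named integer vector, cluster id -> number of
#'   variants. Default `c("4" = 12, "6" = 48, "9" = 33)`.
#' @param exon_length_range Length-2 integer vector `(min, max)` for
#'   variable exon lengths in nt; one length is drawn per cluster. Must lie
#'   within `[30, 500]`.
#' @param min_intervariant_divergence Minimum pairwise per-site divergence
#'   between any two variants of a cluster, in `(0, 1]`. Default 0.25.
#' @param seed Integer seed; the library is reproducible for a fixed seed.
#' @param constitutive_length Length in nt of the constitutive exons.
#' @param pseudo_exons Character vector of variant ids that are present in
#'   the genome but never expressed (default `"6.11"`).
#' @param max_rounds Maximum rejection-sampling attempts per variant before
#'   the divergence constraint is declared unsatisfiable.
#'
#' @return An object of class `exon_library`: a list with elements
#'   `constitutive` (data.frame `exon_id`, `sequence`), `clusters` (named
#'   list of data.frames `variant_id`, `sequence`), `pseudo_exons`,
#'   `min_intervariant_divergence` and `unmodeled_clusters` (named integer
#'   vector of variable-exon counts outside the amplicon, default
#'   `c("17" = 2)`).
#' @examples
#' lib <- build_reference(cluster_sizes = c("4" = 2, "6" = 3, "9" = 2),
#'                        seed = 1)
#' isoform_space_size(lib)
#' @export
build_reference <- function(cluster_sizes = c("4" = 12L, "6" = 48L, "9" = 33L),
                            exon_length_range = c(120L, 120L),
                            min_intervariant_divergence = 0.25,
                            seed = 1L,
                            constitutive_length = 150L,
                            pseudo_exons = "6.11",
                            max_rounds = 500L) {
  stopifnot(length(cluster_sizes) >= 1, all(cluster_sizes >= 1))
  if (is.null(names(cluster_sizes)) || any(!nzchar(names(cluster_sizes))))
    stop("cluster_sizes must be a named vector (cluster id -> size)")
  if (!(min_intervariant_divergence > 0 && min_intervariant_divergence <= 1))
    stop("min_intervariant_divergence must lie in (0, 1]")
  stopifnot(length(exon_length_range) == 2,
            exon_length_range[1] <= exon_length_range[2])
  if (exon_length_range[1] < 30 || exon_length_range[2] > 500)
    stop("exon_length_range must lie within [30, 500] nt")
  if (constitutive_length < 30 || constitutive_length > 500)
    stop("constitutive_length must lie within [30, 500] nt")

  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) sample(bases, n, replace = TRUE)

  # Per-site mutation rate targeted so that expected pairwise divergence
  # between two independently mutated copies comfortably exceeds the
  # requested minimum: D(m) = 2m - (4/3)m^2, maximized at 0.75.
  target <- min(0.70, 1.5 * min_intervariant_divergence)
  disc <- 4 - (16 / 3) * target
  mrate <- if (disc > 0) (2 - sqrt(disc)) / (8 / 3) else 0.75
  mrate <- min(0.75, max(mrate, min_intervariant_divergence))

  mutate_seq <- function(s, m) {
    hit <- runif(length(s)) < m
    if (any(hit)) {
      # substitute to a uniformly chosen different base
      s[hit] <- vapply(s[hit],
                       function(b) sample(setdiff(bases, b), 1L), "")
    }
    s
  }

  constitutive_ids <- c("3", "5", "7", "8", "10")
  constitutive <- data.frame(
    exon_id = constitutive_ids,
    sequence = unname(vapply(constitutive_ids,
                             function(i) paste(rand_seq(constitutive_length),
                                               collapse = ""), "")),
    stringsAsFactors = FALSE
  )

  clusters <- vector("list", length(cluster_sizes))
  names(clusters) <- names(cluster_sizes)
  for (cl in names(cluster_sizes)) {
    n_var <- as.integer(cluster_sizes[[cl]])
    len <- if (exon_length_range[1] == exon_length_range[2])
      exon_length_range[1]
    else sample(seq(exon_length_range[1], exon_length_range[2]), 1L)
    ancestor <- rand_seq(len)
    accepted <- list()
    for (v in seq_len(n_var)) {
      ok <- FALSE
      for (round in seq_len(max_rounds)) {
        cand <- mutate_seq(ancestor, mrate)
        divs <- vapply(accepted, function(a) mean(a != cand), 0)
        if (all(divs >= min_intervariant_divergence)) {
          accepted[[v]] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not satisfy min_intervariant_divergence = ",
             min_intervariant_divergence, " for cluster ", cl,
             " (variant ", v, " of ", n_var, ") after ", max_rounds,
             " rejection-sampling rounds")
    }
    clusters[[cl]] <- data.frame(
      variant_id = paste(cl, seq_len(n_var), sep = "."),
      sequence = vapply(accepted, paste, "", collapse = ""),
      stringsAsFactors = FALSE
    )
  }

  lib <- structure(
    list(constitutive = constitutive,
         clusters = clusters,
         pseudo_exons = intersect(pseudo_exons,
                                  unlist(lapply(clusters, `[[`, "variant_id"))),
         min_intervariant_divergence = min_intervariant_divergence,
         unmodeled_clusters = c("17" = 2L)),
    class = "exon_library"
  )
  validate_exon_library(lib)
  lib
}

#' Validate an exon library
#'
#' Checks the structural invariants of an [build_reference()] library:
#' sequences over `{A,C,G,T}` of length >= 30 nt, library-wide unique
#' variant ids, and pairwise within-cluster divergence at or above
#' `min_intervariant_divergence`.
#'
#' @param lib An `exon_library`.
#' @return `lib`, invisibly; errors on violation.
#' @export
validate_exon_library <- function(lib) {
  stopifnot(inherits(lib, "exon_library"))
  all_seqs <- c(lib$constitutive$sequence,
                unlist(lapply(lib$clusters, `[[`, "sequence")))
  if (any(nchar(all_seqs) < 30))
    stop("all exon sequences must be at least 30 nt")
  if (any(grepl("[^ACGT]", all_seqs)))
    stop("exon sequences must be over {A,C,G,T}")
  ids <- unlist(lapply(lib$clusters, `[[`, "variant_id"))
  if (anyDuplicated(ids))
    stop("variant ids must be unique library-wide")
  dmin <- lib$min_intervariant_divergence
  for (cl in names(lib$clusters)) {
    seqs <- lib$clusters[[cl]]$sequence
    if (length(seqs) < 2) next
    mat <- do.call(rbind, strsplit(seqs, ""))
    for (i in seq_len(nrow(mat) - 1)) {
      div <- rowMeans(mat[(i + 1):nrow(mat), , drop = FALSE] !=
                        matrix(mat[i, ], nrow(mat) - i, ncol(mat),
                               byrow = TRUE))
      if (any(div < dmin))
        stop("cluster ", cl, ": pairwise divergence below ", dmin)
    }
  }
  invisible(lib)
}

#' Number of possible mutually exclusive isoforms
#'
#' The isoform space is the product of the cluster sizes: one variant per
#' cluster per transcript. The default library yields
#' 12 x 48 x 33 = 19,008 combinations.
#'
#' @param lib An `exon_library`.
#' @return A positive integer (as double to avoid overflow for large
#'   hypothetical libraries).
#' @export
isoform_space_size <- function(lib) {
  stopifnot(inherits(lib, "exon_library"))
  prod(vapply(lib$clusters, nrow, 0L))
}

#' Count variable exons, optionally including unmodeled clusters
#'
#' With `include_unmodeled = TRUE` (default) the count includes variable
#' exons recorded only as metadata, i.e. the two variants of the
#' intracellular cluster 17 that lie outside the exon 3--10 amplicon; the
#' default library then reports 93 + 2 = 95 variable exons.
#'
#' @param lib An `exon_library`.
#' @param include_unmodeled Include metadata-only clusters?
#' @return Integer count.
#' @export
n_variable_exons <- function(lib, include_unmodeled = TRUE) {
  n <- sum(vapply(lib$clusters, nrow, 0L))
  if (include_unmodeled) n <- n + sum(lib$unmodeled_clusters)
  as.integer(n)
}

#' Map variant ids to cluster ids
#' @param lib An `exon_library`.
#' @return Named character vector, variant_id -> cluster id.
#' @keywords internal
variant_clusters <- function(lib) {
  out <- unlist(lapply(names(lib$clusters), function(cl)
    setNames(rep(cl, nrow(lib$clusters[[cl]])),
             lib$clusters[[cl]]$variant_id)))
  out
}

#' All exon sequences of a library as one named vector
#' @keywords internal
library_sequences <- function(lib) {
  c(setNames(lib$constitutive$sequence,
             paste0("constitutive|", lib$constitutive$exon_id)),
    unlist(lapply(names(lib$clusters), function(cl)
      setNames(lib$clusters[[cl]]$sequence,
               paste0("cluster", cl, "|",
                      lib$clusters[[cl]]$variant_id)))))
}

#' Write an exon library to FASTA plus a sidecar annotation TSV
#'
#' FASTA headers encode the exon role and id (e.g. `cluster6|6.11`,
#' `constitutive|3`); the TSV lists `exon_id`, `role`, `cluster` and
#' `pseudo` (whether the variant is a never-expressed pseudo-exon).
#'
#' @param lib An `exon_library`.
#' @param fasta,tsv Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_exon_library <- function(lib, fasta, tsv) {
  seqs <- library_sequences(lib)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  vc <- variant_clusters(lib)
  ann <- rbind(
    data.frame(exon_id = lib$constitutive$exon_id, role = "constitutive",
               cluster = NA_character_, pseudo = FALSE,
               stringsAsFactors = FALSE),
    data.frame(exon_id = names(vc), role = "variable", cluster = unname(vc),
               pseudo = names(vc) %in% lib$pseudo_exons,
               stringsAsFactors = FALSE)
  )
  write.table(ann, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Read an exon library from FASTA plus sidecar TSV
#'
#' Inverse of [write_exon_library()]. The divergence threshold is not
#' stored in the files; supply the value the library was built with if the
#' reloaded object is to be re-validated.
#'
#' @param fasta,tsv Paths written by [write_exon_library()].
#' @param min_intervariant_divergence Divergence annotation to attach.
#' @return An `exon_library`.
#' @export
read_exon_library <- function(fasta, tsv, min_intervariant_divergence = 0.25) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ann <- read.table(tsv, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "logical"))
  seqv <- setNames(as.character(seqs), sub("\\|.*$", "", names(seqs)))
  ids <- sub("^[^|]*\\|", "", names(seqs))
  names(seqv) <- ids
  const <- ann[ann$role == "constitutive", ]
  vars <- ann[ann$role == "variable", ]
  clusters <- lapply(split(vars, vars$cluster), function(d)
    data.frame(variant_id = d$exon_id, sequence = unname(seqv[d$exon_id]),
               stringsAsFactors = FALSE))
  lib <- structure(
    list(constitutive = data.frame(exon_id = const$exon_id,
                                   sequence = unname(seqv[const$exon_id]),
                                   stringsAsFactors = FALSE),
         clusters = clusters[order(as.numeric(names(clusters)))],
         pseudo_exons = vars$exon_id[vars$pseudo],
         min_intervariant_divergence = min_intervariant_divergence,
         unmodeled_clusters = c("17" = 2L)),
    class = "exon_library"
  )
  validate_exon_library(lib)
  lib
}

#' @export
print.exon_library <- function(x, ...) {
  sizes <- vapply(x$clusters, nrow, 0L)
  cat("Mutually exclusive exon library\n")
  cat("  constitutive exons:", nrow(x$constitutive),
      paste0("(", paste(x$constitutive$exon_id, collapse = ", "), ")\n"))
  cat("  variable clusters: ",
      paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "), "\n")
  cat("  pseudo-exons:", if (length(x$pseudo_exons))
    paste(x$pseudo_exons, collapse = ", ") else "none", "\n")
  cat("  isoform space:", format(isoform_space_size(x), big.mark = ","), "\n")
  invisible(x)
}
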