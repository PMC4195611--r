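#' Built-in sample barcodes
#'
#' Eight 7-nt barcodes with minimum pairwise Hamming distance 3 (also
#' against reverse complements), used to tag amplicons at the 5' end of
#' the forward primer and (reverse-complemented) at the 3' end.
#'
#' @return Character vector of 7-nt barcodes.
#' @export
default_barcodes <- function() {
  c("AAAACTC", "CATGTGT", "AACTCCG", "GAAGTAG",
    "AATCTTG", "CCTTTCC", "GTGAACC", "CCCTGCA")
}

#' Aligner parameters
#'
#' Thresholds and scoring for the k-mer seeded banded local aligner.
#' The defaults mirror a BLAT-style search of short exons in long reads:
#' 8-mer tiles indexed every 5 bp with one mismatch allowed per tile,
#' minimum alignment score 20 and minimum percent identity 70. Scoring is
#' match +1, mismatch -1, gap open 2, gap extend 1 (a length-L gap costs
#' 2 + L), and identity is matches / aligned columns x 100.
#'
#' `min_seed_support` (minimum tile hits clustered on nearby diagonals
#' before extension), `diag_window` (diagonal clustering window),
#' `band_slack` (extra diagonals on either side of the seeded band) and
#' `prescreen` (minimum ungapped score on a seeded diagonal before the
#' banded extension is run) govern the seeding heuristic.
#'
#' @param min_score Minimum reported alignment score.
#' @param min_identity Minimum percent identity of reported hits.
#' @param tile_size k-mer tile size for seeding.
#' @param step Tile sampling step along the exon.
#' @param one_off Allow one mismatch inside a seed tile?
#' @param min_seed_support Minimum clustered seed count to attempt
#'   extension.
#' @param diag_window Diagonal window (bp) for seed clustering.
#' @param band_slack Extra band width (diagonals) beyond the seed window.
#' @param prescreen Minimum ungapped diagonal score before banded
#'   extension.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_ext Gap penalties (positive costs).
#' @return A named list of class `aligner_params`.
#' @export
aligner_params <- function(min_score = 20L, min_identity = 70,
                           tile_size = 8L, step = 5L, one_off = TRUE,
                           min_seed_support = 2L, diag_window = 10L,
                           band_slack = 6L, prescreen = 8L,
                           match = 1L, mismatch = -1L,
                           gap_open = 2L, gap_ext = 1L) {
  structure(list(min_score = as.integer(min_score),
                 min_identity = as.numeric(min_identity),
                 tile_size = as.integer(tile_size), step = as.integer(step),
                 one_off = isTRUE(one_off),
                 min_seed_support = as.integer(min_seed_support),
                 diag_window = as.integer(diag_window),
                 band_slack = as.integer(band_slack),
                 prescreen = as.integer(prescreen),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext)),
            class = "aligner_params")
}

# exon sequences, ids, roles and cluster-group codes in index order
exon_panel <- function(lib) {
  seqs <- library_sequences(lib)
  full <- names(seqs)
  role <- sub("\\|.*$", "", full)
  id <- sub("^[^|]*\\|", "", full)
  cluster <- ifelse(role == "constitutive", NA_character_,
                    sub("^cluster", "", role))
  group <- integer(length(full))
  cl_names <- names(lib$clusters)
  group[!is.na(cluster)] <- match(cluster[!is.na(cluster)], cl_names)
  list(sequence = unname(seqs), exon_id = id, cluster = cluster,
       group = group, cluster_names = cl_names)
}

#' Demultiplex reads by 5' sample barcode
#'
#' Each read is assigned to the unique barcode lying within
#' `max_mismatch` of its 7-nt 5' prefix in either read orientation
#' (amplicons carry the barcode at the 5' end of both strands). Reads
#' whose prefixes match no barcode, or that lie within `max_mismatch` of
#' two different barcodes (possible only across the two orientations),
#' go to the unassigned bin.
#'
#' @param reads Character vector of read sequences (optionally named by
#'   read id), or a data.frame with columns `read_id` and `sequence`.
#' @param barcode_map Named character vector, sample -> 7-nt barcode.
#'   Barcodes must be unique; `max_mismatch` must be below half the
#'   minimum pairwise Hamming distance between them.
#' @param max_mismatch Maximum allowed mismatches (default 1).
#' @return A data.frame with `read_id` and `sample` (`NA` for the
#'   unassigned bin), one row per input read, in input order.
#' @export
demultiplex <- function(reads, barcode_map, max_mismatch = 1L) {
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- reads$sequence
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(reads))) names(reads)
           else sprintf("read%d", seq_along(reads))
  }
  bc <- toupper(barcode_map)
  if (anyDuplicated(bc)) stop("duplicate barcodes in barcode_map")
  blen <- unique(nchar(bc))
  if (length(blen) != 1) stop("barcodes must share one length")
  bm <- do.call(rbind, strsplit(bc, ""))
  if (length(bc) > 1) {
    dmin <- min(vapply(seq_len(nrow(bm) - 1), function(i)
      min(rowSums(bm[-seq_len(i), , drop = FALSE] !=
                    matrix(bm[i, ], nrow(bm) - i, blen, byrow = TRUE))),
      0))
    if (max_mismatch >= dmin / 2)
      stop("max_mismatch must be < minimum pairwise barcode distance / 2 (",
           dmin, ")")
  }
  n <- length(seqs)
  if (n == 0)
    return(data.frame(read_id = character(0), sample = character(0),
                      stringsAsFactors = FALSE))
  pre_f <- toupper(substr(seqs, 1L, blen))
  tails <- substr(seqs, pmax(1L, nchar(seqs) - blen + 1L), nchar(seqs))
  pre_r <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(tails))))
  mm_for <- function(prefixes) {
    ok <- nchar(prefixes) == blen
    pm <- matrix(".", n, blen)
    pm[ok, ] <- do.call(rbind, strsplit(prefixes[ok], ""))
    vapply(seq_along(bc), function(b)
      rowSums(pm != matrix(bm[b, ], n, blen, byrow = TRUE)), numeric(n))
  }
  mm <- matrix(pmin(mm_for(pre_f), mm_for(pre_r)), nrow = n)
  within <- mm <= max_mismatch
  n_cand <- rowSums(within)
  sample_idx <- max.col(-mm, ties.method = "first")
  assigned <- ifelse(n_cand == 1, names(bc)[sample_idx], NA_character_)
  data.frame(read_id = ids, sample = assigned, stringsAsFactors = FALSE)
}

#' Align reads to the exon library
#'
#' k-mer seeded banded local alignment of each read against every exon.
#' Both read orientations are tried and the better-seeded orientation is
#' used for all exons jointly (a read is one molecule). Only hits with
#' score >= `min_score` and identity >= `min_identity` are returned, at
#' most one per (read, exon) pair. Intervals are 0-based half-open; read
#' intervals refer to the original read strand.
#'
#' @param reads Character vector of read sequences (optionally named).
#' @param lib An `exon_library`.
#' @param params An [aligner_params()] list.
#' @return A data.frame of hits: `read_id`, `exon_id`, `cluster` (`NA`
#'   for constitutive exons), `score`, `identity`, `read_start`,
#'   `read_end`, `exon_start`, `exon_end`, `strand` (`"+"`/`"-"`).
#' @export
align_reads <- function(reads, lib, params = aligner_params()) {
  panel <- exon_panel(lib)
  ids <- if (!is.null(names(reads))) names(reads)
         else sprintf("read%d", seq_along(reads))
  res <- mx_align_batch(as.character(reads), panel$sequence,
                        as.integer(panel$group), unclass(params), TRUE)
  data.frame(
    read_id = ids[res$read],
    exon_id = panel$exon_id[res$exon],
    cluster = panel$cluster[res$exon],
    score = res$score,
    identity = res$identity,
    read_start = res$read_start, read_end = res$read_end,
    exon_start = res$exon_start, exon_end = res$exon_end,
    strand = ifelse(res$strand > 0, "+", "-"),
    stringsAsFactors = FALSE
  )
}

#' @rdname align_reads
#' @param read A single read sequence.
#' @export
align_read <- function(read, lib, params = aligner_params()) {
  align_reads(read, lib, params)
}

#' Call one variant per cluster from alignment hits
#'
#' For each read and each variable cluster, the cluster is `assigned` iff
#' exactly one variant's best score exceeds every other variant's best
#' score by at least `margin`; `ambiguous` if two or more variants lie
#' within `margin` of the top score; `missing` if no hit passed the
#' alignment thresholds. A read is retained iff all three clusters are
#' assigned; only then is its isoform reported. Constitutive-exon hits do
#' not enter the retention decision.
#'
#' @param hits A hit data.frame from [align_reads()] (one or many reads).
#' @param lib An `exon_library`.
#' @param margin Score units by which the best variant must beat the
#'   runner-up (default 1, i.e. a strict maximum on integer scores).
#' @return A data.frame with one row per read: `read_id`, one
#'   status/variant column pair per cluster (`status_4`, `v4`, ...),
#'   `retained` and `isoform` (`NA` unless retained).
#' @export
call_read <- function(hits, lib, margin = 1) {
  cl_names <- names(lib$clusters)
  read_ids <- unique(hits$read_id)
  per_read <- function(h) {
    out <- list()
    retained <- TRUE
    for (cl in cl_names) {
      hc <- h[!is.na(h$cluster) & h$cluster == cl, , drop = FALSE]
      if (nrow(hc) == 0) {
        out[[paste0("status_", cl)]] <- "missing"
        out[[paste0("v", cl)]] <- NA_character_
        retained <- FALSE
        next
      }
      best_by_var <- tapply(hc$score, hc$exon_id, max)
      ord <- order(best_by_var, decreasing = TRUE)
      top <- best_by_var[ord[1]]
      second <- if (length(ord) > 1) best_by_var[ord[2]] else -Inf
      if (top - second >= margin) {
        out[[paste0("status_", cl)]] <- "assigned"
        out[[paste0("v", cl)]] <- names(best_by_var)[ord[1]]
      } else {
        out[[paste0("status_", cl)]] <- "ambiguous"
        out[[paste0("v", cl)]] <- NA_character_
        retained <- FALSE
      }
    }
    out$retained <- retained
    out$isoform <- if (retained)
      paste(unlist(out[paste0("v", cl_names)]), collapse = "|")
      else NA_character_
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(split(hits, factor(hits$read_id, read_ids)),
                               per_read))
  cbind(data.frame(read_id = read_ids, stringsAsFactors = FALSE),
        res, row.names = NULL)
}

#' Demultiplex-free fast path: align and call a batch of reads
#'
#' Runs the same aligner and calling rule as [align_reads()] +
#' [call_read()] without materializing the full hit table, which keeps
#' memory flat for libraries of 10^5 reads and more.
#'
#' @param reads Character vector of read sequences (optionally named).
#' @param lib An `exon_library`.
#' @param params An [aligner_params()] list.
#' @param margin Assignment margin in score units (see [call_read()]).
#' @return Same shape as [call_read()].
#' @export
classify_reads <- function(reads, lib, params = aligner_params(),
                           margin = 1) {
  panel <- exon_panel(lib)
  ids <- if (!is.null(names(reads))) names(reads)
         else sprintf("read%d", seq_along(reads))
  res <- mx_align_batch(as.character(reads), panel$sequence,
                        as.integer(panel$group), unclass(params), FALSE)
  cl_names <- panel$cluster_names
  out <- data.frame(read_id = ids, stringsAsFactors = FALSE)
  retained <- rep(TRUE, length(ids))
  for (g in seq_along(cl_names)) {
    n_pass <- res$n_pass[, g]
    best <- res$best_score[, g]
    second <- res$second_score[, g]
    second[is.na(second)] <- -Inf
    status <- rep("assigned", length(ids))
    status[n_pass == 0] <- "missing"
    amb <- n_pass > 1 & (best - second) < margin
    status[!is.na(amb) & amb & n_pass > 0] <- "ambiguous"
    v <- ifelse(status == "assigned",
                panel$exon_id[res$best_exon[, g]], NA_character_)
    out[[paste0("status_", cl_names[g])]] <- status
    out[[paste0("v", cl_names[g])]] <- v
    retained <- retained & status == "assigned"
  }
  out$retained <- retained
  iso <- do.call(paste, c(out[paste0("v", cl_names)], sep = "|"))
  out$isoform <- ifelse(retained, iso, NA_character_)
  out
}

#' Tally retained calls into per-variant and per-isoform count tables
#'
#' Counts satisfy the conservation invariants: within each cluster the
#' variant counts sum to the retained read count, as do the isoform
#' counts, and retained + dropped = total. Dropped reads are tallied by
#' reason (`missing` takes precedence over `ambiguous` when both occur on
#' one read) and per cluster.
#'
#' @param calls A call data.frame from [call_read()] or
#'   [classify_reads()].
#' @param sample Sample label stored in the table.
#' @param lib Optional `exon_library`; when supplied, variants with zero
#'   counts are included so all tables share the library's id universe.
#' @return An object of class `count_table`: list with `sample`,
#'   `variant_counts` (data.frame `cluster`, `variant_id`, `count`),
#'   `isoform_counts` (data.frame `isoform`, `count`), `n_total`,
#'   `n_retained`, `drop_reasons` and `cluster_status` tallies.
#' @export
count_assignments <- function(calls, sample = "sample", lib = NULL) {
  cl_names <- sub("^status_", "",
                  grep("^status_", names(calls), value = TRUE))
  retained <- calls[isTRUE_vec(calls$retained), , drop = FALSE]
  variant_counts <- do.call(rbind, lapply(cl_names, function(cl) {
    tab <- table(retained[[paste0("v", cl)]])
    ids <- if (!is.null(lib)) lib$clusters[[cl]]$variant_id
           else sort(names(tab))
    cnt <- setNames(integer(length(ids)), ids)
    cnt[names(tab)] <- as.integer(tab)
    data.frame(cluster = cl, variant_id = ids, count = unname(cnt),
               stringsAsFactors = FALSE)
  }))
  iso_tab <- table(retained$isoform)
  isoform_counts <- data.frame(isoform = names(iso_tab),
                               count = as.integer(iso_tab),
                               stringsAsFactors = FALSE)
  status_mat <- as.matrix(calls[paste0("status_", cl_names)])
  any_missing <- apply(status_mat == "missing", 1, any)
  any_amb <- apply(status_mat == "ambiguous", 1, any)
  drop_reasons <- c(missing = sum(any_missing),
                    ambiguous = sum(any_amb & !any_missing))
  cluster_status <- lapply(setNames(nm = cl_names), function(cl)
    table(factor(calls[[paste0("status_", cl)]],
                 levels = c("assigned", "ambiguous", "missing"))))
  structure(list(sample = sample,
                 variant_counts = variant_counts,
                 isoform_counts = isoform_counts,
                 n_total = nrow(calls),
                 n_retained = nrow(retained),
                 drop_reasons = drop_reasons,
                 cluster_status = cluster_status),
            class = "count_table")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.count_table <- function(x, ...) {
  cat("Count table for sample:", x$sample, "\n")
  cat("  reads:", x$n_total, " retained:", x$n_retained,
      sprintf("(%.1f%%)\n",
              if (x$n_total > 0) 100 * x$n_retained / x$n_total else 0))
  cat("  dropped: missing =", x$drop_reasons[["missing"]],
      ", ambiguous =", x$drop_reasons[["ambiguous"]], "\n")
  cat("  distinct isoforms:", nrow(x$isoform_counts), "\n")
  invisible(x)
}

#' Assemble a variant x sample count matrix from count tables
#'
#' @param tables Named list of `count_table` objects (names become
#'   column/sample names; unnamed lists use each table's `sample` field).
#' @return Integer matrix, variants x samples, with a `cluster` attribute
#'   giving each row's cluster id.
#' @export
counts_matrix <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, `[[`, "", "sample")
  vc <- tables[[1]]$variant_counts
  mat <- vapply(tables, function(tb) {
    stopifnot(identical(tb$variant_counts$variant_id, vc$variant_id))
    tb$variant_counts$count
  }, numeric(nrow(vc)))
  mat <- matrix(mat, nrow = nrow(vc),
                dimnames = list(vc$variant_id, names(tables)))
  attr(mat, "cluster") <- setNames(vc$cluster, vc$variant_id)
  mat
}

#' Read a count table back from its TSV serialization
#'
#' Inverse of [write_count_table()]. Drop-reason tallies are not stored
#' in the TSVs, so the reconstructed table carries zero drop counts and
#' `n_total = n_retained` (the retained-read universe the counts
#' describe).
#'
#' @param variant_tsv Path to a per-variant count TSV (columns `sample`,
#'   `cluster`, `variant_id`, `count`).
#' @param isoform_tsv Optional path to the matching per-isoform TSV.
#' @return A `count_table`.
#' @export
read_count_table <- function(variant_tsv, isoform_tsv = NULL) {
  vc <- read.table(variant_tsv, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "character",
                                  "integer"))
  sample <- unique(vc$sample)
  if (length(sample) != 1)
    stop("expected exactly one sample per count TSV, got: ",
         paste(sample, collapse = ", "))
  ic <- if (!is.null(isoform_tsv)) {
    d <- read.table(isoform_tsv, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer"))
    data.frame(isoform = d$isoform, count = d$count,
               stringsAsFactors = FALSE)
  } else {
    data.frame(isoform = character(0), count = integer(0))
  }
  n_ret <- sum(vc$count[vc$cluster == vc$cluster[1]])
  structure(list(sample = sample,
                 variant_counts = vc[, c("cluster", "variant_id", "count")],
                 isoform_counts = ic,
                 n_total = n_ret, n_retained = n_ret,
                 drop_reasons = c(missing = 0L, ambiguous = 0L),
                 cluster_status = list()),
            class = "count_table")
}

#' Write a count table's variant and isoform tallies to TSV
#' @param x A `count_table`.
#' @param variant_tsv,isoform_tsv Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_count_table <- function(x, variant_tsv = NULL, isoform_tsv = NULL) {
  if (!is.null(variant_tsv)) {
    d <- cbind(sample = x$sample, x$variant_counts)
    write.table(d, variant_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(isoform_tsv)) {
    d <- cbind(sample = x$sample, x$isoform_counts)
    write.table(d, isoform_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(variant_tsv, isoform_tsv))
}
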