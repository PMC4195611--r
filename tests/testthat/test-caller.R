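test_that("demultiplexing assigns exact and near-exact prefixes", {
  bc <- setNames(default_barcodes()[1:3], c("s1", "s2", "s3"))
  body <- paste(rep("ACGT", 30), collapse = "")
  reads <- c(exact = paste0(bc[["s1"]], body),
             onemm = paste0(sub("^A", "T", bc[["s2"]]), body),
             junk = paste0("GGGGGGG", body))
  res <- demultiplex(reads, bc, max_mismatch = 1)
  expect_identical(res$sample, c("s1", "s2", NA))
  expect_identical(res$read_id, names(reads))
  # reverse-oriented reads demultiplex through the 3' end
  rc_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(bc[["s3"]], body))))
  expect_identical(demultiplex(rc_read, bc)$sample, "s3")
})

test_that("cross-orientation barcode ties fall into the unassigned bin", {
  # forward prefix matches b1 exactly while the reverse-complement prefix
  # matches b2 exactly: equidistant, so the read must stay unassigned
  bc <- setNames(default_barcodes()[1:2], c("s1", "s2"))
  body <- paste(rep("ACGT", 25), collapse = "")
  tie <- paste0(bc[["s1"]], body,
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(bc[["s2"]]))))
  expect_identical(demultiplex(tie, bc)$sample, NA_character_)
})

test_that("demultiplex preconditions reject unsafe configurations", {
  bc <- setNames(default_barcodes()[1:2], c("s1", "s2"))
  expect_error(demultiplex("ACGT", c(a = "AAAACTC", b = "AAAACTC")),
               "duplicate")
  close_pair <- c(a = "AAAAAAA", b = "AAAATTT")   # Hamming distance 3
  expect_error(demultiplex("ACGT", close_pair, max_mismatch = 2),
               "distance")
  expect_silent(demultiplex("ACGTACGTACGT", close_pair, max_mismatch = 1))
  empty <- demultiplex(character(0), bc)
  expect_equal(nrow(empty), 0)
})

test_that("the calling rule implements margin, ambiguity and missingness", {
  lib <- tiny_library()
  hit <- function(read_id, exon_id, cluster, score)
    data.frame(read_id = read_id, exon_id = exon_id, cluster = cluster,
               score = score, identity = 95, read_start = 0, read_end = 50,
               exon_start = 0, exon_end = 50, strand = "+",
               stringsAsFactors = FALSE)
  hits <- rbind(
    # r1: clean winner per cluster -> retained
    hit("r1", "4.1", "4", 50), hit("r1", "6.2", "6", 55),
    hit("r1", "6.1", "6", 30), hit("r1", "9.1", "9", 48),
    # r2: two exon-6 variants tie at the top -> ambiguous, dropped
    hit("r2", "4.1", "4", 50), hit("r2", "6.1", "6", 40),
    hit("r2", "6.2", "6", 40), hit("r2", "9.1", "9", 48),
    # r3: no exon-9 hit passed -> missing, dropped
    hit("r3", "4.2", "4", 50), hit("r3", "6.3", "6", 44))
  calls <- call_read(hits, lib)
  expect_identical(calls$retained, c(TRUE, FALSE, FALSE))
  expect_identical(calls$isoform[1], "4.1|6.2|9.1")
  expect_identical(calls$status_6[2], "ambiguous")
  expect_identical(calls$status_9[3], "missing")
  expect_true(is.na(calls$isoform[2]) && is.na(calls$isoform[3]))
  # margin wider than the gap turns a winner into an ambiguity
  calls_wide <- call_read(hits[hits$read_id == "r1", ], lib, margin = 30)
  expect_identical(calls_wide$status_6, "ambiguous")
})

test_that("the fast path and the hit-level calling rule agree", {
  lib <- default_library()
  sim <- sim_with_truth(lib, 100,
                        error_rates = c(sub = 0.04, ins = 0.004,
                                        del = 0.004), seed = 13)
  seqs <- setNames(sim$reads$sequence, sim$reads$read_id)
  fast <- classify_reads(seqs, lib)
  slow <- call_read(align_reads(seqs, lib), lib)
  fast_cmp <- fast[match(slow$read_id, fast$read_id),
                   c("read_id", "status_4", "v4", "status_6", "v6",
                     "status_9", "v9", "retained", "isoform")]
  rownames(fast_cmp) <- NULL
  expect_identical(fast_cmp, slow[, names(fast_cmp)])
  # reads dropped by the aligner entirely (no hits) appear only in fast
  expect_true(all(fast$read_id[!fast$read_id %in% slow$read_id] ==
                    fast$read_id[fast$status_4 == "missing" &
                                   fast$status_6 == "missing" &
                                   fast$status_9 == "missing"]))
})

test_that("count tables satisfy the conservation invariants", {
  lib <- default_library()
  sim <- sim_with_truth(lib, 300, seed = 17)
  calls <- classify_reads(setNames(sim$reads$sequence, sim$reads$read_id),
                          lib)
  tb <- count_assignments(calls, sample = "pooled", lib = lib)
  expect_equal(tb$n_total, 600)
  for (cl in c("4", "6", "9"))
    expect_equal(sum(tb$variant_counts$count[tb$variant_counts$cluster ==
                                               cl]),
                 tb$n_retained)
  expect_equal(sum(tb$isoform_counts$count), tb$n_retained)
  expect_equal(tb$n_retained + sum(tb$drop_reasons), tb$n_total)
  expect_identical(tb$variant_counts$count[tb$variant_counts$variant_id ==
                                             "6.11"], 0L)
})

test_that("degenerate call sets tally to zero and single-isoform tables", {
  lib <- tiny_library()
  empty <- classify_reads(character(0), lib)
  tb0 <- count_assignments(empty, lib = lib)
  expect_equal(tb0$n_total, 0)
  expect_true(all(tb0$variant_counts$count == 0))

  amp <- build_amplicon(lib, c("4" = "4.1", "6" = "6.2", "9" = "9.1"),
                        default_barcodes()[1])
  calls <- classify_reads(rep(amp, 10), lib)
  tb <- count_assignments(calls, lib = lib)
  expect_equal(tb$n_retained, 10)
  expect_identical(tb$isoform_counts,
                   data.frame(isoform = "4.1|6.2|9.1", count = 10L,
                              stringsAsFactors = FALSE))
  vc <- tb$variant_counts
  expect_equal(vc$count[vc$variant_id %in% c("4.1", "6.2", "9.1")],
               rep(10L, 3))
})

test_that("misassignment stays below 0.1% at default error rates", {
  lib <- default_library()
  sim <- sim_with_truth(lib, 1000, error_rates = c(sub = 0.005,
                                                   ins = 0.005,
                                                   del = 0.005), seed = 29)
  calls <- classify_reads(setNames(sim$reads$sequence,
                                   sim$reads$read_id), lib)
  retained <- calls[calls$retained, ]
  truth <- sim$truth[match(retained$read_id, sim$truth$read_id), ]
  mis <- mean(retained$isoform != truth$isoform)
  expect_lt(mis, 0.001)
  expect_gte(mean(calls$retained), 0.95)
})

test_that("count tables round-trip through their TSV serialization", {
  lib <- tiny_library()
  sim <- sim_with_truth(lib, 80, seed = 23)
  calls <- classify_reads(sim$reads$sequence, lib)
  tb <- count_assignments(calls, sample = "rt", lib = lib)
  vtsv <- tempfile(fileext = ".tsv")
  itsv <- tempfile(fileext = ".tsv")
  write_count_table(tb, vtsv, itsv)
  back <- read_count_table(vtsv, itsv)
  expect_identical(back$sample, "rt")
  expect_equal(back$variant_counts, tb$variant_counts)
  expect_equal(back$isoform_counts, tb$isoform_counts)
  expect_equal(back$n_retained, tb$n_retained)
})

test_that("counts_matrix aligns samples over one variant universe", {
  lib <- tiny_library()
  mk <- function(seed) {
    sim <- sim_with_truth(lib, 50, seed = seed)
    calls <- classify_reads(sim$reads$sequence, lib)
    count_assignments(calls, lib = lib)
  }
  mat <- counts_matrix(list(a = mk(1), b = mk(2)))
  expect_identical(colnames(mat), c("a", "b"))
  expect_equal(nrow(mat), 7)
  expect_identical(unname(attr(mat, "cluster")[rownames(mat)]),
                   sub("\\..*", "", rownames(mat)))
})
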