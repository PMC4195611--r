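test_that("amplicons concatenate components in order, deterministically", {
  lib <- tiny_library()
  bc <- default_barcodes()[1]
  iso <- data.frame(v4 = "4.1", v6 = "6.2", v9 = "9.1",
                    stringsAsFactors = FALSE)
  amp <- build_amplicons(lib, iso, bc)
  expected_len <- 2 * 7 + 5 * 80 + 3 * 60
  expect_equal(nchar(amp), expected_len)
  expect_identical(amp, build_amplicons(lib, iso, bc))
  expect_true(startsWith(amp, bc))
  # two isoforms differing only in v6 differ only within the exon-6 segment
  iso2 <- iso
  iso2$v6 <- "6.3"
  amp2 <- build_amplicons(lib, iso2, bc)
  a <- strsplit(amp, "")[[1]]
  b <- strsplit(amp2, "")[[1]]
  seg_start <- 7 + 80 + 60 + 80   # barcode + exon3 + v4 + exon5
  diffs <- which(a != b)
  expect_true(all(diffs > seg_start & diffs <= seg_start + 60))
  expect_error(build_amplicons(lib, data.frame(v4 = "4.9", v6 = "6.1",
                                               v9 = "9.1"), bc),
               "unknown variant")
})

test_that("error-free simulation returns templates unchanged", {
  rr <- simulate_reads(c("ACGTACGTAA", "TTTTCCCCGG"),
                       c(sub = 0, ins = 0, del = 0))
  expect_identical(rr$sequence, c("ACGTACGTAA", "TTTTCCCCGG"))
  expect_true(all(rr$n_sub == 0 & rr$n_ins == 0 & rr$n_del == 0))
})

test_that("substitution counts follow the binomial error model", {
  set.seed(1)
  templates <- replicate(100, paste(sample(c("A", "C", "G", "T"), 100,
                                           TRUE), collapse = ""))
  rr <- simulate_reads(templates, c(sub = 0.01, ins = 0, del = 0),
                       seed = 5)
  n_bases <- 100 * 100
  expected <- n_bases * 0.01
  se <- sqrt(n_bases * 0.01 * 0.99)
  expect_true(abs(sum(rr$n_sub) - expected) <= 3 * se)
  expect_identical(nchar(rr$sequence), nchar(templates))
  rr2 <- simulate_reads(templates, c(sub = 0, ins = 0.02, del = 0.02),
                        seed = 6)
  expect_equal(nchar(rr2$sequence) - 100, rr2$n_ins - rr2$n_del)
})

test_that("error rates outside [0, 0.2] are rejected", {
  expect_error(simulate_reads("ACGT", c(sub = 0, ins = 0, del = 1)),
               "0, 0.2")
  expect_error(simulate_reads("ACGT", c(sub = 0.5, ins = 0, del = 0)),
               "0, 0.2")
  expect_error(experiment_config(10, uniform_profile(tiny_library()),
                                 error_rates = c(sub = 0.3, ins = 0,
                                                 del = 0)),
               "0, 0.2")
})

test_that("experiment simulation emits a complete, seeded truth table", {
  lib <- tiny_library()
  sim <- sim_with_truth(lib, 200, seed = 3)
  expect_equal(nrow(sim$reads), 400)
  expect_identical(sim$reads$read_id, sim$truth$read_id)
  expect_identical(anyDuplicated(sim$truth$read_id), 0L)
  expect_true(all(table(sim$truth$condition) == 200))
  expect_true(all(nchar(sim$truth$barcode) == 7))
  sim2 <- sim_with_truth(lib, 200, seed = 3)
  expect_identical(sim$reads, sim2$reads)
})

test_that("null mode forbids fold changes and divergent profiles", {
  lib <- tiny_library()
  prof <- uniform_profile(lib)
  expect_error(experiment_config(10, prof, mode = "null",
                                 fold_changes = c("4.1" = 2)),
               "not allowed")
  other <- apply_fold_change(prof, "4.1", 2)
  expect_error(experiment_config(10, prof, mode = "null",
                                 profile_treated = other),
               "identical")
  cfg <- experiment_config(10, prof, mode = "effect",
                           fold_changes = c("4.1" = 2))
  expect_gt(cfg$profile_treated[["4"]]["4.1"],
            cfg$profile_control[["4"]]["4.1"])
})

test_that("FASTQ output round-trips and n_reads = 0 yields valid files", {
  lib <- tiny_library()
  dir <- tempfile("sim")
  cfg <- experiment_config(25, uniform_profile(lib), mode = "null",
                           error_rates = c(sub = 0, ins = 0, del = 0),
                           seed = 4)
  sim <- suppressMessages(simulate_experiment(cfg, lib, dir = dir))
  reads <- read_fastq(file.path(dir, "control.fastq"))
  ctrl <- sim$reads[sim$reads$condition == "control", ]
  expect_identical(unname(reads), ctrl$sequence)
  expect_identical(names(reads), ctrl$read_id)
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE,
                      sep = "\t", colClasses = "character")
  expect_equal(nrow(truth), 50)

  dir0 <- tempfile("sim0")
  cfg0 <- experiment_config(0, uniform_profile(lib), mode = "null")
  sim0 <- suppressMessages(simulate_experiment(cfg0, lib, dir = dir0))
  expect_equal(nrow(sim0$truth), 0)
  expect_length(read_fastq(file.path(dir0, "control.fastq")), 0)
})

test_that("experiment configs round-trip through JSON", {
  lib <- tiny_library()
  cfg <- experiment_config(500, uniform_profile(lib), mode = "effect",
                           fold_changes = c("4.1" = 3),
                           error_rates = c(sub = 0.01, ins = 0,
                                           del = 0.002),
                           seed = 12)
  path <- tempfile(fileext = ".json")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path, lib)
  expect_equal(back$profile_control, cfg$profile_control)
  expect_equal(back$profile_treated, cfg$profile_treated)
  expect_identical(back$n_reads, cfg$n_reads)
  expect_identical(back$barcodes, cfg$barcodes)
  expect_equal(back$error_rates, cfg$error_rates)
  expect_identical(back$seed, cfg$seed)
})

test_that("simulated Cp tables honour effects, noise and the reference", {
  noiseless <- simulate_cp_table(effects = c(Diptericin = 0), noise_sd = 0,
                                 n_reps = 3, seed = 1)
  v <- noiseless$values
  for (g in unique(v$gene))
    expect_equal(v$cp[v$gene == g & v$group == "control"],
                 v$cp[v$gene == g & v$group == "treated"])
  shifted <- simulate_cp_table(effects = c(Diptericin = -2), noise_sd = 0,
                               n_reps = 3, seed = 1)
  v <- shifted$values
  expect_equal(unique(v$cp[v$gene == "Diptericin" & v$group == "treated"]) -
                 unique(v$cp[v$gene == "Diptericin" & v$group == "control"]),
               -2)
  expect_equal(v$cp[v$gene == "rpL13a" & v$group == "control"],
               v$cp[v$gene == "rpL13a" & v$group == "treated"])
  expect_error(simulate_cp_table(effects = c(rpL13a = -1), noise_sd = 0.1),
               "reference gene")
  expect_error(simulate_cp_table(n_reps = 1), "n_reps")
})

test_that("cp_table constructor enforces its invariants", {
  genes <- default_gene_panel()
  vals <- data.frame(gene = "Diptericin", group = "control",
                     replicate = "rep1", cp = 24)
  expect_s3_class(cp_table(vals, genes), "cp_table")
  expect_error(cp_table(transform(vals, cp = -1), genes), "positive")
  bad_e <- transform(genes, efficiency = c(2.2, 1.9, 2, 1.98))
  expect_error(cp_table(vals, bad_e), "1, 2")
  two_ref <- transform(genes, role = c("reference", "target", "target",
                                       "reference"))
  expect_error(cp_table(vals, two_ref), "exactly one reference")
})
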