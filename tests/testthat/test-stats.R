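test_that("size factors reproduce hand-computed median-of-ratios", {
  a <- c(10, 20, 40)
  m <- cbind(a = a, b = 2 * a)
  expect_equal(unname(size_factors(m) / size_factors(m)["a"]),
               c(1, 2))
  ident <- cbind(x = a, y = a)
  expect_equal(unname(size_factors(ident)), c(1, 1))
  # 3-variant toy, worked by hand: geometric means (14.142, 14.142,
  # 56.569); per-sample ratio medians 1/sqrt(2) and sqrt(2)
  toy <- cbind(s1 = c(10, 20, 40), s2 = c(20, 10, 80))
  expect_equal(unname(size_factors(toy)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_error(size_factors(cbind(c(0, 5), c(3, 0))), "nonzero")
})

test_that("identical counts give p = 1 and all-zero variants are flagged", {
  m <- cbind(a = c(30L, 50L, 0L), b = c(30L, 50L, 0L))
  rownames(m) <- c("v1", "v2", "v3")
  res <- nb_exact_test(m, c("a", "b"))
  expect_equal(res$p_value[1:2], c(1, 1))
  expect_equal(res$p_value[3], 1)
  expect_identical(res$flag[3], "all_zero")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("the exact test matches binomial enumeration in the Poisson limit", {
  eq <- rep(20:39, 3)
  m <- cbind(a = c(eq, 10L), b = c(eq, 40L))
  rownames(m) <- c(sprintf("v%d", seq_along(eq)), "target")
  res <- nb_exact_test(m, c("a", "b"))
  tr <- res[res$variant_id == "target", ]
  expect_equal(tr$dispersion, 0)
  # independent conditional-binomial oracle: given 50 total and equal
  # size factors, counts in condition A are Binomial(50, 1/2)
  d <- dbinom(0:50, 50, 0.5)
  p_oracle <- sum(d[d <= d[11] * (1 + 1e-7)])
  expect_equal(tr$p_value, p_oracle, tolerance = 1e-6)
  expect_equal(tr$fold_change, 4)
})

test_that("the exact test is symmetric under condition-label swap", {
  set.seed(8)
  m <- cbind(a = rpois(30, 60), b = rpois(30, 60))
  rownames(m) <- sprintf("v%d", 1:30)
  res_ab <- nb_exact_test(m, c("a", "b"))
  res_ba <- nb_exact_test(m[, c(2, 1)], c("b", "a"))
  expect_equal(res_ab$p_value, res_ba$p_value, tolerance = 1e-12)
})

test_that("BH adjustment equals a brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("exon proportions normalize per cluster and resist scaling", {
  lib <- tiny_library()
  calls <- classify_reads(rep(build_amplicon(
    lib, c("4" = "4.1", "6" = "6.2", "9" = "9.1"),
    default_barcodes()[1]), 4), lib)
  tb <- count_assignments(calls, lib = lib)
  tb$variant_counts$count <- c(10L, 30L, 0L, 60L, 40L, 5L, 0L)[
    seq_len(nrow(tb$variant_counts))]
  # cluster 4 counts (10, 30) -> proportions (0.25, 0.75)
  prop <- exon_proportions(tb)
  expect_equal(unname(prop[["4"]]), c(0.25, 0.75))
  expect_equal(sum(prop[["6"]]), 1)
  scaled <- tb
  scaled$variant_counts$count <- tb$variant_counts$count * 7L
  expect_equal(exon_proportions(scaled), prop)
  zero <- tb
  zero$variant_counts$count[zero$variant_counts$cluster == "9"] <- 0L
  expect_warning(pz <- exon_proportions(zero), "zero total")
  expect_length(pz[["9"]], 0)
})

test_that("frequency correlations behave at both extremes", {
  lib <- tiny_library()
  sim <- sim_with_truth(lib, 150, seed = 5)
  calls <- classify_reads(setNames(sim$reads$sequence,
                                   sim$reads$read_id), lib)
  ctrl <- sim$truth$read_id[sim$truth$condition == "control"]
  tb_a <- count_assignments(calls[calls$read_id %in% ctrl, ],
                            sample = "ctrl", lib = lib)
  tb_b <- count_assignments(calls[!calls$read_id %in% ctrl, ],
                            sample = "trt", lib = lib)
  self <- frequency_correlation(tb_a, tb_a, level = "exon")
  expect_equal(self$r_squared, 1)
  both <- frequency_correlation(tb_a, tb_b, level = "isoform")
  expect_gte(both$n_points, 3)
  expect_true(both$p_value >= 0 && both$p_value <= 1)
  const <- tb_a
  const$variant_counts$count <- rep(1L, nrow(const$variant_counts))
  expect_error(frequency_correlation(const, tb_b, level = "exon"),
               "zero variance")
})

test_that("independent null frequencies show no systematic correlation", {
  # null behaviour of r^2 between unrelated frequency profiles
  set.seed(31)
  mk_table <- function(counts, sample) {
    structure(list(sample = sample,
                   variant_counts = data.frame(
                     cluster = "4",
                     variant_id = sprintf("4.%d", seq_along(counts)),
                     count = counts, stringsAsFactors = FALSE),
                   isoform_counts = data.frame(isoform = character(0),
                                               count = integer(0)),
                   n_total = sum(counts), n_retained = sum(counts),
                   drop_reasons = c(missing = 0L, ambiguous = 0L),
                   cluster_status = list()),
              class = "count_table")
  }
  r2 <- replicate(500, {
    a <- mk_table(1L + rpois(30, lambda = 50), "a")
    b <- mk_table(1L + rpois(30, lambda = 50), "b")
    frequency_correlation(a, b, level = "exon")$r_squared
  })
  expect_lt(mean(r2), 0.05)   # null r^2 has mean ~ 1/(n - 1)
})

test_that("exon_usage_test corrects within the requested family", {
  lib <- default_library()
  mk <- function(n, profile, seed) {
    cnt <- sample_variant_counts(lib, profile, n, seed = seed)
    calls <- data.frame()   # construct the count_table directly
    vc <- do.call(rbind, lapply(names(lib$clusters), function(cl) {
      ids <- lib$clusters[[cl]]$variant_id
      data.frame(cluster = cl, variant_id = ids,
                 count = as.integer(cnt[ids]), stringsAsFactors = FALSE)
    }))
    structure(list(sample = paste0("s", seed), variant_counts = vc,
                   isoform_counts = data.frame(isoform = character(0),
                                               count = integer(0)),
                   n_total = n, n_retained = n,
                   drop_reasons = c(missing = 0L, ambiguous = 0L),
                   cluster_status = list()),
              class = "count_table")
  }
  prof <- uniform_profile(lib)
  shifted <- apply_fold_change(prof, "4.3", 4)
  res <- exon_usage_test(mk(20000, prof, 1), mk(20000, shifted, 2))
  expect_identical(attr(res, "correction_family"), "per-cluster")
  expect_lt(res$p_adjusted[res$variant_id == "4.3"], 0.05)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  pooled <- exon_usage_test(mk(20000, prof, 1), mk(20000, shifted, 2),
                            family = "pooled")
  expect_equal(pooled$p_adjusted, bh_adjust(pooled$p_value))
})
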