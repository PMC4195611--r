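#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each count is divided by its
#' variant's geometric mean across samples, and the size factor is the
#' per-sample median of those ratios over variants with nonzero counts in
#' every sample.
#'
#' @param counts Numeric matrix, variants x samples.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no variant has nonzero counts in all samples; ",
         "size factors are undefined")
  loggm <- rowMeans(log(counts[ok, , drop = FALSE]))
  apply(counts[ok, , drop = FALSE], 2, function(col)
    median(exp(log(col) - loggm)))
}

# method-of-moments dispersion estimates with a parametric fit
# alpha(q) = a0 + a1/q, least squares over variants; the fitted value is
# truncated at 0 (Poisson limit).
fit_dispersions <- function(counts, sf, labels, mode) {
  q <- sweep(counts, 2, sf, "/")
  q0 <- rowSums(counts) / sum(sf)
  minv <- mean(1 / sf)
  if (mode == "blind-pooled") {
    w <- apply(q, 1, stats::var)
  } else {
    lv <- unique(labels)
    parts <- lapply(lv, function(l)
      apply(q[, labels == l, drop = FALSE], 1, stats::var))
    dfs <- vapply(lv, function(l) sum(labels == l) - 1, 0)
    if (any(dfs < 1))
      stop("per-condition dispersion needs >= 2 samples per condition")
    w <- (parts[[1]] * dfs[1] + parts[[2]] * dfs[2]) / sum(dfs)
  }
  raw <- (w - q0 * minv) / q0^2
  use <- is.finite(raw) & q0 > 0
  fitted <- rep(0, length(q0))
  if (sum(use) >= 2 && stats::var(1 / q0[use]) > 0) {
    fit <- lm(raw[use] ~ I(1 / q0[use]))
    a <- coef(fit)
    fitted <- a[1] + a[2] / q0
  } else if (any(use)) {
    fitted <- rep(mean(raw[use]), length(q0))
  }
  fitted[!is.finite(fitted)] <- 0
  pmax(fitted, 0)
}

#' Negative binomial exact test for per-variant count differences
#'
#' For each exon variant, tests whether counts differ between two
#' conditions using an exact test conditional on the variant's total:
#' under the null the probability of observing `k` reads in condition A
#' given `k_A + k_B` total is proportional to the product of two negative
#' binomial densities with pooled mean and fitted dispersion, and the
#' two-sided p-value sums the probabilities of all outcomes at most as
#' likely as the observed one. Samples are depth-normalized with
#' median-of-ratios [size_factors()]. Dispersions are method-of-moments
#' estimates shrunk through a parametric mean-dispersion fit
#' (`alpha = a0 + a1/mean`, least squares); with only one sample per
#' condition the `"blind-pooled"` mode treats the two conditions as
#' replicates, the conservative no-replicate strategy. Where the fitted
#' dispersion is zero or below, the Poisson limit is used. Variants with
#' zero counts everywhere get `p = 1` and are flagged.
#'
#' @param counts Integer matrix, variants x samples (rownames = variant
#'   ids).
#' @param labels Character/factor vector of length `ncol(counts)` with
#'   exactly two levels (first level = condition A).
#' @param dispersion_mode `"blind-pooled"` (default) or
#'   `"per-condition"` (requires >= 2 samples per condition).
#' @return A data.frame with one row per variant: `variant_id`,
#'   `count_a`, `count_b` (raw totals), `base_mean_a`, `base_mean_b`
#'   (normalized means), `fold_change` (B over A of normalized means; no
#'   pseudocount, `Inf` when A is zero and B is not), `dispersion`,
#'   `p_value` and `flag`.
#' @export
nb_exact_test <- function(counts, labels,
                          dispersion_mode = c("blind-pooled",
                                              "per-condition")) {
  dispersion_mode <- match.arg(dispersion_mode)
  counts <- as.matrix(counts)
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2)
    stop("exactly two conditions are required (got ",
         length(lv), ")")
  sf <- size_factors(counts)
  alpha <- fit_dispersions(counts, sf, labels, dispersion_mode)
  in_a <- labels == lv[1]
  sA <- sum(sf[in_a]); sB <- sum(sf[!in_a])
  s2A <- sum(sf[in_a]^2); s2B <- sum(sf[!in_a]^2)
  kA <- rowSums(counts[, in_a, drop = FALSE])
  kB <- rowSums(counts[, !in_a, drop = FALSE])
  q0 <- (kA + kB) / (sA + sB)
  base_a <- kA / sA
  base_b <- kB / sB
  n_var <- nrow(counts)
  p <- numeric(n_var)
  flag <- character(n_var)
  for (i in seq_len(n_var)) {
    tot <- kA[i] + kB[i]
    if (tot == 0) {
      p[i] <- 1
      flag[i] <- "all_zero"
      next
    }
    muA <- q0[i] * sA
    muB <- q0[i] * sB
    ks <- 0:tot
    if (alpha[i] <= 0) {
      lp <- dpois(ks, muA, log = TRUE) + dpois(tot - ks, muB, log = TRUE)
    } else {
      sizeA <- sA^2 / (alpha[i] * s2A)
      sizeB <- sB^2 / (alpha[i] * s2B)
      lp <- dnbinom(ks, mu = muA, size = sizeA, log = TRUE) +
        dnbinom(tot - ks, mu = muB, size = sizeB, log = TRUE)
    }
    w <- exp(lp - max(lp))
    p[i] <- sum(w[w <= w[kA[i] + 1] * (1 + 1e-7)]) / sum(w)
    flag[i] <- ""
  }
  fc <- ifelse(base_a == 0 & base_b == 0, NA_real_, base_b / base_a)
  flag[is.infinite(fc)] <- paste0(flag[is.infinite(fc)], "zero_denominator")
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("variant%d", seq_len(n_var))
  data.frame(variant_id = ids, count_a = kA, count_b = kB,
             base_mean_a = base_a, base_mean_b = base_b,
             fold_change = fc, dispersion = alpha,
             p_value = pmin(1, p), flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False discovery rate control across a family of tests; adjusted
#' values are monotone in rank order, capped at 1, and returned in the
#' input order. Thin wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-exon differential usage between two count tables
#'
#' Convenience wrapper joining two samples' variant counts, running
#' [nb_exact_test()] and attaching BH-adjusted p-values. The
#' multiple-testing family defaults to one family per cluster (each
#' cluster's variants corrected together); `"pooled"` corrects all
#' variants as one family. The choice is recorded in the result's
#' `correction_family` attribute.
#'
#' @param table_a,table_b `count_table` objects (condition A and B).
#' @param family `"per-cluster"` (default) or `"pooled"`.
#' @param dispersion_mode Passed to [nb_exact_test()].
#' @return The [nb_exact_test()] data.frame plus `cluster` and
#'   `p_adjusted` columns.
#' @export
exon_usage_test <- function(table_a, table_b,
                            family = c("per-cluster", "pooled"),
                            dispersion_mode = "blind-pooled") {
  family <- match.arg(family)
  mat <- counts_matrix(list(a = table_a, b = table_b))
  res <- nb_exact_test(mat, c("a", "b"), dispersion_mode)
  res$cluster <- unname(attr(mat, "cluster")[res$variant_id])
  res$p_adjusted <- if (family == "pooled") bh_adjust(res$p_value)
  else stats::ave(res$p_value, res$cluster,
                  FUN = function(x) bh_adjust(x))
  attr(res, "correction_family") <- family
  res
}

#' Per-cluster exon usage proportions
#'
#' Each variant's retained read count divided by its cluster's total.
#' A cluster with zero total yields an explicit empty profile (with a
#' warning), never NaNs.
#'
#' @param count_table A `count_table`.
#' @return A named list (one element per cluster) of named proportion
#'   vectors, class `proportion_profile`.
#' @export
exon_proportions <- function(count_table) {
  vc <- count_table$variant_counts
  out <- lapply(split(vc, vc$cluster), function(d) {
    tot <- sum(d$count)
    if (tot == 0) {
      warning("cluster ", d$cluster[1],
              ": zero total count, empty proportion profile")
      return(setNames(numeric(0), character(0)))
    }
    setNames(d$count / tot, d$variant_id)
  })
  structure(out[order(as.numeric(names(out)))],
            class = "proportion_profile")
}

freq_vector <- function(tb, level) {
  if (tb$n_retained == 0) stop("count table '", tb$sample,
                               "' has no retained reads")
  if (level == "exon") {
    setNames(tb$variant_counts$count / tb$n_retained,
             tb$variant_counts$variant_id)
  } else {
    setNames(tb$isoform_counts$count / tb$n_retained,
             tb$isoform_counts$isoform)
  }
}

#' Correlation of exon or isoform frequencies between two samples
#'
#' Pearson correlation of per-id frequencies (counts over retained
#' total) on the union of ids observed in either sample (absent = 0),
#' with a two-sided p-value from the t-distribution.
#'
#' @param table_a,table_b `count_table` objects.
#' @param level `"exon"` (per-variant frequencies) or `"isoform"`.
#' @return List with `r_squared`, `p_value` and `n_points`.
#' @export
frequency_correlation <- function(table_a, table_b,
                                  level = c("exon", "isoform")) {
  level <- match.arg(level)
  fa <- freq_vector(table_a, level)
  fb <- freq_vector(table_b, level)
  ids <- union(names(fa), names(fb))
  if (length(ids) < 3)
    stop("need at least 3 shared ids to correlate (got ",
         length(ids), ")")
  x <- ifelse(ids %in% names(fa), fa[ids], 0)
  y <- ifelse(ids %in% names(fb), fb[ids], 0)
  if (stats::var(x) == 0)
    stop("zero variance in frequencies of sample '", table_a$sample, "'")
  if (stats::var(y) == 0)
    stop("zero variance in frequencies of sample '", table_b$sample, "'")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value,
       n_points = length(ids))
}
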