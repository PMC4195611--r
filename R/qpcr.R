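#' Crossing-point (Cp) table with per-gene amplification efficiencies
#'
#' Holds qPCR crossing points (cycle at which fluorescence crosses the
#' detection criterion; lower Cp = more template) for target and
#' reference genes over biological replicates in two groups, plus each
#' gene's amplification efficiency E (per-cycle amplification factor,
#' ideally 2). Exactly one gene must carry the `reference` role, all Cp
#' values must be positive, and efficiencies must lie in (1, 2].
#'
#' @param values A data.frame with columns `gene`, `group`, `replicate`
#'   and `cp` (cycles).
#' @param genes A data.frame with columns `gene`, `efficiency` and
#'   `role` (`"target"` or `"reference"`).
#' @return An object of class `cp_table`.
#' @export
cp_table <- function(values, genes) {
  stopifnot(all(c("gene", "group", "replicate", "cp") %in% names(values)),
            all(c("gene", "efficiency", "role") %in% names(genes)))
  if (any(values$cp <= 0)) stop("Cp values must be positive")
  if (any(genes$efficiency <= 1 | genes$efficiency > 2))
    stop("amplification efficiencies must lie in (1, 2]")
  if (sum(genes$role == "reference") != 1)
    stop("exactly one reference gene is required")
  if (anyDuplicated(genes$gene)) stop("duplicate gene metadata rows")
  unknown <- setdiff(values$gene, genes$gene)
  if (length(unknown))
    stop("Cp rows for genes without metadata: ",
         paste(unknown, collapse = ", "))
  structure(list(values = values, genes = genes), class = "cp_table")
}

#' @export
print.cp_table <- function(x, ...) {
  cat("Cp table:", length(unique(x$values$gene)), "genes,",
      length(unique(x$values$group)), "groups,",
      nrow(x$values), "measurements\n")
  ref <- x$genes$gene[x$genes$role == "reference"]
  cat("  reference gene:", ref, "\n")
  invisible(x)
}

#' Default gene panel for qPCR simulations
#'
#' Two antimicrobial peptide targets (*Diptericin*, *Drosomycin*), the
#' *Dscam1* constitutive-exon assay, and the *rpL13a* reference, with
#' their measured amplification efficiencies (1.979, 1.945, 2.0, 1.98).
#'
#' @return A gene metadata data.frame for [cp_table()].
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("Diptericin", "Drosomycin", "Dscam1", "rpL13a"),
    efficiency = c(1.979, 1.945, 2.0, 1.98),
    role = c("target", "target", "target", "reference"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a Cp table under group effects and Gaussian cycle noise
#'
#' Each gene gets a control-group mean Cp (`baseline`) and a treated
#' group mean shifted by `effects[gene]` cycles (negative shift = more
#' template in the treated group = upregulation). Replicate Cp values are
#' the group mean plus Gaussian noise on the cycle scale. The reference
#' gene is never shifted between groups.
#'
#' @param effects Named numeric vector, gene -> Cp shift of the treated
#'   group (cycles). Genes not named get shift 0; the reference gene's
#'   shift must be 0 if named.
#' @param noise_sd Gaussian Cp noise (cycles), `>= 0`.
#' @param n_reps Biological replicates per group, `>= 2`.
#' @param genes Gene metadata (see [cp_table()]); default
#'   [default_gene_panel()].
#' @param baseline Named numeric vector of control-group mean Cp values;
#'   genes not named default to 24 cycles.
#' @param groups Length-2 character vector of group labels.
#' @param seed Integer seed.
#' @return A `cp_table`.
#' @export
simulate_cp_table <- function(effects = c(Diptericin = 0),
                              noise_sd = 0.2, n_reps = 3,
                              genes = default_gene_panel(),
                              baseline = NULL,
                              groups = c("control", "treated"),
                              seed = 1L) {
  stopifnot(n_reps >= 2, noise_sd >= 0, length(groups) == 2)
  ref <- genes$gene[genes$role == "reference"]
  if (!is.null(effects) && ref %in% names(effects) &&
      effects[[ref]] != 0)
    stop("the reference gene must not be shifted between groups")
  base <- setNames(rep(24, nrow(genes)), genes$gene)
  if (!is.null(baseline)) base[names(baseline)] <- baseline
  set.seed(as.integer(seed))
  rows <- list()
  for (g in genes$gene) {
    shift <- if (!is.null(effects) && g %in% names(effects))
      effects[[g]] else 0
    for (grp_i in 1:2) {
      mu <- base[[g]] + if (grp_i == 2) shift else 0
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, group = groups[grp_i],
        replicate = sprintf("rep%d", seq_len(n_reps)),
        cp = mu + rnorm(n_reps, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  cp_table(do.call(rbind, rows), genes)
}

cp_pairs <- function(cp, target_gene, reference_gene, groups) {
  v <- cp$values
  for (g in c(target_gene, reference_gene)) {
    if (!g %in% v$gene) stop("gene not present in Cp table: ", g)
    for (grp in groups)
      if (!any(v$gene == g & v$group == grp))
        stop("gene ", g, " has no replicates in group '", grp, "'")
  }
  tg <- v[v$gene == target_gene, ]
  rf <- v[v$gene == reference_gene, ]
  m <- merge(tg[, c("group", "replicate", "cp")],
             rf[, c("group", "replicate", "cp")],
             by = c("group", "replicate"), suffixes = c("_target", "_ref"))
  if (nrow(m) < nrow(tg) || nrow(m) < nrow(rf))
    stop("target and reference replicates do not pair up by ",
         "(group, replicate)")
  m[order(match(m$group, groups), m$replicate), ]
}

ratio_from_groups <- function(cp_t, cp_r, is_control, e_t, e_r) {
  dct <- mean(cp_t[is_control]) - mean(cp_t[!is_control])
  dcr <- mean(cp_r[is_control]) - mean(cp_r[!is_control])
  e_t^dct / e_r^dcr
}

#' Efficiency-corrected relative expression ratio (Pfaffl model)
#'
#' Computes `ratio = E_target^dCp_target / E_reference^dCp_reference`
#' with `dCp = mean Cp(control) - mean Cp(treated)` per gene and E the
#' gene's amplification efficiency. A ratio above 1 means the target is
#' upregulated in the treated group relative to the reference gene.
#'
#' @param cp A `cp_table`.
#' @param target_gene,reference_gene Gene names present in `cp`.
#' @param groups Length-2 character vector naming the control and
#'   treated groups, in that order.
#' @return The ratio (positive scalar).
#' @export
pfaffl_ratio <- function(cp, target_gene, reference_gene,
                         groups = c("control", "treated")) {
  stopifnot(inherits(cp, "cp_table"))
  eff <- setNames(cp$genes$efficiency, cp$genes$gene)
  m <- cp_pairs(cp, target_gene, reference_gene, groups)
  is_control <- m$group == groups[1]
  ratio_from_groups(m$cp_target, m$cp_ref, is_control,
                    eff[[target_gene]], eff[[reference_gene]])
}

#' Pair-wise fixed reallocation randomization test for relative expression
#'
#' Tests whether the efficiency-corrected expression ratio of a target
#' gene (normalized to the reference gene) differs between two groups.
#' The observed per-replicate (target Cp, reference Cp) pairs are
#' repeatedly reallocated to two groups of the original sizes -- each
#' replicate's target and reference values stay together ("fixed"
#' pairing) -- and the ratio is recomputed for each reallocation. The
#' two-sided p-value is the proportion of reallocations whose
#' `|log ratio|` is at least the observed `|log ratio|`. When the number
#' of distinct reallocations does not exceed `n_reallocations` the test
#' enumerates them exhaustively (the observed allocation is then one of
#' them); otherwise `n_reallocations` random reallocations are drawn.
#' The mean and standard error of the reallocated ratio distribution are
#' reported alongside the point ratio.
#'
#' @inheritParams pfaffl_ratio
#' @param n_reallocations Number of reallocations (default 2000).
#' @param seed Integer seed (used only when sampling).
#' @return An object of class `rest_result`: list with `gene`, `ratio`,
#'   `mean_ratio`, `se_ratio`, `p_value`, `n_reallocations` and
#'   `exhaustive`.
#' @export
fixed_reallocation_test <- function(cp, target_gene, reference_gene,
                                    groups = c("control", "treated"),
                                    n_reallocations = 2000L, seed = 1L) {
  stopifnot(inherits(cp, "cp_table"))
  eff <- setNames(cp$genes$efficiency, cp$genes$gene)
  e_t <- eff[[target_gene]]
  e_r <- eff[[reference_gene]]
  m <- cp_pairs(cp, target_gene, reference_gene, groups)
  n1 <- sum(m$group == groups[1])
  n2 <- sum(m$group == groups[2])
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 replicates (got ", n1, " and ",
         n2, ")")
  n <- n1 + n2
  obs_ratio <- ratio_from_groups(m$cp_target, m$cp_ref,
                                 m$group == groups[1], e_t, e_r)
  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= n_reallocations
  alloc <- if (exhaustive) {
    combn(n, n1)
  } else {
    set.seed(as.integer(seed))
    replicate(n_reallocations, sample.int(n, n1))
  }
  k <- ncol(alloc)
  ratios <- numeric(k)
  for (j in seq_len(k)) {
    is_ctrl <- logical(n)
    is_ctrl[alloc[, j]] <- TRUE
    ratios[j] <- ratio_from_groups(m$cp_target, m$cp_ref, is_ctrl,
                                   e_t, e_r)
  }
  tol <- 1e-12
  p <- mean(abs(log(ratios)) >= abs(log(obs_ratio)) - tol)
  structure(list(gene = target_gene, ratio = obs_ratio,
                 mean_ratio = mean(ratios),
                 se_ratio = stats::sd(ratios) / sqrt(k),
                 p_value = p, n_reallocations = k,
                 exhaustive = exhaustive),
            class = "rest_result")
}

#' @export
print.rest_result <- function(x, ...) {
  cat(sprintf(
    "%s: ratio = %.4g (reallocation mean %.4g, SE %.3g), p = %.4g [%s n = %d]\n",
    x$gene, x$ratio, x$mean_ratio, x$se_ratio, x$p_value,
    if (x$exhaustive) "exhaustive," else "sampled,", x$n_reallocations))
  invisible(x)
}
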