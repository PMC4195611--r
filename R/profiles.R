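#' Construct and validate a cluster usage profile
#'
#' A usage profile gives, for each variable cluster, the probability with
#' which each variant is chosen during splicing. Within a cluster the
#' probabilities must sum to 1 (tolerance 1e-9) and every pseudo-exon
#' (e.g. 6.11) must have probability exactly 0.
#'
#' @param lib An `exon_library`.
#' @param probs Named list, cluster id -> named numeric vector of
#'   probabilities over that cluster's variant ids. Variants omitted from a
#'   vector get probability 0.
#' @return A `usage_profile`: named list of full-length probability
#'   vectors, one per cluster, in library variant order.
#' @export
usage_profile <- function(lib, probs) {
  stopifnot(inherits(lib, "exon_library"))
  if (!all(names(probs) %in% names(lib$clusters)))
    stop("unknown cluster id(s): ",
         paste(setdiff(names(probs), names(lib$clusters)), collapse = ", "))
  out <- lapply(names(lib$clusters), function(cl) {
    ids <- lib$clusters[[cl]]$variant_id
    p <- setNames(numeric(length(ids)), ids)
    given <- probs[[cl]]
    if (is.null(given))
      stop("no probabilities supplied for cluster ", cl)
    unknown <- setdiff(names(given), ids)
    if (length(unknown))
      stop("unknown variant id(s) in cluster ", cl, ": ",
           paste(unknown, collapse = ", "))
    p[names(given)] <- given
    p
  })
  names(out) <- names(lib$clusters)
  profile <- structure(out, class = "usage_profile")
  validate_usage_profile(lib, profile)
  profile
}

#' @rdname usage_profile
#' @param profile A `usage_profile` to validate against `lib`.
#' @export
validate_usage_profile <- function(lib, profile) {
  for (cl in names(profile)) {
    p <- profile[[cl]]
    if (any(p < 0)) stop("cluster ", cl, ": negative probabilities")
    if (abs(sum(p) - 1) > 1e-9)
      stop("cluster ", cl, ": probabilities must sum to 1 (got ", sum(p), ")")
    bad <- intersect(names(p)[p > 0], lib$pseudo_exons)
    if (length(bad))
      stop("pseudo-exon(s) must have probability 0: ",
           paste(bad, collapse = ", "))
  }
  invisible(profile)
}

#' Uniform usage over all expressed (non-pseudo) variants
#' @param lib An `exon_library`.
#' @return A `usage_profile`.
#' @export
uniform_profile <- function(lib) {
  usage_profile(lib, lapply(setNames(nm = names(lib$clusters)), function(cl) {
    ids <- setdiff(lib$clusters[[cl]]$variant_id, lib$pseudo_exons)
    setNames(rep(1 / length(ids), length(ids)), ids)
  }))
}

#' Point-mass usage profile on a single isoform
#' @param lib An `exon_library`.
#' @param isoform Named character vector or list with one variant id per
#'   cluster, e.g. `c("4" = "4.1", "6" = "6.2", "9" = "9.3")`.
#' @return A `usage_profile`.
#' @export
point_profile <- function(lib, isoform) {
  usage_profile(lib, lapply(setNames(nm = names(lib$clusters)), function(cl)
    setNames(1, isoform[[cl]])))
}

#' Profile emulating the expression pattern seen in vivo
#'
#' Cluster 4 is uniform except one variant (default 4.9) down-weighted
#' ten-fold, cluster 6 is uniform over expressed variants (6.11 stays at
#' zero), and cluster 9 is restricted to a small set of expressed variants
#' (default the first four). The identities of the restricted exon-9
#' variants are a synthetic choice; only the pattern (one lowly expressed
#' cluster-4 variant, a silent 6.11, four expressed exon-9 variants) is
#' being emulated.
#'
#' @param lib An `exon_library`.
#' @param low_exon4 Variant of cluster 4 expressed an order of magnitude
#'   below the rest.
#' @param exon9_expressed Expressed exon-9 variants.
#' @return A `usage_profile`.
#' @export
study_profile <- function(lib, low_exon4 = "4.9",
                          exon9_expressed = c("9.1", "9.2", "9.3", "9.4")) {
  c4 <- lib$clusters[["4"]]$variant_id
  w4 <- setNames(rep(1, length(c4)), c4)
  if (low_exon4 %in% c4) w4[low_exon4] <- 0.1
  c6 <- setdiff(lib$clusters[["6"]]$variant_id, lib$pseudo_exons)
  c9 <- intersect(lib$clusters[["9"]]$variant_id, exon9_expressed)
  usage_profile(lib, list(
    "4" = w4 / sum(w4),
    "6" = setNames(rep(1 / length(c6), length(c6)), c6),
    "9" = setNames(rep(1 / length(c9), length(c9)), c9)
  ))
}

#' Restrict cluster 9 of an existing profile to a few expressed variants
#' @param lib An `exon_library`.
#' @param variants Expressed exon-9 variant ids (uniform among them).
#' @return A `usage_profile` uniform elsewhere.
#' @export
restricted_exon9_profile <- function(lib,
                                     variants = c("9.1", "9.2", "9.3", "9.4")) {
  prof <- uniform_profile(lib)
  ids <- lib$clusters[["9"]]$variant_id
  p <- setNames(numeric(length(ids)), ids)
  keep <- intersect(ids, variants)
  p[keep] <- 1 / length(keep)
  prof[["9"]] <- p
  validate_usage_profile(lib, prof)
  prof
}

#' Multiply one variant's usage by a fold change and renormalize
#'
#' Used to construct effect-mode generating profiles: the targeted
#' variant's probability is multiplied by `fold` and the cluster is
#' renormalized to sum to 1.
#'
#' @param profile A `usage_profile`.
#' @param variant Variant id to perturb.
#' @param fold Positive multiplier.
#' @return A `usage_profile`.
#' @export
apply_fold_change <- function(profile, variant, fold) {
  stopifnot(fold > 0)
  cl <- NULL
  for (k in names(profile)) if (variant %in% names(profile[[k]])) cl <- k
  if (is.null(cl)) stop("unknown variant id: ", variant)
  p <- profile[[cl]]
  p[variant] <- p[variant] * fold
  profile[[cl]] <- p / sum(p)
  profile
}

#' Sample mutually exclusive isoforms from a usage profile
#'
#' One variant per cluster is drawn independently per cluster for each of
#' `n` transcripts. Pseudo-exons have probability zero and are never
#' drawn.
#'
#' @param lib An `exon_library`.
#' @param profile A `usage_profile` (validated against `lib`).
#' @param n Number of isoforms to draw.
#' @param seed Integer seed.
#' @return A data.frame with one column per cluster (named `v4`, `v6`,
#'   `v9` for the default library) and `n` rows.
#' @export
sample_isoforms <- function(lib, profile, n, seed = 1L) {
  validate_usage_profile(lib, profile)
  set.seed(as.integer(seed))
  out <- lapply(names(profile), function(cl) {
    p <- profile[[cl]]
    sample(names(p), n, replace = TRUE, prob = p)
  })
  names(out) <- paste0("v", names(profile))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Sample per-variant read counts directly (count-level shortcut)
#'
#' Marginally equivalent to tabulating [sample_isoforms()]: per cluster the
#' variant counts of `n` reads are multinomial with the profile's
#' probabilities. Used by replicated simulation studies where the read
#' sequences themselves are not needed.
#'
#' @inheritParams sample_isoforms
#' @return Named integer vector of counts over all variable variants.
#' @export
sample_variant_counts <- function(lib, profile, n, seed = 1L) {
  validate_usage_profile(lib, profile)
  set.seed(as.integer(seed))
  unlist(lapply(names(profile), function(cl) {
    p <- profile[[cl]]
    setNames(as.integer(rmultinom(1, n, p)), names(p))
  }))
}
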