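# small fixtures shared across test files; everything is generated in code

# compact library: 2/3/2 variants, quick to align against
tiny_library <- function(seed = 11) {
  build_reference(cluster_sizes = c("4" = 2L, "6" = 3L, "9" = 2L),
                  exon_length_range = c(60L, 60L),
                  constitutive_length = 80L,
                  pseudo_exons = character(0),
                  seed = seed)
}

default_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_reference(seed = 1)
    cache
  }
})

# simulate an experiment and return reads + truth isoform strings
sim_with_truth <- function(lib, n_reads, error_rates = c(sub = 0, ins = 0,
                                                         del = 0),
                           mode = "null", profile = uniform_profile(lib),
                           fold_changes = NULL, seed = 1) {
  cfg <- experiment_config(n_reads = n_reads, profile_control = profile,
                           mode = mode, fold_changes = fold_changes,
                           error_rates = error_rates, seed = seed)
  sim <- simulate_experiment(cfg, lib)
  sim$truth$isoform <- paste(sim$truth$v4, sim$truth$v6, sim$truth$v9,
                             sep = "|")
  sim
}

# independent step-up FDR oracle, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    val <- min(1, m * p[ord[i]] / i, prev)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# brute-force fixed-reallocation randomization oracle: enumerate every
# assignment of the pooled (target, ref) pairs to groups of the original
# sizes and count |log ratio| exceedances
rest_oracle <- function(cp_t, cp_r, group, e_t, e_r,
                        groups = c("control", "treated")) {
  ratio_of <- function(is_ctrl) {
    dct <- mean(cp_t[is_ctrl]) - mean(cp_t[!is_ctrl])
    dcr <- mean(cp_r[is_ctrl]) - mean(cp_r[!is_ctrl])
    e_t^dct / e_r^dcr
  }
  n1 <- sum(group == groups[1])
  obs <- ratio_of(group == groups[1])
  sets <- combn(length(group), n1)
  ratios <- apply(sets, 2, function(idx) {
    is_ctrl <- seq_along(group) %in% idx
    ratio_of(is_ctrl)
  })
  list(p = mean(abs(log(ratios)) >= abs(log(obs)) - 1e-12),
       ratios = ratios, obs = obs)
}
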