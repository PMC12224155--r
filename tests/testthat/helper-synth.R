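# Reduced-scale synthetic space shared across tests: same structure as the
# full campaign defaults (4 unequal classes, shifted class centers, eluent
# grid, redundant + near-constant descriptor fodder) at simulation-friendly
# sizes.
small_space_spec <- function(seed = 42, ...) {
  args <- list(
    n_explored_chemicals = 30, n_unexplored_chemicals = 120,
    n_classes = 4, class_proportions = c(0.35, 0.3, 0.2, 0.15),
    n_descriptors = 16, n_informative = 6,
    n_conditions_per_chemical = c(4, 8),
    class_shift = 6, cluster_spread = 1, noise_sd = 0.3,
    nonlinear = TRUE, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(space_spec, args)
}

# Noise-free, single-class, unshifted space: the response is exactly linear
# in the informative descriptors.
noisefree_spec <- function(seed = 7, ...) {
  small_space_spec(seed = seed, noise_sd = 0,
                   condition_effect = rep(0, 5),
                   n_classes = 1, class_proportions = 1,
                   class_shift = 0, class_offset_sd = 0,
                   nonlinear = FALSE, ...)
}

fast_params <- function() regressor_params(nrounds = 60, max_depth = 4)

fast_config <- function(strategy, n_sample, n_repetitions = 3,
                        n_iterations = 1, seed = 5, ...) {
  campaign_config(strategy, n_sample, n_iterations = n_iterations,
                  n_repetitions = n_repetitions, seed = seed,
                  params = fast_params(), interval_trees = 200, ...)
}

# chemical-level scaled feature matrix + ids for sampler tests
scaled_pool <- function(dataset) {
  inst <- dataset$instances
  cs <- clean_and_scale(inst[inst$class == "explored", , drop = FALSE],
                        pool = inst[inst$class != "explored", , drop = FALSE])
  pool <- chemical_table(cs$pool)
  pool <- pool[order(pool$chemical_id), , drop = FALSE]
  list(pool = pool, explored = cs$explored, feat = cs$report$kept,
       desc = cs$report$kept_descriptors)
}

# brute-force anticlustering optimum for n points in 2 equal groups
brute_force_anticluster <- function(D) {
  n <- nrow(D)
  half <- n / 2
  combos <- utils::combn(n, half)
  # fix point 1 in group 1 to halve the symmetric duplicates
  combos <- combos[, combos[1, ] == 1, drop = FALSE]
  best <- -Inf
  for (c_i in seq_len(ncol(combos))) {
    g1 <- combos[, c_i]
    g2 <- setdiff(seq_len(n), g1)
    obj <- sum(D[g1, g1]) / 2 + sum(D[g2, g2]) / 2
    if (obj > best) best <- obj
  }
  best
}
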