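# Small cohort configuration used throughout the unit tests: three groups of
# 20, a 60-ASV / 20-genus table, shallow depth. Null (no planted effects)
# unless overridden.
small_config <- function(seed = 1L, ...) {
  args <- list(n_no_cad = 20L, n_nonobstructive = 20L, n_obstructive = 20L,
               n_asvs = 60L, n_genera = 20L,
               depth_mean = 3000, depth_floor = 2001L,
               effect_up = 1, effect_down = 1, imp_coupling = 0,
               confounding_shift = 0, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

# hand-built 4-tip tree ((A:1,B:1):1,(C:1,D:1):1);
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# independent brute-force Spearman rho (no ties assumed)
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
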