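# Small configuration builders shared across test files.

# one product of the given effect seeded in entity 1, nothing else enabled
# unless overridden
seeded_config <- function(effect = 0.1, entity = 1L, ...) {
  sim_config(
    lambda_stim = 0,
    seed_products = data.frame(effect_size = effect, entity = entity),
    ...
  )
}

# run `n` replicates of cfg with seeds base, base+1, ... and collect a scalar
replicate_stat <- function(cfg, n, f, base_seed = 1L) {
  vapply(seq_len(n), function(i) {
    cfg$seed <- as.integer(base_seed + i - 1L)
    f(sim_run(cfg))
  }, numeric(1))
}
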