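# Replicate batches and the paired selection-vs-no-selection experiment.

#' Run a batch of replicate simulations
#'
#' Runs `replicates` independent simulations of one configuration with seeds
#' `base_seed, base_seed + 1, ...` and returns one summary row per replicate
#' (the [glance()] of each run).
#'
#' @param config A `sor_config` or anything [validate_config()] accepts.
#' @param replicates Number of replicates.
#' @param base_seed First seed; replicate `i` uses `base_seed + i - 1`.
#'   Defaults to `config$seed`.
#' @param keep_sims If `TRUE`, attach each `sor_sim` in a list column `sim`.
#' @return A tibble with columns `replicate`, `seed`, the [glance()] summary
#'   columns, and optionally `sim`.
#' @examples
#' cfg <- sim_config(N = 5, beta = 1, lambda_stim = 0, t_max = 50,
#'                   seed_products = data.frame(effect_size = 0.1, entity = 1))
#' sim_replicates(cfg, replicates = 3, base_seed = 7)
#' @export
sim_replicates <- function(config, replicates, base_seed = NULL,
                           keep_sims = FALSE) {
  cfg <- validate_config(config)
  if (is.null(base_seed)) base_seed <- cfg$seed
  stopifnot(replicates >= 1)
  rows <- purrr::map(seq_len(replicates), function(i) {
    cfg$seed <- as.integer(base_seed + i - 1L)
    sim <- sim_run(cfg)
    out <- dplyr::bind_cols(
      tibble::tibble(replicate = i, seed = cfg$seed),
      glance(sim)
    )
    if (keep_sims) out$sim <- list(sim)
    out
  })
  dplyr::bind_rows(rows)
}

#' Draw a fixed stimulus schedule
#'
#' Generates a realisation of the Poisson innovation stream as a table of
#' stimulus times and pre-drawn effects, so that the identical stream can be
#' replayed through several runs (via the `stimulus_schedule` configuration
#' field). Interarrival times are exponential with rate `lambda_stim`; effect
#' classes and sizes follow the configuration's effect distribution.
#'
#' @param config A `sor_config` supplying `lambda_stim`, the effect-class
#'   probabilities, the effect magnitudes, and `t_max`.
#' @param seed Seed for the schedule draw.
#' @return A tibble with columns `time`, `effect_class`, `effect_size`.
#' @export
stimulus_schedule <- function(config, seed) {
  cfg <- validate_config(config)
  stopifnot(cfg$lambda_stim > 0)
  withr::with_seed(as.integer(seed), {
    # over-draw and truncate at the horizon
    times <- numeric(0)
    t <- 0
    repeat {
      gap <- stats::rexp(64L, cfg$lambda_stim)
      times <- c(times, t + cumsum(gap))
      t <- times[length(times)]
      if (t > cfg$t_max) break
    }
    times <- times[times <= cfg$t_max]
    n <- length(times)
    u <- stats::runif(n)
    cls <- ifelse(u < cfg$p_beneficial, "beneficial",
                  ifelse(u < cfg$p_beneficial + cfg$p_neutral, "neutral",
                         "deleterious"))
    sz <- ifelse(cls == "beneficial", cfg$s_beneficial,
                 ifelse(cls == "neutral", 0, -cfg$s_deleterious))
    tibble::tibble(time = times, effect_class = cls, effect_size = sz)
  })
}

#' Paired selection vs no-selection experiment
#'
#' The head-to-head comparison at the heart of the Darwinian-takeover
#' demonstration: each pair of runs shares one fixed innovation stream (same
#' stimulus times, same effect draws); the selection arm runs with Moran
#' birth-death (`mu > 0`, fitness-proportional reproduction, imperfect
#' inheritance `epsilon`), the neutral arm with `mu = 0`. Because percolation
#' is blind to effect sign, the neutral arm accumulates whatever the lottery
#' delivers, while the selection arm can purge deleterious products.
#'
#' @param config Base configuration. Its `lambda_stim` and effect
#'   distribution define the shared innovation stream; its `mu` and `epsilon`
#'   apply to the selection arm only.
#' @param n_pairs Number of paired replicates.
#' @param base_seed First seed for the schedule/arm seed derivation.
#' @return A tibble with one row per pair: `pair`, `n_stimuli`,
#'   `fitness_selection`, `fitness_neutral`, `diff`.
#' @export
paired_selection_experiment <- function(config, n_pairs, base_seed = NULL) {
  cfg <- validate_config(config)
  stopifnot(cfg$mu > 0, cfg$lambda_stim > 0, n_pairs >= 1)
  if (is.null(base_seed)) base_seed <- cfg$seed
  purrr::map_dfr(seq_len(n_pairs), function(i) {
    sched <- stimulus_schedule(cfg, seed = base_seed + i - 1L)
    arm <- function(mu, eps, seed_offset) {
      c2 <- cfg
      c2$lambda_stim <- 0
      c2$mu <- mu
      c2$epsilon <- eps
      c2$stimulus_schedule <- sched
      c2$seed <- as.integer(base_seed + i - 1L + seed_offset)
      sim_run(c2)
    }
    sel <- arm(cfg$mu, cfg$epsilon, 500000L)
    neu <- arm(0, 0, 1000000L)
    tibble::tibble(
      pair = i,
      n_stimuli = nrow(sched),
      fitness_selection = mean_fitness(sel),
      fitness_neutral = mean_fitness(neu),
      diff = mean_fitness(sel) - mean_fitness(neu)
    )
  })
}
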