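# Experiment presets and the one-command replicate runner.
#
# Each preset packages one demonstration:
#   sor_baseline           beneficial-only, loss-free corner: monotone mean
#                          fitness, certain fixation, monomorphic endpoints.
#   regime_map             innovation rate vs fixation speed: monomorphic
#                          ("community-based") vs polymorphic
#                          ("individual-based") time budgets.
#   triple_lottery_relaxed mixed beneficial/neutral/deleterious lottery with
#                          no selection: mean fitness drifts with E[effect].
#   degradation_collapse   degradation without replenishment: every product
#                          is eventually lost.
#   darwinian_takeover     paired arms sharing one innovation stream:
#                          Moran selection vs pure percolation.
#   multi_sir              recurrent introductions with recovery (multi-wave
#                          SIR), the epidemic reading of the model.

.sor_presets <- function() {
  list(
    sor_baseline = list(
      config = list(N = 50L, lambda_stim = 0.05, beta = 1, gamma = 0,
                    delta = 0, mu = 0, epsilon = 0,
                    p_beneficial = 1, p_neutral = 0, p_deleterious = 0,
                    s_beneficial = 0.1, cumulative = TRUE,
                    t_max = 200, sample_dt = 1),
      replicates = 10L,
      description = "Baseline SOR corner: beneficial-only percolation, no loss."
    ),
    regime_map = list(
      config = list(N = 20L, lambda_stim = 2.818, beta = 1, gamma = 0,
                    delta = 0, mu = 0, p_beneficial = 1, p_neutral = 0,
                    p_deleterious = 0, s_beneficial = 0.1,
                    t_max = 50, sample_dt = 0.5),
      replicates = 20L,
      description = "Marginal regime ratio ~ 1; sweep lambda_stim/beta via overrides or regime_map()."
    ),
    triple_lottery_relaxed = list(
      config = list(N = 50L, lambda_stim = 0.5, beta = 1, gamma = 0,
                    delta = 0, mu = 0, epsilon = 0,
                    p_beneficial = 0.25, p_neutral = 0.25, p_deleterious = 0.5,
                    s_beneficial = 0.1, s_deleterious = 0.1,
                    t_max = 60, sample_dt = 1),
      replicates = 100L,
      description = "Mixed-effect lottery, no selection: E[effect] = -0.025 per innovation."
    ),
    degradation_collapse = list(
      config = list(N = 10L, lambda_stim = 0, beta = 0.1, gamma = 0,
                    delta = 1, mu = 0, p_beneficial = 1, p_neutral = 0,
                    p_deleterious = 0, s_beneficial = 0.1,
                    t_max = 500, sample_dt = 5,
                    seed_products = data.frame(effect_size = 0.1,
                                               entity = NA_integer_)),
      replicates = 100L,
      description = "Degradation without replenishment: extinction of every product."
    ),
    darwinian_takeover = list(
      config = list(N = 30L, lambda_stim = 0.5, beta = 0.03, gamma = 0,
                    delta = 0, mu = 1, epsilon = 0.02,
                    p_beneficial = 0.25, p_neutral = 0.25, p_deleterious = 0.5,
                    s_beneficial = 0.1, s_deleterious = 0.1,
                    t_max = 40, sample_dt = 1),
      replicates = 100L,
      description = "Paired arms on one innovation stream: Moran selection vs percolation only."
    ),
    multi_sir = list(
      config = list(N = 200L, lambda_stim = 0.5, beta = 2 / 199, gamma = 1,
                    delta = 0, mu = 0, p_beneficial = 1, p_neutral = 0,
                    p_deleterious = 0, s_beneficial = 0.1,
                    t_max = 40, sample_dt = 0.5),
      replicates = 20L,
      description = "Recurrent introductions with recovery (R0 = 2 per product)."
    )
  )
}

#' Available experiment presets
#'
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(.sor_presets())

#' Retrieve a preset configuration
#'
#' @param name One of [preset_names()].
#' @param overrides Named list of configuration fields to override.
#' @return A validated `sor_config` with attributes `replicates` (the
#'   preset's default replicate count) and `description`.
#' @examples
#' sim_preset("sor_baseline")
#' sim_preset("triple_lottery_relaxed", overrides = list(N = 20))
#' @export
sim_preset <- function(name, overrides = list()) {
  presets <- .sor_presets()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  raw <- utils::modifyList(p$config, overrides)
  cfg <- validate_config(raw)
  attr(cfg, "replicates") <- p$replicates
  attr(cfg, "description") <- p$description
  attr(cfg, "preset") <- name
  cfg
}

#' Run an experiment preset and write its result files
#'
#' Runs the preset's replicate batch with per-replicate seeds
#' `base_seed + replicate - 1` and writes: one trajectory CSV per replicate
#' (`trajectory_###.csv`), a pooled per-replicate summary
#' (`summary.csv`), the resolved configuration (`config.json`), and a run log
#' with versions and seeds (`run_log.json`). For `darwinian_takeover` the
#' pooled summary holds one row per pair (selection vs neutral arm) and the
#' per-pair trajectories are skipped.
#'
#' @param preset_name One of [preset_names()].
#' @param overrides Named list of configuration overrides.
#' @param out_dir Output directory (created if needed).
#' @param replicates Replicate count; defaults to the preset's.
#' @param base_seed Base seed; defaults to the resolved configuration's seed.
#' @param quiet Suppress the progress message on stderr.
#' @return The pooled summary tibble, invisibly; written files as a side
#'   effect.
#' @export
run_experiment <- function(preset_name, overrides = list(), out_dir,
                           replicates = NULL, base_seed = NULL,
                           quiet = FALSE) {
  cfg <- sim_preset(preset_name, overrides)
  if (is.null(replicates)) replicates <- attr(cfg, "replicates")
  if (is.null(base_seed)) base_seed <- cfg$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!quiet) {
    message(sprintf("running preset '%s': %d replicate(s), base seed %d",
                    preset_name, replicates, as.integer(base_seed)))
  }

  if (preset_name == "darwinian_takeover") {
    summary <- paired_selection_experiment(cfg, n_pairs = replicates,
                                           base_seed = base_seed)
  } else {
    summary <- sim_replicates(cfg, replicates, base_seed = base_seed,
                              keep_sims = TRUE)
    purrr::walk2(summary$sim, summary$replicate, function(sim, i) {
      readr::write_csv(sim$trajectory,
                       file.path(out_dir, sprintf("trajectory_%03d.csv", i)))
    })
    summary$sim <- NULL
  }

  readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  config_to_json(cfg, file.path(out_dir, "config.json"))
  log <- list(
    preset = preset_name,
    description = attr(cfg, "description"),
    replicates = replicates,
    base_seed = as.integer(base_seed),
    seeds = as.integer(base_seed + seq_len(replicates) - 1L),
    package_version = as.character(utils::packageVersion("sorsim")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run_log.json"))
  invisible(summary)
}

#' Map the monomorphic/polymorphic regime over a parameter grid
#'
#' For every combination of population size, transmission rate, and stimulus
#' rate, runs a replicate batch and records the regime ratio
#' `expected_si_fixation_time(N, beta) * lambda_stim`, the observed
#' monomorphic time-fraction (pooled over replicates), and the regime
#' classification.
#'
#' @param n_grid,beta_grid,lambda_grid Numeric vectors of grid values.
#' @param config Base configuration supplying everything else (horizon,
#'   thresholds, effect distribution).
#' @param replicates Replicates per grid point.
#' @param base_seed Base seed (advanced per grid point and replicate).
#' @return A tibble of class `sor_regime_map` with columns `N`, `beta`,
#'   `lambda_stim`, `regime_ratio`, `monomorphic_fraction`,
#'   `classified_regime`.
#' @export
regime_map <- function(n_grid, beta_grid, lambda_grid,
                       config = sim_preset("regime_map"),
                       replicates = 20, base_seed = NULL) {
  cfg <- validate_config(config)
  if (is.null(base_seed)) base_seed <- cfg$seed
  grid <- tidyr::expand_grid(N = n_grid, beta = beta_grid,
                             lambda_stim = lambda_grid)
  grid$.point <- seq_len(nrow(grid))
  out <- purrr::pmap_dfr(grid, function(N, beta, lambda_stim, .point) {
    c2 <- cfg
    c2$N <- as.integer(N); c2$beta <- beta; c2$lambda_stim <- lambda_stim
    fracs <- purrr::map_dbl(seq_len(replicates), function(i) {
      c2$seed <- as.integer(base_seed + (.point - 1L) * replicates + i - 1L)
      mean(sim_run(c2)$trajectory$monomorphic)
    })
    ratio <- if (lambda_stim == 0) 0 else
      expected_si_fixation_time(N, beta) * lambda_stim
    tibble::tibble(
      N = as.integer(N), beta = beta, lambda_stim = lambda_stim,
      regime_ratio = ratio,
      monomorphic_fraction = mean(fracs),
      classified_regime = if (ratio < cfg$ratio_low) "community_based"
                          else if (ratio > cfg$ratio_high) "individual_based"
                          else "marginal"
    )
  })
  class(out) <- c("sor_regime_map", class(out))
  out
}
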