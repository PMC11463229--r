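# Model configuration: every rate, probability and mode toggle of the simulator.
# One corner of this parameter space (gamma = delta = mu = 0, p_beneficial = 1)
# is exactly baseline SOR: beneficial-only innovations percolating over a static
# population with no loss process of any kind.

.sor_config_fields <- c(
  "N", "lambda_stim", "beta", "gamma", "delta", "mu", "epsilon",
  "p_beneficial", "p_neutral", "p_deleterious",
  "s_beneficial", "s_deleterious",
  "cumulative", "t_max", "sample_dt", "seed",
  "ratio_low", "ratio_high",
  "stop_when_fixed", "max_events",
  "seed_products", "stimulus_schedule"
)

#' Build a simulation configuration
#'
#' Assembles and validates the full parameter set of the stochastic engine.
#' All processes are switched on and off through their rates: `gamma = 0`
#' disables recovery (the SOR/SI corner), `delta = 0` disables degradation,
#' `mu = 0` disables birth-death. With `gamma = delta = mu = 0` and
#' `p_beneficial = 1` the model reduces to baseline SOR: beneficial-only
#' products spreading over a fixed, immortal population.
#'
#' @param N Population size (integer, >= 2). Constant throughout a run in
#'   every mode: the Moran scheme replaces one entity per birth-death event.
#' @param lambda_stim Stimulus arrival rate per population per unit time.
#'   Each stimulus creates one new product in one entity.
#' @param beta Transmission rate per ordered (holder, eligible non-holder)
#'   pair per product (density-dependent pairwise contact).
#' @param gamma Recovery rate per held product per entity. A recovered
#'   entity-product pair is permanently immune (classic SIR). 0 = SOR/SI.
#' @param delta Degradation rate per held product per entity. Unlike
#'   recovery, a degraded product can be re-acquired by transmission.
#' @param mu Birth-death (Moran) event rate per entity. At each event one
#'   parent is sampled proportionally to fitness and its copy replaces a
#'   uniformly sampled victim. 0 = no population dynamics.
#' @param epsilon Per-product loss probability during replication (imperfect
#'   inheritance), in \[0, 1\].
#' @param p_beneficial,p_neutral,p_deleterious Effect-class probabilities for
#'   newly created products; must sum to 1 (tolerance 1e-12).
#' @param s_beneficial,s_deleterious Effect-size magnitudes (>= 0). A
#'   beneficial product adds `+s_beneficial` to fitness, a deleterious one
#'   `-s_deleterious`, a neutral one 0. Fitness is `max(0, 1 + sum(effects))`.
#' @param cumulative If `TRUE`, each new product requires its parent: a
#'   stimulus only creates the next product in an entity holding the current
#'   lineage tip (product lineages p, p', p'', ...). If no entity is eligible
#'   the stimulus is logged as a no-op.
#' @param t_max Simulation horizon (> 0).
#' @param sample_dt Trajectory recording interval (> 0).
#' @param seed Integer seed; all stochastic choices of a run flow from it.
#' @param ratio_low,ratio_high Regime-classification thresholds on the ratio
#'   (expected fixation time) x (stimulus rate); see [classify_regime()].
#' @param stop_when_fixed If `TRUE`, terminate once every product in the
#'   catalog is either fixed (held by all N) or lost, no further stimuli can
#'   arrive, and no recovery/degradation can undo the state. Needed for
#'   Moran fixation experiments, where the total event rate never reaches 0.
#' @param max_events Optional cap on the number of events (default `Inf`).
#' @param seed_products Optional initial seeding: a data frame with columns
#'   `effect_size` (numeric) and `entity` (integer or `NA` for a uniformly
#'   random entity), one row per product present at time 0.
#' @param stimulus_schedule Optional fixed innovation stream: a data frame
#'   with columns `time`, `effect_class`, `effect_size`. Scheduled stimuli
#'   fire deterministically at the given times (targets still sampled
#'   uniformly); used to share one stimulus stream between paired runs.
#'
#' @return A validated list of class `sor_config`.
#' @seealso [validate_config()], [sim_run()], [sim_preset()]
#' @examples
#' cfg <- sim_config(N = 10, beta = 1, lambda_stim = 0.1, t_max = 20, seed = 1)
#' cfg$N
#' @export
sim_config <- function(N = 100,
                       lambda_stim = 0.1,
                       beta = 1,
                       gamma = 0,
                       delta = 0,
                       mu = 0,
                       epsilon = 0,
                       p_beneficial = 1,
                       p_neutral = 0,
                       p_deleterious = 0,
                       s_beneficial = 0.1,
                       s_deleterious = 0.1,
                       cumulative = FALSE,
                       t_max = 100,
                       sample_dt = 1,
                       seed = 1L,
                       ratio_low = 0.1,
                       ratio_high = 10,
                       stop_when_fixed = FALSE,
                       max_events = Inf,
                       seed_products = NULL,
                       stimulus_schedule = NULL) {
  cfg <- list(
    N = N, lambda_stim = lambda_stim, beta = beta, gamma = gamma,
    delta = delta, mu = mu, epsilon = epsilon,
    p_beneficial = p_beneficial, p_neutral = p_neutral,
    p_deleterious = p_deleterious,
    s_beneficial = s_beneficial, s_deleterious = s_deleterious,
    cumulative = cumulative, t_max = t_max, sample_dt = sample_dt,
    seed = seed, ratio_low = ratio_low, ratio_high = ratio_high,
    stop_when_fixed = stop_when_fixed, max_events = max_events,
    seed_products = seed_products, stimulus_schedule = stimulus_schedule
  )
  validate_config(cfg)
}

#' Validate a configuration
#'
#' Checks every model invariant and returns a fully-defaulted, validated
#' `sor_config`. Accepts a plain named list, an existing `sor_config`, a JSON
#' string, or a path to a JSON file (keys exactly as the [sim_config()]
#' argument names; unknown keys are rejected). Every violated invariant
#' produces one named error message; all violations are reported together.
#'
#' @param x A named list, `sor_config`, JSON string, or JSON file path.
#' @return A validated `sor_config` list.
#' @examples
#' validate_config(list(N = 5, beta = 2))$beta
#' try(validate_config(list(beta = -1)))
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- config_from_json(x, validate = FALSE)
  }
  stopifnot(is.list(x))
  x <- unclass(x)

  unknown <- setdiff(names(x), .sor_config_fields)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # fill defaults from the sim_config() formals
  defaults <- formals(sim_config)
  cfg <- lapply(stats::setNames(.sor_config_fields, .sor_config_fields),
                function(f) if (f %in% names(x)) x[[f]] else eval(defaults[[f]]))

  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)

  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  chk(num1(cfg$N) && cfg$N >= 2 && cfg$N == round(cfg$N),
      "N: must be a single integer >= 2")
  for (f in c("lambda_stim", "beta", "gamma", "delta", "mu",
              "s_beneficial", "s_deleterious")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0,
        paste0(f, ": must be a single non-negative number"))
  }
  chk(num1(cfg$epsilon) && cfg$epsilon >= 0 && cfg$epsilon <= 1,
      "epsilon: must lie in [0, 1]")
  pv <- c(cfg$p_beneficial, cfg$p_neutral, cfg$p_deleterious)
  chk(all(vapply(pv, num1, logical(1))) && all(pv >= 0) &&
        abs(sum(pv) - 1) <= 1e-12,
      "p_beneficial + p_neutral + p_deleterious: must sum to 1 (tolerance 1e-12), each in [0, 1]")
  chk(num1(cfg$t_max) && cfg$t_max > 0, "t_max: must be > 0")
  chk(num1(cfg$sample_dt) && cfg$sample_dt > 0, "sample_dt: must be > 0")
  chk(num1(cfg$seed) && cfg$seed == round(cfg$seed), "seed: must be an integer")
  chk(num1(cfg$ratio_low) && cfg$ratio_low > 0, "ratio_low: must be > 0")
  chk(num1(cfg$ratio_high) && cfg$ratio_high > cfg$ratio_low,
      "ratio_high: must exceed ratio_low")
  chk(is.logical(cfg$cumulative) && length(cfg$cumulative) == 1L,
      "cumulative: must be TRUE or FALSE")
  chk(is.logical(cfg$stop_when_fixed) && length(cfg$stop_when_fixed) == 1L,
      "stop_when_fixed: must be TRUE or FALSE")
  chk(is.numeric(cfg$max_events) && length(cfg$max_events) == 1L &&
        (is.infinite(cfg$max_events) || cfg$max_events >= 1),
      "max_events: must be >= 1 (or Inf)")

  if (!is.null(cfg$seed_products)) {
    sp <- cfg$seed_products
    ok <- is.data.frame(sp) && all(c("effect_size", "entity") %in% names(sp))
    chk(ok, "seed_products: must be a data frame with columns effect_size, entity")
    if (ok) {
      cfg$seed_products <- tibble::as_tibble(sp)
      chk(all(is.na(sp$entity) |
                (sp$entity >= 1 & sp$entity <= cfg$N & sp$entity == round(sp$entity))),
          "seed_products: entity must be NA or an integer in 1..N")
    }
  }
  if (!is.null(cfg$stimulus_schedule)) {
    ss <- cfg$stimulus_schedule
    ok <- is.data.frame(ss) &&
      all(c("time", "effect_class", "effect_size") %in% names(ss))
    chk(ok, "stimulus_schedule: must be a data frame with columns time, effect_class, effect_size")
    if (ok) {
      cfg$stimulus_schedule <- dplyr::arrange(tibble::as_tibble(ss), .data$time)
      chk(all(ss$time >= 0), "stimulus_schedule: times must be >= 0")
      chk(all(ss$effect_class %in% c("beneficial", "neutral", "deleterious")),
          "stimulus_schedule: effect_class must be beneficial/neutral/deleterious")
    }
  }

  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$N <- as.integer(cfg$N)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sor_config")
}

#' Serialize a configuration to JSON
#'
#' @param cfg A `sor_config`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
config_to_json <- function(cfg, path = NULL) {
  cfg <- validate_config(cfg)
  out <- unclass(cfg)
  out$max_events <- if (is.infinite(out$max_events)) NULL else out$max_events
  out <- out[!vapply(out, is.null, logical(1))]
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a configuration from JSON
#'
#' @param x A JSON string or path to a JSON file.
#' @param validate Validate after parsing (default `TRUE`).
#' @return A `sor_config` (or raw list when `validate = FALSE`).
#' @export
config_from_json <- function(x, validate = TRUE) {
  raw <- jsonlite::fromJSON(x, simplifyDataFrame = TRUE)
  if (!is.list(raw)) stop("configuration JSON must be an object", call. = FALSE)
  for (f in c("seed_products", "stimulus_schedule")) {
    if (!is.null(raw[[f]])) raw[[f]] <- tibble::as_tibble(raw[[f]])
  }
  if (validate) validate_config(raw) else raw
}

#' @export
print.sor_config <- function(x, ...) {
  cat("<sor_config>\n")
  cat(sprintf("  N = %d, t_max = %g, sample_dt = %g, seed = %d\n",
              x$N, x$t_max, x$sample_dt, x$seed))
  cat(sprintf("  rates: lambda_stim = %g, beta = %g, gamma = %g, delta = %g, mu = %g\n",
              x$lambda_stim, x$beta, x$gamma, x$delta, x$mu))
  cat(sprintf("  effects: p = (%g, %g, %g), s = (+%g, -%g), epsilon = %g\n",
              x$p_beneficial, x$p_neutral, x$p_deleterious,
              x$s_beneficial, x$s_deleterious, x$epsilon))
  cat(sprintf("  cumulative lineages: %s\n", x$cumulative))
  if (!is.null(x$seed_products)) {
    cat(sprintf("  seeded products at t = 0: %d\n", nrow(x$seed_products)))
  }
  if (!is.null(x$stimulus_schedule)) {
    cat(sprintf("  scheduled stimuli: %d\n", nrow(x$stimulus_schedule)))
  }
  invisible(x)
}
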