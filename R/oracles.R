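# Closed-form oracles used to validate the stochastic engine and to classify
# dynamical regimes.

#' Expected SI fixation time
#'
#' Expected time for a single product to percolate from one holder to all `N`
#' entities under pairwise density-dependent transmission at rate `beta` per
#' ordered (holder, non-holder) pair, with no loss process. The holder count
#' is a pure-birth chain with rate `beta * k * (N - k)` out of state `k`, so
#' the expected absorption time is
#' \deqn{\sum_{k=1}^{N-1} \frac{1}{\beta k (N-k)} = \frac{2 H_{N-1}}{\beta N}}
#' with \eqn{H_n} the harmonic number.
#'
#' @param N Population size (integer >= 2).
#' @param beta Pairwise transmission rate (> 0).
#' @return Expected fixation time (scalar).
#' @examples
#' expected_si_fixation_time(2, 1)   # 1
#' expected_si_fixation_time(20, 1)
#' @export
expected_si_fixation_time <- function(N, beta) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 2, N == round(N))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("beta must be > 0", call. = FALSE)
  }
  k <- seq_len(N - 1)
  sum(1 / (beta * k * (N - k)))
}

#' Moran fixation probability
#'
#' Probability that a single mutant with selective advantage `s` (relative
#' fitness `r = 1 + s`) fixes in a Moran population of size `N` (birth
#' proportional to fitness, death uniform):
#' \deqn{\rho = \frac{1 - r^{-1}}{1 - r^{-N}}}
#' reducing to the neutral `1/N` at `s = 0`.
#'
#' @param N Population size (integer >= 2).
#' @param s Selection coefficient; `r = 1 + s` must be positive.
#' @return Fixation probability in \[0, 1\].
#' @examples
#' moran_fixation_probability(20, 0)    # 1/20
#' moran_fixation_probability(2, 1)     # 2/3
#' @export
moran_fixation_probability <- function(N, s) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 2, N == round(N))
  r <- 1 + s
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    stop("relative fitness 1 + s must be > 0", call. = FALSE)
  }
  if (s == 0) return(1 / N)
  (1 - 1 / r) / (1 - r^(-N))
}

#' Deterministic SIR final size
#'
#' Largest root `z` of the final-size relation `z = 1 - exp(-R0 * z)`: the
#' large-population attack fraction of an SIR epidemic with basic
#' reproduction number `R0`, conditional on a major outbreak. Returns 0 for
#' `R0 <= 1` (subcritical). Solved to an absolute tolerance below 1e-10.
#'
#' @param R0 Basic reproduction number (>= 0).
#' @return Attack fraction in \[0, 1).
#' @examples
#' sir_final_size(0.8)  # 0
#' sir_final_size(2)    # ~0.797
#' @export
sir_final_size <- function(R0) {
  stopifnot(is.numeric(R0), length(R0) == 1L, R0 >= 0)
  if (R0 <= 1) return(0)
  f <- function(z) 1 - exp(-R0 * z) - z
  # f > 0 just right of 0 (slope R0 - 1 > 0) and f(1) = -exp(-R0) < 0
  stats::uniroot(f, lower = 1e-12, upper = 1, tol = 1e-12)$root
}

#' Polymorphism index
#'
#' Probability that two distinct entities drawn uniformly without replacement
#' hold unequal product sets: 0 when the population is monomorphic (all sets
#' identical), 1 when all sets are pairwise distinct. Invariant under entity
#' and product relabeling.
#'
#' @param x A `sor_sim` (evaluated at its final state) or a long data frame
#'   with columns `entity` and `product_id` (one row per held product;
#'   entities with empty sets may be absent but must be counted via
#'   `n_entities`).
#' @param n_entities Total number of entities; required for data-frame input,
#'   taken from the configuration for a `sor_sim`.
#' @return A number in \[0, 1\].
#' @examples
#' h <- tibble::tibble(entity = c(1, 2, 3, 3), product_id = c(1, 1, 1, 2))
#' polymorphism_index(h, n_entities = 4)
#' @export
polymorphism_index <- function(x, n_entities = NULL) {
  if (inherits(x, "sor_sim")) {
    h <- x$holdings
    n_entities <- x$config$N
  } else {
    h <- x
    if (is.null(n_entities)) {
      stop("n_entities is required for data-frame input", call. = FALSE)
    }
  }
  stopifnot(is.data.frame(h), all(c("entity", "product_id") %in% names(h)))
  if (n_entities < 2) stop("polymorphism_index needs at least 2 entities", call. = FALSE)
  key <- vapply(split(h$product_id, factor(h$entity, levels = seq_len(n_entities))),
                function(p) paste(sort(p), collapse = ","), character(1))
  cnt <- tabulate(match(key, unique(key)))
  1 - sum(cnt * (cnt - 1)) / (n_entities * (n_entities - 1))
}

#' Mean population fitness
#'
#' Arithmetic mean over entities of `max(0, 1 + sum of held effect sizes)`.
#' The floor at 0 encodes that an entity overwhelmed by deleterious products
#' cannot reproduce (and a wholly floored population collapses under
#' birth-death dynamics).
#'
#' @param x A `sor_sim` (final state) or a data frame with a `fitness` column.
#' @return Mean fitness (>= 0).
#' @export
mean_fitness <- function(x) {
  f <- if (inherits(x, "sor_sim")) x$entities$fitness else x$fitness
  stopifnot(is.numeric(f), length(f) >= 1L)
  mean(pmax(0, f))
}

#' Fitness variance across the population
#'
#' Population variance (denominator `N`) of entity fitness: the raw material
#' selection acts on. Zero iff the population is fitness-monomorphic;
#' invariant under entity permutation.
#'
#' @param x A `sor_sim` (final state) or a data frame with a `fitness` column.
#' @return Non-negative variance.
#' @examples
#' selection_differential(data.frame(fitness = c(1, 1, 1, 2)))  # 0.1875
#' @export
selection_differential <- function(x) {
  f <- if (inherits(x, "sor_sim")) x$entities$fitness else x$fitness
  stopifnot(is.numeric(f), length(f) >= 2L)
  f <- pmax(0, f)
  mean((f - mean(f))^2)
}

#' Classify the innovation regime of a run
#'
#' Compares the expected fixation time of a single product,
#' `expected_si_fixation_time(N, beta)`, with the innovation interarrival
#' time `1/lambda_stim`. When fixation is much faster than innovation
#' (`regime_ratio = T_fix * lambda_stim` small) the population spends most of
#' its time monomorphic ("community-based" dynamics); when innovations
#' outpace fixation it stays polymorphic ("individual-based" dynamics).
#'
#' @param config A `sor_config`.
#' @param trajectory A trajectory tibble from [sim_run()] (>= 2 samples), used
#'   for the observed monomorphic time-fraction.
#' @return A one-row tibble: `expected_fixation_time`,
#'   `innovation_interarrival`, `regime_ratio`, `classified_regime`
#'   (`community_based` if ratio < `ratio_low`, `individual_based` if
#'   > `ratio_high`, else `marginal`; `lambda_stim = 0` is community-based by
#'   convention), `observed_monomorphic_fraction`.
#' @export
classify_regime <- function(config, trajectory) {
  cfg <- validate_config(config)
  stopifnot(is.data.frame(trajectory), nrow(trajectory) >= 2L,
            "monomorphic" %in% names(trajectory))
  tfix <- expected_si_fixation_time(cfg$N, max(cfg$beta, .Machine$double.xmin))
  ratio <- if (cfg$lambda_stim == 0) 0 else tfix * cfg$lambda_stim
  regime <- if (ratio < cfg$ratio_low) "community_based"
            else if (ratio > cfg$ratio_high) "individual_based"
            else "marginal"
  tibble::tibble(
    expected_fixation_time = tfix,
    innovation_interarrival = if (cfg$lambda_stim > 0) 1 / cfg$lambda_stim else Inf,
    regime_ratio = ratio,
    classified_regime = regime,
    observed_monomorphic_fraction = mean(trajectory$monomorphic)
  )
}
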