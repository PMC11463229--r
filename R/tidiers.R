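# broom-style tidiers and ggplot2 methods for simulation objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation
#'
#' @param x A `sor_sim`.
#' @param what Which table to return: `"samples"` (the trajectory, default),
#'   `"events"` (the event log), `"products"` (the product catalog with final
#'   holder counts), or `"entities"` (final per-entity fitness and repertoire
#'   size).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sor_sim <- function(x, what = c("samples", "events", "products", "entities"),
                         ...) {
  what <- match.arg(what)
  switch(what,
    samples = x$trajectory,
    events = x$events,
    products = x$catalog,
    entities = x$entities
  )
}

#' One-row summary of a simulation
#'
#' @param x A `sor_sim`.
#' @param ... Unused.
#' @return A one-row tibble: `final_time`, `n_events`, `n_products_created`,
#'   `n_products_extant`, `n_products_fixed`, `mean_fitness`,
#'   `polymorphism_index`, `monomorphic`, `absorbed`, `collapsed`,
#'   `stopped_fixed`.
#' @export
glance.sor_sim <- function(x, ...) {
  nfix <- sum(x$catalog$holders == x$config$N)
  tibble::tibble(
    final_time = x$final_time,
    n_events = x$n_events,
    n_products_created = nrow(x$catalog),
    n_products_extant = sum(x$catalog$holders > 0L),
    n_products_fixed = nfix,
    mean_fitness = mean_fitness(x),
    polymorphism_index = polymorphism_index(x),
    monomorphic = as.integer(polymorphism_index(x) == 0),
    absorbed = x$absorbed,
    collapsed = x$collapsed,
    stopped_fixed = x$stopped_fixed
  )
}

#' Plot a simulation trajectory
#'
#' Mean fitness, number of extant products, and polymorphism index against
#' time, as stacked panels.
#'
#' @param object A `sor_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sor_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trajectory,
    c("mean_fitness", "n_products_extant", "polymorphism_index"),
    names_to = "statistic", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a regime map
#'
#' Observed monomorphic time-fraction against the regime ratio
#' (expected fixation time x stimulus rate), coloured by classified regime.
#'
#' @param object A tibble from [regime_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sor_regime_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$regime_ratio,
                               y = .data$monomorphic_fraction,
                               colour = .data$classified_regime)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "regime ratio (T_fix x lambda_stim)",
                  y = "monomorphic time-fraction", colour = "regime") +
    ggplot2::theme_minimal()
}
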