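# Plain-text output: event logs and trajectories as diff-able CSV.

#' Write the event log of a run to CSV
#'
#' Columns: `time`, `kind` (stimulus / transmission / recovery / degradation /
#' birth_death), `actor_primary`, `actor_secondary`, `product_id`,
#' `products_lost` (semicolon-joined ids dropped during an imperfect copy;
#' empty otherwise). Two runs with identical configuration and seed produce
#' byte-identical files.
#'
#' @param sim A `sor_sim`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sim, path) {
  stopifnot(inherits(sim, "sor_sim"))
  readr::write_csv(sim$events, path)
  invisible(path)
}

#' Write the trajectory samples of a run to CSV
#'
#' Columns: `time`, `mean_fitness`, `n_products_extant`,
#' `polymorphism_index`, `monomorphic` (0/1), `n_entities`.
#'
#' @param sim A `sor_sim`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  stopifnot(inherits(sim, "sor_sim"))
  readr::write_csv(sim$trajectory, path)
  invisible(path)
}
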