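# Exact stochastic event engine (Gillespie direct method).
#
# State bookkeeping kept incremental so that each event is O(affected
# products), not O(catalog):
#   held[N, P]    logical, entity holds product
#   recov[N, P]   logical, entity permanently immune to product (SIR)
#   holders[p]    column sums of held
#   nrec[p]       column sums of recov   (held and recov are disjoint)
#   kpair[p]      holders * (N - holders - nrec): ordered transmissible pairs
#   K             sum(kpair), H = sum(holders)
#   raw_fit[e]    1 + sum of effect sizes held by e (fitness = max(0, raw))
#
# Total event rate:
#   Lambda = lambda_stim + beta*K + gamma*H + delta*H + mu*N
# Event kind sampled proportionally to its component; instance within a kind
# uniform over enabled instances. Waiting times are exponential(Lambda); a
# deterministic stimulus schedule is interleaved by the standard race
# (advance to the scheduled time when it precedes the next stochastic event).

.EV_KINDS <- c("stimulus", "transmission", "recovery", "degradation", "birth_death")

#' Run one stochastic simulation
#'
#' Iterates the exact Gillespie step until the horizon `t_max`, absorption
#' (total event rate 0 and no pending scheduled stimuli), population collapse
#' (all fitness 0 when `mu > 0`), or — with `stop_when_fixed = TRUE` — until
#' every catalogued product is fixed or lost. Fully reproducible from
#' `config$seed`: identical configurations yield byte-identical event logs.
#'
#' @param config A `sor_config` (see [sim_config()]) or anything
#'   [validate_config()] accepts. An object already classed `sor_config` is
#'   trusted as-is (the hot path for replicate batches); re-run
#'   [validate_config()] after editing fields by hand.
#' @return An object of class `sor_sim`: a list with elements
#'   \describe{
#'     \item{trajectory}{tibble of samples every `sample_dt`: `time`,
#'       `mean_fitness`, `n_products_extant`, `polymorphism_index`,
#'       `monomorphic` (0/1), `n_entities`.}
#'     \item{events}{tibble event log: `time`, `kind`, `actor_primary`,
#'       `actor_secondary`, `product_id`, `products_lost`.}
#'     \item{catalog}{tibble of product types: `id`, `effect_class`,
#'       `effect_size`, `parent_id`, `origin_time`, plus final `holders`.}
#'     \item{entities}{tibble of final per-entity state: `entity`, `fitness`,
#'       `n_products`.}
#'     \item{holdings, recovered}{long tibbles (`entity`, `product_id`) of the
#'       final held / recovered sets.}
#'     \item{final_time, n_events, absorbed, collapsed, stopped_fixed}{run
#'       termination summary.}
#'     \item{config}{the validated configuration.}
#'   }
#' @examples
#' cfg <- sim_config(N = 10, lambda_stim = 0.2, beta = 1, t_max = 30, seed = 42)
#' sim <- sim_run(cfg)
#' sim
#' dplyr::count(sim$events, kind)
#' @export
sim_run <- function(config) {
  # an existing sor_config is trusted as-is (hot path for replicate batches);
  # hand-edited lists go through the validator
  cfg <- if (inherits(config, "sor_config")) config else validate_config(config)
  withr::with_seed(cfg$seed, .sim_run_impl(cfg))
}

.sim_run_impl <- function(cfg) {
  N <- cfg$N
  lambda <- cfg$lambda_stim; beta <- cfg$beta
  gamma <- cfg$gamma; delta <- cfg$delta; mu <- cfg$mu
  eps <- cfg$epsilon
  p_b <- cfg$p_beneficial; p_n <- cfg$p_neutral
  s_b <- cfg$s_beneficial; s_d <- cfg$s_deleterious
  cumulative <- cfg$cumulative
  t_max <- cfg$t_max; sample_dt <- cfg$sample_dt

  # --- product/state storage (grown by doubling) ---
  cap <- 8L
  held  <- matrix(FALSE, N, cap)
  recov <- matrix(FALSE, N, cap)
  eff <- numeric(cap); eff_class <- character(cap)
  parent <- rep(NA_integer_, cap); origin <- numeric(cap)
  holders <- integer(cap); nrec <- integer(cap); kpair <- numeric(cap)
  np <- 0L; K <- 0; H <- 0L
  raw_fit <- rep(1, N)
  t <- 0
  collapsed <- FALSE; absorbed <- FALSE; stopped_fixed <- FALSE

  grow <- function() {
    held  <<- cbind(held,  matrix(FALSE, N, cap))
    recov <<- cbind(recov, matrix(FALSE, N, cap))
    eff <<- c(eff, numeric(cap)); eff_class <<- c(eff_class, character(cap))
    parent <<- c(parent, rep(NA_integer_, cap)); origin <<- c(origin, numeric(cap))
    holders <<- c(holders, integer(cap)); nrec <<- c(nrec, integer(cap))
    kpair <<- c(kpair, numeric(cap))
    cap <<- 2L * cap
  }

  gain <- function(e, p) {
    held[e, p] <<- TRUE
    h <- holders[p] + 1L; holders[p] <<- h; H <<- H + 1L
    nk <- h * (N - h - nrec[p])
    K <<- K + nk - kpair[p]; kpair[p] <<- nk
    raw_fit[e] <<- raw_fit[e] + eff[p]
  }
  lose <- function(e, p, to_recov) {
    held[e, p] <<- FALSE
    h <- holders[p] - 1L; holders[p] <<- h; H <<- H - 1L
    if (to_recov) { recov[e, p] <<- TRUE; nrec[p] <<- nrec[p] + 1L }
    nk <- h * (N - h - nrec[p])
    K <<- K + nk - kpair[p]; kpair[p] <<- nk
    raw_fit[e] <<- raw_fit[e] - eff[p]
  }
  new_product <- function(e, size, class, par, when) {
    if (np == cap) grow()
    np <<- np + 1L
    eff[np] <<- size; eff_class[np] <<- class
    parent[np] <<- par; origin[np] <<- when
    gain(e, np)
    np
  }

  # --- event log (doubling buffers) ---
  ev_cap <- 256L; ev_n <- 0L
  ev_time <- numeric(ev_cap); ev_kind <- integer(ev_cap)
  ev_a1 <- integer(ev_cap); ev_a2 <- integer(ev_cap)
  ev_prod <- integer(ev_cap); ev_lost <- character(ev_cap)
  log_event <- function(kind, a1, a2, prod, lost = "") {
    if (ev_n == ev_cap) {
      ev_time <<- c(ev_time, numeric(ev_cap)); ev_kind <<- c(ev_kind, integer(ev_cap))
      ev_a1 <<- c(ev_a1, integer(ev_cap)); ev_a2 <<- c(ev_a2, integer(ev_cap))
      ev_prod <<- c(ev_prod, integer(ev_cap)); ev_lost <<- c(ev_lost, character(ev_cap))
      ev_cap <<- 2L * ev_cap
    }
    ev_n <<- ev_n + 1L
    ev_time[ev_n] <<- t; ev_kind[ev_n] <<- kind
    ev_a1[ev_n] <<- a1; ev_a2[ev_n] <<- a2
    ev_prod[ev_n] <<- prod; ev_lost[ev_n] <<- lost
  }

  # --- trajectory samples (doubling buffers) ---
  sm_cap <- 128L; sm_n <- 0L
  sm <- matrix(0, sm_cap, 6L)
  record_sample <- function(at) {
    if (sm_n == sm_cap) { sm <<- rbind(sm, matrix(0, sm_cap, 6L)); sm_cap <<- 2L * sm_cap }
    sm_n <<- sm_n + 1L
    pm <- .poly_mono(held, holders, np, N)
    sm[sm_n, ] <<- c(at, mean(pmax(0, raw_fit)), sum(holders[seq_len(np)] > 0L),
                     pm[1L], pm[2L], N)
  }

  draw_effect <- function() {
    u <- stats::runif(1)
    if (u < p_b) c(s_b, 1) else if (u < p_b + p_n) c(0, 2) else c(-s_d, 3)
  }
  class_names <- c("beneficial", "neutral", "deleterious")

  do_stimulus <- function(size, class_code) {
    class <- class_names[class_code]
    if (cumulative && np > 0L) {
      elig <- which(held[, np])
      if (!length(elig)) { log_event(1L, NA_integer_, NA_integer_, NA_integer_); return(invisible()) }
      par <- np
    } else {
      elig <- seq_len(N)
      par <- if (cumulative && np > 0L) np else NA_integer_
    }
    e <- if (length(elig) == 1L) elig else elig[sample.int(length(elig), 1L)]
    pid <- new_product(e, size, class, par, t)
    log_event(1L, e, NA_integer_, pid)
  }

  do_transmission <- function() {
    idx <- seq_len(np)
    p <- if (np == 1L) 1L else sample.int(np, 1L, prob = kpair[idx])
    hs <- which(held[, p])
    donor <- if (length(hs) == 1L) hs else hs[sample.int(length(hs), 1L)]
    el <- which(!held[, p] & !recov[, p])
    recip <- if (length(el) == 1L) el else el[sample.int(length(el), 1L)]
    gain(recip, p)
    log_event(2L, donor, recip, p)
  }

  do_removal <- function(kind) {  # kind 3 = recovery, 4 = degradation
    idx <- seq_len(np)
    p <- if (np == 1L) 1L else sample.int(np, 1L, prob = holders[idx])
    hs <- which(held[, p])
    e <- if (length(hs) == 1L) hs else hs[sample.int(length(hs), 1L)]
    lose(e, p, to_recov = (kind == 3L))
    log_event(kind, e, NA_integer_, p)
  }

  do_birth_death <- function() {
    fit <- pmax(0, raw_fit)
    tot <- sum(fit)
    if (tot <= 0) { collapsed <<- TRUE; return(invisible()) }
    par <- sample.int(N, 1L, prob = fit)
    vic <- sample.int(N, 1L)
    idx <- seq_len(np)
    vh <- idx[held[vic, idx]]
    ph <- idx[held[par, idx]]
    keep <- if (eps > 0 && length(ph)) ph[stats::runif(length(ph)) >= eps] else ph
    lost <- setdiff(ph, keep)
    vr <- idx[recov[vic, idx]]
    pr <- idx[recov[par, idx]]
    # replace victim by the (imperfect) copy of the parent
    if (length(vh)) { held[vic, vh] <<- FALSE; holders[vh] <<- holders[vh] - 1L; H <<- H - length(vh) }
    if (length(vr)) { recov[vic, vr] <<- FALSE; nrec[vr] <<- nrec[vr] - 1L }
    if (length(pr)) { recov[vic, pr] <<- TRUE;  nrec[pr] <<- nrec[pr] + 1L }
    if (length(keep)) { held[vic, keep] <<- TRUE; holders[keep] <<- holders[keep] + 1L; H <<- H + length(keep) }
    raw_fit[vic] <<- 1 + sum(eff[keep])
    aff <- unique(c(vh, keep, vr, pr))
    if (length(aff)) {
      nk <- holders[aff] * (N - holders[aff] - nrec[aff])
      K <<- K + sum(nk - kpair[aff]); kpair[aff] <<- nk
    }
    log_event(5L, par, vic, NA_integer_,
              if (length(lost)) paste(lost, collapse = ";") else "")
  }

  # --- initial seeding ---
  if (!is.null(cfg$seed_products)) {
    for (i in seq_len(nrow(cfg$seed_products))) {
      sz <- cfg$seed_products$effect_size[i]
      e <- cfg$seed_products$entity[i]
      if (is.na(e)) e <- sample.int(N, 1L)
      cls <- if (sz > 0) "beneficial" else if (sz < 0) "deleterious" else "neutral"
      new_product(as.integer(e), sz, cls,
                  if (cumulative && np > 0L) np else NA_integer_, 0)
    }
  }

  sched <- cfg$stimulus_schedule
  n_sched <- if (is.null(sched)) 0L else nrow(sched)
  si <- 1L

  record_sample(0)
  next_sample <- sample_dt

  all_fixed_or_lost <- function() {
    np > 0L && all(holders[seq_len(np)] == 0L | holders[seq_len(np)] == N)
  }

  repeat {
    if (ev_n >= cfg$max_events) break
    if (cfg$stop_when_fixed && lambda == 0 && si > n_sched &&
        gamma == 0 && delta == 0 && (mu == 0 || eps == 0) &&
        all_fixed_or_lost()) {
      stopped_fixed <- TRUE
      break
    }
    Lam <- lambda + beta * K + (gamma + delta) * H + mu * N
    t_sched <- if (si <= n_sched) sched$time[si] else Inf
    if (Lam <= 0) {
      if (is.infinite(t_sched) || t_sched > t_max) { absorbed <- TRUE; break }
      t_new <- t_sched; scheduled <- TRUE
    } else {
      t_new <- t + stats::rexp(1, Lam)
      scheduled <- t_new >= t_sched
      if (scheduled) t_new <- t_sched
    }
    if (t_new > t_max) {
      while (next_sample <= t_max + 1e-12) { record_sample(next_sample); next_sample <- next_sample + sample_dt }
      t <- t_max
      break
    }
    while (next_sample < t_new) { record_sample(next_sample); next_sample <- next_sample + sample_dt }
    t <- t_new
    if (scheduled) {
      cls <- sched$effect_class[si]
      do_stimulus(sched$effect_size[si], match(cls, class_names))
      si <- si + 1L
    } else {
      u <- stats::runif(1) * Lam
      if (u < lambda) {
        de <- draw_effect()
        do_stimulus(de[1L], de[2L])
      } else if (u < lambda + beta * K) {
        do_transmission()
      } else if (u < lambda + beta * K + gamma * H) {
        do_removal(3L)
      } else if (u < lambda + beta * K + (gamma + delta) * H) {
        do_removal(4L)
      } else {
        do_birth_death()
        if (collapsed) break
      }
    }
  }

  idx <- seq_len(np)
  catalog <- tibble::new_tibble(list(
    id = idx,
    effect_class = eff_class[idx],
    effect_size = eff[idx],
    parent_id = parent[idx],
    origin_time = origin[idx],
    holders = holders[idx]
  ), nrow = np)
  hw <- which(held[, idx, drop = FALSE], arr.ind = TRUE)
  rw <- which(recov[, idx, drop = FALSE], arr.ind = TRUE)
  ei <- seq_len(sm_n)
  ej <- seq_len(ev_n)
  structure(list(
    trajectory = tibble::new_tibble(list(
      time = sm[ei, 1L], mean_fitness = sm[ei, 2L],
      n_products_extant = as.integer(sm[ei, 3L]),
      polymorphism_index = sm[ei, 4L],
      monomorphic = as.integer(sm[ei, 5L]),
      n_entities = as.integer(sm[ei, 6L])
    ), nrow = sm_n),
    events = tibble::new_tibble(list(
      time = ev_time[ej],
      kind = .EV_KINDS[ev_kind[ej]],
      actor_primary = ev_a1[ej],
      actor_secondary = ev_a2[ej],
      product_id = ev_prod[ej],
      products_lost = ev_lost[ej]
    ), nrow = ev_n),
    catalog = catalog,
    entities = tibble::new_tibble(list(
      entity = seq_len(N),
      fitness = pmax(0, raw_fit),
      n_products = as.integer(rowSums(held[, idx, drop = FALSE]))
    ), nrow = N),
    holdings = tibble::new_tibble(list(entity = as.integer(hw[, 1L]),
                                       product_id = as.integer(hw[, 2L])),
                                  nrow = nrow(hw)),
    recovered = tibble::new_tibble(list(entity = as.integer(rw[, 1L]),
                                        product_id = as.integer(rw[, 2L])),
                                   nrow = nrow(rw)),
    final_time = t,
    n_events = ev_n,
    absorbed = absorbed,
    collapsed = collapsed,
    stopped_fixed = stopped_fixed,
    config = cfg
  ), class = "sor_sim")
}

# polymorphism index and monomorphic flag from the raw held matrix:
# probability that two distinct entities drawn without replacement differ in
# product set, restricted to extant products (lost columns are all-FALSE and
# cannot discriminate).
.poly_mono <- function(held, holders, np, N) {
  if (np == 0L) return(c(0, 1))
  ext <- which(holders[seq_len(np)] > 0L)
  if (!length(ext)) return(c(0, 1))
  sub <- held[, ext, drop = FALSE]
  key <- do.call(paste0, lapply(seq_along(ext), function(j) as.integer(sub[, j])))
  cnt <- tabulate(match(key, unique(key)))
  same <- sum(cnt * (cnt - 1))
  c(1 - same / (N * (N - 1)), as.numeric(length(cnt) == 1L))
}

#' @export
print.sor_sim <- function(x, ...) {
  cat("<sor_sim>\n")
  cat(sprintf("  N = %d entities, %d products created, %d extant\n",
              x$config$N, nrow(x$catalog), sum(x$catalog$holders > 0)))
  cat(sprintf("  final time %.4g after %d events", x$final_time, x$n_events))
  flags <- c(if (x$absorbed) "absorbed", if (x$collapsed) "collapsed",
             if (x$stopped_fixed) "all products fixed or lost")
  if (length(flags)) cat(" (", paste(flags, collapse = ", "), ")", sep = "")
  cat("\n")
  poly <- polymorphism_index(x)
  cat(sprintf("  final mean fitness %.4f, polymorphism %.3f, %s\n",
              mean_fitness(x), poly,
              if (poly == 0) "monomorphic" else "polymorphic"))
  invisible(x)
}
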