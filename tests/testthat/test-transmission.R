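test_that("effect draws follow the class probabilities exactly at the corners", {
  # beneficial-only corner
  cfg <- sim_config(N = 5, lambda_stim = 50, beta = 0, t_max = 2,
                    p_beneficial = 1, s_beneficial = 0.2, seed = 2)
  s <- sim_run(cfg)
  expect_true(all(s$catalog$effect_class == "beneficial"))
  expect_true(all(s$catalog$effect_size == 0.2))

  # neutral-only corner
  cfg$p_beneficial <- 0; cfg$p_neutral <- 1
  s <- sim_run(validate_config(unclass(cfg)))
  expect_true(all(s$catalog$effect_class == "neutral"))
  expect_true(all(s$catalog$effect_size == 0))
})

test_that("mixed lottery matches its expected per-innovation effect", {
  # (0.25, 0.25, 0.5) with s_b = s_d = 0.1: E[effect] = -0.025
  cfg <- sim_config(N = 5, lambda_stim = 100, beta = 0, t_max = 30,
                    p_beneficial = 0.25, p_neutral = 0.25, p_deleterious = 0.5,
                    s_beneficial = 0.1, s_deleterious = 0.1, seed = 8)
  s <- sim_run(cfg)
  n <- nrow(s$catalog)
  expect_gt(n, 2000)
  se <- sd(s$catalog$effect_size) / sqrt(n)
  expect_lt(abs(mean(s$catalog$effect_size) + 0.025), 3 * se)
})

test_that("stimulus targets are uniform over entities", {
  cfg <- sim_config(N = 10, lambda_stim = 100, beta = 0, t_max = 10, seed = 4)
  s <- sim_run(cfg)
  tgt <- s$events$actor_primary[s$events$kind == "stimulus"]
  expect_gt(length(tgt), 500)
  pval <- stats::chisq.test(tabulate(tgt, nbins = 10))$p.value
  expect_gt(pval, 0.01)
})

test_that("cumulative mode chains lineages through the current tip", {
  cfg <- sim_config(N = 2, lambda_stim = 1, beta = 0, t_max = 30,
                    cumulative = TRUE, seed = 6)
  s <- sim_run(cfg)
  created <- s$events[s$events$kind == "stimulus" & !is.na(s$events$product_id), ]
  expect_gt(nrow(created), 3)
  # with beta = 0 the tip never leaves its creator: one entity owns the lineage
  expect_length(unique(created$actor_primary), 1L)
  # each product's parent is its predecessor
  expect_true(all(is.na(s$catalog$parent_id[1])))
  expect_identical(s$catalog$parent_id[-1], s$catalog$id[-nrow(s$catalog)])
  expect_true(all(s$catalog$parent_id[-1] < s$catalog$id[-1]))
})

test_that("cumulative stimuli with no eligible entity are logged as no-ops", {
  # the tip degrades quickly and cannot spread (beta = 0), so later stimuli
  # find no holder of the lineage tip
  cfg <- sim_config(N = 2, lambda_stim = 1, beta = 0, delta = 10, t_max = 30,
                    cumulative = TRUE, seed = 9)
  s <- sim_run(cfg)
  stim <- s$events[s$events$kind == "stimulus", ]
  expect_gt(sum(is.na(stim$product_id)), 0)   # no-ops present and auditable
  expect_gt(sum(!is.na(stim$product_id)), 0)  # at least the first one succeeded
})

test_that("simulated SI fixation time matches the closed form", {
  cfg <- seeded_config(N = 20, beta = 1, t_max = 1e6, sample_dt = 1e6)
  ft <- replicate_stat(cfg, 400, function(s) s$final_time)
  expect_lt(abs(mean(ft) - expected_si_fixation_time(20, 1)),
            3 * sd(ft) / sqrt(length(ft)))
})

test_that("recovered entities never re-acquire a product", {
  cfg <- sim_config(N = 25, lambda_stim = 0.5, beta = 0.2, gamma = 0.5,
                    t_max = 30, seed = 12)
  s <- sim_run(cfg)
  expect_gt(sum(s$events$kind == "recovery"), 0)
  rec <- s$events[s$events$kind == "recovery", ]
  tra <- s$events[s$events$kind == "transmission", ]
  for (i in seq_len(nrow(rec))) {
    later <- tra$time > rec$time[i] &
      tra$actor_secondary == rec$actor_primary[i] &
      tra$product_id == rec$product_id[i]
    expect_false(any(later))
  }
})

test_that("degraded products can be re-acquired by transmission", {
  cfg <- sim_config(N = 4, lambda_stim = 0.2, beta = 2, delta = 1,
                    t_max = 40, seed = 13)
  s <- sim_run(cfg)
  deg <- s$events[s$events$kind == "degradation", ]
  tra <- s$events[s$events$kind == "transmission", ]
  regained <- FALSE
  for (i in seq_len(nrow(deg))) {
    if (any(tra$time > deg$time[i] &
              tra$actor_secondary == deg$actor_primary[i] &
              tra$product_id == deg$product_id[i])) {
      regained <- TRUE
      break
    }
  }
  expect_true(regained)
})

test_that("degradation without replenishment always empties the population", {
  cfg <- seeded_config(N = 10, beta = 0.1, delta = 1, t_max = 500,
                       sample_dt = 50)
  extant <- replicate_stat(cfg, 30, function(s) glance(s)$n_products_extant)
  expect_true(all(extant == 0))
})

test_that("the polymorphism trajectory operationalizes the regime dichotomy", {
  # innovation much slower than fixation: mostly monomorphic samples
  tfix <- expected_si_fixation_time(10, 1)
  cfg <- sim_config(N = 10, beta = 1, lambda_stim = 0.02 / tfix, t_max = 300,
                    sample_dt = 1, seed = 21)
  slow <- mean(sim_run(cfg)$trajectory$monomorphic)
  # innovation much faster than fixation: mostly polymorphic samples
  cfg2 <- sim_config(N = 10, beta = 1, lambda_stim = 50 / tfix, t_max = 1,
                     sample_dt = 0.01, seed = 21)
  fast <- mean(sim_run(cfg2)$trajectory$monomorphic)
  expect_gt(slow, fast)
})
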