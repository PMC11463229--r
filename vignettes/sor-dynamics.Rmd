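---
title: "Percolation, lotteries and selection: the model behind sorsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percolation, lotteries and selection: the model behind sorsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorsim)
```

## The process being simulated

Self–other reorganization (SOR) describes a fixed population of `N`
self-maintaining entities — abstracted here to holders of *product sets* —
that never reproduce, die, or vary internally. External stimuli occasionally
trigger one entity to generate a new discrete product (an "innovation"), and
products then spread horizontally: any holder can transmit a product to any
entity that lacks it. In its baseline form every product is beneficial and
nothing is ever lost, so the population ratchets upward in fitness and ends
up uniform — the process is exactly an SI epidemic (susceptible–infected with
no recovery), with the product playing the role of the infection.

`sorsim` implements that baseline corner *and* the processes it omits, each
switched by a single rate:

* **recovery** (`gamma`): an entity clears a held product and becomes
  permanently immune to it — the full SIR model;
* **degradation** (`delta`): a held product decays; unlike recovery it can be
  re-acquired by transmission, so degradation alone turns each product into
  an SIS-type contact process whose only absorbing state is extinction;
* **mixed effect lotteries** (`p_beneficial`, `p_neutral`, `p_deleterious`):
  innovations are no longer guaranteed to help;
* **birth–death** (`mu`, `epsilon`): a Moran process — one parent sampled in
  proportion to fitness replaces one uniformly sampled entity with a copy
  that retains each product independently with probability `1 - epsilon`.

The point of the design is comparative: with all four extensions off, the
simulator reproduces the frictionless percolation story; turning any one of
them on either destroys cumulative adaptation (degradation, bad lotteries)
or restores ordinary Darwinian dynamics (birth–death with selection).

## State, fitness and events

Each entity holds a *set* of product ids — presence or absence, no copy
number, because products stand for topology changes in the underlying
entity, not concentrations. Entity fitness is additive with a floor:

$$ w_e = \max\!\Big(0,\; 1 + \sum_{p \,\in\, \text{products}(e)} s_p \Big), $$

where `s_p` is `+s_beneficial`, `0`, or `-s_deleterious` by effect class.
Additivity makes "cumulative" literal; the floor prevents negative
reproduction rates and lets a population whose every member is floored be
declared *collapsed* when birth–death dynamics are active (there is no
parent left to sample). Effect sizes are fixed magnitudes rather than draws
from a continuous distribution so that every validation has an exact
closed-form counterpart; a continuous-effect variant would be an extension
point, not a change to the engine.

The engine is an exact Gillespie direct-method sampler. The total rate is

$$ \Lambda = \lambda_{\text{stim}}
   + \beta \sum_p h_p (N - h_p - r_p)
   + (\gamma + \delta) \sum_p h_p
   + \mu N, $$

with `h_p` holders and `r_p` recovered entities of product `p`. Waiting
times are exponential with rate $\Lambda$; the event kind is sampled in
proportion to its component and the instance uniformly over enabled
instances (holder–recipient pairs, entity–product pairs). Populations here
are desk-scale (tens to hundreds of entities), so exactness is cheap and
preferred over tau-leaping. Transmission is density-dependent and pairwise —
each ordered (holder, eligible non-holder) pair transmits at rate `beta` —
the simplest well-mixed contact process; a frequency-dependent variant is
deliberately out of scope.

Stimuli arrive as a *population-level* Poisson process at rate
`lambda_stim`, hitting a uniformly chosen entity. That choice (rather than a
per-entity rate) makes the regime analysis below scale-explicit: the product
of fixation time and stimulus rate is the single dial. In *cumulative* mode
each new product requires its parent — the entity struck by the stimulus
must hold the current lineage tip, otherwise the stimulus is logged as a
no-op rather than silently dropped, so innovation opportunities remain
auditable in the event log.

## The closed-form oracles

Three classical results validate the engine, each implemented in the package
and cross-checked in the test suite by an independent route:

* **SI fixation time.** With one seeded product and no losses the holder
  count is a pure-birth chain with rate $\beta k (N-k)$, so
  $E[T_{\text{fix}}] = \sum_{k=1}^{N-1} 1/(\beta k (N-k)) = 2H_{N-1}/(\beta N)$.
* **Moran fixation probability.** A single product of advantage `s`
  (relative fitness $r = 1+s$) fixes with probability
  $(1 - r^{-1})/(1 - r^{-N})$, reducing to $1/N$ when neutral. The tests
  verify the formula against a first-step absorbing-chain linear solve up to
  `N = 50` at tolerance 1e-10.
* **SIR final size.** For basic reproduction number $R_0$ the attack
  fraction conditional on a major outbreak solves $z = 1 - e^{-R_0 z}$;
  `sir_final_size()` returns the positive root (Brent's method, tolerance
  1e-12, and 0 for $R_0 \le 1$). Stochastic runs are compared after
  excluding minor outbreaks, defined as final size below 10% of the
  predicted root — a documented rule, since the stochastic model always has
  a point mass of early extinctions of order $1/R_0$.

## Monomorphic vs polymorphic regimes

Whether the population looks uniform ("community-based" dynamics) or diverse
("individual-based" dynamics) is a race between fixation and innovation.
`classify_regime()` reduces it to one ratio,

$$ \text{regime ratio} = E[T_{\text{fix}}](N, \beta) \times \lambda_{\text{stim}}, $$

classifying a configuration as community-based below `ratio_low` (default
0.1), individual-based above `ratio_high` (default 10), and marginal in
between. The thresholds are this package's convention — the underlying claim
is only about "faster on average" — and both are configuration fields. The
observed counterpart is the fraction of equally spaced trajectory samples in
which all entities hold identical product sets. Monomorphism is exact
set equality, not fitness equality: two entities with different products of
equal total effect count as distinct. The continuous polymorphism index is
the probability that two entities drawn without replacement differ in
product set — a set-discordance measure chosen here because no standard
definition exists for this model family; it is invariant under entity and
product relabeling.

## What the presets demonstrate

Generator defaults were fixed once, on the following reasoning, and are not
tuned against outcomes:

* `sor_baseline` (`N = 50`, `beta = 1`, `lambda_stim = 0.05`): the regime
  ratio is `r round(expected_si_fixation_time(50, 1) * 0.05, 4)`, deep in
  community-based territory, so the corner shows its advertised behaviour —
  monotone mean fitness and a monomorphic quiescent end state. Where the
  demonstration needs every percolation to complete (the "ends monomorphic"
  check), the innovation stream is drawn once as a schedule and the run
  continues to quiescence, so the endpoint is not an artifact of truncating
  a percolation mid-flight.
* `triple_lottery_relaxed` (`p = (0.25, 0.25, 0.5)`, equal magnitudes 0.1):
  random effects skewed toward neutral-or-worse, giving
  `E[effect] = -0.025` per innovation. With `lambda_stim = 0.5` over a
  horizon of 60 time units (~30 innovations) the expected drift is large
  relative to the starting fitness of 1, without being dominated by the
  fitness floor.
* `degradation_collapse` (`N = 10`, `beta = 0.1`, `delta = 1`): degradation
  only, parameterized subcritical (`beta * (N - 1) < delta`) so extinction
  of the seeded product occurs well within the horizon in every replicate.
  Extinction is certain for *any* finite parameterization — it is the only
  absorbing state — but supercritical SIS quasi-stationarity makes the
  waiting time grow exponentially in `N`, which would turn an
  all-replicates demonstration into a statement about the horizon rather
  than the process.
* `darwinian_takeover` (`N = 30`, `mu = 1`, `beta = 0.03`,
  `epsilon = 0.02`, lottery as above): `beta` is set so that percolation is
  slow relative to reproduction (expected fixation time ~9 vs ~30 Moran
  events per time unit), leaving selection variation to act on. Both arms of
  each pair replay the *same* stimulus times and effect draws; only the arm
  with `mu > 0` can purge deleterious products.
* `multi_sir` (`N = 200`, `gamma = 1`, `beta = 2/(N-1)`): recurrent
  introductions with `R0 = 2` per product, the epidemic reading of the
  model with recovery restored.

## Numerical and reproducibility choices

* One RNG stream per run, seeded from `config$seed`; replicate batches use
  `base_seed + replicate - 1`, and paired arms use fixed large offsets so
  that the schedule draw and the two arms never share a stream. Identical
  configuration and seed give byte-identical event logs.
* Tie-breaking within an event kind is uniform over enabled instances;
  entities are iterated by id. The effect-class simplex is enforced to
  1e-12. Time is continuous; trajectory samples are left-limits at the
  sampling grid, so a sample at the exact instant of an event reflects the
  pre-event state.
* Runs terminate at `t_max`, at absorption (zero total rate with no pending
  scheduled stimuli — e.g. full fixation in SI mode, or an empty, stimulus-
  free population), on collapse, or — with `stop_when_fixed = TRUE` — once
  every catalogued product is fixed or lost and no process can undo that.
  The last option exists because Moran dynamics keep a positive event rate
  forever; it is only honoured when recovery, degradation and (with
  `epsilon > 0`) imperfect copying cannot reopen the race.
* Validation problem sizes were chosen to keep Monte Carlo error well inside
  the closed-form targets: 1,000 replicates for the SI fixation-time check,
  5,000 for each Moran fixation frequency (binomial 99% CI half-width under
  0.012), 200 SIR epidemics at `N = 500`, and 100 replicates per regime and
  per demonstration preset.

## What the generator does and does not emulate

The simulator *is* the data generator: there is no external data. Its
synthetic regime captures well-mixed contact, discrete presence/absence
innovations, fixed effect magnitudes, and constant population size. It does
not attempt spatial structure or contact networks, within-entity reaction
kinetics, copy-number dynamics, continuous effect-size distributions,
co-transmission of product bundles, or fitness-dependent stimulus targeting.
Conclusions drawn from it therefore concern the logical structure of the
modelled process — what percolation alone can and cannot accumulate, and
what selection adds — not quantitative predictions for any empirical
population, chemical or cultural.

## Known limitations

* The Moran victim is sampled uniformly *including* the parent (the standard
  convention that makes the neutral `1/N` exact); variants excluding the
  parent would shift fixation probabilities at small `N`.
* Imperfect inheritance is loss-only: a copy never gains a product or
  mutates an effect size. Gains enter only through stimuli.
* `stop_when_fixed` and `max_events` are termination conveniences; runs that
  rely on them report `final_time` at the stopping event, not at `t_max`.
* The regime classifier uses the closed-form SI fixation time even when
  loss processes are active; it is a design diagnostic, not an estimator.
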