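# Deterministic 31-bit seed mixing so every (master seed, scenario,
# replicate) triple gets its own reproducible stream.  Multiplier kept small
# enough that products stay exact in double precision.
mix31 <- function(s, k) ((s %% 2147483647) * 69069 + k) %% 2147483647

replicate_seed <- function(master_seed, scenario_id, replicate) {
  sidx <- match(scenario_id, scenario_flag_table()$id, nomatch = 0L)
  mix31(mix31(master_seed, 1000L + sidx), replicate)
}

#' Initialise a population
#'
#' A founding dispersal of adults arriving at a fresh habitat: all founders
#' enter the uninfected adult class; every egg and pre-adult age class is
#' empty; the day counter is zero.
#'
#' @param n_founders Number of founding adults (>= 0).
#' @param rates A `"vital_rates"` object (fixes the number of daily age
#'   classes).
#' @return An object of class `"population_state"`: integer egg and
#'   pre-adult age-class vectors, `adults_uninfected`, `adults_infected`,
#'   `day`, and the per-day tallies `matured_today` / `infected_today`
#'   (zero at initialisation).
#' @examples
#' init_population(50, vital_rates())
#' @export
init_population <- function(n_founders, rates) {
  stopifnot(n_founders >= 0, inherits(rates, "vital_rates"))
  structure(list(
    eggs = integer(rates$egg_duration),
    preadults = integer(rates$preadult_duration),
    adults_uninfected = as.integer(n_founders),
    adults_infected = 0L,
    day = 0L,
    matured_today = 0L,
    infected_today = 0L
  ), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Day %d: %d eggs, %d pre-adults, %d adults (%d infected)\n",
              x$day, sum(x$eggs), sum(x$preadults),
              x$adults_uninfected + x$adults_infected, x$adults_infected))
  invisible(x)
}

#' Advance a population by one day
#'
#' One day of the stochastic update, in a fixed event order:
#'
#' 1. **survival** --- every class survives independently (binomial draws);
#'    eggs survive within the egg stage with probability 1, their mortality
#'    entering through the hatch probability;
#' 2. **infection** --- each surviving uninfected adult becomes infected with
#'    probability `daily_infection_prob` (permanent transition);
#' 3. **advancement** --- eggs and pre-adults age one class; the oldest egg
#'    class hatches into the first pre-adult class with probability
#'    `hatch_prob` per egg; the oldest pre-adult class matures into the
#'    uninfected adult class (new adults are exposed to infection from the
#'    following day);
#' 4. **reproduction** --- eggs laid is a Poisson draw with mean
#'    `adults_uninfected * daily_fecundity_uninfected + adults_infected *
#'    daily_fecundity_infected`;
#' 5. **establishment** --- with finite capacity `K`, each laid egg enters
#'    the first egg class with probability `K/(K + eggs_laid)` (binomial
#'    thinning); with `K = Inf` all enter.
#'
#' The empty population is absorbing.  Uses the current R random stream;
#' callers control reproducibility through `set.seed()` (as
#' [run_replicates()] does per replicate).
#'
#' @param state A `"population_state"`.
#' @param rates A `"vital_rates"` object.
#' @return The next day's `"population_state"`; `matured_today` and
#'   `infected_today` tally that day's maturations into adulthood and new
#'   infections.
#' @export
step_day <- function(state, rates) {
  eggs <- state$eggs
  pre <- state$preadults
  # 1. survival
  pre <- stats::rbinom(length(pre), pre, rates$preadult_daily_survival)
  au <- stats::rbinom(1L, state$adults_uninfected,
                      rates$adult_daily_survival_uninfected)
  ai <- stats::rbinom(1L, state$adults_infected,
                      rates$adult_daily_survival_infected)
  # 2. infection
  new_inf <- stats::rbinom(1L, au, rates$daily_infection_prob)
  au <- au - new_inf
  ai <- ai + new_inf
  # 3. advancement
  ne <- length(eggs)
  np <- length(pre)
  hatched <- stats::rbinom(1L, eggs[ne], rates$hatch_prob)
  matured <- pre[np]
  pre <- c(hatched, pre[-np])
  eggs <- c(0L, eggs[-ne])
  au <- au + matured
  # 4. reproduction
  laid <- stats::rpois(1L, au * rates$daily_fecundity_uninfected +
                           ai * rates$daily_fecundity_infected)
  # 5. establishment
  K <- rates$recruitment_capacity
  eggs[1L] <- if (is.finite(K)) stats::rbinom(1L, laid, K / (K + laid))
              else laid
  structure(list(
    eggs = as.integer(eggs),
    preadults = as.integer(pre),
    adults_uninfected = as.integer(au),
    adults_infected = as.integer(ai),
    day = state$day + 1L,
    matured_today = as.integer(matured),
    infected_today = as.integer(new_inf)
  ), class = "population_state")
}

#' Simulate a replicate ensemble for one scenario
#'
#' Runs `design$n_replicates` independent populations for `design$horizon`
#' days under the scenario's vital rates.  Each replicate's random stream is
#' seeded deterministically from `(master_seed, scenario id, replicate
#' index)`, so every replicate --- and every scenario --- is independently
#' reproducible.  Records the adult count (uninfected + infected) per day
#' per replicate and tallies every fly that ever reached adulthood (founders
#' included) and every adult that ever entered the infected class.
#'
#' @param scenario A `"scenario"`.
#' @param effects An `"effect_table"`.
#' @param baseline Mite-free baseline `"vital_rates"`.
#' @param design An `"experiment_design"`.
#' @param infection_prob Daily infection probability for scenarios with
#'   consumptive effects (ignored otherwise); defaults to the baseline's
#'   value.  Obtain a calibrated value with [calibrate_infection()].
#' @return An object of class `"replicate_set"`: the scenario, the resolved
#'   `rates`, an integer `adult_trajectories` matrix (`n_replicates` x
#'   `horizon + 1`, column 1 = day 0), per-replicate `adults_ever` /
#'   `ever_infected` vectors and their totals, the design and master seed.
#' @examples
#' rs <- run_replicates(make_scenario("A"), default_effect_table(),
#'                      vital_rates(),
#'                      experiment_design(n_replicates = 5, horizon = 10))
#' rs
#' @export
run_replicates <- function(scenario, effects, baseline = vital_rates(),
                           design = experiment_design(),
                           infection_prob = baseline$daily_infection_prob) {
  stopifnot(inherits(design, "experiment_design"))
  rates <- build_vital_rates(effects, scenario, baseline, infection_prob)
  n <- design$n_replicates
  h <- design$horizon
  traj <- matrix(0L, nrow = n, ncol = h + 1L)
  itraj <- matrix(0L, nrow = n, ncol = h + 1L)
  adults_ever <- integer(n)
  ever_infected <- integer(n)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (r in seq_len(n)) {
    set.seed(replicate_seed(design$master_seed, scenario$id, r))
    st <- init_population(design$n_founders, rates)
    traj[r, 1L] <- st$adults_uninfected
    a_ever <- st$adults_uninfected   # founders entered adulthood
    i_ever <- 0L
    for (d in seq_len(h)) {
      st <- step_day(st, rates)
      traj[r, d + 1L] <- st$adults_uninfected + st$adults_infected
      itraj[r, d + 1L] <- st$adults_infected
      a_ever <- a_ever + st$matured_today
      i_ever <- i_ever + st$infected_today
    }
    adults_ever[r] <- a_ever
    ever_infected[r] <- i_ever
  }
  structure(list(
    scenario = scenario,
    rates = rates,
    adult_trajectories = traj,
    infected_trajectories = itraj,
    adults_ever = adults_ever,
    ever_infected = ever_infected,
    adults_ever_total = sum(adults_ever),
    ever_infected_total = sum(ever_infected),
    seed = design$master_seed,
    design = design
  ), class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  n <- nrow(x$adult_trajectories)
  h <- ncol(x$adult_trajectories) - 1L
  cat(sprintf("Scenario %s replicate set: %d replicates x %d days\n",
              x$scenario$id, n, h))
  cat(sprintf("  mean final adults: %.1f\n", mean_final_adults(x)))
  if (x$scenario$ce_adult)
    cat(sprintf("  realized prevalence: %.3f (infection prob %.4g/d)\n",
                realized_prevalence(x), x$rates$daily_infection_prob))
  invisible(x)
}

#' Ensemble mean adult trajectory
#'
#' @param rep_set A `"replicate_set"`.
#' @return Numeric vector of length `horizon + 1` (extinct replicates
#'   contribute zeros, they are not dropped).
#' @export
mean_trajectory <- function(rep_set) {
  stopifnot(inherits(rep_set, "replicate_set"))
  colMeans(rep_set$adult_trajectories)
}

#' Ensemble mean adult count on the final day
#'
#' @param rep_set A `"replicate_set"`.
#' @return A number.
#' @export
mean_final_adults <- function(rep_set) {
  stopifnot(inherits(rep_set, "replicate_set"))
  mean(rep_set$adult_trajectories[, ncol(rep_set$adult_trajectories)])
}

#' Simulate adult-count trajectories from a set of vital rates
#'
#' Convenience [stats::simulate()] method: runs `nsim` independent
#' populations under the given rates (no scenario machinery) and returns the
#' adult-count trajectories.
#'
#' @param object A `"vital_rates"` object.
#' @param nsim Number of replicate populations.
#' @param seed Integer seed (required for reproducibility; `NULL` uses the
#'   current stream).
#' @param n_founders,horizon Founding adults and days simulated.
#' @param ... Unused.
#' @return Integer matrix `nsim` x `horizon + 1` of adult counts.
#' @export
simulate.vital_rates <- function(object, nsim = 1, seed = NULL,
                                 n_founders = 50, horizon = 100, ...) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  traj <- matrix(0L, nrow = nsim, ncol = horizon + 1L)
  for (r in seq_len(nsim)) {
    st <- init_population(n_founders, object)
    traj[r, 1L] <- st$adults_uninfected + st$adults_infected
    for (d in seq_len(horizon)) {
      st <- step_day(st, object)
      traj[r, d + 1L] <- st$adults_uninfected + st$adults_infected
    }
  }
  traj
}
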