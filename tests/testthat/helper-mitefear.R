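# Shared fixtures, built in code.

# A replicate_set with hand-specified trajectories, for summary-level tests.
fake_set <- function(traj, scenario_id = "A", n_founders = 50L) {
  traj <- as.matrix(traj)
  n <- nrow(traj)
  structure(list(
    scenario = make_scenario(scenario_id),
    rates = vital_rates(),
    adult_trajectories = traj,
    infected_trajectories = traj * 0L,
    adults_ever = as.integer(round(traj[, 1])),
    ever_infected = integer(n),
    adults_ever_total = sum(round(traj[, 1])),
    ever_infected_total = 0L,
    seed = 1L,
    design = experiment_design(n_replicates = n, horizon = ncol(traj) - 1L,
                               n_founders = n_founders)
  ), class = "replicate_set")
}

# Deterministic rates: nothing dies, nothing reproduces, nothing infects.
inert_rates <- function(...) {
  vital_rates(hatch_prob = 1, preadult_daily_survival = 1,
              preadult_daily_survival_exposed = 1,
              adult_daily_survival_uninfected = 1,
              adult_daily_survival_infected = 1,
              daily_fecundity_uninfected = 0, daily_fecundity_infected = 0,
              daily_infection_prob = 0, recruitment_capacity = Inf, ...)
}

state_as_vector <- function(st) {
  c(st$eggs, st$preadults, st$adults_uninfected, st$adults_infected)
}

total_population <- function(st) sum(state_as_vector(st))
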