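#' Convert a lifetime survival probability to a daily survival probability
#'
#' Given the probability of surviving an entire stage of known duration,
#' returns the constant daily survival probability that reproduces it:
#' `lifetime^(1/duration)`.
#'
#' @param lifetime Probability of surviving the whole stage, in (0, 1].
#' @param duration Stage duration in days (>= 1).
#' @return Daily survival probability; raising it to the `duration` power
#'   recovers `lifetime` to machine precision.
#' @examples
#' daily_survival_from_lifetime(0.7076, 12)  # ~0.9716
#' @export
daily_survival_from_lifetime <- function(lifetime, duration) {
  stopifnot(is.numeric(lifetime), is.numeric(duration), duration >= 1)
  if (any(lifetime <= 0))
    stop("'lifetime' must be positive: a zero lifetime survival has no ",
         "finite daily rate")
  if (any(lifetime > 1)) stop("'lifetime' must be a probability in (0, 1]")
  lifetime^(1 / duration)
}

#' Infer the pre-adult stage duration from a lifetime survival reduction
#'
#' The mesh-exposure experiments report a lifetime reduction in survival to
#' adulthood together with the two daily survival probabilities (unexposed
#' and exposed).  The stage duration consistent with all three is the number
#' of days `d` for which compounding the daily survival ratio reproduces the
#' lifetime reduction: the integer `d >= 1` minimising
#' `|1 - (s_exposed/s_unexposed)^d - lifetime_reduction|`, ties broken toward
#' the smaller `d`.
#'
#' @param s_unexposed,s_exposed Daily pre-adult survival without and with
#'   mites present; `0 < s_exposed < s_unexposed <= 1`.
#' @param lifetime_reduction Reported lifetime reduction in survival to
#'   adulthood, as a fraction in (0, 1).
#' @param max_days Upper bound of the scanned durations.
#' @return Integer duration in days.
#' @examples
#' preadult_duration_from_effect(0.9716, 0.8965, 0.61)  # 12 days
#' @export
preadult_duration_from_effect <- function(s_unexposed, s_exposed,
                                          lifetime_reduction, max_days = 60L) {
  stopifnot(s_unexposed <= 1, lifetime_reduction > 0, lifetime_reduction < 1)
  if (s_exposed >= s_unexposed || s_exposed <= 0)
    stop("'s_exposed' must lie in (0, s_unexposed): there is no survival ",
         "reduction to explain otherwise")
  d <- seq_len(max_days)
  err <- abs(1 - (s_exposed / s_unexposed)^d - lifetime_reduction)
  # smallest duration whose error is within rounding of the minimum, so
  # exact ties resolve toward the smaller d despite floating-point noise
  d[which(err <= min(err) + 1e-12)[1L]]
}

#' Daily vital rates for one scenario
#'
#' The complete set of daily demographic parameters driving the simulation.
#' The defaults are the mite-free baseline: stage structure and larval
#' survivals from the exposure experiments (egg stage 2 days, hatch
#' probability 0.95, pre-adult stage 12 days at daily survival 0.9716, or
#' 0.8965 under mite exposure), and the two free parameters --- adult daily
#' survival and effective daily fecundity --- set by the deterministic
#' baseline calibration described in the methods vignette
#' (`vignette("mite-fear-model")`): adult survival 1 - 1/600 per day (adult
#' background mortality is negligible on the timescale of an ephemeral
#' cactus-rot habitat, so population contrasts are recruitment-driven) and
#' 0.052 effective eggs per adult per day (net egg-deposition rate absorbing
#' unmodelled egg losses; not a laboratory fecundity).  Daily egg
#' establishment saturates with capacity `recruitment_capacity` (Beverton-
#' Holt form); `Inf` gives pure branching growth.
#'
#' @param egg_duration Egg stage duration, days.
#' @param hatch_prob Probability that an egg completing the egg stage
#'   hatches.
#' @param preadult_duration Larval + pupal stage duration, days.
#' @param preadult_daily_survival Daily pre-adult survival without mites.
#' @param preadult_daily_survival_exposed Daily pre-adult survival when mites
#'   are present (larval NCE).
#' @param adult_daily_survival_uninfected,adult_daily_survival_infected Daily
#'   adult survival probabilities.
#' @param daily_fecundity_uninfected,daily_fecundity_infected Effective eggs
#'   laid per adult per day.
#' @param daily_infection_prob Daily probability that an uninfected adult
#'   becomes infected (0 outside infection scenarios; set by
#'   [calibrate_infection()] otherwise).
#' @param recruitment_capacity Daily egg-establishment capacity `K`; each egg
#'   laid on a day when `E` eggs are laid establishes with probability
#'   `K/(K + E)`.  `Inf` disables density dependence.
#' @return An object of class `"vital_rates"`.
#' @examples
#' vital_rates()  # mite-free baseline
#' @export
vital_rates <- function(egg_duration = 2L,
                        hatch_prob = 0.95,
                        preadult_duration = 12L,
                        preadult_daily_survival = 0.9716,
                        preadult_daily_survival_exposed = 0.8965,
                        adult_daily_survival_uninfected = 1 - 1 / 600,
                        adult_daily_survival_infected =
                          adult_daily_survival_uninfected,
                        daily_fecundity_uninfected = 0.052,
                        daily_fecundity_infected = daily_fecundity_uninfected,
                        daily_infection_prob = 0,
                        recruitment_capacity = 500) {
  r <- structure(list(
    egg_duration = as.integer(egg_duration),
    hatch_prob = hatch_prob,
    preadult_duration = as.integer(preadult_duration),
    preadult_daily_survival = preadult_daily_survival,
    preadult_daily_survival_exposed = preadult_daily_survival_exposed,
    adult_daily_survival_uninfected = adult_daily_survival_uninfected,
    adult_daily_survival_infected = adult_daily_survival_infected,
    daily_fecundity_uninfected = daily_fecundity_uninfected,
    daily_fecundity_infected = daily_fecundity_infected,
    daily_infection_prob = daily_infection_prob,
    recruitment_capacity = recruitment_capacity
  ), class = "vital_rates")
  validate_vital_rates(r)
}

validate_vital_rates <- function(r) {
  probs <- c("hatch_prob", "preadult_daily_survival",
             "preadult_daily_survival_exposed",
             "adult_daily_survival_uninfected",
             "adult_daily_survival_infected", "daily_infection_prob")
  for (nm in probs) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a probability in [0, 1], got ", format(v))
  }
  if (r$egg_duration < 1L || r$preadult_duration < 1L)
    stop("stage durations must be at least 1 day")
  for (nm in c("daily_fecundity_uninfected", "daily_fecundity_infected"))
    if (r[[nm]] < 0) stop("'", nm, "' must be non-negative")
  if (!(is.infinite(r$recruitment_capacity) || r$recruitment_capacity > 0))
    stop("'recruitment_capacity' must be positive or Inf")
  r
}

#' @export
print.vital_rates <- function(x, ...) {
  cat("Daily vital rates:\n")
  cat(sprintf("  egg stage:      %d d, hatch probability %.4g\n",
              x$egg_duration, x$hatch_prob))
  cat(sprintf("  pre-adult:      %d d, daily survival %.4f (%.4f exposed)\n",
              x$preadult_duration, x$preadult_daily_survival,
              x$preadult_daily_survival_exposed))
  cat(sprintf("  adult survival: %.6f/d uninfected, %.6f/d infected\n",
              x$adult_daily_survival_uninfected,
              x$adult_daily_survival_infected))
  cat(sprintf("  fecundity:      %.4g eggs/adult/d uninfected, %.4g infected\n",
              x$daily_fecundity_uninfected, x$daily_fecundity_infected))
  cat(sprintf("  infection:      %.4g/d;  establishment capacity K = %s\n",
              x$daily_infection_prob, format(x$recruitment_capacity)))
  invisible(x)
}

#' Resolve the daily vital rates of a scenario
#'
#' Applies the life-stage effect sizes selected by a scenario's flags to the
#' mite-free baseline rates:
#'
#' * `nce_larva`: pre-adult daily survival switches to the mite-exposed
#'   value (0.8965 instead of 0.9716 at defaults).
#' * `nce_adult`: adult daily mortality is divided by `1 - 0.21` (mean
#'   lifespan scaled by 0.79, geometric-lifespan algebra) and daily fecundity
#'   multiplied by `(1 - 0.13)/(1 - 0.21)` (about 1.1013) --- the measured 13%
#'   reduction in lifetime reproductive output compressed into a 21% shorter
#'   life implies a *higher* daily laying rate, the compensatory egg
#'   production mechanism.
#' * `ce_adult`: the infected class receives daily mortality divided by the
#'   longevity multiplier `1/(1 + 0.670)` (infected lifespan about 0.599 of
#'   uninfected), daily fecundity multiplied by `1/(1 + 1.019)` (about
#'   0.495), and `daily_infection_prob` is set to `infection_prob`
#'   (the calibrated value); without `ce_adult` the infection probability
#'   is 0 and the infected class matches the uninfected class.
#'
#' Hatch probability and stage durations are unmodified in all scenarios.
#'
#' @param effects An `"effect_table"`.
#' @param scenario A `"scenario"`.
#' @param baseline Mite-free baseline `"vital_rates"`.
#' @param infection_prob Daily infection probability used when the scenario
#'   has consumptive effects; defaults to the baseline's value.
#' @return A `"vital_rates"` object for the scenario.  Any resulting
#'   probability outside \[0, 1\] is an error naming the offending field.
#' @examples
#' eff <- default_effect_table()
#' build_vital_rates(eff, make_scenario("C"), vital_rates())
#' @export
build_vital_rates <- function(effects, scenario, baseline = vital_rates(),
                              infection_prob = baseline$daily_infection_prob) {
  stopifnot(inherits(effects, "effect_table"), inherits(scenario, "scenario"),
            inherits(baseline, "vital_rates"))
  r <- baseline
  r$daily_infection_prob <- 0
  r$preadult_daily_survival <- if (scenario$nce_larva)
    baseline$preadult_daily_survival_exposed
  else baseline$preadult_daily_survival

  if (scenario$nce_adult) {
    lifespan_mult <- 1 - effects$adult_nce_lifespan$point   # 0.79
    output_mult <- 1 - effects$adult_nce_fecundity$point    # 0.87
    mort <- (1 - baseline$adult_daily_survival_uninfected) / lifespan_mult
    r$adult_daily_survival_uninfected <- 1 - mort
    r$daily_fecundity_uninfected <-
      baseline$daily_fecundity_uninfected * output_mult / lifespan_mult
  }
  # infected class only meaningful with ce_adult; keep it mirrored otherwise
  r$adult_daily_survival_infected <- r$adult_daily_survival_uninfected
  r$daily_fecundity_infected <- r$daily_fecundity_uninfected

  if (scenario$ce_adult) {
    longevity_mult <- 1 / (1 + effects$adult_ce_longevity$point)  # ~0.599
    fecundity_mult <- 1 / (1 + effects$adult_ce_fecundity$point)  # ~0.495
    mort_i <- (1 - r$adult_daily_survival_uninfected) / longevity_mult
    r$adult_daily_survival_infected <- 1 - mort_i
    r$daily_fecundity_infected <- r$daily_fecundity_uninfected * fecundity_mult
    r$daily_infection_prob <- infection_prob
  }

  for (nm in c("adult_daily_survival_uninfected",
               "adult_daily_survival_infected", "daily_infection_prob")) {
    if (r[[nm]] < 0 || r[[nm]] > 1)
      stop("scenario ", scenario$id, ": resulting '", nm,
           "' = ", format(r[[nm]]), " is outside [0, 1]")
  }
  validate_vital_rates(r)
}

#' Expected lifetime reproductive output per founder
#'
#' Closed-form expectation under pure branching growth (no density
#' dependence): hatch probability x pre-adult stage survival x expected
#' adult lifespan x daily fecundity, averaged over infection where relevant.
#' Used for scenario-monotonicity checks; not part of the simulation itself.
#'
#' @param rates A `"vital_rates"` object.
#' @return Expected eggs produced over the lifetime of one (uninfected)
#'   recruit's descendant line, per newly laid egg... see Details.
#' @details Returns the expected number of eggs eventually laid by the fly
#'   developing from one newly laid egg: `hatch_prob *
#'   preadult_daily_survival^preadult_duration * V`, where `V` is the
#'   expected adult output under the geometric-lifespan convention (mean
#'   lifespan `1/(1 - s)`): an adult lays on the current day and then
#'   survives to the next with probability `s`, possibly transitioning to
#'   the infected class first.  Without infection `V = f/(1 - s) = f *
#'   lifespan`, so applying the adult NCEs (daily fecundity x0.87/0.79,
#'   mortality /0.79) rescales `V` by exactly 0.87.
#' @export
lifetime_reproductive_output <- function(rates) {
  su <- rates$adult_daily_survival_uninfected
  si <- rates$adult_daily_survival_infected
  p <- rates$daily_infection_prob
  fu <- rates$daily_fecundity_uninfected
  fi <- rates$daily_fecundity_infected
  vi <- if (si >= 1) Inf else fi / (1 - si)            # infected-adult value
  vu <- if (su * (1 - p) >= 1) Inf
        else (fu + su * p * vi) / (1 - su * (1 - p))   # uninfected-adult value
  rates$hatch_prob *
    rates$preadult_daily_survival^rates$preadult_duration *
    vu
}
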