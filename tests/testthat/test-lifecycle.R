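test_that("lifetime-to-daily survival conversion is exact", {
  expect_equal(daily_survival_from_lifetime(1.0, 12), 1.0)
  expect_equal(daily_survival_from_lifetime(0.25, 2), 0.5)
  # the reported mite-free daily survival: 0.9716 compounds to ~0.7076 over
  # the 12-day pre-adult stage (direct multiplication as the oracle)
  lifetime <- prod(rep(0.9716, 12))
  expect_equal(lifetime, 0.7076, tolerance = 1e-3)
  expect_equal(daily_survival_from_lifetime(0.7076, 12), 0.9716,
               tolerance = 1e-4)
  # round trip across a grid of lifetimes and durations
  for (lt in c(0.01, 0.3, 0.7076, 0.99)) {
    for (d in c(1, 2, 12, 40)) {
      expect_equal(daily_survival_from_lifetime(lt, d)^d, lt,
                   tolerance = 1e-12)
    }
  }
  expect_error(daily_survival_from_lifetime(0, 5), "positive")
  expect_error(daily_survival_from_lifetime(1.2, 5), "probability")
})

test_that("pre-adult duration is recovered from the lifetime effect", {
  # independent oracle: exhaustive scan over candidate durations
  scan_oracle <- function(su, se, red, dmax = 60) {
    errs <- vapply(1:dmax, function(d) abs(1 - (se / su)^d - red), 0)
    which.min(errs)
  }
  cases <- list(c(0.9716, 0.8965, 0.61), c(0.9716, 0.8965, 0.588),
                c(0.9, 0.45, 0.5), c(0.98, 0.9, 0.3))
  for (cs in cases) {
    expect_identical(preadult_duration_from_effect(cs[1], cs[2], cs[3]),
                     scan_oracle(cs[1], cs[2], cs[3]),
                     info = paste(cs, collapse = ", "))
  }
  expect_identical(preadult_duration_from_effect(0.9716, 0.8965, 0.61), 12L)
  expect_identical(preadult_duration_from_effect(0.9716, 0.8965, 0.588), 11L)
  # one day at half survival is exactly a 50% reduction
  expect_identical(preadult_duration_from_effect(0.9, 0.45, 0.5), 1L)
  # exact tie between d and d+1 breaks toward the smaller duration
  r <- 0.9
  tie_red <- 1 - (r^3 + r^4) / 2
  expect_identical(preadult_duration_from_effect(1, r, tie_red), 3L)
  expect_error(preadult_duration_from_effect(0.9, 0.95, 0.5),
               "no survival reduction")
})

test_that("vital-rate validation names the offending field", {
  expect_error(vital_rates(hatch_prob = 1.2), "hatch_prob")
  expect_error(vital_rates(daily_fecundity_uninfected = -1),
               "daily_fecundity_uninfected")
  expect_error(vital_rates(egg_duration = 0), "duration")
  expect_error(vital_rates(recruitment_capacity = 0), "recruitment_capacity")
})

test_that("scenario A leaves the baseline untouched and C changes only larvae", {
  eff <- default_effect_table()
  base <- vital_rates()
  a <- build_vital_rates(eff, make_scenario("A"), base)
  expect_equal(unclass(a), unclass(base))
  c_ <- build_vital_rates(eff, make_scenario("C"), base)
  expect_equal(c_$preadult_daily_survival, 0.8965)
  same <- setdiff(names(base), "preadult_daily_survival")
  expect_equal(unclass(c_)[same], unclass(base)[same])
})

test_that("adult NCEs shorten life and raise the daily laying rate", {
  eff <- default_effect_table()
  base <- vital_rates(adult_daily_survival_uninfected = 0.9667,
                      daily_fecundity_uninfected = 1.2)
  b <- build_vital_rates(eff, make_scenario("B"), base)
  expect_equal(b$adult_daily_survival_uninfected, 1 - 0.0333 / 0.79,
               tolerance = 1e-10)
  expect_equal(b$daily_fecundity_uninfected / 1.2, 0.87 / 0.79,
               tolerance = 1e-10)
  # without infection the infected class mirrors the uninfected class
  expect_equal(b$daily_infection_prob, 0)
  expect_equal(b$adult_daily_survival_infected,
               b$adult_daily_survival_uninfected)
})

test_that("consumptive effects hit only the infected class", {
  eff <- default_effect_table()
  base <- vital_rates(adult_daily_survival_uninfected = 0.96,
                      daily_fecundity_uninfected = 1.0)
  e <- build_vital_rates(eff, make_scenario("E"), base, infection_prob = 0.02)
  expect_equal(e$daily_infection_prob, 0.02)
  expect_lte(e$adult_daily_survival_infected,
             e$adult_daily_survival_uninfected)
  # infected lifespan x 1/1.670, fecundity x 1/2.019 relative to uninfected
  expect_equal(1 - e$adult_daily_survival_infected,
               (1 - e$adult_daily_survival_uninfected) * 1.670,
               tolerance = 1e-10)
  expect_equal(e$daily_fecundity_infected / e$daily_fecundity_uninfected,
               1 / 2.019, tolerance = 1e-10)
  # scenarios without consumptive effects never infect
  for (id in c("A", "B", "C", "D")) {
    expect_equal(build_vital_rates(eff, make_scenario(id), base,
                                   infection_prob = 0.02)$daily_infection_prob,
                 0, info = id)
  }
})

test_that("impossible derived probabilities are rejected by name", {
  eff <- default_effect_table()
  # adult survival so low that dividing mortality by the CE longevity
  # multiplier pushes infected mortality past 1
  base <- vital_rates(adult_daily_survival_uninfected = 0.35)
  expect_error(build_vital_rates(eff, make_scenario("E"), base,
                                 infection_prob = 0.01),
               "adult_daily_survival_infected")
})

test_that("lifetime reproductive output orders the scenarios", {
  eff <- default_effect_table()
  base <- vital_rates()
  out <- function(id) lifetime_reproductive_output(
    build_vital_rates(eff, make_scenario(id), base, infection_prob = 0.0176))
  # larval fear cuts recruitment: C < A and D < B
  expect_lt(out("C"), out("A"))
  expect_lt(out("D"), out("B"))
  # adult NCEs rescale lifetime output by exactly 0.87 (13% reduction
  # compressed into a 21% shorter life)
  expect_equal(out("B") / out("A"), 0.87, tolerance = 1e-12)
  expect_equal(out("D") / out("C"), 0.87, tolerance = 1e-12)
})
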