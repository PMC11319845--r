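#' Realized lifetime prevalence of infection among adults
#'
#' The operational definition of "overall percentage of adults parasitized":
#' lifetime incidence --- the fraction of all flies that ever reached
#' adulthood (founders included) that were ever infected, pooled across
#' replicates.  This matches a mesocosm endpoint count of parasitized
#' adults; a cross-sectional (standing) prevalence would weight long-lived
#' adults differently and is not used.
#'
#' @param rep_set A `"replicate_set"`.
#' @return Fraction in \[0, 1\].
#' @export
realized_prevalence <- function(rep_set) {
  stopifnot(inherits(rep_set, "replicate_set"))
  if (rep_set$adults_ever_total <= 0)
    stop("no fly ever reached adulthood: prevalence is undefined")
  rep_set$ever_infected_total / rep_set$adults_ever_total
}

# Replicate-level (cluster) standard error of the pooled prevalence ratio,
# by the delta method: the pooled estimate is sum(x_r)/sum(n_r) over
# replicates, whose variance is driven by between-replicate variation of
# x_r - p*n_r.
prevalence_se <- function(rep_set) {
  x <- rep_set$ever_infected
  n <- rep_set$adults_ever
  p <- sum(x) / sum(n)
  m <- length(x)
  resid <- x - p * n
  sqrt(m * stats::var(resid) / sum(n)^2)
}

#' Calibrate the daily infection probability to a target prevalence
#'
#' Mirrors the tuning step of the study design: bisection on the daily
#' infection probability over \[0, 1\], where each probe evaluates
#' [realized_prevalence()] on a reduced replicate ensemble run with a fixed
#' calibration seed (so successive probes are paired and the probe function
#' is deterministic).  Stops when the realized prevalence is within
#' `tolerance` of `target` or after `max_iter` bisections.
#'
#' Calibration is performed once, on the scenario where only adults carry
#' the parasite's effects (scenario E at defaults); the resulting
#' probability is reused for the "wild" scenario F, whose realized
#' prevalence then emerges from its own age structure.
#'
#' @param target Target lifetime prevalence, in (0, 1).
#' @param scenario A `"scenario"` with `ce_adult = TRUE`.
#' @param effects An `"effect_table"`.
#' @param baseline Mite-free baseline `"vital_rates"`.
#' @param design An `"experiment_design"`; the calibration runs use its
#'   horizon and founders but `n_replicates` probe replicates, with a seed
#'   derived from its master seed.
#' @param tolerance Stopping tolerance on `|realized - target|`.
#' @param max_iter Maximum bisection iterations.
#' @param n_replicates Replicates per probe evaluation.
#' @return An object of class `"infection_calibration"`: fields
#'   `daily_infection_prob`, `realized_prevalence`, `iterations`,
#'   `converged`, plus the probe `history` data frame and the settings.
#' @examples
#' \donttest{
#' cal <- calibrate_infection(0.41, make_scenario("E"),
#'                            default_effect_table(), vital_rates(),
#'                            experiment_design(master_seed = 1))
#' cal
#' }
#' @export
calibrate_infection <- function(target, scenario, effects,
                                baseline = vital_rates(),
                                design = experiment_design(),
                                tolerance = 0.01, max_iter = 30L,
                                n_replicates = 200L) {
  stopifnot(target > 0, target < 1, inherits(scenario, "scenario"))
  if (!scenario$ce_adult)
    stop("scenario ", scenario$id, " has no consumptive effects: ",
         "there is no infection probability to calibrate")
  probe_design <- experiment_design(
    n_replicates = n_replicates,
    horizon = design$horizon,
    n_founders = design$n_founders,
    master_seed = mix31(design$master_seed, 777L)
  )
  probe <- function(p) realized_prevalence(
    run_replicates(scenario, effects, baseline, probe_design,
                   infection_prob = p)
  )
  lo <- 0; hi <- 1
  history <- data.frame(iteration = integer(), prob = numeric(),
                        realized = numeric())
  p <- NA_real_; realized <- NA_real_; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p <- (lo + hi) / 2
    realized <- probe(p)
    history[it, ] <- list(it, p, realized)
    if (abs(realized - target) <= tolerance) { converged <- TRUE; break }
    if (realized < target) lo <- p else hi <- p
  }
  structure(list(daily_infection_prob = p,
                 realized_prevalence = realized,
                 iterations = it,
                 converged = converged,
                 target = target,
                 tolerance = tolerance,
                 scenario_id = scenario$id,
                 n_replicates = as.integer(n_replicates),
                 history = history),
            class = "infection_calibration")
}

#' @export
print.infection_calibration <- function(x, ...) {
  cat(sprintf(
    "Infection-probability calibration (scenario %s, target %.3f):\n",
    x$scenario_id, x$target))
  cat(sprintf(
    "  daily infection probability %.5f -> realized prevalence %.4f\n",
    x$daily_infection_prob, x$realized_prevalence))
  cat(sprintf("  %d bisection iterations (%d probe replicates), %s\n",
              x$iterations, x$n_replicates,
              if (x$converged) sprintf("converged within %.3g", x$tolerance)
              else "NOT converged"))
  invisible(x)
}
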