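#' Percent change in ensemble-mean final adult population
#'
#' `100 * (meanFinal(treated) - meanFinal(baseline)) / meanFinal(baseline)`,
#' where `meanFinal` is the ensemble mean adult count on the final simulated
#' day (extinct replicates contribute zeros).  Negative values are
#' reductions.
#'
#' @param treated,baseline `"replicate_set"` objects sharing horizon and
#'   founder count.
#' @return Percent change (a number).
#' @export
percent_change <- function(treated, baseline) {
  stopifnot(inherits(treated, "replicate_set"),
            inherits(baseline, "replicate_set"))
  if (ncol(treated$adult_trajectories) != ncol(baseline$adult_trajectories) ||
      treated$design$n_founders != baseline$design$n_founders)
    stop("'treated' and 'baseline' must share horizon and founder count")
  mb <- mean_final_adults(baseline)
  if (mb == 0)
    stop("baseline ensemble-mean final adult count is zero: ",
         "percent change is undefined")
  100 * (mean_final_adults(treated) - mb) / mb
}

# Eigen-analysis of a non-negative projection matrix: dominant eigenvalue
# magnitude, and the elasticity matrix e_ij = (a_ij/lambda) v_i w_j / <v,w>
# from the leading right (w) and left (v) eigenvectors.
eigen_analysis <- function(A) {
  er <- eigen(A)
  k <- which.max(Mod(er$values))
  lambda <- Mod(er$values[k])
  w <- Re(er$vectors[, k])
  if (sum(w) < 0) w <- -w
  el <- eigen(t(A))
  kl <- which.max(Mod(el$values))
  v <- Re(el$vectors[, kl])
  if (sum(v) < 0) v <- -v
  denom <- lambda * sum(v * w)
  E <- if (denom > 0) (A * outer(v, w)) / denom else A * NA_real_
  list(growth_rate = lambda, elasticities = E)
}

#' Daily projection matrix, growth rate and elasticities
#'
#' Builds the deterministic daily transition matrix over the model's age
#' classes (egg age classes, pre-adult age classes, uninfected adults,
#' infected adults) and analyses it: `A[i, j]` is the expected number of
#' class-`i` individuals tomorrow per class-`j` individual today, matching
#' the expectation of [step_day()] with infinite recruitment capacity
#' (density dependence is excluded from the linear analysis).  Entries:
#' aging within the egg stage (survival 1), hatching of the oldest egg class
#' (`hatch_prob`), pre-adult aging and maturation with pre-adult daily
#' survival, adult survival with the infection transition between adult
#' classes, and fecundity entries from the adult classes (and the maturing
#' pre-adult class, which reproduces on its maturation day) into the first
#' egg class.
#'
#' The dominant eigenvalue magnitude is the asymptotic daily growth rate;
#' the elasticity `e_ij = (a_ij/lambda) v_i w_j / <v, w>` is the
#' proportional sensitivity of the growth rate to entry `a_ij`, and the
#' elasticities sum to 1.  For degenerate (reducible) matrices --- e.g. zero
#' fecundity --- the growth rate is still returned but elasticities are
#' flagged unreliable.
#'
#' @param rates A `"vital_rates"` object.
#' @return An object of class `"projection_analysis"`: `matrix`,
#'   `growth_rate`, `elasticities`, `elasticities_reliable`.
#' @examples
#' pa <- projection_matrix(vital_rates())
#' pa$growth_rate
#' sum(pa$elasticities)  # 1
#' @export
projection_matrix <- function(rates) {
  stopifnot(inherits(rates, "vital_rates"))
  ne <- rates$egg_duration
  np <- rates$preadult_duration
  sp <- rates$preadult_daily_survival
  su <- rates$adult_daily_survival_uninfected
  si <- rates$adult_daily_survival_infected
  p <- rates$daily_infection_prob
  fu <- rates$daily_fecundity_uninfected
  fi <- rates$daily_fecundity_infected
  cls <- c(paste0("egg", seq_len(ne)), paste0("preadult", seq_len(np)),
           "adult_uninfected", "adult_infected")
  m <- length(cls)
  A <- matrix(0, m, m, dimnames = list(cls, cls))
  iU <- m - 1L
  iI <- m
  for (k in seq_len(ne - 1L)) A[k + 1L, k] <- 1           # egg aging
  A[ne + 1L, ne] <- rates$hatch_prob                       # hatching
  for (k in seq_len(np - 1L))
    A[ne + k + 1L, ne + k] <- sp                           # pre-adult aging
  A[iU, ne + np] <- sp                                     # maturation
  A[iU, iU] <- su * (1 - p)
  A[iI, iU] <- su * p
  A[iI, iI] <- si
  A[1L, iU] <- su * ((1 - p) * fu + p * fi)                # reproduction
  A[1L, iI] <- si * fi
  A[1L, ne + np] <- sp * fu       # matured adults lay on maturation day
  ea <- eigen_analysis(A)
  reliable <- fu > 0 && rates$hatch_prob > 0 && sp > 0 &&
    all(is.finite(ea$elasticities)) && ea$growth_rate > 0
  structure(list(matrix = A, growth_rate = ea$growth_rate,
                 elasticities = ea$elasticities,
                 elasticities_reliable = reliable),
            class = "projection_analysis")
}

#' @export
print.projection_analysis <- function(x, ...) {
  m <- nrow(x$matrix)
  cat(sprintf("Daily projection matrix over %d age classes\n", m))
  cat(sprintf("  asymptotic daily growth rate: %.5f\n", x$growth_rate))
  if (x$elasticities_reliable) {
    s_pre <- sum(x$elasticities[grep("^preadult", rownames(x$matrix)),
                                grep("^preadult|^egg", colnames(x$matrix))])
    cat(sprintf("  elasticity mass on pre-adult transitions: %.3f\n", s_pre))
  } else {
    cat("  elasticities unreliable (degenerate matrix)\n")
  }
  invisible(x)
}

#' Summarise a six-scenario experiment
#'
#' One row per scenario: ensemble-mean final adult count, percent change
#' versus the baseline scenario, and realized lifetime prevalence (only
#' where infection is active).  The ensemble mean trajectories are attached
#' as the `"mean_trajectories"` attribute (scenarios in rows).
#'
#' @param all_sets A list of `"replicate_set"` objects (typically named by
#'   scenario id).
#' @param baseline_id Scenario id of the baseline (default `"A"`).
#' @return A data frame of class `"scenario_summary"` with columns
#'   `scenario`, `mean_final_adults`, `pct_change_vs_baseline`,
#'   `realized_prevalence` (`NA` without infection).
#' @export
summarize_experiment <- function(all_sets, baseline_id = "A") {
  stopifnot(length(all_sets) >= 1,
            all(vapply(all_sets, inherits, TRUE, "replicate_set")))
  ids <- vapply(all_sets, function(s) s$scenario$id, "")
  names(all_sets) <- ids
  if (!baseline_id %in% ids)
    stop("baseline scenario ", deparse(baseline_id),
         " is not among the simulated scenarios (", paste(ids, collapse = ", "),
         ")")
  base <- all_sets[[baseline_id]]
  out <- data.frame(
    scenario = ids,
    mean_final_adults = vapply(all_sets, mean_final_adults, 0),
    pct_change_vs_baseline = vapply(all_sets, percent_change, 0,
                                    baseline = base),
    realized_prevalence = vapply(all_sets, function(s)
      if (s$scenario$ce_adult) realized_prevalence(s) else NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "mean_trajectories") <-
    do.call(rbind, lapply(all_sets, mean_trajectory))
  class(out) <- c("scenario_summary", "data.frame")
  out
}

#' @export
print.scenario_summary <- function(x, digits = 4, ...) {
  y <- x
  attr(y, "mean_trajectories") <- NULL
  class(y) <- "data.frame"
  print(y, digits = digits, ...)
  invisible(x)
}
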