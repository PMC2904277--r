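#' Specification of a synthetic virtual cohort
#'
#' Describes the seeded distributions from which individuals are drawn:
#' fructose-absorption completion times (log-normal around a median, with a
#' malabsorber subgroup fixed at a long completion time) and daily drink
#' counts over \{0..6\}.  The default drink-count distribution has a median
#' of 2.5 drinks/day, the habitual soft-drink exposure the model targets;
#' fructose grams/day are derived from the beverage composition, never
#' sampled separately, so exposure and physiology stay consistent.
#'
#' @param n number of individuals (>= 0).
#' @param seed integer seed for the cohort's single random stream.
#' @param beverage the \code{beverage} every individual drinks.
#' @param drink_volume_L per-drink volume, litres.
#' @param drinks_per_day_probs probability vector over 0..6 drinks/day.
#' @param fructose_completion_median_h median fructose completion time, h.
#' @param fructose_completion_sigma log-scale standard deviation of the
#'   completion-time log-normal.
#' @param malabsorber_fraction probability of being a fructose malabsorber.
#' @param malabsorber_completion_h completion time assigned to malabsorbers,
#'   h.
#' @param diet_sodium_mmol_day dietary sodium intake, mmol/day.
#' @param hypertension_threshold_mmHg MAP surrogate at or above which an
#'   individual is flagged hypertensive.
#' @param duration_days per-individual simulated duration, days.
#' @param summary_window_days trailing window for the steady-state summary,
#'   days.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n,
                        seed = 1L,
                        beverage = preset_beverage("hfcs_softdrink"),
                        drink_volume_L = 0.5,
                        drinks_per_day_probs = c(0.12, 0.16, 0.22, 0.20,
                                                 0.14, 0.10, 0.06),
                        fructose_completion_median_h = 4,
                        fructose_completion_sigma = 0.25,
                        malabsorber_fraction = 0.1,
                        malabsorber_completion_h = 8,
                        diet_sodium_mmol_day = 150,
                        hypertension_threshold_mmHg = 96,
                        duration_days = 14,
                        summary_window_days = 3) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("'n' must be a non-negative integer")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  stopifnot(inherits(beverage, "beverage"))
  if (!is.numeric(drinks_per_day_probs) || length(drinks_per_day_probs) != 7L ||
      any(drinks_per_day_probs < 0) || sum(drinks_per_day_probs) <= 0)
    stop("'drinks_per_day_probs' must be 7 non-negative weights over 0..6 drinks/day")
  if (malabsorber_fraction < 0 || malabsorber_fraction > 1)
    stop("'malabsorber_fraction' must lie in [0, 1]")
  if (fructose_completion_median_h <= 2 || malabsorber_completion_h <= 2)
    stop("fructose completion times must exceed the 2 h fast window")
  if (fructose_completion_sigma < 0)
    stop("'fructose_completion_sigma' must be >= 0")
  if (drink_volume_L <= 0) stop("'drink_volume_L' must be positive")
  structure(
    list(n = as.integer(n), seed = as.integer(seed), beverage = beverage,
         drink_volume_L = drink_volume_L,
         drinks_per_day_probs = drinks_per_day_probs / sum(drinks_per_day_probs),
         fructose_completion_median_h = fructose_completion_median_h,
         fructose_completion_sigma = fructose_completion_sigma,
         malabsorber_fraction = malabsorber_fraction,
         malabsorber_completion_h = malabsorber_completion_h,
         diet_sodium_mmol_day = diet_sodium_mmol_day,
         hypertension_threshold_mmHg = hypertension_threshold_mmHg,
         duration_days = duration_days,
         summary_window_days = summary_window_days),
    class = "cohort_spec")
}

#' Draw the individual parameters of a cohort
#'
#' One shared random stream, seeded from the spec and consumed in a fixed,
#' documented order: malabsorber flags first (Bernoulli), then fructose
#' completion times (log-normal; malabsorbers overwritten with the fixed
#' malabsorber completion), then drinks/day.  Identical specs give identical
#' cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with columns \code{id}, \code{malabsorber},
#'   \code{fructose_completion_h}, \code{drinks_per_day}.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  out <- data.frame(id = integer(0), malabsorber = logical(0),
                    fructose_completion_h = numeric(0),
                    drinks_per_day = integer(0))
  if (n == 0L) return(out)
  set.seed(spec$seed)
  flags <- stats::runif(n) < spec$malabsorber_fraction
  times <- exp(stats::rnorm(n, log(spec$fructose_completion_median_h),
                            spec$fructose_completion_sigma))
  times <- pmax(times, 2.25)  # keep the slow window non-degenerate
  times[flags] <- spec$malabsorber_completion_h
  drinks <- sample(0:6, n, replace = TRUE, prob = spec$drinks_per_day_probs)
  data.frame(id = seq_len(n), malabsorber = flags,
             fructose_completion_h = times, drinks_per_day = drinks)
}

#' Simulate every individual of a cohort to steady state
#'
#' Each individual runs their own regular daily schedule (their sampled
#' drinks/day of the spec's beverage) through [simulate_schedule()] with
#' their sampled fructose completion time, and is summarised over the
#' trailing window.  Deterministic given the spec (the seed fixes the
#' sampled parameters; the dynamics are noise-free).
#'
#' @param spec a [cohort_spec()].
#' @param params baseline [physiology_params()]; the spec's dietary sodium
#'   and each individual's fructose completion override the corresponding
#'   fields.
#' @param ... further arguments passed to [simulate_schedule()].
#' @return An object of class \code{"cohort_result"}: a data frame with one
#'   row per individual (sampled parameters, fructose g/day, steady-state
#'   MAP, ECF expansion %, aldosterone exposure, hypertensive flag), with the
#'   spec attached as attribute \code{"spec"}.
#' @export
run_cohort <- function(spec, params = physiology_params(), ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  indiv <- sample_cohort(spec)
  params$na_intake_basal <- spec$diet_sodium_mmol_day
  params <- validate_physiology_params(unclass(params))
  fru_per_L <- fructose_content(spec$beverage)
  if (nrow(indiv) == 0L) {
    out <- data.frame(indiv, fructose_g_day = numeric(0),
                      mean_map_mmHg = numeric(0),
                      ecf_expansion_pct = numeric(0),
                      aldo_exposure_per_day = numeric(0),
                      hypertensive = logical(0))
    attr(out, "spec") <- spec
    class(out) <- c("cohort_result", "data.frame")
    return(out)
  }
  rows <- vector("list", nrow(indiv))
  for (i in seq_len(nrow(indiv))) {
    row <- indiv[i, ]
    p_i <- params
    p_i$fructose_completion_h <- row$fructose_completion_h
    p_i <- validate_physiology_params(unclass(p_i))
    sched <- regular_schedule(row$drinks_per_day, spec$beverage,
                              spec$duration_days,
                              volume_L = spec$drink_volume_L)
    ss <- tryCatch(
      steady_state_summary(simulate_schedule(sched, p_i, ...),
                           spec$summary_window_days),
      error = function(e)
        stop(sprintf("individual %d: %s", row$id, conditionMessage(e))))
    rows[[i]] <- data.frame(
      row,
      fructose_g_day = row$drinks_per_day * spec$drink_volume_L * fru_per_L,
      mean_map_mmHg = ss$mean_map_mmHg,
      ecf_expansion_pct = ss$ecf_expansion_pct,
      aldo_exposure_per_day = ss$aldo_exposure_per_day,
      hypertensive = ss$mean_map_mmHg >= spec$hypertension_threshold_mmHg)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  class(out) <- c("cohort_result", "data.frame")
  out
}

# Fructose g/L of a beverage: facilitated-slow solutes plus half the
# disaccharide mass (hydrolysis to roughly equal parts glucose/fructose).
fructose_content <- function(bev) {
  total <- 0
  for (cmp in bev$components) {
    cls <- cmp$solute$absorption_class
    if (cls == "facilitated_slow") total <- total + cmp$concentration
    if (cls == "disaccharide_sucrose") total <- total + 0.5 * cmp$concentration
  }
  total
}

#' @export
print.cohort_result <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<cohort_result> n = %d (seed %d), %.0f%% hypertensive at >= %g mmHg\n",
              nrow(x), spec$seed, 100 * mean(x$hypertensive),
              spec$hypertension_threshold_mmHg))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Dose-response table over fructose intake bins
#'
#' Assigns every individual to exactly one fructose g/day bin (left-closed
#' intervals over the supplied ascending cut points) and reports bin size,
#' mean steady-state MAP and the hypertensive fraction.
#'
#' @param result a [run_cohort()] result.
#' @param breaks ascending fructose g/day cut points; the first must not
#'   exceed 0 and the last should be \code{Inf} to cover all intakes.
#' @return Data frame with columns \code{bin}, \code{n}, \code{mean_map_mmHg},
#'   \code{hypertensive_fraction}.  Empty cohorts give an empty table.
#' @export
dose_response_table <- function(result,
                                breaks = c(0, 25, 50, 100, 150, 200, Inf)) {
  stopifnot(inherits(result, "cohort_result"))
  if (is.unsorted(breaks, strictly = TRUE)) stop("'breaks' must be ascending")
  bins <- cut(result$fructose_g_day, breaks, right = FALSE,
              include.lowest = TRUE)
  agg_by(result, bins)
}

#' @rdname dose_response_table
#' @param drink_breaks drink-count cut points; the default bins are
#'   \{0\}, \{1\}, \{2\}, \{3\}, \{4+\}.
#' @export
drinks_response_table <- function(result,
                                  drink_breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf)) {
  stopifnot(inherits(result, "cohort_result"))
  bins <- cut(result$drinks_per_day, drink_breaks,
              labels = c("0", "1", "2", "3", "4+")[seq_len(length(drink_breaks) - 1)])
  agg_by(result, bins)
}

agg_by <- function(result, bins) {
  if (nrow(result) == 0L)
    return(data.frame(bin = character(0), n = integer(0),
                      mean_map_mmHg = numeric(0),
                      hypertensive_fraction = numeric(0)))
  lv <- levels(bins)
  data.frame(
    bin = lv,
    n = as.integer(tapply(result$id, bins, length, default = 0L)[lv]),
    mean_map_mmHg = as.numeric(tapply(result$mean_map_mmHg, bins, mean)[lv]),
    hypertensive_fraction =
      as.numeric(tapply(result$hypertensive, bins, mean)[lv]),
    row.names = NULL)
}
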