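#' Physiological parameters of the homeostasis loop
#'
#' All constants of the regulatory-loop simulation live in this one object
#' (and in the shipped parameter file
#' \code{system.file("extdata", "params", "default_params.yaml")}).  The
#' regulatory loop is qualitative about every gain and time constant, so the
#' defaults are illustrative, chosen so that the baseline mean arterial
#' pressure surrogate is 93 mmHg and a three-drinks-per-day schedule of the
#' 800 mosm/L HFCS preset settles a few mmHg above it.  They are not a
#' calibration to human hemodynamic data.
#'
#' @param v_ecf0 baseline extracellular fluid volume, L.
#' @param v_circ0 baseline circulating (plasma) volume, L; normalises the
#'   deficit that drives hormone secretion.
#' @param na_conc extracellular sodium concentration, mmol/L; the ECF tracks
#'   total body sodium isotonically at this concentration.
#' @param na_intake_basal dietary sodium intake, mmol/day.
#' @param water_intake_basal basal water intake outside scheduled drinks,
#'   L/day.
#' @param gut_na_bypass fraction of dietary sodium that escapes small-bowel
#'   absorption and reaches the colon, where uptake is limited by the
#'   adapting colonic capacity.
#' @param k_aldo,k_adh hormone gains: index units per unit fractional
#'   circulating-volume deficit.
#' @param aldo_saturation cap on either hormone index.
#' @param tau_colon colon-capacity adaptation time constant, days (cell
#'   renewal makes the trophic response take days to develop or dissolve).
#' @param window_days trailing window over which aldosterone exposure is
#'   averaged ("few previous days").
#' @param c0 baseline colonic sodium absorption capacity, mmol/day.
#' @param c_gain capacity gained per unit of trailing-average aldosterone
#'   index, mmol/day.
#' @param k_renal renal sodium excretion rate constant, /day.
#' @param na_set_gain upward shift of the renal sodium setpoint per unit of
#'   summed hormone index, mmol (sodium sparing by aldosterone/ADH).
#' @param beta_bp pressure coupling: fractional MAP rise per fractional ECF
#'   expansion.
#' @param map0 baseline mean arterial pressure surrogate, mmHg.
#' @param fast_completion_h completion time of sodium-coupled water
#'   absorption, hours.
#' @param fructose_completion_h completion time of fructose-associated water
#'   absorption, hours; raise beyond 4 to model impaired absorbers.
#' @param noise_sd optional Gaussian observation noise on the recorded MAP
#'   column, mmHg (default 0: simulations are fully deterministic).
#' @return An object of class \code{"physiology_params"} (a validated list).
#' @examples
#' p <- physiology_params()
#' p$map0
#' @export
physiology_params <- function(v_ecf0 = 15,
                              v_circ0 = 3,
                              na_conc = 140,
                              na_intake_basal = 150,
                              water_intake_basal = 1.5,
                              gut_na_bypass = 0.4,
                              k_aldo = 1,
                              k_adh = 1,
                              aldo_saturation = 2,
                              tau_colon = 2,
                              window_days = 3,
                              c0 = 20,
                              c_gain = 500,
                              k_renal = 0.5,
                              na_set_gain = 50,
                              beta_bp = 2,
                              map0 = 93,
                              fast_completion_h = 2,
                              fructose_completion_h = 4,
                              noise_sd = 0) {
  p <- list(v_ecf0 = v_ecf0, v_circ0 = v_circ0, na_conc = na_conc,
            na_intake_basal = na_intake_basal,
            water_intake_basal = water_intake_basal,
            gut_na_bypass = gut_na_bypass,
            k_aldo = k_aldo, k_adh = k_adh, aldo_saturation = aldo_saturation,
            tau_colon = tau_colon, window_days = window_days,
            c0 = c0, c_gain = c_gain, k_renal = k_renal,
            na_set_gain = na_set_gain, beta_bp = beta_bp, map0 = map0,
            fast_completion_h = fast_completion_h,
            fructose_completion_h = fructose_completion_h,
            noise_sd = noise_sd)
  validate_physiology_params(p)
}

validate_physiology_params <- function(p) {
  numeric_fields <- setdiff(names(physiology_param_defaults()), character(0))
  for (fld in numeric_fields) {
    v <- p[[fld]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", fld))
    if (v < 0) stop(sprintf("parameter '%s' must be >= 0", fld))
  }
  for (fld in c("v_ecf0", "v_circ0", "na_conc", "k_renal", "map0",
                "fast_completion_h"))
    if (p[[fld]] <= 0) stop(sprintf("parameter '%s' must be > 0", fld))
  if (p$tau_colon < 1) stop("'tau_colon' must be >= 1 day")
  if (p$window_days < 1) stop("'window_days' must be >= 1 day")
  if (p$gut_na_bypass > 1) stop("'gut_na_bypass' must lie in [0, 1]")
  if (p$fructose_completion_h <= p$fast_completion_h)
    stop("'fructose_completion_h' must exceed 'fast_completion_h'")
  structure(p, class = "physiology_params")
}

physiology_param_defaults <- function() {
  formals(physiology_params)
}

# Quantities implied by the baseline fixed point: total body sodium, basal
# sodium absorption, and the renal setpoint that makes the baseline exact.
derived_baselines <- function(p) {
  na0 <- p$na_conc * p$v_ecf0
  absorbed0 <- (1 - p$gut_na_bypass) * p$na_intake_basal +
    min(p$gut_na_bypass * p$na_intake_basal, p$c0)
  list(na0 = na0, absorbed0 = absorbed0,
       na_set0 = na0 - absorbed0 / p$k_renal)
}

#' @export
print.physiology_params <- function(x, ...) {
  cat("<physiology_params>\n")
  for (fld in names(x)) cat(sprintf("  %-22s %g\n", fld, x[[fld]]))
  invisible(x)
}

#' Read or write a physiology parameter file
#'
#' Parameter files are flat key-value YAML with exactly the fields of
#' [physiology_params()].  A written file read back reproduces the identical
#' simulation (round-trip contract).
#'
#' @param path file path.
#' @param params a \code{physiology_params} object (for writing).
#' @return \code{read_physiology_params} returns a \code{physiology_params};
#'   \code{write_physiology_params} returns \code{path} invisibly.
#' @export
read_physiology_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(physiology_param_defaults())
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop(sprintf("unknown parameter field(s): %s", paste(extra, collapse = ", ")))
  do.call(physiology_params, raw)
}

#' @rdname read_physiology_params
#' @export
write_physiology_params <- function(params, path) {
  stopifnot(inherits(params, "physiology_params"))
  yaml::write_yaml(lapply(unclass(params), as.numeric), path)
  invisible(path)
}

#' Hormone drive from a circulating-volume deficit
#'
#' Aldosterone and ADH indices rise linearly with the fractional deficit
#' (deficit over baseline circulating volume), saturating at
#' \code{aldo_saturation}.  While unabsorbed sodium from an electrolyte-rich
#' beverage remains in the lumen the aldosterone response is blunted to zero
#' (set \code{luminal_sodium > 0}); the ADH response is not gated, since it
#' answers the volume deficit directly.
#'
#' @param deficit circulating-volume deficit in litres (>= 0 drives; negative
#'   values are treated as no deficit).  Vectorised.
#' @param params a [physiology_params()] object.
#' @param luminal_sodium unabsorbed luminal sodium load, mmol (vectorised;
#'   any positive value gates aldosterone to zero).
#' @return A list with numeric vectors \code{aldo} and \code{adh}.
#' @export
hormone_drive <- function(deficit, params = physiology_params(),
                          luminal_sodium = 0) {
  stopifnot(inherits(params, "physiology_params"))
  d <- pmax(0, deficit) / params$v_circ0
  aldo <- pmin(params$aldo_saturation, params$k_aldo * d)
  aldo <- aldo * as.numeric(luminal_sodium <= 0)
  adh <- pmin(params$aldo_saturation, params$k_adh * d)
  list(aldo = aldo, adh = adh)
}

#' One update of the adapting colonic sodium-absorption capacity
#'
#' The capacity relaxes first-order toward \code{c0 + c_gain * avg_aldo} with
#' time constant \code{tau_colon}:
#' \deqn{dC/dt = (C_0 + g \bar{a} - C)/\tau.}
#' The update is the exact exponential step for a constant input over
#' \code{dt}, so the integration error comes only from the variation of
#' \code{avg_aldo} within a step.
#'
#' @param C current capacity, mmol/day.
#' @param avg_aldo trailing-average aldosterone index over
#'   \code{window_days}.
#' @param dt step length in days (> 0).
#' @param params a [physiology_params()] object.
#' @return Updated capacity, mmol/day.
#' @export
colon_adaptation_step <- function(C, avg_aldo, dt, params = physiology_params()) {
  stopifnot(inherits(params, "physiology_params"))
  if (!is.numeric(dt) || any(dt <= 0)) stop("'dt' must be > 0 days")
  target <- params$c0 + params$c_gain * avg_aldo
  target + (C - target) * exp(-dt / params$tau_colon)
}
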