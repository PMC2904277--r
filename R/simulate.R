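#' Simulate the homeostasis loop over an ingestion schedule
#'
#' Event-driven compartmental simulation of the regulatory loop.  Each
#' ingestion event instantiates the static trapping model; the body-donated
#' water still sitting in the lumen is the circulating-volume deficit, which
#' drives the aldosterone and ADH indices (aldosterone is blunted while
#' unabsorbed luminal sodium from an electrolyte-rich beverage remains).
#' Colonic sodium-absorption capacity relaxes first-order, with a days-scale
#' time constant, toward a target set by the trailing-average aldosterone
#' index.  Total body sodium obeys
#' \deqn{dNa/dt = \mathrm{absorbed}(C, \mathrm{diet}) - k_{renal}\,
#'   (Na - Na_{set}(t)),}
#' where colonic absorption is capped at the luminal sodium actually reaching
#' the colon and the renal setpoint is shifted upward by the hormone indices
#' (sodium sparing).  The ECF tracks sodium isotonically minus the
#' transiently trapped water, and the pressure surrogate is
#' \code{MAP = map0 * (1 + beta_bp * (ECF - v_ecf0)/v_ecf0)}.
#'
#' Integration is fixed-step and event-aligned -- at most
#' \code{step_fast_min} minutes during absorption windows and
#' \code{step_coarse_min} otherwise, with grid points at every event knot --
#' so trajectories are bit-reproducible across runs.  The colon capacity is
#' advanced with the exact exponential step; sodium with an explicit Euler
#' step (its rate constants are tiny on the step scale).
#'
#' @param schedule an [ingestion_schedule()].
#' @param params a [physiology_params()] object.
#' @param seed optional integer seed; only consumed when
#'   \code{params$noise_sd > 0} (observation noise on the recorded MAP).
#'   The dynamics themselves are deterministic.
#' @param step_fast_min step length during absorption windows, minutes.
#' @param step_coarse_min step length elsewhere, minutes.
#' @param O_iso isotonic reference passed to the trapping model, mosm/L.
#' @return An object of class \code{"homeo_trajectory"}: a list with
#'   \code{data} (one row per grid point: \code{time_h}, \code{luminal_L},
#'   \code{deficit_L}, \code{aldo_index}, \code{adh_index},
#'   \code{avg_aldo_index}, \code{colon_capacity_mmol_day}, \code{na_mmol},
#'   \code{ecf_L}, \code{map_mmHg}, \code{intake_cum_L}, \code{urine_cum_L},
#'   \code{stool_cum_L}), plus the \code{params} and \code{schedule} used.
#' @examples
#' sched <- regular_schedule(3, preset_beverage("hfcs_softdrink"), 7)
#' traj <- simulate_schedule(sched, physiology_params())
#' summary(traj)
#' @export
simulate_schedule <- function(schedule, params = physiology_params(),
                              seed = NULL,
                              step_fast_min = 1, step_coarse_min = 15,
                              O_iso = 300) {
  stopifnot(inherits(schedule, "ingestion_schedule"),
            inherits(params, "physiology_params"))
  if (step_fast_min <= 0 || step_coarse_min <= 0)
    stop("step lengths must be positive (minutes)")

  end_s <- round(schedule$duration_days * 24 * 3600)
  ev <- precompute_events(schedule, params, O_iso, end_s)

  ## --- time grid in integer seconds: coarse everywhere, fine inside
  ##     absorption windows, knots at event boundaries
  t_s <- seq(0L, end_s, by = round(step_coarse_min * 60))
  if (t_s[length(t_s)] != end_s) t_s <- c(t_s, end_s)
  for (e in ev) {
    # the knot 1 s before onset brackets the deficit jump, so the
    # trapezoidal hormone integrals do not smear it over a coarse step
    w_end <- min(e$t0_s + e$ts_s, end_s)
    t_s <- c(t_s, seq(e$t0_s, w_end, by = round(step_fast_min * 60)),
             max(0L, e$t0_s - 1L), e$t0_s,
             min(e$t0_s + e$tf_s, end_s), w_end)
  }
  t_s <- sort(unique(t_s))
  t_h <- t_s / 3600
  n <- length(t_h)

  ## --- vectorised event superpositions on the grid
  deficit <- numeric(n); absorbed_cum <- numeric(n); luminal <- numeric(n)
  jump_cum <- numeric(n); thirst_cum <- numeric(n); stool_cum <- numeric(n)
  bolus_cum <- numeric(n); bev_na_cum <- numeric(n)
  gated <- logical(n)
  for (e in ev) {
    rel <- t_s - e$t0_s
    fast <- e$fastv * pmin(1, pmax(0, rel / e$tf_s))
    slow <- e$slowv * pmin(1, pmax(0, (rel - e$tf_s) / (e$ts_s - e$tf_s)))
    abs_e <- fast + slow
    started <- rel >= 0
    released <- rel >= e$ts_s
    d_e <- ifelse(started, pmax(0, e$V_d - abs_e), 0)
    if (e$nonv > 0) {
      # water trapped with non-absorbable solute leaves to the colon at the
      # slow completion time; any deficit still open then is closed by thirst
      residual <- max(0, e$V_d - e$fastv - e$slowv)
      d_e[released] <- 0
      thirst_cum <- thirst_cum + ifelse(released, residual, 0)
      stool_cum <- stool_cum + ifelse(released, e$nonv, 0)
    }
    deficit <- deficit + d_e
    absorbed_cum <- absorbed_cum + abs_e
    luminal <- luminal + ifelse(started, e$V_a - abs_e, 0) -
      ifelse(released, e$nonv, 0)
    jump_cum <- jump_cum + ifelse(started, e$V_d, 0)
    bolus_cum <- bolus_cum + ifelse(started, e$V, 0)
    if (e$na_mmol > 0) {
      bev_na_cum <- bev_na_cum + e$na_mmol * pmin(1, pmax(0, rel / e$tf_s))
      gated <- gated | (started & rel < e$tf_s)
    }
  }

  ## --- hormone indices and trailing aldosterone average
  hd <- hormone_drive(deficit, params, luminal_sodium = as.numeric(gated))
  aldo <- hd$aldo; adh <- hd$adh
  window_h <- params$window_days * 24
  I_aldo <- c(0, cumsum((aldo[-1] + aldo[-n]) / 2 * diff(t_h)))
  I_lag <- stats::approx(t_h, I_aldo, xout = pmax(0, t_h - window_h),
                         rule = 2)$y
  avg_aldo <- (I_aldo - I_lag) / window_h

  ## --- sequential state: colon capacity (exact exponential), sodium (Euler)
  base <- derived_baselines(params)
  dt_d <- diff(t_h) / 24
  decay <- exp(-dt_d / params$tau_colon)
  target <- params$c0 + params$c_gain * avg_aldo
  C <- numeric(n); C[1] <- params$c0
  for (j in seq_len(n - 1L))
    C[j + 1L] <- target[j] + (C[j] - target[j]) * decay[j]

  colon_inflow <- params$gut_na_bypass * params$na_intake_basal
  na_in <- (1 - params$gut_na_bypass) * params$na_intake_basal +
    pmin(colon_inflow, C)
  na_set <- base$na_set0 + params$na_set_gain * (aldo + adh)
  bev_na_step <- diff(bev_na_cum)
  na <- numeric(n); na[1] <- base$na0
  for (j in seq_len(n - 1L)) {
    na[j + 1L] <- na[j] +
      dt_d[j] * (na_in[j] - params$k_renal * (na[j] - na_set[j])) +
      bev_na_step[j]
    if (!is.finite(na[j + 1L]) || !is.finite(C[j + 1L]))
      stop(sprintf("non-finite state at step %d (t = %.3f h)", j + 1L,
                   t_h[j + 1L]))
  }

  ecf <- na / params$na_conc - deficit
  map <- params$map0 * (1 + params$beta_bp * (ecf - params$v_ecf0) / params$v_ecf0)
  if (params$noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    map <- map + stats::rnorm(n, 0, params$noise_sd)
  }

  ## --- water ledger (see vignette): urine is body inflow minus the ECF
  ##     change not explained by gut secretion
  abs_step <- diff(absorbed_cum)
  thirst_step <- diff(thirst_cum)
  urine_step <- params$water_intake_basal * dt_d + abs_step + thirst_step -
    diff(na) / params$na_conc - (diff(jump_cum) - diff(deficit))
  urine_cum <- c(0, cumsum(urine_step))
  intake_cum <- params$water_intake_basal * t_h / 24 + bolus_cum + thirst_cum

  structure(
    list(data = data.frame(
           time_h = t_h, luminal_L = luminal, deficit_L = deficit,
           aldo_index = aldo, adh_index = adh, avg_aldo_index = avg_aldo,
           colon_capacity_mmol_day = C, na_mmol = na, ecf_L = ecf,
           map_mmHg = map, intake_cum_L = intake_cum,
           urine_cum_L = urine_cum, stool_cum_L = stool_cum),
         params = params, schedule = schedule, O_iso = O_iso,
         step_fast_min = step_fast_min, step_coarse_min = step_coarse_min),
    class = "homeo_trajectory")
}

# Static trapping quantities for every event, in integer seconds.
precompute_events <- function(schedule, params, O_iso, end_s) {
  lapply(schedule$events, function(evt) {
    tr <- osmotic_trapping(evt$beverage, volume = evt$volume_L, O_iso = O_iso,
                           fast_completion = params$fast_completion_h,
                           slow_completion = params$fructose_completion_h)
    p <- tr$partitions
    na_mmol <- 0
    for (cmp in evt$beverage$components)
      if (cmp$solute$absorption_class == "electrolyte")
        na_mmol <- na_mmol +
          cmp$concentration * evt$volume_L / cmp$solute$molar_mass * 1000
    list(t0_s = round(evt$time_h * 3600),
         tf_s = round(params$fast_completion_h * 3600),
         ts_s = round(params$fructose_completion_h * 3600),
         V = evt$volume_L, V_d = tr$V_d, V_a = tr$V_a,
         fastv = p$volume[p$class == "fast"],
         slowv = p$volume[p$class == "slow"],
         nonv = p$volume[p$class == "nonabsorbed"],
         na_mmol = na_mmol)
  })
}

#' Trailing steady-state summary of a trajectory
#'
#' Time-weighted means over the trailing \code{last_n_days}: the MAP
#' surrogate, ECF expansion as a percentage of baseline, colon capacity, the
#' mean aldosterone index, and the daily aldosterone exposure (time integral
#' of the index per day, i.e. 24 x the mean index).
#'
#' @param traj a \code{homeo_trajectory}.
#' @param last_n_days length of the trailing averaging window, days; must
#'   not exceed the trajectory duration.
#' @return An object of class \code{"homeo_summary"}.
#' @export
steady_state_summary <- function(traj, last_n_days = 3) {
  stopifnot(inherits(traj, "homeo_trajectory"))
  d <- traj$data
  t_end <- d$time_h[nrow(d)]
  if (last_n_days <= 0 || last_n_days * 24 > t_end)
    stop("'last_n_days' must be positive and no longer than the trajectory")
  sel <- d$time_h >= t_end - last_n_days * 24
  tw_mean <- function(y) {
    tt <- d$time_h[sel]; yy <- y[sel]
    sum((yy[-1] + yy[-length(yy)]) / 2 * diff(tt)) / (tt[length(tt)] - tt[1])
  }
  p <- traj$params
  mean_ecf <- tw_mean(d$ecf_L)
  mean_aldo <- tw_mean(d$aldo_index)
  structure(
    list(window_days = last_n_days,
         mean_map_mmHg = tw_mean(d$map_mmHg),
         mean_ecf_L = mean_ecf,
         ecf_expansion_pct = 100 * (mean_ecf - p$v_ecf0) / p$v_ecf0,
         mean_colon_capacity_mmol_day = tw_mean(d$colon_capacity_mmol_day),
         mean_aldo_index = mean_aldo,
         aldo_exposure_per_day = 24 * mean_aldo),
    class = "homeo_summary")
}

#' @export
print.homeo_summary <- function(x, ...) {
  cat(sprintf("<steady state, trailing %g day(s)>\n", x$window_days))
  cat(sprintf("  mean MAP            %8.3f mmHg\n", x$mean_map_mmHg))
  cat(sprintf("  ECF expansion       %8.3f %%\n", x$ecf_expansion_pct))
  cat(sprintf("  colon capacity      %8.3f mmol/day\n",
              x$mean_colon_capacity_mmol_day))
  cat(sprintf("  aldosterone exposure%8.4f index*h/day\n",
              x$aldo_exposure_per_day))
  invisible(x)
}

#' @export
print.homeo_trajectory <- function(x, ...) {
  d <- x$data
  cat(sprintf("<homeo_trajectory> %g day(s), %d steps, %d ingestion event(s)\n",
              x$schedule$duration_days, nrow(d), length(x$schedule$events)))
  cat(sprintf("  final MAP %.2f mmHg, ECF %.3f L, colon capacity %.2f mmol/day\n",
              d$map_mmHg[nrow(d)], d$ecf_L[nrow(d)],
              d$colon_capacity_mmol_day[nrow(d)]))
  invisible(x)
}

#' @export
summary.homeo_trajectory <- function(object, last_n_days = 3, ...) {
  steady_state_summary(object, last_n_days)
}

#' @export
as.data.frame.homeo_trajectory <- function(x, ...) x$data

#' Plot a simulated trajectory
#'
#' Four base-graphics panels: luminal water and circulating deficit, hormone
#' indices, colonic sodium-absorption capacity, and the ECF/MAP outcome.
#'
#' @param x a \code{homeo_trajectory}.
#' @param ... ignored.
#' @return \code{x}, invisibly.
#' @export
plot.homeo_trajectory <- function(x, ...) {
  d <- x$data
  t_d <- d$time_h / 24
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1), mgp = c(2, 0.6, 0))
  on.exit(graphics::par(op))
  graphics::plot(t_d, d$luminal_L, type = "l", xlab = "", ylab = "water (L)")
  graphics::lines(t_d, d$deficit_L, col = 2)
  graphics::legend("topright", c("luminal", "deficit"), col = 1:2, lty = 1,
                   bty = "n", cex = 0.8)
  graphics::plot(t_d, d$aldo_index, type = "l", xlab = "", ylab = "hormone index")
  graphics::lines(t_d, d$avg_aldo_index, col = 4)
  graphics::legend("topright", c("aldosterone", "trailing mean"), col = c(1, 4),
                   lty = 1, bty = "n", cex = 0.8)
  graphics::plot(t_d, d$colon_capacity_mmol_day, type = "l", xlab = "",
                 ylab = "colon (mmol/day)")
  graphics::plot(t_d, d$map_mmHg, type = "l", xlab = "time (days)",
                 ylab = "MAP (mmHg)")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' One row per integration step, columns as in the \code{data} element.
#'
#' @param traj a \code{homeo_trajectory}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "homeo_trajectory"))
  utils::write.csv(traj$data, path, row.names = FALSE)
  invisible(path)
}
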