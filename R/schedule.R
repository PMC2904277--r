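#' Multi-day ingestion schedules
#'
#' An ingestion schedule is a duration in days plus a list of events, each an
#' ingestion of a beverage at a given hour since the start of the simulation.
#'
#' @param events list of events, each \code{list(time_h =, beverage =,
#'   volume_L =)}; \code{volume_L} defaults to the beverage's serving volume.
#'   May be empty (a pure baseline run).
#' @param duration_days length of the simulated period, days (> 0).
#' @return An object of class \code{"ingestion_schedule"}; events are sorted
#'   by time.
#' @export
ingestion_schedule <- function(events = list(), duration_days) {
  if (!is.numeric(duration_days) || length(duration_days) != 1L ||
      !is.finite(duration_days) || duration_days <= 0)
    stop("'duration_days' must be a single positive number")
  events <- lapply(events, function(ev) {
    if (!is.list(ev) || is.null(ev$time_h) || is.null(ev$beverage))
      stop("each event must be list(time_h =, beverage =)")
    if (!inherits(ev$beverage, "beverage"))
      stop("event 'beverage' must be a beverage object")
    if (!is.numeric(ev$time_h) || length(ev$time_h) != 1L || ev$time_h < 0 ||
        ev$time_h > duration_days * 24)
      stop(sprintf("event time %s h lies outside [0, %g] h",
                   format(ev$time_h), duration_days * 24))
    ev$volume_L <- ev$volume_L %||% ev$beverage$volume
    if (!is.numeric(ev$volume_L) || length(ev$volume_L) != 1L || ev$volume_L <= 0)
      stop("event 'volume_L' must be positive")
    ev[c("time_h", "beverage", "volume_L")]
  })
  if (length(events))
    events <- events[order(vapply(events, `[[`, numeric(1), "time_h"))]
  structure(list(events = events, duration_days = duration_days),
            class = "ingestion_schedule")
}

#' Regular daily drinking schedule
#'
#' The habitual-exposure pattern: the same beverage taken \code{drinks_per_day}
#' times each day at fixed daytime hours (a single drink at noon; several
#' drinks spread evenly between 08:00 and 18:00, along meals).
#'
#' @param drinks_per_day non-negative integer count of drinks per day.
#' @param bev the \code{beverage} ingested at each event.
#' @param duration_days simulated duration, days.
#' @param volume_L per-drink volume, litres; defaults to the beverage's
#'   serving volume.
#' @return An \code{ingestion_schedule}.
#' @examples
#' sched <- regular_schedule(3, preset_beverage("hfcs_softdrink"), 14)
#' @export
regular_schedule <- function(drinks_per_day, bev, duration_days,
                             volume_L = bev$volume) {
  if (!is.numeric(drinks_per_day) || length(drinks_per_day) != 1L ||
      drinks_per_day < 0 || drinks_per_day != round(drinks_per_day))
    stop("'drinks_per_day' must be a non-negative integer")
  if (drinks_per_day == 0)
    return(ingestion_schedule(list(), duration_days))
  hours <- if (drinks_per_day == 1) 12 else
    seq(8, 18, length.out = drinks_per_day)
  events <- list()
  for (day in seq_len(ceiling(duration_days)) - 1) {
    for (h in hours) {
      t <- day * 24 + h
      if (t <= duration_days * 24)
        events[[length(events) + 1L]] <-
          list(time_h = t, beverage = bev, volume_L = volume_L)
    }
  }
  ingestion_schedule(events, duration_days)
}

#' @export
print.ingestion_schedule <- function(x, ...) {
  cat(sprintf("<ingestion_schedule> %g day(s), %d event(s)\n",
              x$duration_days, length(x$events)))
  if (length(x$events)) {
    first <- x$events[seq_len(min(5L, length(x$events)))]
    for (ev in first)
      cat(sprintf("  t = %6.1f h: %.3g L of %s\n", ev$time_h, ev$volume_L,
                  ev$beverage$label))
    if (length(x$events) > 5L) cat(sprintf("  ... %d more\n", length(x$events) - 5L))
  }
  invisible(x)
}

#' Read an ingestion schedule from a config file
#'
#' YAML with \code{duration_days} and either an \code{events} list
#' (\code{time_h}, \code{beverage} as a preset name or file path, optional
#' \code{volume_L}) or a \code{pattern} block (\code{drinks_per_day},
#' \code{beverage}, optional \code{volume_L}) expanded by
#' [regular_schedule()].
#'
#' @param path schedule file path.
#' @return An \code{ingestion_schedule}.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop(sprintf("schedule file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$duration_days)) stop(sprintf("%s: missing 'duration_days'", path))
  resolve_bev <- function(ref) {
    if (file.exists(ref)) read_beverage(ref) else preset_beverage(ref)
  }
  if (!is.null(raw$pattern)) {
    pb <- raw$pattern
    if (is.null(pb$drinks_per_day) || is.null(pb$beverage))
      stop(sprintf("%s: pattern needs 'drinks_per_day' and 'beverage'", path))
    bev <- resolve_bev(pb$beverage)
    return(regular_schedule(pb$drinks_per_day, bev, raw$duration_days,
                            volume_L = pb$volume_L %||% bev$volume))
  }
  events <- lapply(raw$events, function(ev) {
    list(time_h = ev$time_h, beverage = resolve_bev(ev$beverage),
         volume_L = ev$volume_L)
  })
  ingestion_schedule(events, raw$duration_days)
}
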