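# Shared fixtures and independent oracles, built in code at test time.

hfcs_drink <- function() preset_beverage("hfcs_softdrink")

# Brute-force discrete absorption oracle: walks 1-second steps applying each
# kinetic class's constant rate inside its window.  Independent of the
# closed-form timecourse it cross-checks.
brute_absorbed <- function(result, t_query, dt_h = 1 / 3600) {
  p <- result$partitions
  fastv <- p$volume[p$class == "fast"]
  slowv <- p$volume[p$class == "slow"]
  tf <- result$fast_completion
  ts <- result$slow_completion
  rate <- function(t) {
    (t < tf) * fastv / tf + (t >= tf & t < ts) * slowv / (ts - tf)
  }
  vapply(t_query, function(tq) {
    if (tq <= 0) return(0)
    steps <- seq(0, tq, by = dt_h)
    sum(rate(steps[-length(steps)])) * dt_h
  }, numeric(1))
}

# A small sugar drink built from composition only (no declared override).
sugar_drink <- function(total_sugar_g_L, volume = 0.5,
                        label = sprintf("sugar %g g/L", total_sugar_g_L)) {
  beverage(label, volume, hfcs_composition(total_sugar_g_L))
}
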