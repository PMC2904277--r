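#' Built-in beverage presets
#'
#' The four common-diet reference beverages of the static trapping model --
#' salty commercial soup (1.3% NaCl, declared 400 mosm/L), sucrose soft drink
#' (13.3% sucrose, declared 400), HFCS soft drink (glucose 360 + fructose
#' 440 = 800 mosm/L by composition), WHO oral rehydration solution (glucose
#' 75 + salt 170 = 245 mosm/L) -- plus pure water and a hypertonic lactulose
#' solution.  Each ships as a key-value config file under
#' \code{system.file("extdata", "beverages", package = "osmotrap")}.
#'
#' The soup and sucrose presets carry declared osmolarities: their labelled
#' compositions (13 and 133 g/L) do not reproduce the declared 400 mosm/L
#' under ideal arithmetic, and the declared value takes precedence, as it
#' does for any labelled commercial product.
#'
#' @param name one of \code{"salty_soup"}, \code{"sucrose_softdrink"},
#'   \code{"hfcs_softdrink"}, \code{"who_ors"}, \code{"water"},
#'   \code{"lactulose_solution"}.
#' @return A \code{beverage}, or (for \code{preset_library()}) a named list
#'   of all presets.
#' @examples
#' beverage_osmolarity(preset_beverage("hfcs_softdrink"))  # 800
#' @export
preset_beverage <- function(name) {
  name <- match.arg(name, preset_names())
  path <- system.file("extdata", "beverages", paste0(name, ".yaml"),
                      package = "osmotrap", mustWork = TRUE)
  read_beverage(path)
}

#' @rdname preset_beverage
#' @export
preset_library <- function() {
  stats::setNames(lapply(preset_names(), preset_beverage), preset_names())
}

preset_names <- function() {
  c("salty_soup", "sucrose_softdrink", "hfcs_softdrink", "who_ors",
    "water", "lactulose_solution")
}

# Printed reference values (L, truncated to 2 decimals) for the four
# reference beverages at V = 0.5 L: trapped volume, absorbable volume,
# fast share, slow share.  "none" entries are compared as 0.
table1_reference <- function() {
  data.frame(
    preset = c("salty_soup", "sucrose_softdrink", "hfcs_softdrink", "who_ors"),
    v_d = c(0.16, 0.16, 0.83, 0),
    v_a = c(0.66, 0.66, 1.33, 0.5),
    fast = c(0.66, 0.33, 0.60, 0.5),
    slow = c(0, 0.33, 0.73, 0),
    stringsAsFactors = FALSE)
}

#' Reference-table report for the four beverage presets
#'
#' Runs the static trapping model on each reference beverage at the given
#' ingested volume and compares the computed trapped volume, absorbable
#' volume and fast/slow partition -- truncated to two decimals, the display
#' convention -- against the printed reference values, with a pass flag per
#' row.  Full-precision values are kept alongside.
#'
#' @param volume_L ingested volume, litres (default 0.5, the reference
#'   serving).
#' @param O_iso isotonic reference, mosm/L; overriding it away from 300
#'   makes the computed values diverge from the printed ones, which the
#'   report then flags.
#' @return An object of class \code{"table1_report"}: a data frame with
#'   computed, reference and pass columns and an \code{overall_pass}
#'   attribute.
#' @export
table1_report <- function(volume_L = 0.5, O_iso = 300) {
  ref <- table1_reference()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    tr <- osmotic_trapping(preset_beverage(ref$preset[i]), volume = volume_L,
                           O_iso = O_iso)
    p <- tr$partitions
    comp <- c(v_d = tr$V_d, v_a = tr$V_a,
              fast = p$volume[p$class == "fast"],
              slow = p$volume[p$class == "slow"])
    disp <- display_2dp(comp)
    expect <- as.numeric(ref[i, c("v_d", "v_a", "fast", "slow")])
    data.frame(
      preset = ref$preset[i],
      v_d = disp[["v_d"]], v_a = disp[["v_a"]],
      fast = disp[["fast"]], slow = disp[["slow"]],
      v_d_ref = expect[1], v_a_ref = expect[2],
      fast_ref = expect[3], slow_ref = expect[4],
      v_d_full = comp[["v_d"]], v_a_full = comp[["v_a"]],
      fast_full = comp[["fast"]], slow_full = comp[["slow"]],
      pass = all(abs(disp - expect) < 1e-9),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_pass") <- all(out$pass)
  class(out) <- c("table1_report", "data.frame")
  out
}

#' @export
print.table1_report <- function(x, ...) {
  cat("Reference-beverage trapping report (volumes in L, truncated to 2 dp)\n")
  show <- as.data.frame(x)[, c("preset", "v_d", "v_d_ref", "v_a", "v_a_ref",
                               "fast", "fast_ref", "slow", "slow_ref", "pass")]
  print.data.frame(show, row.names = FALSE, ...)
  cat(sprintf("overall: %s\n", if (attr(x, "overall_pass")) "PASS" else "FAIL"))
  invisible(x)
}
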