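#' Beverages: labelled volumes with a solute composition
#'
#' A beverage couples a label and serving volume to a list of solute
#' components (concentrations in g/L) and, optionally, a declared osmolarity
#' that overrides the value computed from composition.  Declared osmolarities
#' accommodate labelled products whose printed value does not match ideal
#' arithmetic (commercial soups, sodas) and ethanol-containing drinks, whose
#' osmolarity is never computed from mass here.
#'
#' @param label beverage name.
#' @param volume serving volume in litres (> 0).
#' @param components list of components, each \code{list(solute = <solute>,
#'   concentration = <g/L>)}; may be empty (pure water).
#' @param declared_osmolarity optional mosm/L override (>= 0).
#' @return An object of class \code{"beverage"}.
#' @examples
#' b <- beverage("soda", 0.5, hfcs_composition(110))
#' beverage_osmolarity(b)
#' @export
beverage <- function(label, volume, components = list(),
                     declared_osmolarity = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a non-empty character scalar")
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) || volume <= 0)
    stop("'volume' must be a single positive number (L)")
  components <- lapply(components, function(cmp) {
    if (!is.list(cmp) || is.null(cmp$solute) || is.null(cmp$concentration))
      stop("each component must be list(solute =, concentration =)")
    if (!inherits(cmp$solute, "solute"))
      stop("component 'solute' must be a solute object")
    if (!is.numeric(cmp$concentration) || length(cmp$concentration) != 1L ||
        !is.finite(cmp$concentration) || cmp$concentration < 0)
      stop(sprintf("component '%s': 'concentration' must be >= 0 g/L",
                   cmp$solute$name))
    cmp[c("solute", "concentration")]
  })
  if (!is.null(declared_osmolarity)) {
    if (!is.numeric(declared_osmolarity) || length(declared_osmolarity) != 1L ||
        !is.finite(declared_osmolarity) || declared_osmolarity < 0)
      stop("'declared_osmolarity' must be a single number >= 0 (mosm/L)")
  }
  structure(
    list(label = label, volume = volume, components = components,
         declared_osmolarity = declared_osmolarity),
    class = "beverage")
}

#' Overall beverage osmolarity
#'
#' Returns the declared osmolarity when one is present, otherwise the sum of
#' the ideal-solution osmolarity contributions of all components.
#'
#' @param bev a \code{beverage}.
#' @return Osmolarity in mosm/L.
#' @export
beverage_osmolarity <- function(bev) {
  stopifnot(inherits(bev, "beverage"))
  if (!is.null(bev$declared_osmolarity)) return(bev$declared_osmolarity)
  computed_osmolarity(bev)
}

# Sum of component contributions, ignoring any declared override.
computed_osmolarity <- function(bev) {
  if (length(bev$components) == 0L) return(0)
  sum(vapply(bev$components,
             function(cmp) component_osmolarity(cmp$solute, cmp$concentration),
             numeric(1)))
}

#' Pre-dilute a beverage with fresh water
#'
#' Adds water until the target osmolarity is reached (concentrations and any
#' declared osmolarity scale by the volume ratio).  Diluting a hyperosmolar
#' drink to isotonicity before ingestion removes the trapped-volume deficit
#' entirely -- the model's mitigation manoeuvre.
#'
#' @param bev a \code{beverage} with osmolarity above \code{target}.
#' @param target target osmolarity in mosm/L (default 300, the model's
#'   plasma-isotonic reference).
#' @return A new, larger-volume \code{beverage} at the target osmolarity.
#' @export
dilute_to_osmolarity <- function(bev, target = 300) {
  stopifnot(inherits(bev, "beverage"))
  osm <- beverage_osmolarity(bev)
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("'target' must be a single positive osmolarity (mosm/L)")
  if (osm <= target) return(bev)
  factor <- osm / target
  comps <- lapply(bev$components, function(cmp) {
    cmp$concentration <- cmp$concentration / factor
    cmp
  })
  beverage(paste0(bev$label, " (diluted)"), bev$volume * factor, comps,
           declared_osmolarity = if (!is.null(bev$declared_osmolarity)) target)
}

#' @export
print.beverage <- function(x, ...) {
  cat(sprintf("<beverage> %s: %.3g L at %s mosm/L%s\n", x$label, x$volume,
              format(round(beverage_osmolarity(x))),
              if (!is.null(x$declared_osmolarity)) " (declared)" else ""))
  for (cmp in x$components)
    cat(sprintf("  - %-10s %8.3f g/L  (%s mosm/L, %s)\n", cmp$solute$name,
                cmp$concentration,
                format(round(component_osmolarity(cmp$solute, cmp$concentration), 1)),
                cmp$solute$absorption_class))
  invisible(x)
}

#' Read a beverage definition from a config file
#'
#' The file is structured key-value text (YAML) with fields \code{label},
#' \code{volume_L}, optional \code{declared_osmolarity_mosm_L}, and
#' \code{components}, a list of \code{solute}/\code{concentration_g_L} pairs.
#' Solutes are looked up in the built-in registry; custom solutes can be
#' declared under \code{solutes} with \code{name}, \code{molar_mass},
#' \code{particles_per_formula} and \code{absorption_class}.
#'
#' @param path path to the beverage file.
#' @return A \code{beverage}.
#' @seealso [preset_beverage()] for the built-in presets shipped in this
#'   format under \code{system.file("extdata", "beverages", package = "osmotrap")}.
#' @export
read_beverage <- function(path) {
  if (!file.exists(path)) stop(sprintf("beverage file not found: %s", path))
  raw <- yaml::read_yaml(path)
  beverage_from_list(raw, context = path)
}

beverage_from_list <- function(raw, context = "beverage config") {
  for (fld in c("label", "volume_L"))
    if (is.null(raw[[fld]]))
      stop(sprintf("%s: missing field '%s'", context, fld))
  custom <- list()
  for (sdef in raw$solutes) {
    s <- solute(sdef$name, sdef$molar_mass,
                sdef$particles_per_formula %||% 1,
                sdef$absorption_class %||% "sodium_coupled_fast")
    custom[[tolower(s$name)]] <- s
  }
  comps <- lapply(raw$components, function(cdef) {
    if (is.null(cdef$solute) || is.null(cdef$concentration_g_L))
      stop(sprintf("%s: each component needs 'solute' and 'concentration_g_L'",
                   context))
    key <- tolower(cdef$solute)
    sol <- if (key %in% names(custom)) custom[[key]] else registered_solute(key)
    list(solute = sol, concentration = cdef$concentration_g_L)
  })
  beverage(raw$label, raw$volume_L, comps,
           declared_osmolarity = raw$declared_osmolarity_mosm_L)
}

#' Write an osmolarity report for a set of beverages
#'
#' @param beverages a list of \code{beverage} objects.
#' @param path optional CSV output path; when \code{NULL} the data frame is
#'   only returned.
#' @return Invisibly, a data frame with one row per beverage: label, volume,
#'   overall osmolarity, and the component breakdown
#'   (\code{"name conc g/L"} pairs separated by \code{"; "}).
#' @export
osmolarity_report <- function(beverages, path = NULL) {
  if (inherits(beverages, "beverage")) beverages <- list(beverages)
  rows <- lapply(beverages, function(b) {
    data.frame(
      label = b$label,
      volume_L = b$volume,
      osmolarity_mosm_per_L = round(beverage_osmolarity(b)),
      declared = !is.null(b$declared_osmolarity),
      components = paste(
        vapply(b$components,
               function(cmp) sprintf("%s %g g/L", cmp$solute$name, cmp$concentration),
               character(1)),
        collapse = "; "),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
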