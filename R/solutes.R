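#' Osmotically active solutes
#'
#' A solute is a named osmotically active species characterised by its molar
#' mass, the number of osmotically active particles each formula unit yields
#' in ideal solution (2 for NaCl, 1 for sugars), and the class of intestinal
#' handling that decides how fast the water associated with it can leave the
#' small bowel:
#'
#' \describe{
#'   \item{\code{sodium_coupled_fast}}{glucose and galactose, absorbed with
#'     sodium by the SGLT1 cotransporter; associated water is absorbed within
#'     about two hours.}
#'   \item{\code{facilitated_slow}}{fructose, absorbed by facilitated
#'     diffusion (GLUT5) along the entire small bowel; absorption can take up
#'     to four hours (longer in fructose malabsorbers).}
#'   \item{\code{disaccharide_sucrose}}{sucrose, hydrolysed to equimolar
#'     glucose + fructose; its osmolar share splits half fast, half slow.}
#'   \item{\code{electrolyte}}{salt (NaCl); sodium-driven, fast, and while it
#'     sits unabsorbed in the lumen it blunts the aldosterone response.}
#'   \item{\code{nonabsorbed_osmotic}}{lactulose and similar: never absorbed,
#'     carries its water to the colon.}
#'   \item{\code{ethanol_declared}}{ethanol; its osmolarity is never computed
#'     from mass here (ideal arithmetic does not reproduce measured values),
#'     beverages containing it must declare their osmolarity.}
#' }
#'
#' @param name solute name (character scalar).
#' @param molar_mass molar mass in g/mol; must be positive.
#' @param particles_per_formula ideal dissociation factor (>= 1).
#' @param absorption_class one of the classes listed above.
#' @return An object of class \code{"solute"}.
#' @examples
#' s <- solute("sucrose", 342.3, 1, "disaccharide_sucrose")
#' component_osmolarity(s, 125)   # ~365 mosm/L
#' @export
solute <- function(name, molar_mass, particles_per_formula = 1,
                   absorption_class = "sodium_coupled_fast") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty character scalar")
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || !is.finite(molar_mass) ||
      molar_mass <= 0)
    stop("'molar_mass' must be a positive number (g/mol)")
  if (!is.numeric(particles_per_formula) || length(particles_per_formula) != 1L ||
      particles_per_formula < 1)
    stop("'particles_per_formula' must be >= 1")
  if (!is.character(absorption_class) || length(absorption_class) != 1L ||
      !absorption_class %in% absorption_classes())
    stop(sprintf("'absorption_class' must be one of: %s",
                 paste(absorption_classes(), collapse = ", ")))
  structure(
    list(name = name, molar_mass = molar_mass,
         particles_per_formula = particles_per_formula,
         absorption_class = absorption_class),
    class = "solute")
}

#' @rdname solute
#' @export
absorption_classes <- function() {
  c("sodium_coupled_fast", "facilitated_slow", "disaccharide_sucrose",
    "electrolyte", "nonabsorbed_osmotic", "ethanol_declared")
}

#' Built-in solute registry
#'
#' Ships the solutes needed for the common-diet beverages: glucose, fructose
#' and galactose (180.16 g/mol), sucrose and lactulose (342.3 g/mol), and NaCl
#' (58.44 g/mol, dissociation factor 2).
#'
#' @param name optional solute name; if omitted the whole registry (a named
#'   list of \code{solute} objects) is returned.
#' @return A \code{solute}, or the named list of all registered solutes.
#' @export
registered_solute <- function(name) {
  reg <- list(
    glucose   = solute("glucose",   180.16, 1, "sodium_coupled_fast"),
    galactose = solute("galactose", 180.16, 1, "sodium_coupled_fast"),
    fructose  = solute("fructose",  180.16, 1, "facilitated_slow"),
    sucrose   = solute("sucrose",   342.3,  1, "disaccharide_sucrose"),
    nacl      = solute("nacl",      58.44,  2, "electrolyte"),
    lactulose = solute("lactulose", 342.3,  1, "nonabsorbed_osmotic"))
  if (missing(name)) return(reg)
  key <- tolower(name)
  if (!key %in% names(reg))
    stop(sprintf("unknown solute '%s'; registered: %s", name,
                 paste(names(reg), collapse = ", ")))
  reg[[key]]
}

#' @export
print.solute <- function(x, ...) {
  cat(sprintf("<solute> %s: %.2f g/mol, %g particle(s)/formula, class %s\n",
              x$name, x$molar_mass, x$particles_per_formula, x$absorption_class))
  invisible(x)
}

#' Ideal-solution osmolarity of one dissolved component
#'
#' Computes \code{concentration / molar_mass * particles_per_formula * 1000}
#' mosm/L, the ideal-solution arithmetic used throughout the model (no
#' osmotic coefficients).  Ethanol-class solutes are refused: their measured
#' osmolarity is far from ideal and must be declared at the beverage level.
#'
#' @param solute a \code{solute} object.
#' @param concentration concentration in g/L (vectorised, all >= 0).
#' @return Osmolarity contribution in mosm/L.
#' @examples
#' component_osmolarity(registered_solute("nacl"), 12.7)  # ~435 mosm/L
#' @export
component_osmolarity <- function(solute, concentration) {
  stopifnot(inherits(solute, "solute"))
  if (!is.numeric(concentration) || any(!is.finite(concentration)))
    stop("'concentration' must be finite numeric (g/L)")
  if (any(concentration < 0))
    stop("'concentration' must be >= 0 g/L")
  if (solute$absorption_class == "ethanol_declared")
    stop("ethanol osmolarity is not computed from mass; use a declared beverage osmolarity")
  concentration / solute$molar_mass * solute$particles_per_formula * 1000
}

#' HFCS composition from total sugar content
#'
#' Splits a total sugar concentration into fructose and glucose at the typical
#' soft-drink high-fructose corn syrup ratio of 55% fructose / 45% glucose by
#' mass.  Because the two monosaccharides share a molar mass (180.16 g/mol),
#' osmolar shares equal mass shares.
#'
#' @param total_sugar total sugar concentration in g/L (>= 0).
#' @param fructose_mass_fraction mass fraction of fructose, in [0, 1].
#' @return A list of two components, each \code{list(solute =, concentration =)}.
#' @examples
#' hfcs_composition(100)  # fructose 55 g/L + glucose 45 g/L
#' @export
hfcs_composition <- function(total_sugar, fructose_mass_fraction = 0.55) {
  if (!is.numeric(total_sugar) || length(total_sugar) != 1L || total_sugar < 0)
    stop("'total_sugar' must be a single number >= 0 (g/L)")
  if (!is.numeric(fructose_mass_fraction) || length(fructose_mass_fraction) != 1L ||
      fructose_mass_fraction < 0 || fructose_mass_fraction > 1)
    stop("'fructose_mass_fraction' must lie in [0, 1]")
  list(
    list(solute = registered_solute("fructose"),
         concentration = fructose_mass_fraction * total_sugar),
    list(solute = registered_solute("glucose"),
         concentration = (1 - fructose_mass_fraction) * total_sugar))
}
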