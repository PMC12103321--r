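#' Define a polymer or reference compound
#'
#' A `polymer_spec` couples a name, an empirical formula (repeat unit for
#' polymers, full compound for calibration salts) and an optional bulk
#' density. The carbon mass fraction is computed from the formula at
#' construction, never stored independently.
#'
#' @param name Material name (e.g. `"PS"`).
#' @param formula Hill-notation formula string or named count vector.
#' @param density Bulk density in g/cm3, or `NA` if not needed.
#' @param label Optional human-readable label.
#' @return Object of class `polymer_spec` with fields `name`, `formula`
#'   (count vector), `carbon_fraction`, `density`, `label`.
#' @examples
#' polymer_spec("PS", "C8H8", density = 1.05)
#' @export
polymer_spec <- function(name, formula, density = NA_real_, label = name) {
  f <- .as_formula_counts(formula)
  if (!is.na(density) && density <= 0) stop("'density' must be positive")
  structure(
    list(name = name, formula = f,
         carbon_fraction = carbon_mass_fraction(f),
         density = as.numeric(density), label = label),
    class = "polymer_spec"
  )
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf("<polymer_spec> %s (%s): %s, %.2f %%C, density %s g/cm3\n",
              x$name, x$label,
              paste0(names(x$formula), ifelse(x$formula > 1, x$formula, ""),
                     collapse = ""),
              100 * x$carbon_fraction,
              ifelse(is.na(x$density), "NA", format(x$density))))
  invisible(x)
}

#' Registry of the study's materials
#'
#' Loads the packaged registry of polymers and calibration compounds
#' (PS, PE, PP, PVC, PET, cellulose, KHP, Na2CO3) and recomputes every
#' carbon fraction from its formula.
#'
#' @param file Path to a registry JSON file; defaults to the packaged one.
#' @return Named list of [polymer_spec()] objects.
#' @examples
#' reg <- polymer_registry()
#' reg$PS$carbon_fraction
#' @export
polymer_registry <- function(file = system.file("extdata", "polymers.json",
                                                package = "fractoc")) {
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  out <- lapply(raw$materials, function(m)
    polymer_spec(m$name, m$formula,
                 density = if (is.null(m$density)) NA_real_ else m$density,
                 label = if (is.null(m$label)) m$name else m$label))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Look up one material from the packaged registry
#'
#' @param name Registry key, e.g. `"PS"`.
#' @param registry Registry list; defaults to [polymer_registry()].
#' @return A [polymer_spec()].
#' @export
get_polymer <- function(name, registry = polymer_registry()) {
  if (!name %in% names(registry))
    stop(sprintf("material '%s' not in registry (have: %s)", name,
                 paste(names(registry), collapse = ", ")))
  registry[[name]]
}
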