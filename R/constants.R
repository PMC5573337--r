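#' Equilibrium constant set for the inorganic speciation solver
#'
#' Loads the thermodynamic formation constants (log10, 25 degrees C, infinite
#' dilution) used by [speciate()]. Defaults ship with the package as an
#' editable JSON table (`inst/extdata/equilibrium_constants.json`), with the
#' reaction convention and provenance recorded per constant. All reactions are
#' written in terms of the free ligand the solver tracks: OH-, HCO3-, CO3(2-)
#' and SO4(2-).
#'
#' The constants cover the hydroxide and carbonate complexes of Cu and Co
#' (CuOH+, CuCO3(aq), CuHCO3+, CoOH+, CoHCO3+), the open-system carbonate
#' chain (Henry constant of CO2 and the two acidity constants), the water ion
#' product, and the MgSO4(aq)/CaSO4(aq) ion pairs.
#'
#' @param file Path to a JSON table with the same layout as the shipped
#'   default. `NULL` uses the packaged table.
#' @param overrides Named list of `logK_*` values replacing individual
#'   defaults, e.g. `list(logK_CuHCO3 = 1.8)`. Use `-Inf` to switch a complex
#'   off.
#' @return A named list of class `equilibrium_constants` with one numeric
#'   log10 K per reaction.
#' @examples
#' kset <- default_constants()
#' kset$logK_CuOH
#' no_pairs <- default_constants(overrides = list(logK_MgSO4 = -Inf,
#'                                                logK_CaSO4 = -Inf))
#' @export
default_constants <- function(file = NULL, overrides = list()) {
  if (is.null(file)) {
    file <- system.file("extdata", "equilibrium_constants.json",
                        package = "blmtu")
  }
  raw <- jsonlite::read_json(file)
  raw[["_comment"]] <- NULL
  kset <- lapply(raw, function(entry) {
    if (is.list(entry)) as.numeric(entry$value) else as.numeric(entry)
  })
  required <- c("logK_H_CO2", "logKa1", "logKa2", "logKw",
                "logK_CuOH", "logK_CuCO3", "logK_CuHCO3",
                "logK_CoOH", "logK_CoHCO3", "logK_MgSO4", "logK_CaSO4")
  missing <- setdiff(required, names(kset))
  if (length(missing) > 0L) {
    stop("constants table is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(overrides) > 0L) {
    unknown <- setdiff(names(overrides), required)
    if (length(unknown) > 0L) {
      stop("unknown constant(s) in overrides: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    kset[names(overrides)] <- lapply(overrides, as.numeric)
  }
  structure(kset, class = "equilibrium_constants")
}

# charge lookup for every species the solver can report
.species_charge <- c(
  K = 1, Na = 1, Ca = 2, Mg = 2, Cu = 2, Co = 2,
  Cl = -1, SO4 = -2, H = 1, OH = -1,
  CO2 = 0, HCO3 = -1, CO3 = -2,
  CuOH = 1, CuCO3 = 0, CuHCO3 = 1,
  CoOH = 1, CoHCO3 = 1,
  MgSO4 = 0, CaSO4 = 0
)

#' Charge of a tracked aqueous species
#'
#' @param species Character vector of species names (free ions by bare element
#'   symbol, complexes by formula, e.g. `"CuHCO3"`).
#' @return Integer charges.
#' @examples
#' species_charge(c("Mg", "SO4", "CuCO3"))
#' @export
species_charge <- function(species) {
  unknown <- setdiff(species, names(.species_charge))
  if (length(unknown) > 0L) {
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  .species_charge[species]
}
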