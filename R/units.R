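#' Energy unit conversion
#'
#' Converts scalar (or vector) energies between the units that occur in a
#' conformer-analysis workflow: electronic energies arrive in hartree,
#' CREST selection windows are quoted in kcal/mol, relative-energy plots
#' use kJ/mol and orbital gaps are reported in eV.
#'
#' Conversion factors (CODATA 2018):
#' 1 hartree = 2625.499639 kJ/mol = 627.509474 kcal/mol = 27.211386245988 eV,
#' and the thermochemical calorie, 1 kcal = 4.184 kJ.
#'
#' @param value numeric vector of energies.
#' @param from unit of `value`: one of `"hartree"`, `"kJ/mol"`,
#'   `"kcal/mol"`, `"eV"`.
#' @param to target unit, same choices.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "kJ/mol")    # 2625.499639
#' convert_energy(6, "kcal/mol", "kJ/mol")   # 25.104
#' @export
convert_energy <- function(value, from, to) {
  from <- match_energy_unit(from)
  to <- match_energy_unit(to)
  if (from == to) return(value)
  value * .kj_per_unit[[from]] / .kj_per_unit[[to]]
}

# kJ/mol per one unit of each energy unit
.kj_per_unit <- c(
  "hartree"  = 2625.499639,
  "kJ/mol"   = 1,
  "kcal/mol" = 4.184,
  "eV"       = 2625.499639 / 27.211386245988
)

match_energy_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L ||
      !(unit %in% names(.kj_per_unit))) {
    stop("unknown energy unit: ", deparse(unit),
         " (expected one of ", paste(names(.kj_per_unit), collapse = ", "),
         ")", call. = FALSE)
  }
  unit
}

#' Molar gas constant in kJ/(mol K)
#'
#' Used as the molar form of the Boltzmann constant when conformer
#' energies are expressed per mole.
#' @keywords internal
R_KJ_PER_MOL_K <- 8.314462618e-3
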