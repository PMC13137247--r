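#' Standard-state correction for a binding free energy
#'
#' Converts a binding free energy computed in a simulation box of volume
#' `V_box` to the 1 M standard state:
#' `-kB T log(V_box / V_standard)`, with `V_standard = 1.66054` nm^3 the
#' volume per molecule at 1 mol/L. For boxes larger than `V_standard` the
#' correction is negative (binding looks more favorable at 1 M than in the
#' dilute box). A 12 nm cubic box at 298.15 K gives about -17.2 kJ/mol.
#'
#' @param V_box box volume, nm^3.
#' @param temperature K.
#' @param constants a [thermo_constants()].
#' @return Correction in kJ/mol.
#' @examples
#' standard_state_correction(12^3) # about -17.2
#' @export
standard_state_correction <- function(V_box,
                                      temperature = constants$temperature,
                                      constants = thermo_constants()) {
  if (!is.numeric(V_box) || any(V_box <= 0)) stop("box volume must be positive")
  -constants$kB * temperature * log(V_box / constants$V_standard)
}

#' Standard-state unbinding free energy
#'
#' `dF_unbind^o = -(dF_box + standard_state_correction)`: the box-volume
#' binding free energy is corrected to 1 M and negated, since unbinding is
#' minus binding. Box binding free energies of -60 and -25 kJ/mol in a
#' 12 nm cubic box give about +77 and +42 kJ/mol.
#'
#' @param dF_box binding free-energy difference from the box simulation,
#'   kJ/mol (bound minus unbound; negative = bound favored).
#' @param V_box box volume, nm^3.
#' @param temperature K.
#' @param constants a [thermo_constants()].
#' @return Standard unbinding free energy, kJ/mol.
#' @examples
#' standard_unbinding(-60, 12^3) # about 77
#' @export
standard_unbinding <- function(dF_box, V_box,
                               temperature = constants$temperature,
                               constants = thermo_constants()) {
  stopifnot(is.finite(dF_box))
  -(dF_box + standard_state_correction(V_box, temperature, constants))
}

#' Population depletion factor
#'
#' The Boltzmann fold-change `exp(dF / kB T)` by which a free-energy
#' penalty `dF > 0` depletes the population of a state: a 25 kJ/mol
#' penalty at 298.15 K depletes a catalytically competent ensemble about
#' 24 000-fold.
#'
#' @param dF free-energy penalty, kJ/mol.
#' @param temperature K.
#' @param constants a [thermo_constants()].
#' @return Dimensionless fold-change (> 1 for dF > 0); multiplicative in
#'   `dF`.
#' @examples
#' population_depletion_factor(25) # about 2.4e4
#' @export
population_depletion_factor <- function(dF,
                                        temperature = constants$temperature,
                                        constants = thermo_constants()) {
  if (temperature <= 0) stop("temperature must be positive")
  stopifnot(is.finite(dF))
  exp(dF / (constants$kB * temperature))
}

#' Per-monomer free energy
#'
#' Divides an oligomer-level free energy evenly over its repeat units:
#' 77 kJ/mol over a tetramer is 19.25 kJ/mol per monomer, 42 kJ/mol is
#' 10.5.
#'
#' @param dF free energy, kJ/mol.
#' @param n_monomers number of repeat units (>= 1).
#' @return kJ/mol per monomer.
#' @export
per_monomer <- function(dF, n_monomers) {
  if (n_monomers < 1) stop("n_monomers must be >= 1")
  dF / n_monomers
}

#' Fold-surface energetics of a polymer crystal
#'
#' @param sigma_e fold surface free energy, J/m^2.
#' @param A_chain chain cross-sectional area, nm^2.
#' @return An object of class `surface_energetics`.
#' @export
surface_energetics <- function(sigma_e = 0.106, A_chain = 0.20) {
  stopifnot(sigma_e >= 0, A_chain >= 0)
  structure(list(sigma_e = sigma_e, A_chain = A_chain),
            class = "surface_energetics")
}

#' Detachment cost from fold-surface free energy
#'
#' Converts the macroscopic fold surface free energy of a polymer crystal
#' lamella into a molar energetic cost per repeat unit pulled off the
#' crystal face: `dF = 2 * sigma_e * A_chain * N_A` (two new surfaces are
#' created), with units converted from J/m^2 x nm^2 to kJ/mol. The
#' experimental sigma_e = 0.106 J/m^2 and A_chain = 0.20 nm^2 give about
#' 25.5 kJ/mol per PET repeat unit.
#'
#' @param surface a [surface_energetics()].
#' @param constants a [thermo_constants()].
#' @return kJ/mol per repeat unit; linear in both inputs.
#' @examples
#' fold_surface_cost(surface_energetics(0.106, 0.20)) # about 25.5
#' @export
fold_surface_cost <- function(surface = surface_energetics(),
                              constants = thermo_constants()) {
  stopifnot(inherits(surface, "surface_energetics"))
  # J/m^2 * nm^2 = 1e-18 J; * N_A -> J/mol; /1000 -> kJ/mol
  2 * surface$sigma_e * surface$A_chain * 1e-18 * constants$N_A / 1000
}
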