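# Thermodynamic-cycle arithmetic for water binding free energies. The
# alchemical legs themselves (exnihilation from the cavity, insertion into
# bulk) are sampled quantities supplied by the user; this module provides
# the analytic harmonic-restraint correction and the cycle composition.

#' Harmonic restraint specification
#'
#' @param k_harm harmonic force constant on the water oxygen,
#'   kcal/mol/Angstrom^2 (> 0).
#' @param temperature temperature, K.
#' @param c0_molar standard bulk water concentration, mol/dm^3; converted
#'   internally to molecules/Angstrom^3 (55 M = 0.03312).
#' @return An object of class \code{restraint_spec}.
#' @export
restraint_spec <- function(k_harm, temperature = 300, c0_molar = 55) {
  stopifnot(k_harm > 0, temperature > 0, c0_molar > 0)
  structure(list(k_harm = k_harm, temperature = temperature,
                 c0_molar = c0_molar,
                 c0 = .molar_to_number_density(c0_molar)),
            class = "restraint_spec")
}

#' Effective volume of a harmonically restrained water
#'
#' \deqn{V_{harm} = (2\pi RT / k_{harm})^{3/2}}
#' in Angstrom^3, with RT in kcal/mol and the force constant in
#' kcal/mol/Angstrom^2.
#'
#' @param k_harm force constant, kcal/mol/Angstrom^2.
#' @param temperature temperature, K.
#' @return volume in Angstrom^3.
#' @export
harmonic_volume <- function(k_harm, temperature = 300) {
  (2 * pi * GAS_CONSTANT_KCAL * temperature / k_harm)^(3 / 2)
}

#' Analytic free-energy penalty of a harmonic restraint
#'
#' Restraining the water oxygen in a harmonic well of force constant
#' \code{k_harm} confines it from the standard bulk concentration to the
#' effective volume \eqn{V_{harm}}, with the analytic penalty
#' \deqn{\Delta G_{restrain} = -RT \ln[C_0 V_{harm}]}.
#' At the production settings (k = 0.5 kcal/mol/Angstrom^2, 300 K, 55 M)
#' this evaluates to +0.23 kcal/mol.
#'
#' @param spec a [restraint_spec()], or a force constant (then
#'   \code{temperature} and \code{c0_molar} apply).
#' @param temperature,c0_molar used when \code{spec} is numeric.
#' @return Delta G_restrain in kcal/mol.
#' @examples
#' restraint_correction(0.5)  # +0.23 at 300 K, 55 M
#' @export
restraint_correction <- function(spec, temperature = 300, c0_molar = 55) {
  if (!inherits(spec, "restraint_spec"))
    spec <- restraint_spec(spec, temperature, c0_molar)
  v <- harmonic_volume(spec$k_harm, spec$temperature)
  -GAS_CONSTANT_KCAL * spec$temperature * log(spec$c0 * v)
}

#' Legs of the water binding free-energy cycle
#'
#' The cycle transfers a water molecule from bulk at standard concentration
#' into a protein cavity: liberation to a fixed point (cancels with the
#' reverse transfer in vacuum), annihilation from bulk
#' (\code{dG_insertion}), harmonic restraint in the cavity
#' (\code{dG_restrain}, analytic), exnihilation in the cavity
#' (\code{dG_exnihilation}, sampled), and restraint removal
#' (\code{dG_unrestrain}, assumed zero: the force constant is small
#' relative to the atomic fluctuations of a cavity water).
#'
#' @param dG_exnihilation sampled cavity exnihilation free energy, kcal/mol.
#' @param dG_insertion bulk insertion free energy, kcal/mol; the default is
#'   the TIP4P-2005 value for a fixed water at 300 K.
#' @param dG_restrain restraint correction, kcal/mol; defaults to the
#'   analytic value at k = 0.5 kcal/mol/Angstrom^2.
#' @param dG_unrestrain restraint-removal leg, kcal/mol.
#' @return An object of class \code{cycle_legs}.
#' @export
cycle_legs <- function(dG_exnihilation, dG_insertion = -6.95,
                       dG_restrain = restraint_correction(0.5),
                       dG_unrestrain = 0) {
  stopifnot(is.finite(dG_exnihilation), is.finite(dG_insertion),
            is.finite(dG_restrain), is.finite(dG_unrestrain))
  structure(list(dG_exnihilation = dG_exnihilation,
                 dG_insertion = dG_insertion,
                 dG_restrain = dG_restrain,
                 dG_unrestrain = dG_unrestrain),
            class = "cycle_legs")
}

#' Water binding free energy from the cycle legs
#'
#' \deqn{\Delta G_{bind} = \Delta G_{exnihilation} - \Delta G_{insertion}
#'   + \Delta G_{restrain} + \Delta G_{unrestrain}}
#' No symmetry-number correction is applied: with the unbound water fixed
#' and the bound water kinetically trapped in one symmetry-related state,
#' the symmetry contribution vanishes.
#'
#' @param legs a [cycle_legs()] object.
#' @return Delta G_bind in kcal/mol.
#' @examples
#' binding_free_energy(cycle_legs(-14.27))  # an IL-1beta cavity water
#' @export
binding_free_energy <- function(legs) {
  stopifnot(inherits(legs, "cycle_legs"))
  legs$dG_exnihilation - legs$dG_insertion + legs$dG_restrain +
    legs$dG_unrestrain
}
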