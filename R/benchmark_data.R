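# Published benchmark values for 23 buried water molecules in five proteins
# (IL-1beta, T4 lysozyme, FKBP-2, carbonic anhydrase II, beta-lactamase),
# shipped as plain-text tables: the per-site thermodynamic components from
# explicit-solvent IFST analysis and the head-to-head comparison of IFST
# and alchemical (FEP) binding free energies for the 19 cavities.

#' Benchmark comparison of IFST and alchemical binding free energies
#'
#' Nineteen protein cavities (doubly occupied cavities count once, with
#' both waters removed together): the alchemical-cycle reference binding
#' free energy and the IFST prediction, kcal/mol.
#'
#' @return data frame with columns system, site_id, dG_reference, dG_ifst.
#' @examples
#' b <- hydration_benchmark()
#' comparison_stats(b$dG_reference, b$dG_ifst)
#' @export
hydration_benchmark <- function() {
  utils::read.csv(system.file("extdata", "cavity_water_benchmark.csv",
                              package = "hydrosite"),
                  stringsAsFactors = FALSE)
}

#' Benchmark per-site thermodynamic components
#'
#' The per-water IFST ledger for the 23 benchmark hydration sites: mean
#' interaction energies, entropy contributions as -T S terms, and the
#' resulting free energies, kcal/mol. Water-water columns are NA for
#' singly occupied cavities.
#'
#' @return data frame with columns system, water_id, E_sw, E_ww, dE_ifst,
#'   mTS_sw, mTS_ww, mTdS_ifst, dG_ifst.
#' @export
hydration_site_table <- function() {
  utils::read.csv(system.file("extdata", "hydration_site_thermo.csv",
                              package = "hydrosite"),
                  stringsAsFactors = FALSE)
}
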