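#' Convert a docking binding free energy to pKi
#'
#' Uses the standard thermodynamic relation \eqn{\Delta G = -RT \ln K_i},
#' so that \eqn{pK_i = -\Delta G / (\ln 10 \cdot R T)} with
#' R = 1.9872e-3 kcal/(mol K).  A favourable (negative) affinity gives a
#' positive pKi; the mapping is linear in the affinity.
#'
#' @param affinity Binding free energy, kcal/mol (negative = favourable;
#'   vectorised).
#' @param temperature Absolute temperature in K (default 298.15).
#' @return pKi (dimensionless).
#' @examples
#' pki_from_affinity(-10.3)   # 7.55
#' @export
pki_from_affinity <- function(affinity, temperature = 298.15) {
  if (temperature <= 0) abort("temperature must be > 0",
                              class = "seedshield_domain_error")
  -affinity / (log(10) * R_KCAL * temperature)
}

#' @rdname pki_from_affinity
#' @param pki pKi value(s) to convert back to a free energy.
#' @export
affinity_from_pki <- function(pki, temperature = 298.15) {
  if (temperature <= 0) abort("temperature must be > 0",
                              class = "seedshield_domain_error")
  -pki * log(10) * R_KCAL * temperature
}

#' Ligand efficiency
#'
#' Binding free-energy magnitude per heavy (non-hydrogen) atom of the
#' ligand: `LE = |affinity| / heavy_atoms`.  The default heavy-atom count
#' of 24 corresponds to the C19H10N2O3 alkaloid used as the active
#' compound.
#'
#' @inheritParams pki_from_affinity
#' @param heavy_atoms Number of heavy atoms (integer `>= 1`).
#' @return Ligand efficiency, kcal/mol per heavy atom.
#' @examples
#' ligand_efficiency(-10.3)   # 0.429
#' @export
ligand_efficiency <- function(affinity, heavy_atoms = 24) {
  if (any(heavy_atoms < 1) || any(heavy_atoms != round(heavy_atoms))) {
    abort("heavy_atoms must be an integer >= 1", class = "seedshield_domain_error")
  }
  abs(affinity) / heavy_atoms
}

#' Post-process docking affinities
#'
#' Derives pKi and ligand efficiency for a table of docking results.
#'
#' @param data Tibble with columns `target` and `affinity_kcal_mol`.
#' @inheritParams ligand_efficiency
#' @inheritParams pki_from_affinity
#' @return The input tibble with `pki` and `ligand_efficiency` columns
#'   appended.
#' @examples
#' docking_summary(cb3c_fixtures()$docking)
#' @export
docking_summary <- function(data, heavy_atoms = 24, temperature = 298.15) {
  stopifnot(all(c("target", "affinity_kcal_mol") %in% names(data)))
  dplyr::mutate(
    as_tibble(data),
    pki = pki_from_affinity(.data$affinity_kcal_mol, temperature),
    ligand_efficiency = ligand_efficiency(.data$affinity_kcal_mol, heavy_atoms)
  )
}
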