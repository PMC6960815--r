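# Physical constants at T = 298.15 K.  All internal energies are in kBT,
# lengths in nm; user-facing force constants are in the kcal/mol units
# conventional in molecular force fields.

#' Physical constants used by the model
#'
#' Fixed conversion factors at the working temperature of 298.15 K:
#' `kcal_mol_to_kBT` (1 kcal/mol in kBT), `kBT_pN_nm` (kBT in pN nm),
#' `bjerrum_nm` (Bjerrum length of water, nm) and `debye_prefactor_nm`
#' (so that the Debye length is `debye_prefactor_nm / sqrt(I)` nm for an
#' ionic strength I in mol/L).
#'
#' @format A named list of scalars.
#' @export
sbris_constants <- list(
  temperature_K      = 298.15,
  kcal_mol_to_kBT    = 1.6878,
  kBT_pN_nm          = 4.1164,
  bjerrum_nm         = 0.7,
  debye_prefactor_nm = 0.304
)

#' Electrostatic environment of the chain
#'
#' Bundles the Debye-Hueckel parameters for aqueous 1:1 salt at 298.15 K.
#' The Bjerrum length is fixed at 0.7 nm and the Debye screening length is
#' \eqn{\kappa^{-1} = 0.304/\sqrt{I}} nm for ionic strength \eqn{I} in mol/L.
#'
#' @param ionic_strength Ionic strength in mol/L (> 0), or 0 for an
#'   unscreened Coulomb potential.
#' @param bjerrum_length Bjerrum length in nm.  The default is the value for
#'   water at 298.15 K; setting it to 0 switches all long-range
#'   electrostatics off.
#' @return An object of class `electrostatic_environment` with fields
#'   `ionic_strength`, `bjerrum_length`, `debye_length` (nm, `Inf` at I = 0),
#'   `kappa` (1/nm) and `temperature`.
#' @examples
#' electrostatic_environment(1)$debye_length      # 0.304 nm
#' electrostatic_environment(0.001)$debye_length  # ~9.61 nm
#' @export
electrostatic_environment <- function(ionic_strength,
                                      bjerrum_length = sbris_constants$bjerrum_nm) {
  stopifnot(is.numeric(ionic_strength), length(ionic_strength) == 1L,
            ionic_strength >= 0, is.finite(ionic_strength))
  stopifnot(is.numeric(bjerrum_length), bjerrum_length >= 0)
  kappa <- if (ionic_strength > 0)
    sqrt(ionic_strength) / sbris_constants$debye_prefactor_nm else 0
  structure(list(
    ionic_strength = ionic_strength,
    bjerrum_length = bjerrum_length,
    debye_length   = if (kappa > 0) 1 / kappa else Inf,
    kappa          = kappa,
    temperature    = sbris_constants$temperature_K
  ), class = "electrostatic_environment")
}

#' @export
print.electrostatic_environment <- function(x, ...) {
  cat("Debye-Hueckel environment (T = ", x$temperature, " K)\n", sep = "")
  cat("  ionic strength : ", x$ionic_strength, " M\n", sep = "")
  cat("  Bjerrum length : ", x$bjerrum_length, " nm\n", sep = "")
  cat("  Debye length   : ", signif(x$debye_length, 6), " nm\n", sep = "")
  invisible(x)
}
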