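# Physical constants and equilibrium potentials.
#
# Internal unit system (conversions happen only at I/O boundaries):
#   potential mV, concentration mM, current nA, conductance uS (nA/mV),
#   capacitance nF, volume L, time s.

#' Ion species handled by the model
#'
#' The model tracks exactly three ionic species: K+, Na+ and Cl-.
#' @format Named integer vector of valences.
#' @export
LW_IONS <- c(K = 1L, Na = 1L, Cl = -1L)

#' Physical constants
#'
#' Gas constant, Faraday constant and absolute temperature, bundled with the
#' precomputed thermal voltage `RT/F` in mV. All simulations run at body
#' temperature (310.15 K) unless a different temperature is supplied.
#'
#' @param temperature_k absolute temperature in kelvin.
#' @return list with elements `R` (J/(mol K)), `T` (K), `F` (C/mol) and
#'   `rtf_mv` (mV).
#' @examples
#' physical_constants()$rtf_mv # about 26.7 mV at 310.15 K
#' @export
physical_constants <- function(temperature_k = 310.15) {
  if (!is.numeric(temperature_k) || length(temperature_k) != 1L ||
      !is.finite(temperature_k) || temperature_k <= 0) {
    stop("temperature_k must be a single positive number", call. = FALSE)
  }
  R <- 8.314462618
  F <- 96485.33212
  list(R = R, T = temperature_k, F = F,
       rtf_mv = 1000 * R * temperature_k / F)
}

#' Ion valence
#'
#' @param ion one of `"K"`, `"Na"`, `"Cl"`.
#' @return integer charge number.
#' @export
ion_valence <- function(ion) {
  ion <- match.arg(ion, names(LW_IONS))
  unname(LW_IONS[ion])
}

#' Nernst equilibrium potential
#'
#' `E_X = (RT / zF) ln([X]_out / [X]_in)`, the membrane potential at which the
#' net flux of ion X through a perfectly selective conductance vanishes.
#' Potentials follow the membrane convention used throughout the package:
#' intracellular minus adjacent extracellular.
#'
#' @param ion one of `"K"`, `"Na"`, `"Cl"`.
#' @param conc_out extracellular concentration (mM), must be positive.
#' @param conc_in intracellular concentration (mM), must be positive.
#' @param constants output of [physical_constants()].
#' @param where optional label (compartment/membrane) used in error messages.
#' @return equilibrium potential in mV.
#' @examples
#' nernst_potential("K", 5, 140)   # deeply negative
#' nernst_potential("K", 10, 10)   # zero at equal concentrations
#' @export
nernst_potential <- function(ion, conc_out, conc_in,
                             constants = physical_constants(),
                             where = NULL) {
  z <- ion_valence(ion)
  bad <- !is.finite(conc_out) | conc_out <= 0 | !is.finite(conc_in) | conc_in <= 0
  if (any(bad)) {
    loc <- if (is.null(where)) "" else paste0(" at ", where)
    stop(sprintf("non-positive %s concentration%s: out = %s mM, in = %s mM",
                 ion, loc, paste(signif(conc_out, 6), collapse = ","),
                 paste(signif(conc_in, 6), collapse = ",")), call. = FALSE)
  }
  (constants$rtf_mv / z) * log(conc_out / conc_in)
}
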