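# Transport elements: the per-element flux laws from which membrane currents
# and the system ODEs are assembled. Every flux law is a deterministic pure
# function of (membrane potential, adjacent concentrations, parameters).

LW_ELEMENT_KINDS <- c("ohmic_channel", "met_channel", "nak_atpase",
                      "leak_conductance", "nsc_conductance",
                      "na_transporter", "cl_transporter", "clc_channel")

# kinds whose per-ion currents are Ohmic: I_X = g_X (v - E_X)
LW_OHMIC_KINDS <- c("ohmic_channel", "met_channel", "leak_conductance",
                    "nsc_conductance", "clc_channel")

#' Construct a transport element
#'
#' A channel or transporter attached to one membrane domain. `magnitude` is a
#' per-cell quantity (conductance in nS for Ohmic kinds, maximal turnover
#' current in nA for transporters) and is multiplied by `n_cells`, the number
#' of cells whose membranes make up the domain.
#'
#' @param kind one of `"ohmic_channel"`, `"met_channel"`, `"nak_atpase"`,
#'   `"leak_conductance"`, `"nsc_conductance"`, `"na_transporter"`,
#'   `"cl_transporter"`, `"clc_channel"`.
#' @param magnitude per-cell conductance (nS) or maximal transporter current
#'   (nA); non-negative.
#' @param n_cells positive integer cell-count multiplier.
#' @param ions named weights over `K`, `Na`, `Cl` giving the per-ion split of
#'   the conductance for Ohmic kinds; they must sum to 1. Ignored for
#'   transporters, whose stoichiometry is fixed by `kind`.
#' @param params kinetic parameters. For `nak_atpase`: `km_na_mM`, `km_k_mM`,
#'   `hill_na`, `hill_k` (saturable Michaelis-Menten dependence of the pump
#'   rate on intracellular Na+ and extracellular K+). For `na_transporter` /
#'   `cl_transporter`: `km_mM`.
#' @param label identifier used in flux tables (defaults to `kind`).
#' @param provenance free-text note recording where the magnitude comes from.
#' @return object of class `lw_element`.
#' @export
transport_element <- function(kind, magnitude, n_cells = 1L, ions = NULL,
                              params = list(), label = kind,
                              provenance = "unspecified") {
  kind <- match.arg(kind, LW_ELEMENT_KINDS)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0 ||
      !is.finite(magnitude)) {
    stop("element magnitude must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1) {
    stop("n_cells must be a positive count", call. = FALSE)
  }
  if (kind %in% LW_OHMIC_KINDS) {
    if (is.null(ions)) {
      ions <- switch(kind,
        met_channel = c(K = 1),
        clc_channel = c(Cl = 1),
        nsc_conductance = c(K = 0.5, Na = 0.5),
        stop(sprintf("element kind '%s' needs explicit per-ion weights", kind),
             call. = FALSE))
    }
    if (is.null(names(ions)) || !all(names(ions) %in% names(LW_IONS)) ||
        any(ions < 0) || abs(sum(ions) - 1) > 1e-12) {
      stop("ion weights must be named over K/Na/Cl, non-negative, summing to 1",
           call. = FALSE)
    }
  } else {
    ions <- switch(kind,
      nak_atpase = c(K = 1, Na = 1),      # fixed 3:2 stoichiometry, see flux law
      na_transporter = c(Na = 1),
      cl_transporter = c(Cl = 1))
  }
  defaults <- switch(kind,
    nak_atpase = list(km_na_mM = 10, km_k_mM = 1.5, hill_na = 3, hill_k = 2),
    na_transporter = list(km_mM = 20),
    cl_transporter = list(km_mM = 30),
    list())
  params <- utils::modifyList(defaults, params)
  structure(list(kind = kind, magnitude = magnitude, n_cells = as.integer(n_cells),
                 ions = ions, params = params, label = label,
                 provenance = provenance),
            class = "lw_element")
}

# full per-ion weight vector (K, Na, Cl) for an element
.ion_weights <- function(element) {
  w <- c(K = 0, Na = 0, Cl = 0)
  w[names(element$ions)] <- element$ions
  w
}

#' Current through an Ohmic channel
#'
#' `I = G (v - E_X)`, split per ion according to the element's weights, and
#' scaled by the cell count. Positive current carries positive charge from the
#' intracellular to the extracellular (reference) side.
#'
#' @param element a conductance-type [transport_element()].
#' @param v membrane potential (mV).
#' @param e_rev reversal potential(s): either one value shared by all permeant
#'   ions or a named vector per ion (mV).
#' @return named per-ion currents (nA) over `K`, `Na`, `Cl`.
#' @export
ohmic_channel_current <- function(element, v, e_rev) {
  if (!element$kind %in% LW_OHMIC_KINDS) {
    stop(sprintf("element kind '%s' is not a conductance", element$kind),
         call. = FALSE)
  }
  w <- .ion_weights(element)
  g_uS <- element$magnitude * element$n_cells / 1000  # nS -> uS
  e <- c(K = 0, Na = 0, Cl = 0)
  if (is.null(names(e_rev))) e[] <- e_rev else e[names(e_rev)] <- e_rev
  w * g_uS * (v - e)
}

#' Mechanoelectrical transduction (MET) current
#'
#' The resting K+ current through the hair-bundle MET channels, proportional
#' to the driving force across the hair-cell apical membrane:
#' `I_MET = G_MET (v_HA - (RT/F) ln([K+]_EL / [K+]_HC))`.
#' With the apical potential `v_HA = v_HB - EP` far below the K+ equilibrium
#' term, the current is inward (negative in the intracellular-to-extracellular
#' convention); the loop-oriented circulation current is `I_Cir = -I_MET`.
#'
#' @param g_met summed MET conductance of all hair cells in the slice (nS).
#' @param v_ha hair-cell apical membrane potential (mV).
#' @param conc_el_k endolymph K+ (mM).
#' @param conc_hc_k hair-cell K+ (mM).
#' @param constants output of [physical_constants()].
#' @return MET current in nA (intracellular-to-extracellular positive).
#' @export
met_current <- function(g_met, v_ha, conc_el_k, conc_hc_k,
                        constants = physical_constants()) {
  if (!is.finite(conc_el_k) || conc_el_k <= 0 ||
      !is.finite(conc_hc_k) || conc_hc_k <= 0) {
    stop("non-positive K+ concentration for the MET channel (endolymph/hair cell)",
         call. = FALSE)
  }
  (g_met / 1000) * (v_ha - constants$rtf_mv * log(conc_el_k / conc_hc_k))
}

#' Na+,K+-ATPase current
#'
#' Saturable pump flux with fixed 3 Na+ : 2 K+ stoichiometry (net one positive
#' charge extruded per cycle). The cycle rate is Michaelis-Menten in
#' intracellular Na+ and extracellular K+ and voltage-independent:
#' `p = p_max (Na_in/(Na_in+Km_Na))^3 (K_out/(K_out+Km_K))^2 (1 - block)`.
#' The Na+ component (+3p) is outward, the K+ component (-2p) inward.
#'
#' @param element a `nak_atpase` [transport_element()]; `magnitude` is the
#'   per-cell maximal cycle current `p_max` in nA.
#' @param v membrane potential (mV); unused by this kinetic form, kept for the
#'   common transporter signature.
#' @param substrate_concs named list/vector with `na_in` and `k_out` (mM).
#' @param block_fraction fraction of pump activity blocked, in `[0, 1]`.
#' @return named per-ion currents (nA).
#' @export
nak_atpase_current <- function(element, v, substrate_concs, block_fraction = 0) {
  if (element$kind != "nak_atpase") stop("element is not a nak_atpase", call. = FALSE)
  if (!is.numeric(block_fraction) || block_fraction < 0 || block_fraction > 1) {
    stop("block_fraction must lie in [0, 1]", call. = FALSE)
  }
  na_in <- substrate_concs[["na_in"]]
  k_out <- substrate_concs[["k_out"]]
  if (na_in < 0 || k_out < 0) stop("pump substrate concentrations must be >= 0",
                                   call. = FALSE)
  pr <- element$params
  p <- element$magnitude * element$n_cells * (1 - block_fraction) *
    (na_in / (na_in + pr$km_na_mM))^pr$hill_na *
    (k_out / (k_out + pr$km_k_mM))^pr$hill_k
  c(K = -2 * p, Na = 3 * p, Cl = 0)
}

#' Current through a secondary transporter or conductance element
#'
#' Generic dispatcher for the non-pump elements: Ohmic kinds (plain channels,
#' leak, nonselective cation conductance, ClC-type Cl- channels, MET) evaluate
#' `g_X (v - E_X)` per permeant ion with Nernstian reversal from the adjacent
#' concentrations; `na_transporter` and `cl_transporter` are saturable uptake
#' fluxes of the extracellular substrate. Per-ion components always sum to the
#' element's net current.
#'
#' @param element a [transport_element()].
#' @param v membrane potential (mV).
#' @param conc_in,conc_out named concentration vectors over `K`, `Na`, `Cl`
#'   (mM) on the intracellular / extracellular side.
#' @param constants output of [physical_constants()].
#' @param activity multiplier in `[0, 1]`, `1 - block_fraction`; applied to
#'   transporter turnover (and pump activity when dispatched here).
#' @return named per-ion currents (nA), intracellular-to-extracellular positive.
#' @export
transporter_current <- function(element, v, conc_in, conc_out,
                                constants = physical_constants(), activity = 1) {
  kind <- element$kind
  tot <- element$magnitude * element$n_cells
  zero <- c(K = 0, Na = 0, Cl = 0)
  if (kind %in% LW_OHMIC_KINDS) {
    w <- .ion_weights(element)
    e <- zero
    for (ion in names(LW_IONS)[w > 0]) {
      e[ion] <- nernst_potential(ion, conc_out[[ion]], conc_in[[ion]], constants,
                                 where = element$label)
    }
    return(w * (tot / 1000) * (v - e))
  }
  if (kind == "nak_atpase") {
    return(nak_atpase_current(element, v,
                              c(na_in = conc_in[["Na"]], k_out = conc_out[["K"]]),
                              block_fraction = 1 - activity))
  }
  if (kind == "na_transporter") {
    # electrogenic Na+ uptake from the extracellular side (inward current)
    s <- conc_out[["Na"]]
    if (s < 0) stop("negative Na+ substrate concentration", call. = FALSE)
    out <- zero
    out["Na"] <- -tot * activity * s / (s + element$params$km_mM)
    return(out)
  }
  if (kind == "cl_transporter") {
    # Cl- uptake: anion inward flux is an outward-positive conventional current
    s <- conc_out[["Cl"]]
    if (s < 0) stop("negative Cl- substrate concentration", call. = FALSE)
    out <- zero
    out["Cl"] <- tot * activity * s / (s + element$params$km_mM)
    return(out)
  }
  stop(sprintf("unknown element kind '%s'", kind), call. = FALSE)
}

#' Per-ion currents of any element
#'
#' Thin wrapper used by the ODE right-hand side: routes every element kind
#' through its flux law with a single signature.
#'
#' @inheritParams transporter_current
#' @return named per-ion currents (nA).
#' @export
element_currents <- function(element, v, conc_in, conc_out,
                             constants = physical_constants(), activity = 1) {
  transporter_current(element, v, conc_in, conc_out, constants, activity)
}
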