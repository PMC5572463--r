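# Model assembly: compartments, membrane domains and the compiled flux network.
#
# Topology (fixed): the circulation current flows around the closed loop
#   endolymph -(HA)-> hair cell -(HB)-> perilymph -(SB)-> syncytium
#   -(SA)-> intrastrial space -(MB)-> marginal cell -(MA)-> endolymph.
# Membrane potentials are intracellular minus adjacent extracellular.
# Crossing a membrane in the loop direction, the potential changes by +v on
# the "into-cell" membranes (HA, SB, MB) and by -v on the "out-of-cell"
# membranes (HB, SA, MA); summing the jumps around the loop gives
# EP = v_SB - v_SA + v_MB - v_MA and the constraint v_HA = v_HB - EP, so v_HA
# is derived, never stored. With I_Cir positive in the loop direction and
# element currents positive intracellular-to-extracellular, the steady state
# satisfies I_m = sigma_m I_Cir with sigma = +1 (HB, SA, MA) / -1 (SB, MB);
# at SB this is literally "sum of SB element currents = -I_Cir".

LW_MEMBRANES <- c("SB", "SA", "MB", "MA", "HB", "HA")
LW_SIGMA <- c(SB = -1, SA = 1, MB = -1, MA = 1, HB = 1)
LW_COMPARTMENT_IDS <- c("perilymph_ST", "perilymph_SV", "endolymph",
                        "intrastrial_space", "syncytium", "marginal_cell",
                        "hair_cell")

#' Assemble a lateral-wall model from a configuration
#'
#' Validates the configuration (see [load_config()] for the schema), builds
#' the compartment/membrane objects and compiles the flux network into the
#' fast form used by the ODE right-hand side.
#'
#' @param config a configuration list, e.g. from [load_config()] or
#'   [reference_config()].
#' @return object of class `lw_model`.
#' @export
lateral_wall_model <- function(config) {
  validate_config(config)
  constants <- physical_constants(config$constants$T)
  # trust but record R/F if overridden: only T is tunable
  compartments <- list()
  for (cp in config$compartments) {
    compartments[[cp$id]] <- list(
      id = cp$id, volume = cp$volume_l, dynamic = isTRUE(cp$dynamic),
      conc = c(K = cp$conc$K, Na = cp$conc$Na, Cl = cp$conc$Cl))
  }
  membranes <- list()
  for (mb in config$membranes) {
    els <- lapply(mb$elements, function(e) {
      transport_element(kind = e$kind, magnitude = e$magnitude,
                        n_cells = if (is.null(e$n_cells)) 1L else e$n_cells,
                        ions = if (is.null(e$ions)) NULL else unlist(e$ions),
                        params = if (is.null(e$params)) list() else e$params,
                        label = if (is.null(e$label)) e$kind else e$label,
                        provenance = if (is.null(e$provenance)) "unspecified"
                                     else e$provenance)
    })
    membranes[[mb$id]] <- list(id = mb$id, inner = mb$inner, outer = mb$outer,
                               capacitance_nf = mb$capacitance_nf,
                               potential_mv = mb$potential_mv, elements = els)
  }
  membranes <- membranes[LW_MEMBRANES]
  model <- structure(list(config = config, constants = constants,
                          compartments = compartments, membranes = membranes),
                     class = "lw_model")
  model$cm <- .compile_model(model)
  model
}

#' @export
print.lw_model <- function(x, ...) {
  cat("<lw_model>", x$config$name, "\n")
  cat(sprintf("  %d compartments, %d membranes, %d transport elements\n",
              length(x$compartments), length(x$membranes),
              length(x$cm$els)))
  cat(sprintf("  state vector: %d potentials + %d concentrations\n",
              x$cm$n_v, length(x$cm$act_lin)))
  invisible(x)
}

# ---- compilation ------------------------------------------------------------

.compile_model <- function(model) {
  cm <- new.env(parent = emptyenv())
  comp_ids <- names(model$compartments)
  nc <- length(comp_ids)
  cm$comp_ids <- comp_ids
  cm$vol <- vapply(model$compartments, `[[`, numeric(1), "volume")
  cm$dynamic <- vapply(model$compartments, `[[`, logical(1), "dynamic")
  conc0 <- vapply(model$compartments, `[[`, numeric(3), "conc")
  rownames(conc0) <- names(LW_IONS)
  cm$conc0 <- conc0
  cm$z <- as.numeric(LW_IONS)
  cm$Fc <- model$constants$F
  cm$rtf <- model$constants$rtf_mv
  cm$sigma <- as.numeric(LW_SIGMA)
  cm$cap5 <- vapply(model$membranes[names(LW_SIGMA)], `[[`, numeric(1),
                    "capacitance_nf")
  cm$mem_inner <- vapply(model$membranes[LW_MEMBRANES], function(m)
    match(m$inner, comp_ids), integer(1))
  cm$mem_outer <- vapply(model$membranes[LW_MEMBRANES], function(m)
    match(m$outer, comp_ids), integer(1))
  cm$n_v <- 5L

  # flatten elements with integer codes for the hot path
  codes <- c(ohmic = 1L, nak = 2L, na_t = 3L, cl_t = 4L)
  els <- list(); carried <- matrix(FALSE, 3, nc, dimnames = dimnames(conc0))
  for (mi in seq_along(LW_MEMBRANES)) {
    mb <- model$membranes[[LW_MEMBRANES[mi]]]
    ii <- match(mb$inner, comp_ids); oi <- match(mb$outer, comp_ids)
    for (el in mb$elements) {
      w <- .ion_weights(el)
      rec <- list(mem = mi, inner = ii, outer = oi, label = el$label,
                  key = paste0(mb$id, "/", el$kind), kind = el$kind,
                  element = el)
      if (el$kind %in% LW_OHMIC_KINDS) {
        rec$code <- codes[["ohmic"]]
        rec$g <- w * el$magnitude * el$n_cells / 1000  # uS per ion
      } else if (el$kind == "nak_atpase") {
        rec$code <- codes[["nak"]]
        rec$pmax <- el$magnitude * el$n_cells
        rec$km_na <- el$params$km_na_mM; rec$km_k <- el$params$km_k_mM
        rec$hna <- el$params$hill_na; rec$hk <- el$params$hill_k
      } else if (el$kind == "na_transporter") {
        rec$code <- codes[["na_t"]]
        rec$umax <- el$magnitude * el$n_cells; rec$km <- el$params$km_mM
      } else {
        rec$code <- codes[["cl_t"]]
        rec$umax <- el$magnitude * el$n_cells; rec$km <- el$params$km_mM
      }
      els[[length(els) + 1L]] <- rec
      for (ion in which(w > 0)) {
        carried[ion, ii] <- TRUE; carried[ion, oi] <- TRUE
      }
    }
  }
  cm$els <- els
  # a concentration is a state variable iff its compartment is dynamic and at
  # least one element on a bounding membrane carries the ion
  act <- carried & rep(cm$dynamic, each = 3)
  cm$act_lin <- which(act)
  ion_names <- rownames(conc0)[((cm$act_lin - 1) %% 3) + 1]
  comp_names <- comp_ids[((cm$act_lin - 1) %/% 3) + 1]
  cm$state_names <- c(paste0("v_", names(LW_SIGMA)),
                      paste0(ion_names, "_", comp_names))
  cm$act_ion <- ((cm$act_lin - 1) %% 3) + 1
  cm$act_comp <- ((cm$act_lin - 1) %/% 3) + 1
  cm$carried <- carried
  cm
}

#' Initial state vector of a model
#'
#' Potentials and active concentrations as stored in the configuration
#' (the measured/calibrated operating point of the bundled fixture).
#'
#' @param model an `lw_model`.
#' @return named numeric state vector.
#' @export
initial_state <- function(model) {
  cm <- model$cm
  v <- vapply(model$membranes[names(LW_SIGMA)], `[[`, numeric(1), "potential_mv")
  y <- c(v, cm$conc0[cm$act_lin])
  names(y) <- cm$state_names
  y
}

# ---- right-hand side core ---------------------------------------------------

# Per-element per-ion currents at a given full concentration matrix.
# Returns 3 x n_elements matrix (rows K, Na, Cl), nA, intra->extra positive.
.element_current_matrix <- function(cm, vmem, conc, factors) {
  ne <- length(cm$els)
  out <- matrix(0, 3, ne)
  rtf <- cm$rtf
  for (k in seq_len(ne)) {
    el <- cm$els[[k]]
    v <- vmem[el$mem]
    code <- el$code
    if (code == 1L) {              # ohmic family
      g <- el$g
      for (i in 1:3) {
        if (g[i] > 0) {
          e <- (rtf / cm$z[i]) * log(conc[i, el$outer] / conc[i, el$inner])
          out[i, k] <- g[i] * (v - e)
        }
      }
    } else if (code == 2L) {       # Na+,K+-ATPase
      na_in <- conc[2L, el$inner]; k_out <- conc[1L, el$outer]
      p <- el$pmax * factors[k] *
        (na_in / (na_in + el$km_na))^el$hna * (k_out / (k_out + el$km_k))^el$hk
      out[1L, k] <- -2 * p; out[2L, k] <- 3 * p
    } else if (code == 3L) {       # Na+ transporter (uptake)
      s <- conc[2L, el$outer]
      out[2L, k] <- -el$umax * factors[k] * s / (s + el$km)
    } else {                       # Cl- transporter (uptake)
      s <- conc[3L, el$outer]
      out[3L, k] <- el$umax * factors[k] * s / (s + el$km)
    }
  }
  out
}

# Build the full concentration matrix and membrane-potential vector from y.
.unpack_state <- function(cm, y) {
  conc <- cm$conc0
  if (length(cm$act_lin)) conc[cm$act_lin] <- y[cm$n_v + seq_along(cm$act_lin)]
  v5 <- y[1:5]
  ep <- v5[1] - v5[2] + v5[3] - v5[4]
  vmem <- c(v5, v5[5] - ep)   # v_HA = v_HB - EP
  list(conc = conc, vmem = vmem, ep = ep)
}

# dy/dt given state y and per-element activity factors.
.rhs_core <- function(cm, y, factors) {
  up <- .unpack_state(cm, y)
  conc <- up$conc
  if (any(conc[cm$act_lin] <= 0)) {
    bad <- cm$state_names[cm$n_v + which(conc[cm$act_lin] <= 0)]
    stop(sprintf("non-positive concentration reached during integration: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cur <- .element_current_matrix(cm, up$vmem, conc, factors)
  # membrane totals and compartment accumulators
  im <- numeric(6)
  acc <- matrix(0, 3, length(cm$vol))
  for (k in seq_along(cm$els)) {
    el <- cm$els[[k]]
    ik <- cur[, k]
    im[el$mem] <- im[el$mem] + sum(ik)
    flux <- ik / cm$z                     # + means ion leaves the inner side
    acc[, el$inner] <- acc[, el$inner] - flux
    acc[, el$outer] <- acc[, el$outer] + flux
  }
  i_cir <- -im[6L]                        # loop-positive circulation current
  dv <- 1000 * (cm$sigma * i_cir - im[1:5]) / cm$cap5
  dconc <- acc * (1e-6 / cm$Fc) / rep(cm$vol, each = 3)
  dy <- c(dv, dconc[cm$act_lin])
  names(dy) <- cm$state_names
  dy
}

# ---- observables ------------------------------------------------------------

#' Derived observables of a state
#'
#' EP, ISP, the derived hair-cell apical potential and the circulation
#' current. EP and ISP are always derived from the membrane potentials
#' (EP = v_SB - v_SA + v_MB - v_MA; ISP = v_SB - v_SA), never stored.
#' `I_cir` is positive in the loop direction; `I_met` is the MET current in
#' the intracellular-to-extracellular convention (`I_met = -I_cir`), which is
#' also the sign in which the circulation current is usually plotted against
#' the basolateral syncytial membrane currents.
#'
#' @param model an `lw_model`.
#' @param y state vector.
#' @return list with `EP`, `ISP`, `v_HA`, `I_cir`, `I_met`, `potentials`,
#'   `concentrations`.
#' @export
system_state <- function(model, y) {
  cm <- model$cm
  up <- .unpack_state(cm, y)
  isp <- y[[1]] - y[[2]]
  # MET current from the HA membrane elements
  fac <- rep(1, length(cm$els))
  cur <- .element_current_matrix(cm, up$vmem, up$conc, fac)
  ha <- which(vapply(cm$els, function(e) e$mem == 6L, logical(1)))
  i_met <- sum(cur[, ha])
  list(EP = unname(up$ep), ISP = unname(isp), v_HA = unname(up$vmem[6]),
       I_cir = -i_met, I_met = i_met,
       potentials = stats::setNames(up$vmem, LW_MEMBRANES),
       concentrations = up$conc)
}

#' Per-membrane, per-element, per-ion flux breakdown
#'
#' Evaluates every element's flux law at a state and returns the complete
#' current table, with per-membrane totals and the loop current attached.
#'
#' @param model an `lw_model`.
#' @param y state vector.
#' @param factors optional per-element activity multipliers (named by
#'   `membrane/kind` keys), e.g. `c("SB/nak_atpase" = 0.46)`.
#' @return data.frame of class `lw_fluxes` with columns `membrane`, `element`,
#'   `ion`, `current_nA`; attributes `per_membrane_total` (named over the six
#'   membranes), `net_per_ion` (3 x 6 matrix) and `I_cir`.
#' @export
flux_breakdown <- function(model, y, factors = NULL) {
  cm <- model$cm
  fac <- .factor_vector(cm, factors)
  up <- .unpack_state(cm, y)
  cur <- .element_current_matrix(cm, up$vmem, up$conc, fac)
  ne <- length(cm$els)
  mem <- vapply(cm$els, function(e) LW_MEMBRANES[e$mem], character(1))
  lab <- vapply(cm$els, `[[`, character(1), "label")
  df <- data.frame(
    membrane = rep(mem, each = 3),
    element = rep(lab, each = 3),
    ion = rep(names(LW_IONS), ne),
    current_nA = as.numeric(cur),
    stringsAsFactors = FALSE)
  tot <- vapply(LW_MEMBRANES, function(m) sum(cur[, mem == m, drop = FALSE]),
                numeric(1))
  npi <- vapply(LW_MEMBRANES, function(m)
    rowSums(cur[, mem == m, drop = FALSE]), numeric(3))
  attr(df, "per_membrane_total") <- tot
  attr(df, "net_per_ion") <- npi
  attr(df, "I_cir") <- -tot[["HA"]]
  class(df) <- c("lw_fluxes", "data.frame")
  df
}

#' Total current through one membrane domain
#'
#' Sums the per-element, per-ion currents of a membrane at a state; the total
#' equals the sum of its K+, Na+ and Cl- fractions by construction.
#'
#' @param model an `lw_model`.
#' @param membrane one of `"SB"`, `"SA"`, `"MB"`, `"MA"`, `"HB"`, `"HA"`.
#' @param y state vector.
#' @param factors optional per-element activity multipliers.
#' @return list with `total` (nA), `per_ion` (named over K/Na/Cl) and
#'   `elements` (the membrane's rows of the flux table).
#' @export
membrane_total_current <- function(model, membrane, y, factors = NULL) {
  membrane <- match.arg(membrane, LW_MEMBRANES)
  fb <- flux_breakdown(model, y, factors)
  rows <- fb[fb$membrane == membrane, , drop = FALSE]
  per_ion <- vapply(names(LW_IONS),
                    function(i) sum(rows$current_nA[rows$ion == i]), numeric(1))
  list(total = sum(rows$current_nA), per_ion = per_ion, elements = rows)
}

# expand named factors ("SB/nak_atpase" = 0.46) to the per-element vector
.factor_vector <- function(cm, factors) {
  fac <- rep(1, length(cm$els))
  if (is.null(factors)) return(fac)
  keys <- vapply(cm$els, `[[`, character(1), "key")
  for (nm in names(factors)) {
    hit <- keys == nm
    if (!any(hit)) stop(sprintf("no element matches perturbation target '%s'", nm),
                        call. = FALSE)
    fac[hit] <- factors[[nm]]
  }
  fac
}

#' Total ion content per species
#'
#' `sum_c V_c [X]_c` over all compartments (mol); conserved along
#' trajectories when, as in the reference model, every flux moves ions
#' between two dynamic compartments.
#'
#' @param model an `lw_model`.
#' @param y state vector.
#' @return named numeric vector (mol) over K, Na, Cl.
#' @export
total_moles <- function(model, y) {
  cm <- model$cm
  conc <- .unpack_state(cm, y)$conc
  # mM * L = umol; report mol
  rowSums(conc * rep(cm$vol, each = 3)) * 1e-3
}
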