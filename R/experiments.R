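# Scripted experiments: normal steady state, pump blockade, kappa scan.
# Every report carries the configuration hash and solver settings, names the
# reference location of each compared value, and computes pass/fail only
# from the declared tolerances.

#' Reference values used for validation
#'
#' Single place holding the published validation numbers the simulations are
#' compared against: the simulated-column steady-state observables (normal
#' and pump-block conditions), the blockade time constants, the
#' circulation-current plateau, and the experimental mean +/- SD ranges used
#' by the kappa scan. Each entry names its location label so reports can
#' cite it.
#'
#' @return list with `normal`, `block`, `taus`, `i_cir_plateau`,
#'   `control_ranges`, `ouabain_ranges`.
#' @export
reference_values <- function() {
  list(
    normal = data.frame(
      observable = c("EP", "v_SB", "K_SY", "ISP", "K_IS"),
      value = c(72.7, 9.6, 98.3, 81.2, 6.1),
      unit = c("mV", "mV", "mM", "mV", "mM"),
      location = "validation-table, simulated normal column",
      stringsAsFactors = FALSE),
    block = data.frame(
      observable = c("EP", "v_SB", "K_SY", "ISP", "K_IS"),
      value = c(9.6, -3.0, 10.4, 15.1, 4.7),
      unit = c("mV", "mV", "mM", "mV", "mM"),
      location = "validation-table, simulated block column (40 min)",
      stringsAsFactors = FALSE),
    taus = data.frame(
      observable = c("v_SB", "K_SY", "EP", "ISP", "K_IS", "i_cir_sb",
                     "leak_K", "na_conductance"),
      tau_s = c(240.0, 288.2, 454.4, 453.6, 454.1, 467.9, 89.2, 169.6),
      location = "results text, blockade kinetics",
      stringsAsFactors = FALSE),
    i_cir_plateau = -1.9,   # nA, SB-oriented circulation-current trace
    pump_na_band = c(2.5, 2.8),  # nA, outward pump Na+ current during blockade
    control_ranges = data.frame(
      observable = c("EP", "v_SB", "K_SY", "ISP", "K_IS"),
      mean = c(83.2, 9.9, 101.7, 68.7, 8.6),
      sd = c(3.6, 1.2, 15.1, 4.6, 2.5),
      stringsAsFactors = FALSE),
    ouabain_ranges = data.frame(
      observable = c("EP", "v_SB", "K_SY", "ISP", "K_IS"),
      mean = c(5.8, -6.2, 14.3, 10.6, 4.2),
      sd = c(6.2, 2.6, 1.5, 4.4, 1.4),
      stringsAsFactors = FALSE))
}

.observables_from_series <- function(series, row = nrow(series)) {
  c(EP = series$EP[row], v_SB = series$v_SB[row],
    K_SY = series$K_syncytium[row], ISP = series$ISP[row],
    K_IS = series$K_intrastrial_space[row])
}

.report <- function(scenario, observables_df, model, extra = list()) {
  structure(c(list(scenario = scenario, observables = observables_df,
                   config_hash = config_hash(model$config),
                   solver = list(method = "rosenbrock-23", rtol = 1e-8,
                                 atol = 1e-9)),
              extra), class = "lw_report")
}

#' @export
print.lw_report <- function(x, ...) {
  cat("<lw_report>", x$scenario, "\n")
  print(x$observables, row.names = FALSE, digits = 4)
  if (!is.null(x$taus)) { cat("time constants:\n"); print(x$taus, row.names = FALSE, digits = 4) }
  cat("config", substr(x$config_hash, 1, 8), "\n")
  invisible(x)
}

#' Normal-condition steady state
#'
#' Settles the reference (or supplied) model for `settle_s` seconds from its
#' stored initial values, cross-checks against the Newton steady state and
#' reports EP, v_SB, syncytial K+, ISP and intrastrial K+ against the
#' reference simulated values.
#'
#' @param model an `lw_model`.
#' @param settle_s settling time (s), default 600.
#' @param tolerance_mV_mM pass tolerance for potentials (mV) and
#'   concentrations (mM), default 0.5.
#' @return `lw_report` with fields `observables`, `series`, `steady_state`.
#' @export
run_normal_steady <- function(model, settle_s = 600, tolerance_mV_mM = 0.5) {
  series <- integrate_model(model, t_end = settle_s, dt_out = 1)
  obs <- .observables_from_series(series)
  ss <- find_steady_state(model)
  ref <- reference_values()$normal
  df <- data.frame(observable = ref$observable,
                   simulated = unname(obs[ref$observable]),
                   reference = ref$value, unit = ref$unit,
                   tolerance = tolerance_mV_mM,
                   pass = abs(unname(obs[ref$observable]) - ref$value) <= tolerance_mV_mM,
                   location = ref$location, stringsAsFactors = FALSE)
  .report("normal steady state", df, model,
          list(series = series, steady_state = ss))
}

#' Na+,K+-ATPase blockade scenario
#'
#' Settles for `t_settle`, then scales the syncytial basolateral pump
#' activity to `kappa` of normal and integrates for `t_block`. Reports the
#' five observables at 40 min after onset, the fitted time constants of
#' v_SB, [K+]_SY, EP, ISP, [K+]_IS, of the SB-oriented circulation current,
#' of the SB leak K+ current and of the SB Na+-conductance current, the
#' circulation-current plateau, and the outward pump Na+ current range over
#' the transient.
#'
#' @param model an `lw_model`.
#' @param kappa remaining-activity multiplier (0.46 reproduces the 10 uM
#'   ouabain condition).
#' @param t_settle,t_block segment durations (s).
#' @param tolerance_mV_mM pass tolerance for the absolute observables.
#' @param tau_tolerance relative pass tolerance for time constants.
#' @return `lw_report` with `observables`, `taus`, `i_cir_plateau`,
#'   `pump_na_range`, `series`, `onset`.
#' @export
run_ouabain_block <- function(model, kappa = 0.46, t_settle = 600,
                              t_block = 2400, tolerance_mV_mM = 0.5,
                              tau_tolerance = 0.10) {
  pert <- perturbation("SB/nak_atpase", kappa, onset = t_settle)
  series <- integrate_model(model, t_end = t_settle + t_block,
                            perturbations = pert, dt_out = 1)
  obs <- .observables_from_series(series)
  ref <- reference_values()
  df <- data.frame(observable = ref$block$observable,
                   simulated = unname(obs[ref$block$observable]),
                   reference = ref$block$value, unit = ref$block$unit,
                   tolerance = tolerance_mV_mM,
                   pass = abs(unname(obs[ref$block$observable]) - ref$block$value) <= tolerance_mV_mM,
                   location = ref$block$location, stringsAsFactors = FALSE)

  window <- c(t_settle, t_settle + t_block)
  # a null perturbation leaves traces constant; report NA rather than failing
  fit_of <- function(vals) {
    tryCatch(fit_time_constant(series, values = vals, window = window),
             error = function(e) list(tau = NA_real_))
  }
  # SB element current traces for the flux-resolved time constants
  dec <- flux_decomposition(model, series)
  sb_trace <- function(label, ion) {
    sel <- dec$membrane == "SB" & dec$element == label & dec$ion == ion
    dec$current_nA[sel]
  }
  i_cir_sb <- -series$I_cir
  traces <- list(
    v_SB = series$v_SB, K_SY = series$K_syncytium, EP = series$EP,
    ISP = series$ISP, K_IS = series$K_intrastrial_space,
    i_cir_sb = i_cir_sb,
    leak_K = sb_trace("leak", "K"),
    na_conductance = sb_trace("na_conductance", "Na"))
  taus <- vapply(names(traces), function(nm) fit_of(traces[[nm]])$tau, numeric(1))
  tau_ref <- ref$taus
  tau_df <- data.frame(observable = tau_ref$observable,
                       tau_s = unname(taus[tau_ref$observable]),
                       reference_s = tau_ref$tau_s,
                       tolerance = tau_tolerance,
                       pass = abs(unname(taus[tau_ref$observable]) - tau_ref$tau_s) <=
                         tau_tolerance * tau_ref$tau_s,
                       location = tau_ref$location, stringsAsFactors = FALSE)
  pump_na <- sb_trace("nak_atpase", "Na")
  after <- series$time_s >= t_settle
  .report(sprintf("pump blockade, kappa = %.2f", kappa), df, model,
          list(taus = tau_df,
               i_cir_plateau = i_cir_sb[length(i_cir_sb)],
               pump_na_range = range(pump_na[after]),
               series = series, onset = t_settle))
}

#' Blocking-rate scan
#'
#' Runs [estimate_blocking_rate()] over the kappa grid and wraps the per-
#' kappa observable table and the selected kappa in a report.
#'
#' @param model an `lw_model`.
#' @param kappa_grid grid of remaining-activity multipliers.
#' @param ranges experimental acceptance ranges (default: bundled ouabain
#'   mean +/- SD).
#' @param t_eval evaluation time after onset (s).
#' @return `lw_report` with `scan` (the `lw_kappascan`), `kappa`.
#' @export
run_kappa_scan <- function(model, kappa_grid = seq(0.30, 0.60, by = 0.01),
                           ranges = NULL, t_eval = 2400) {
  scan <- estimate_blocking_rate(model, kappa_grid, ranges, t_eval = t_eval)
  df <- data.frame(observable = "selected_kappa", simulated = scan$kappa,
                   reference = 0.46, unit = "", tolerance = 0,
                   pass = scan$kappa == 0.46,
                   location = "blocking-rate estimation section",
                   stringsAsFactors = FALSE)
  .report("kappa scan", df, model, list(scan = scan, kappa = scan$kappa))
}
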