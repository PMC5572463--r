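# Calibration: determine under-constrained parameters from measured
# steady-state data.
#
# At the measured operating point every flux law is linear in its magnitude,
# so steady-state balance equations become linear systems in the unknown
# conductances/activities. For the syncytial basolateral surface (SB) the
# reported balance system is rank-deficient: the charge balance
# (pump + Na conductance + leak = -I_Cir) is identically the sum of the K+
# balance and the Na+-recycling condition once the net apical K+ current
# equals I_Cir. A closure is therefore required; this implementation fixes
# the ratio of Na+ conductance to leak conductance (default 5, "Na+
# conductance significantly exceeds leak") and splits the leak equally
# between its K+ and Na+ partial conductances.

#' Solve the SB parameter triple from a measured steady state
#'
#' Determines the Na+,K+-ATPase activity, Na+ conductance and leak
#' conductance of the syncytial basolateral surface from the measured
#' membrane potential, adjacent concentrations and loop current, by solving
#' the K+ balance (pump K+ uptake + leak K+ efflux feeds the apical K+
#' current) and the local Na+-recycling condition (zero net Na+ flux across
#' SB) together with the conductance-ratio closure. The redundant total
#' charge balance is evaluated as a consistency residual.
#'
#' @param measured list with `v_SB` (mV), `conc_SY` and `conc_PL` (named K/Na
#'   concentration vectors, mM), `I_cir` (loop current, nA) and optionally
#'   `I_K_net_SA` (net apical K+ current, nA; defaults to `I_cir`, their
#'   steady-state identity).
#' @param constants output of [physical_constants()].
#' @param na_leak_ratio closure ratio g_Na / g_leak (default 5).
#' @param leak_split fraction of the leak conductance assigned to K+
#'   (default 0.5, equal partial conductances).
#' @param pump_params kinetic constants used to convert the operating-point
#'   cycle current into the maximal pump activity.
#' @return list with `pump_rate` (operating-point cycle current, nA),
#'   `pump_max` (maximal activity, nA), `g_na`, `g_leak` (uS, totals for the
#'   whole membrane domain), and `residuals` (charge / K+ / Na+ balances, nA).
#' @export
solve_sb_parameters <- function(measured, constants = physical_constants(),
                                na_leak_ratio = 5, leak_split = 0.5,
                                pump_params = list(km_na_mM = 10, km_k_mM = 1.5,
                                                   hill_na = 0, hill_k = 2)) {
  v <- measured$v_SB
  csy <- measured$conc_SY; cpl <- measured$conc_PL
  i_cir <- measured$I_cir
  i_knet <- if (is.null(measured$I_K_net_SA)) i_cir else measured$I_K_net_SA
  dK <- v - nernst_potential("K", cpl[["K"]], csy[["K"]], constants, "SB")
  dNa <- v - nernst_potential("Na", cpl[["Na"]], csy[["Na"]], constants, "SB")
  wk <- leak_split; wn <- 1 - leak_split
  # unknowns x = (p, g_na, g_leak)
  A <- rbind(c(-2, 0, wk * dK),            # K+ balance (feeds apical current)
             c(3, dNa, wn * dNa),          # local Na+ recycling
             c(0, 1, -na_leak_ratio))      # closure
  b <- c(-i_knet, 0, 0)
  x <- tryCatch(solve(A, b), error = function(e)
    stop("singular SB calibration system; check the measured state", call. = FALSE))
  p <- x[1]; g_na <- x[2]; g_leak <- x[3]
  res <- c(charge = p + g_na * dNa + g_leak * (wk * dK + wn * dNa) + i_cir,
           K = -2 * p + g_leak * wk * dK + i_knet,
           Na = 3 * p + (g_na + g_leak * wn) * dNa)
  if (any(x < 0)) {
    nm <- c("pump activity", "Na+ conductance", "leak conductance")[x < 0]
    stop(sprintf("calibration produced negative %s", paste(nm, collapse = ", ")),
         call. = FALSE)
  }
  if (abs(res[["charge"]]) > 1e-8 * max(1, abs(i_cir))) {
    stop(sprintf(paste0("inconsistent SB calibration: charge-balance residual ",
                        "%.3g nA (net apical K+ current and loop current ",
                        "disagree)"), res[["charge"]]), call. = FALSE)
  }
  mm <- (csy[["Na"]] / (csy[["Na"]] + pump_params$km_na_mM))^pump_params$hill_na *
        (cpl[["K"]] / (cpl[["K"]] + pump_params$km_k_mM))^pump_params$hill_k
  list(pump_rate = p, pump_max = p / mm, g_na = g_na, g_leak = g_leak,
       residuals = res)
}

#' Cell counts from lateral-wall morphometry
#'
#' Converts measured tissue cross-section areas and cellular-area fractions
#' into the stria:ligament cellular ratio and the fibrocyte count, assuming
#' equal cell volumes across cell types (so cellular area ratios equal cell
#' number ratios in a fixed-thickness slice). The ratio is rounded to the
#' nearest integer before scaling the strial cell count, matching the
#' conventional 1:n bookkeeping of the source measurements.
#'
#' @param area_stria,area_ligament tissue areas (um^2), positive.
#' @param fraction_stria,fraction_ligament cellular-area proportions in (0, 1].
#' @param n_strial_cells number of strial cells per slice (marginal +
#'   intermediate), positive integer.
#' @return list with `raw_ratio` (unrounded ligament:stria cellular ratio),
#'   `tissue_ratio` (rounded integer) and `n_fibrocytes`.
#' @examples
#' morphometry_to_cell_counts(12107.1, 74353.8, 0.916, 0.423, 56)
#' @export
morphometry_to_cell_counts <- function(area_stria, area_ligament,
                                       fraction_stria, fraction_ligament,
                                       n_strial_cells) {
  if (area_stria <= 0 || area_ligament <= 0) {
    stop("tissue areas must be positive", call. = FALSE)
  }
  if (fraction_stria <= 0 || fraction_stria > 1 ||
      fraction_ligament <= 0 || fraction_ligament > 1) {
    stop("cellular fractions must lie in (0, 1]", call. = FALSE)
  }
  cell_stria <- area_stria * fraction_stria
  cell_lig <- area_ligament * fraction_ligament
  if (cell_stria == 0 || cell_lig == 0) stop("zero cellular area", call. = FALSE)
  raw <- cell_lig / cell_stria
  ratio <- round(raw)
  list(raw_ratio = raw, tissue_ratio = ratio,
       n_fibrocytes = as.integer(round(n_strial_cells * ratio)))
}

#' Estimate the pump blocking rate by scenario scanning
#'
#' Runs the blockade scenario over a grid of remaining-activity multipliers
#' kappa, records EP, v_SB, [K+]_SY, ISP and [K+]_IS at a fixed time after
#' onset (default 40 min) and returns the kappa at which all five simulated
#' observables fall within the experimental acceptance ranges (mean +/- SD).
#' If several kappa qualify, the one minimising the summed squared z-scores
#' against the range midpoints is returned (ties broken toward the smallest
#' kappa). Deterministic: same grid and ranges always give the same kappa.
#'
#' @param model an `lw_model`.
#' @param kappa_grid ascending grid of multipliers in `[0, 1]`.
#' @param ranges data.frame with columns `observable` (over `EP`, `v_SB`,
#'   `K_SY`, `ISP`, `K_IS`), `mean`, `sd`; `sd = Inf` makes a range
#'   unconstraining. Defaults to the bundled experimental ouabain ranges.
#' @param t_eval evaluation time after blockade onset (s), default 2400.
#' @param state0 initial (normal steady) state; computed if `NULL`.
#' @param dt_out trajectory sampling used during the scan (s).
#' @param must_qualify if `TRUE` (default) an error listing the per-
#'   observable nearest misses is raised when no kappa qualifies; if `FALSE`
#'   the scan table is returned with `kappa = NA`.
#' @param rtol,atol solver tolerances for the scan runs. Defaults are
#'   deliberately looser than the engine defaults (the scan integrates ~31
#'   blockade trajectories and the selection compares observables against
#'   ranges several mV/mM wide; the loosened tolerances move the 40-min
#'   observables by well under 0.001 units).
#' @return list of class `lw_kappascan`: `kappa` (selected), `table` (per-
#'   kappa observables, qualification flags, scores), `ranges`.
#' @export
estimate_blocking_rate <- function(model, kappa_grid = seq(0.30, 0.60, by = 0.01),
                                   ranges = NULL, t_eval = 2400, state0 = NULL,
                                   dt_out = 60, must_qualify = TRUE,
                                   rtol = 1e-6, atol = 1e-8) {
  if (is.unsorted(kappa_grid, strictly = FALSE)) {
    stop("kappa_grid must be sorted ascending", call. = FALSE)
  }
  if (is.null(ranges)) ranges <- reference_values()$ouabain_ranges
  need <- c("EP", "v_SB", "K_SY", "ISP", "K_IS")
  if (!all(need %in% ranges$observable)) {
    stop("acceptance ranges must cover EP, v_SB, K_SY, ISP, K_IS", call. = FALSE)
  }
  if (is.null(state0)) state0 <- find_steady_state(model)
  rows <- vector("list", length(kappa_grid))
  for (i in seq_along(kappa_grid)) {
    k <- kappa_grid[i]
    ser <- integrate_model(model, t_end = t_eval,
                           perturbations = perturbation("SB/nak_atpase", k, 0),
                           state0 = state0, dt_out = dt_out,
                           rtol = rtol, atol = atol)
    last <- nrow(ser)
    rows[[i]] <- data.frame(kappa = k, EP = ser$EP[last], v_SB = ser$v_SB[last],
                            K_SY = ser$K_syncytium[last], ISP = ser$ISP[last],
                            K_IS = ser$K_intrastrial_space[last])
  }
  tab <- do.call(rbind, rows)
  ok <- rep(TRUE, nrow(tab)); score <- numeric(nrow(tab))
  for (j in seq_len(nrow(ranges))) {
    obs <- ranges$observable[j]; m <- ranges$mean[j]; s <- ranges$sd[j]
    vals <- tab[[obs]]
    if (is.finite(s)) {
      ok <- ok & vals >= m - s & vals <= m + s
      score <- score + ((vals - m) / s)^2
    }
  }
  tab$qualifies <- ok
  tab$score <- score
  if (!any(ok)) {
    miss <- vapply(seq_len(nrow(ranges)), function(j) {
      obs <- ranges$observable[j]; m <- ranges$mean[j]; s <- ranges$sd[j]
      if (!is.finite(s)) return(sprintf("%s: unconstrained", obs))
      d <- pmax(abs(tab[[obs]] - m) - s, 0)
      sprintf("%s: nearest miss %.3g beyond range at kappa = %.2f",
              obs, min(d), tab$kappa[which.min(d)])
    }, character(1))
    if (must_qualify) {
      stop("no kappa satisfies all acceptance ranges;\n  ",
           paste(miss, collapse = "\n  "), call. = FALSE)
    }
    return(structure(list(kappa = NA_real_, table = tab, ranges = ranges),
                     class = "lw_kappascan"))
  }
  qi <- which(ok)
  sel <- qi[which.min(score[qi])]
  structure(list(kappa = tab$kappa[sel], table = tab, ranges = ranges),
            class = "lw_kappascan")
}

#' @export
print.lw_kappascan <- function(x, ...) {
  cat(sprintf("kappa scan over [%.2f, %.2f] (%d points): selected kappa = %.2f\n",
              min(x$table$kappa), max(x$table$kappa), nrow(x$table), x$kappa))
  invisible(x)
}
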