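# Integration, steady-state detection, tau fitting, decomposition.

test_that("assemble_rhs: capacitance scaling and domain errors", {
  m <- ref_model()
  y <- initial_state(m)
  y["v_SB"] <- y["v_SB"] + 5    # off the fixed point
  dy1 <- assemble_rhs(m)(y)
  cfg2 <- reference_config()
  for (i in seq_along(cfg2$membranes)) {
    cfg2$membranes[[i]]$capacitance_nf <- 2 * cfg2$membranes[[i]]$capacitance_nf
  }
  m2 <- lateral_wall_model(cfg2)
  dy2 <- assemble_rhs(m2)(y)
  # doubling every capacitance halves every dv/dt at fixed currents,
  # and leaves concentration derivatives untouched
  expect_equal(dy2[1:5], dy1[1:5] / 2)
  expect_equal(dy2[-(1:5)], dy1[-(1:5)])
  ybad <- initial_state(m); ybad["K_syncytium"] <- -1
  expect_error(assemble_rhs(m)(ybad), "non-positive concentration.*K_syncytium")
})

test_that("integrating from the calibrated steady state does not drift", {
  m <- ref_model()
  ser <- integrate_model(m, t_end = 600, dt_out = 10)
  last <- nrow(ser)
  expect_lt(abs(ser$EP[last] - ser$EP[1]), 0.1)
  expect_lt(abs(ser$v_SB[last] - ser$v_SB[1]), 0.1)
  expect_lt(abs(ser$K_syncytium[last] - ser$K_syncytium[1]), 0.1)
  expect_lt(abs(ser$K_intrastrial_space[last] - ser$K_intrastrial_space[1]), 0.1)
  expect_error(integrate_model(m, t_end = -5), "positive")
})

test_that("integration is deterministic", {
  m <- ref_model()
  p <- perturbation("SB/nak_atpase", 0.46, onset = 20)
  a <- integrate_model(m, 60, perturbations = p, dt_out = 5)
  b <- integrate_model(m, 60, perturbations = p, dt_out = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("perturbation validation", {
  expect_error(perturbation("SB/nak_atpase", 1.2, 0), "factor")
  expect_error(perturbation("SB/nak_atpase", 0.5, 10, offset = 5), "onset")
  m <- ref_model()
  expect_error(
    integrate_model(m, 10, perturbations = perturbation("SB/nowhere", 0.5, 1)),
    "no element matches")
})

test_that("stored trajectories satisfy the potential identities", {
  ser <- ref_block()$series
  expect_equal(ser$EP, ser$v_SB - ser$v_SA + ser$v_MB - ser$v_MA)
  expect_equal(ser$ISP, ser$v_SB - ser$v_SA)
  expect_equal(ser$v_HA, ser$v_HB - ser$EP)
  expect_true(all(diff(ser$time_s) > 0))
})

test_that("ion moles are conserved along the blockade trajectory", {
  m <- ref_model()
  states <- attr(ref_block()$series, "states")
  t0 <- total_moles(m, states[1, ])
  for (i in c(50, 500, 1500, nrow(states))) {
    ti <- total_moles(m, states[i, ])
    expect_lt(max(abs(ti - t0) / t0), 1e-10)
  }
})

test_that("root-finding and long integration agree on the steady state", {
  # fast-settling variant (small cellular volumes) so 600 s is >> every tau
  fm <- fast_model()
  pert <- c("SB/nak_atpase" = 0.9)
  y0 <- initial_state(fm)
  ser <- integrate_model(fm, 600, perturbations = perturbation("SB/nak_atpase", 0.9, 0),
                         dt_out = 50)
  y_int <- attr(ser, "states")[nrow(ser), ]
  y_newton <- find_steady_state(fm, state0 = y0, factors = pert)
  expect_equal(unname(y_newton[names(y0)]), unname(y_int), tolerance = 1e-6)
  expect_rhs_zero(fm, y_newton, factors = pert)
})

test_that("find_steady_state refuses unbalanced states and honours invariants", {
  m <- ref_model()
  y0 <- initial_state(m)
  ss <- find_steady_state(m)
  expect_equal(unname(ss[names(y0)]), unname(y0), tolerance = 1e-9)
  # conservation: the returned state keeps the guess's ion totals
  y1 <- y0; y1["K_syncytium"] <- 90; y1["Na_syncytium"] <- 18.3
  ss1 <- find_steady_state(m, state0 = y1)
  expect_equal(total_moles(m, ss1), total_moles(m, y1), tolerance = 1e-9)
  expect_rhs_zero(m, ss1)
})

test_that("fit_time_constant recovers exact exponentials and flags degeneracy", {
  tt <- seq(0, 1000, by = 1)
  y <- 5 * exp(-tt / 100) + 2
  fit <- fit_time_constant(tt, values = y, window = c(0, 1000))
  expect_equal(fit$tau, 100, tolerance = 1e-6)
  expect_equal(fit$asymptote, 2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 5, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  # negative amplitudes (rising traces) work too
  fit2 <- fit_time_constant(tt, values = -3 * exp(-tt / 250) + 7,
                            window = c(0, 1000))
  expect_equal(fit2$tau, 250, tolerance = 1e-6)
  expect_error(fit_time_constant(tt, values = rep(1, length(tt)),
                                 window = c(0, 1000)), "degenerate")
  expect_error(fit_time_constant(tt[1:5], values = y[1:5], window = c(0, 4)),
               "at least 10 samples")
  # rmse is reported for non-exponential traces rather than failing
  fit3 <- fit_time_constant(tt, values = 5 * exp(-tt / 100) + 0.5 * sin(tt / 30) + 2,
                            window = c(0, 1000))
  expect_gt(fit3$rmse, 0.1)
})

test_that("flux decomposition: bookkeeping and the SB Na+ transient", {
  m <- ref_model()
  rep <- ref_block()
  dec <- flux_decomposition(m, rep$series)
  tot <- attr(dec, "per_membrane_total")
  # per-ion sums reconstruct each membrane total at sampled times
  for (i in c(1, 601, 1500, 3001)) {
    sub <- dec[dec$time_s == rep$series$time_s[i], ]
    for (mem in unique(sub$membrane)) {
      expect_equal(sum(sub$current_nA[sub$membrane == mem]), unname(tot[i, mem]),
                   tolerance = 1e-9)
    }
  }
  # net SB Na+ current: zero at rest, a transient inflow after onset,
  # vanishing again at the blocked steady state
  na_sb <- with(dec[dec$membrane == "SB" & dec$ion == "Na", ],
                tapply(current_nA, time_s, sum))
  tt <- as.numeric(names(na_sb))
  expect_lt(abs(na_sb[tt == 0]), 1e-9)
  expect_lt(min(na_sb[tt > 600 & tt < 1200]), -0.2)   # inward transient
  y_blocked <- find_steady_state(m, state0 = attr(rep$series, "states")[3001, ],
                                 factors = c("SB/nak_atpase" = 0.46))
  fb <- flux_breakdown(m, y_blocked, factors = c("SB/nak_atpase" = 0.46))
  na_net <- sum(fb$current_nA[fb$membrane == "SB" & fb$ion == "Na"])
  expect_lt(abs(na_net), 1e-8)
})

test_that("ISP consistency trace is returned with its differences", {
  m <- ref_model()
  ic <- isp_consistency(m, ref_block()$series)
  expect_named(ic, c("time_s", "ISP_direct", "ISP_approx", "difference"))
  expect_equal(ic$difference, ic$ISP_direct - ic$ISP_approx)
  expect_equal(attr(ic, "max_abs_difference"), max(abs(ic$difference)))
})
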