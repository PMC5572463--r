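# Flux laws and model-core invariants.

test_that("nernst_potential: closed form, antisymmetry, valence", {
  ct <- physical_constants()
  # equal concentrations are at equilibrium
  expect_equal(nernst_potential("K", 10, 10), 0)
  # independent closed-form evaluation at the normal intrastrial/syncytial K+
  rtf <- 1000 * 8.314462618 * 310.15 / 96485.33212
  expect_equal(nernst_potential("K", 6.1, 98.3, ct), rtf * log(6.1 / 98.3))
  expect_equal(nernst_potential("K", 6.1, 98.3, ct), -74.294, tolerance = 1e-4)
  # Cl- flips sign at the same ratio
  expect_equal(nernst_potential("Cl", 6.1, 98.3, ct),
               -nernst_potential("K", 6.1, 98.3, ct))
  # antisymmetry under swapping sides, across random ratios
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.5, 200); b <- runif(1, 0.5, 200)
    ion <- sample(c("K", "Na", "Cl"), 1)
    expect_equal(nernst_potential(ion, a, b), -nernst_potential(ion, b, a))
  }
  expect_error(nernst_potential("K", -1, 10, where = "syncytium"),
               "non-positive K.*syncytium")
  expect_error(nernst_potential("Na", 5, 0), "non-positive Na")
})

test_that("ohmic channels: reversal, unit arithmetic, linearity", {
  el <- transport_element("ohmic_channel", magnitude = 1, n_cells = 1,
                          ions = c(K = 1))
  expect_equal(sum(ohmic_channel_current(el, v = -30, e_rev = -30)), 0)
  # 1 nS across 10 mV is 0.01 nA
  expect_equal(unname(ohmic_channel_current(el, 0, -10)[["K"]]), 0.01)
  el2 <- transport_element("ohmic_channel", magnitude = 2, n_cells = 1,
                           ions = c(K = 1))
  expect_equal(ohmic_channel_current(el2, 0, -10), 2 * ohmic_channel_current(el, 0, -10))
  # cell-count scaling is equivalent to magnitude scaling
  el3 <- transport_element("ohmic_channel", magnitude = 1, n_cells = 2,
                           ions = c(K = 1))
  expect_equal(ohmic_channel_current(el3, 0, -10), ohmic_channel_current(el2, 0, -10))
  expect_error(ohmic_channel_current(
    transport_element("nak_atpase", 1), 0, 0), "not a conductance")
})

test_that("MET current: zero driving force, linearity, resting magnitude", {
  ct <- physical_constants()
  e_term <- ct$rtf_mv * log(150 / 140)
  expect_equal(met_current(24, e_term, 150, 140, ct), 0)
  i1 <- met_current(10, -120, 150, 140, ct)
  expect_equal(met_current(5, -120, 150, 140, ct), i1 / 2)
  expect_error(met_current(10, -120, 0, 140, ct), "non-positive")
  # the reference fixture carries ~1 nA inward per hair cell (3 nA per slice)
  m <- ref_model()
  st <- system_state(m, initial_state(m))
  expect_equal(st$I_met, -3, tolerance = 1e-9)
  expect_equal(st$I_cir, 3, tolerance = 1e-9)
})

test_that("Na+,K+-ATPase: full block, 3:2 stoichiometry, monotone kinetics", {
  el <- transport_element("nak_atpase", magnitude = 2, n_cells = 3,
                          params = list(km_na_mM = 10, km_k_mM = 1.5,
                                        hill_na = 3, hill_k = 2))
  expect_equal(unname(nak_atpase_current(el, 0, c(na_in = 10, k_out = 5), 1)),
               c(0, 0, 0))
  set.seed(2)
  for (i in 1:25) {
    cc <- c(na_in = runif(1, 1, 150), k_out = runif(1, 0.5, 20))
    blk <- runif(1, 0, 0.95)
    iv <- nak_atpase_current(el, runif(1, -80, 20), cc, blk)
    expect_gt(iv[["Na"]], 0)     # Na+ outward
    expect_lt(iv[["K"]], 0)      # K+ inward
    expect_equal(abs(iv[["Na"]]) / abs(iv[["K"]]), 3 / 2)
    expect_equal(iv[["Cl"]], 0)
  }
  rate <- function(na, k) nak_atpase_current(el, 0, c(na_in = na, k_out = k), 0)[["Na"]]
  nas <- seq(1, 140, length.out = 15)
  expect_true(all(diff(vapply(nas, rate, numeric(1), k = 5)) > 0))
  ks <- seq(0.5, 20, length.out = 15)
  expect_true(all(diff(vapply(ks, rate, numeric(1), na = 10)) > 0))
  # hill_na = 0 (the fixture's Na+-saturated form) is flat in Na+, still legal
  el0 <- transport_element("nak_atpase", magnitude = 2,
                           params = list(hill_na = 0))
  expect_equal(nak_atpase_current(el0, 0, c(na_in = 5, k_out = 5), 0),
               nak_atpase_current(el0, 0, c(na_in = 100, k_out = 5), 0))
  expect_error(nak_atpase_current(el, 0, c(na_in = 10, k_out = 5), 1.2),
               "block_fraction")
})

test_that("transporter_current: dispatch, per-ion sums, reversal, errors", {
  ct <- physical_constants()
  cin <- c(K = 100, Na = 10, Cl = 30)
  cout <- c(K = 5, Na = 145, Cl = 130)
  # zero magnitude is zero current for every kind
  for (kind in c("ohmic_channel", "leak_conductance", "nsc_conductance",
                 "clc_channel", "na_transporter", "cl_transporter")) {
    el <- transport_element(kind, 0, ions = if (kind %in% c("ohmic_channel", "leak_conductance"))
      c(K = 0.5, Na = 0.5) else NULL)
    expect_equal(sum(abs(transporter_current(el, -20, cin, cout, ct))), 0)
  }
  # a pure K+ channel reverses exactly at E_K
  el <- transport_element("ohmic_channel", 5, ions = c(K = 1))
  ek <- nernst_potential("K", cout[["K"]], cin[["K"]], ct)
  expect_equal(sum(transporter_current(el, ek, cin, cout, ct)), 0)
  expect_lt(sum(transporter_current(el, ek - 1, cin, cout, ct)), 0)
  expect_gt(sum(transporter_current(el, ek + 1, cin, cout, ct)), 0)
  # multi-ion elements: per-ion components sum to the net current
  leak <- transport_element("leak_conductance", 10, ions = c(K = 0.3, Na = 0.7))
  iv <- transporter_current(leak, -20, cin, cout, ct)
  expect_equal(sum(iv), iv[["K"]] + iv[["Na"]] + iv[["Cl"]])
  # uptake transporters move their substrate inward
  nat <- transport_element("na_transporter", 2)
  expect_lt(transporter_current(nat, 0, cin, cout, ct)[["Na"]], 0)
  clt <- transport_element("cl_transporter", 2)
  expect_gt(transporter_current(clt, 0, cin, cout, ct)[["Cl"]], 0)
  # unknown kinds are a configuration error
  bad <- transport_element("ohmic_channel", 1, ions = c(K = 1))
  bad$kind <- "mystery_pump"
  expect_error(transporter_current(bad, 0, cin, cout, ct), "unknown element kind")
  expect_error(transport_element("osmosis", 1), "'arg' should be one of")
})

test_that("membrane totals and flux breakdown are consistent bookkeeping", {
  m <- ref_model()
  y <- initial_state(m)
  fb <- flux_breakdown(m, y)
  tot <- attr(fb, "per_membrane_total")
  for (mem in c("SB", "SA", "MB", "MA", "HB", "HA")) {
    mt <- membrane_total_current(m, mem, y)
    expect_equal(mt$total, unname(tot[[mem]]))
    expect_equal(sum(mt$per_ion), mt$total, tolerance = 1e-12)
    expect_equal(sum(fb$current_nA[fb$membrane == mem]), mt$total)
  }
  # SB total is the sum of its pump, Na conductance and leak components
  sb <- membrane_total_current(m, "SB", y)
  by_el <- tapply(sb$elements$current_nA, sb$elements$element, sum)
  expect_equal(sum(by_el[c("nak_atpase", "na_conductance", "leak")]), sb$total)
  # and at the calibrated state equals -I_cir
  expect_equal(sb$total, -system_state(m, y)$I_cir, tolerance = 1e-9)
})

test_that("EP/ISP are derived and satisfy their identities on any state", {
  m <- ref_model()
  set.seed(3)
  for (i in 1:10) {
    y <- initial_state(m)
    y[1:5] <- y[1:5] + rnorm(5, 0, 20)
    st <- system_state(m, y)
    expect_equal(st$EP, y[["v_SB"]] - y[["v_SA"]] + y[["v_MB"]] - y[["v_MA"]])
    expect_equal(st$ISP, y[["v_SB"]] - y[["v_SA"]])
    expect_equal(st$EP - st$ISP, y[["v_MB"]] - y[["v_MA"]])
    expect_equal(st$v_HA, y[["v_HB"]] - st$EP)
  }
})
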