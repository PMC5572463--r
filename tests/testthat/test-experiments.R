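# Experiment reports.

test_that("run_normal_steady reproduces the calibrated observables", {
  rep <- run_normal_steady(ref_model())
  expect_s3_class(rep, "lw_report")
  obs <- rep$observables
  expect_setequal(obs$observable, c("EP", "v_SB", "K_SY", "ISP", "K_IS"))
  expect_true(all(obs$pass))
  expect_true(all(nzchar(obs$location)))
  # EP - ISP equals the (small) transmarginal drop
  ser <- rep$series
  expect_equal(ser$EP[1] - ser$ISP[1], ser$v_MB[1] - ser$v_MA[1])
  expect_lt(abs(ser$v_MB[1] - ser$v_MA[1]), 10)
})

test_that("a null perturbation reproduces the normal report", {
  m <- ref_model()
  rep <- run_ouabain_block(m, kappa = 1, t_settle = 60, t_block = 300)
  normal <- reference_values()$normal
  sim <- rep$observables$simulated[match(normal$observable, rep$observables$observable)]
  expect_equal(sim, normal$value, tolerance = 1e-6)
  expect_true(all(is.na(rep$taus$tau_s)))   # constant traces: no tau
})

test_that("blockade report structure and reproducibility metadata", {
  rep <- ref_block()
  expect_equal(rep$config_hash, config_hash(ref_model()$config))
  expect_true(all(c("observables", "taus", "i_cir_plateau", "pump_na_range") %in%
                  names(rep)))
  # the report's pass flags follow only from the declared tolerances
  with(rep$observables,
       expect_equal(pass, abs(simulated - reference) <= tolerance))
})

test_that("kappa-scan table is consistent with the block scenario", {
  m <- ref_model()
  rep <- ref_block()
  scan <- ref_scan()
  tab <- scan$table
  expect_equal(tab$kappa, seq(0.30, 0.60, by = 0.01))
  # the 40-min observables at kappa = 0.46 match the block run
  row <- tab[abs(tab$kappa - 0.46) < 1e-9, ]
  obs <- rep$observables
  for (nm in c("EP", "v_SB", "K_SY", "ISP", "K_IS")) {
    expect_equal(row[[nm]], obs$simulated[obs$observable == nm], tolerance = 1e-4)
  }
})
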