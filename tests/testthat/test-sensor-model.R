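test_that("divider voltage follows the load-resistor formula and its limits", {
  circ <- circuit_params(v_c = 5, r_load = 1)
  expect_equal(divider_voltage(1, circ), 2.5)          # r_s = r_load
  expect_equal(divider_voltage(3, circ), 1.25)         # hand evaluation
  expect_lt(divider_voltage(1e12, circ), 1e-10)        # open-circuit limit
  expect_error(divider_voltage(0, circ), "r_s")
  expect_error(divider_voltage(-1, circ), "r_s")
  set.seed(11)
  r <- 10^runif(100, -3, 3)
  v <- divider_voltage(r, circ)
  expect_true(all(v > 0 & v < circ$v_c))
})

test_that("sensor resistance: zero-gas identity, hand formula, monotone in concentration", {
  p <- gas_response_params()
  # no gas -> air baseline exactly
  for (v in c(0, 1.3, 2.7, 5))
    expect_identical(sensor_resistance(v, analyte_mix(0, 0), p),
                     air_resistance(v, p))
  # independent plain-arithmetic evaluation of the response formula at 3 V,
  # 0.5 % acetone, default shape constants (amplitude 1)
  r_air <- exp(log(50) + (3 / 5) * (log(8) - log(50)))
  gate <- 1 / (1 + exp(-(3 - 2.4) / 0.35))
  expected <- r_air / (1 + 1 * gate * (0.5 / 0.5)^0.6)
  expect_equal(sensor_resistance(3, analyte_mix(0, 0.5), p), expected,
               tolerance = 1e-12)
  # strictly decreasing in each analyte
  for (v in c(1, 2.5, 4)) {
    expect_lt(sensor_resistance(v, analyte_mix(0, 0.2), p),
              sensor_resistance(v, analyte_mix(0, 0.1), p))
    expect_lt(sensor_resistance(v, analyte_mix(0.2, 0), p),
              sensor_resistance(v, analyte_mix(0.1, 0), p))
  }
  expect_error(analyte_mix(-0.1, 0), "non-negative")
  expect_error(sensor_resistance(3, list(c_ethanol = -1, c_acetone = 0), p),
               "non-negative")
})

test_that("amplitude calibration hits the measured single-gas peaks", {
  p <- calibrate_amplitudes()
  ace <- simulate_sweep(analyte_mix(0, 0.5), params = p, noise_sd = 0)
  eth <- simulate_sweep(analyte_mix(0.5, 0), params = p, noise_sd = 0)
  expect_equal(max(ace$out_v), 4.65, tolerance = 1e-6)
  expect_equal(max(eth$out_v), 4.13, tolerance = 1e-6)
  # divider symmetry: a 2.5 V peak target with unit load means the sensor
  # resistance at the peak equals the load resistance
  p25 <- calibrate_amplitudes(c(acetone = 2.5))
  r_peak <- min(sensor_resistance(heater_ramp()$grid, analyte_mix(0, 0.5), p25))
  expect_equal(r_peak, 1.0, tolerance = 1e-9)
  expect_error(calibrate_amplitudes(c(acetone = 5)), "\\(0, v_c\\)")
  expect_error(calibrate_amplitudes(c(acetone = 0.3)), "unattainable")
})

test_that("sweeps are bounded, reproducible, and the air baseline stays low", {
  p <- calibrate_amplitudes()
  s1 <- simulate_sweep(analyte_mix(0.1, 0.1), params = p, seed = 99L)
  s2 <- simulate_sweep(analyte_mix(0.1, 0.1), params = p, seed = 99L)
  expect_identical(s1$out_v, s2$out_v)
  air <- simulate_sweep(analyte_mix(0, 0), params = p, noise_sd = 0)
  expect_lt(max(air$out_v), 1.0)
  # bounded output over 1e4 random sweeps
  set.seed(5)
  mixes <- matrix(10^runif(2e4, -3, 0), ncol = 2)
  ramp <- heater_ramp(0, 5, 0.05)  # coarser grid, same voltage span
  ok <- vapply(seq_len(1e4), function(i) {
    s <- simulate_sweep(analyte_mix(mixes[i, 1], mixes[i, 2]), ramp, p,
                        noise_sd = 0.02, seed = i)
    all(s$out_v >= 0 & s$out_v <= 5)
  }, logical(1))
  expect_true(all(ok))
})

test_that("noise-free response is monotone in concentration over the design grid", {
  p <- calibrate_amplitudes()
  lv <- concentration_levels()
  v_probe <- c(3, 4, 5)  # past both onsets
  for (v in v_probe) {
    resp_ace <- vapply(lv, function(c)
      divider_voltage(sensor_resistance(v, analyte_mix(0.1, c), p)), numeric(1))
    resp_eth <- vapply(lv, function(c)
      divider_voltage(sensor_resistance(v, analyte_mix(c, 0.1), p)), numeric(1))
    expect_true(all(diff(resp_ace) > 0))
    expect_true(all(diff(resp_eth) > 0))
  }
})

test_that("ethanol onset precedes acetone onset in calibrated sweeps", {
  p <- calibrate_amplitudes()
  eth <- simulate_sweep(analyte_mix(0.5, 0), params = p, noise_sd = 0)
  ace <- simulate_sweep(analyte_mix(0, 0.5), params = p, noise_sd = 0)
  v_on_eth <- eth$heater_v[which(eth$out_v > 1)[1]]
  v_on_ace <- ace$heater_v[which(ace$out_v > 1)[1]]
  expect_lt(v_on_eth, v_on_ace)
  # the parameter object itself enforces the ordering
  expect_error(gas_response_params(
    ethanol = list(amplitude = 1, v_on = 3, w = 0.5, beta = 0.6),
    acetone = list(amplitude = 1, v_on = 2.4, w = 0.35, beta = 0.6)),
    "onset")
})

test_that("concentration ladder is the 13-level serial dilution", {
  lv <- concentration_levels()
  expect_length(lv, 13)
  expect_equal(lv[1], 2^-7)
  expect_equal(lv[13], 0.5)
  expect_equal(round(lv[1] * 1e4), 78)    # lowest level in ppm
  expect_equal(round(lv[13] * 1e4), 5000) # highest level in ppm
  # serial dilution: every second step doubles
  for (i in seq_len(11)) expect_equal(lv[i + 2] / lv[i], 2, tolerance = 1e-12)
})

test_that("factorial dataset generation: counts, seeds, reproducibility", {
  p <- calibrate_amplitudes()
  lv <- concentration_levels()
  expect_length(generate_dataset(lv, lv, 1L, params = p, noise_sd = 0), 169)
  expect_length(generate_dataset(0.5, 0.5, 1L, params = p, noise_sd = 0), 1)
  d3 <- generate_dataset(lv, lv, 3L, params = p, noise_sd = 0.02, seed = 3L)
  expect_length(d3, 507)
  expect_error(generate_dataset(numeric(0), lv, 1L, params = p), "non-empty")
  expect_error(generate_dataset(lv, lv, 0L, params = p), "replicates")
  a <- generate_dataset(c(0.1, 0.5), c(0.1, 0.5), 2L, params = p,
                        noise_sd = 0.02, seed = 17L)
  b <- generate_dataset(c(0.1, 0.5), c(0.1, 0.5), 2L, params = p,
                        noise_sd = 0.02, seed = 17L)
  for (i in seq_along(a)) expect_identical(a[[i]]$out_v, b[[i]]$out_v)
  # replicates differ (independent noise) but share the mix
  expect_false(identical(a[[1]]$out_v, a[[2]]$out_v))
  expect_identical(a[[1]]$mix, a[[2]]$mix)
  man <- sweep_manifest(d3)
  expect_equal(nrow(man), 507)
  expect_equal(sum(man$replicate == 1), 169)
})
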