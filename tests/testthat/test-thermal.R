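test_that("film coefficient and wall-resistance composition", {
  tc <- thermal_config()
  # Nu k / d = 3.66 * 0.2 / 1e-3
  expect_equal(heat_transfer_coefficient(tc), 732)
  tc2 <- thermal_config(lumen_diameter = 2e-3)
  expect_equal(heat_transfer_coefficient(tc2), 366)
  # infinitely conductive wall collapses to the bare film value
  tcw <- thermal_config(include_wall_resistance = TRUE,
                        wall_conductivity = 1e12)
  expect_equal(heat_transfer_coefficient(tcw), 732, tolerance = 1e-9)
  # a real wall strictly reduces the coefficient
  tcr <- thermal_config(include_wall_resistance = TRUE)
  expect_lt(heat_transfer_coefficient(tcr), 732)
})

test_that("temperature profile follows the closed-form exponential", {
  tc <- thermal_config()
  prof <- axial_temperature_profile(tc, n_points = 101)
  expect_equal(prof$temperature_C[1], 20)            # inlet exactly
  # decay length rho c_p Q / (h pi d) ~ 9.4 mm with DMSO defaults
  expect_equal(prof$decay_length_m, 9.4e-3, tolerance = 0.01)
  # a 1 m neurosurgical catheter fully warms the agent
  expect_lt(37 - prof$temperature_C[101], 0.01)
  # monotone non-decreasing and bounded by body temperature
  expect_true(all(diff(prof$temperature_C) >= 0))
  expect_true(all(prof$temperature_C <= 37))
})

test_that("warm-up length has the right closed form and monotonicity", {
  tc <- thermal_config()
  xs <- warmup_length(tc, 1 - exp(-1))
  expect_equal(xs, axial_temperature_profile(tc)$decay_length_m,
               tolerance = 1e-12)
  # 95% warm-up is about 28 mm, far below the 1 m catheter
  x95 <- warmup_length(tc, 0.95)
  expect_equal(x95, 28e-3, tolerance = 0.02)
  expect_lt(x95, 0.1)
  # more inflow carries heat further before equilibrating
  expect_gt(warmup_length(thermal_config(inflow = 2e-8), 0.95), x95)
  expect_error(warmup_length(tc, 1), "\\(0, 1\\)")
  expect_error(warmup_length(tc, 0), "\\(0, 1\\)")
})

test_that("exponential profile matches brute-force axial integration", {
  # independent oracle: midpoint (RK2) integration of the lumped energy
  # balance dT/dx = (T_body - T)/x* with 0.1 mm steps
  tc <- thermal_config(length = 0.2)
  xs <- axial_temperature_profile(tc)$decay_length_m
  h <- 1e-4
  x <- seq(0, 0.2, by = h)
  temp <- numeric(length(x)); temp[1] <- 20
  for (i in seq_len(length(x) - 1)) {
    k1 <- (37 - temp[i]) / xs
    k2 <- (37 - (temp[i] + 0.5 * h * k1)) / xs
    temp[i + 1] <- temp[i] + h * k2
  }
  closed <- 37 - (37 - 20) * exp(-x / xs)
  expect_lt(max(abs(temp - closed)), 0.01)
})

test_that("viscosity profile composes temperature with the viscosity law", {
  law <- embolic_temperature_law("squid12")
  prof <- viscosity_profile(thermal_config(), law)
  # viscosity falls monotonically along the flow (thermal activation)
  expect_true(all(diff(prof$viscosity_mPas) <= 0))
  gam <- wall_shear_rate(1e-8, 1e-3)
  # outlet/inlet ratio approaches the 37/20 degC anchor ratio
  anchor_ratio <- eval_sisko(law$params_warm, gam) /
    eval_sisko(law$params_cold, gam)
  ratio <- prof$viscosity_mPas[length(prof$viscosity_mPas)] /
    prof$viscosity_mPas[1]
  expect_equal(ratio, anchor_ratio, tolerance = 1e-3)
})

test_that("isothermal configuration yields a flat profile at the warm anchor", {
  law <- embolic_temperature_law("squid12")
  tc <- thermal_config(inlet_temperature = 37)
  prof <- viscosity_profile(tc, law)
  gam <- wall_shear_rate(1e-8, 1e-3)
  mu37 <- eval_sisko(law$params_warm, gam)
  expect_equal(prof$viscosity_mPas, rep(mu37, length(prof$x_m)),
               tolerance = 1e-12)
  # integrated pressure drop equals the closed-form Poiseuille value
  dp_exact <- poiseuille_pressure_drop(mu37 * 1e-3, 1,
                                       mean_velocity(1e-8, 1e-3), 1e-3)
  expect_equal(prof$total_pressure_drop_Pa, dp_exact, tolerance = 1e-10)
})

test_that("heated pressure drop lies between the isothermal bounds", {
  law <- embolic_temperature_law("squid12")
  tc <- thermal_config()
  gam <- wall_shear_rate(1e-8, 1e-3)
  c_mean <- mean_velocity(1e-8, 1e-3)
  dp20 <- poiseuille_pressure_drop(eval_sisko(law$params_cold, gam) * 1e-3,
                                   1, c_mean, 1e-3)
  dp37 <- poiseuille_pressure_drop(eval_sisko(law$params_warm, gam) * 1e-3,
                                   1, c_mean, 1e-3)
  dp <- viscosity_profile(tc, law)$total_pressure_drop_Pa
  expect_gt(dp, dp37); expect_lt(dp, dp20)
})

test_that("grid refinement changes the integrated pressure drop marginally", {
  law <- embolic_temperature_law("onyx18")
  dp100 <- viscosity_profile(thermal_config(), law, 100)$total_pressure_drop_Pa
  dp1000 <- viscosity_profile(thermal_config(), law, 1000)$total_pressure_drop_Pa
  expect_lt(abs(dp100 - dp1000) / dp1000, 1e-3)
})

test_that("shorter intracorporeal catheters deliver colder, thicker agent", {
  law <- embolic_temperature_law("squid12")
  lengths <- c(0.01, 0.02, 0.05, 0.2, 1)
  outlet_mu <- vapply(lengths, function(L) {
    prof <- viscosity_profile(thermal_config(length = L), law)
    prof$viscosity_mPas[length(prof$viscosity_mPas)]
  }, numeric(1))
  expect_true(all(diff(outlet_mu) < 0))  # longer catheter -> thinner agent
  # a centimeters-long path leaves the agent visibly under-warmed
  prof <- axial_temperature_profile(thermal_config(length = 0.02))
  expect_lt(prof$temperature_C[length(prof$temperature_C)], 36.5)
})

test_that("thermal configuration enforces the warming scenario", {
  expect_error(thermal_config(inlet_temperature = 38), "warming")
  expect_error(thermal_config(inflow = 0), "inflow")
  expect_error(thermal_config(nusselt = -1), "nusselt")
})
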