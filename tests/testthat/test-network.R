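newtonian <- function(mu_mPas, temperature = 37)
  sisko_params(mu_mPas, 0, 1, temperature = temperature,
               polymer_label = "newtonian")

test_that("hydraulic primitives match hand calculations", {
  # 0.6 mL/min through a 2 mm lumen: about 3 mm/s
  u <- mean_velocity(1e-8, 2e-3)
  expect_equal(u, 1e-8 / (pi * 1e-6), tolerance = 1e-12)
  expect_equal(u, 3.183e-3, tolerance = 1e-3)
  expect_equal(mean_velocity(2e-8, 2e-3), 2 * u)          # linear in Q
  expect_equal(mean_velocity(1, 2 / sqrt(pi)), 1)         # unit area

  # Poiseuille wall shear rate 32 Q / (pi d^3)
  expect_equal(wall_shear_rate(1e-8, 2e-3), 12.732, tolerance = 1e-3)
  expect_equal(wall_shear_rate(1e-8, 1e-3) / wall_shear_rate(1e-8, 2e-3), 8)
  expect_equal(wall_shear_rate(pi / 4 * 64, 8), 1)        # 8 u / d with u=1,d=8

  # pressure drop 32 mu l c / d^2
  dp <- poiseuille_pressure_drop(12.155e-3, 1, 3.183e-3, 2e-3)
  expect_equal(dp, 309.6, tolerance = 1e-3)
  expect_equal(poiseuille_pressure_drop(12.155e-3, 2, 3.183e-3, 2e-3), 2 * dp)
  # algebraic identity with the hydraulic-resistance form 128 mu l Q/(pi d^4)
  Q <- 1e-8; d <- 2e-3
  expect_equal(poiseuille_pressure_drop(12.155e-3, 1, mean_velocity(Q, d), d),
               128 * 12.155e-3 * 1 * Q / (pi * d^4), tolerance = 1e-12)
})

test_that("Darcy-Weisbach with lambda = 64/Re reduces to Poiseuille", {
  set.seed(5)
  for (i in 1:20) {
    rho <- runif(1, 900, 1300); c <- runif(1, 1e-4, 1e-1)
    d <- runif(1, 2e-4, 5e-3); l <- runif(1, 1e-3, 1); mu <- runif(1, 1e-3, 0.1)
    g <- 9.80665
    re <- reynolds_number(rho, c, d, mu)
    h <- darcy_weisbach_head_loss(64 / re, l, d, c, g)
    expect_equal(rho * g * h, poiseuille_pressure_drop(mu, l, c, d),
                 tolerance = 1e-10)
  }
  expect_equal(darcy_weisbach_head_loss(0.02, 1, 1, sqrt(2 * 9.80665), 9.80665),
               0.02, tolerance = 1e-12)
  expect_equal(darcy_weisbach_head_loss(0.02, 1, 1, 1, 4.9) /
                 darcy_weisbach_head_loss(0.02, 1, 1, 1, 9.8), 2,
               tolerance = 1e-12)
})

test_that("Reynolds number composes with the Sisko viscosity", {
  expect_equal(reynolds_number(1, 1, 1, 1), 1)
  expect_equal(reynolds_number(1100, 3.18e-3, 2e-3, 0.02) /
                 reynolds_number(1100, 3.18e-3, 2e-3, 0.04), 2)
  # Squid-12 in the heated catheter: about 0.58
  mu <- eval_sisko(embolic_sisko_params("squid12", 37), 10) * 1e-3
  expect_equal(reynolds_number(1100, mean_velocity(1e-8, 2e-3), 2e-3, mu),
               0.58, tolerance = 0.01)
})

test_that("wall shear stress converts Pa to dyne/cm^2", {
  expect_equal(wall_shear_stress(0.1, 1), 1)
  expect_equal(wall_shear_stress(0.5, 0), 0)
  gam <- wall_shear_rate(1e-8, 2e-3)
  mu <- eval_sisko(embolic_sisko_params("squid12", 37), gam) * 1e-3
  expect_equal(wall_shear_stress(mu, gam), 1.55, tolerance = 5e-3)
})

test_that("Newtonian networks converge in one iteration with symmetric split", {
  net <- default_avm_network(newtonian(15), racemose_diameter = 1e-3)
  sol <- solve_network(net)
  expect_true(sol$converged)
  expect_equal(sol$iterations, 1L)
  rac <- sol$segments[sol$segments$label == "racemose", ]
  expect_equal(rac$flow_m3_s, net$inflow / 10, tolerance = 1e-12)

  netf <- default_avm_network(newtonian(15), racemose_diameter = 1e-3,
                              with_fistula = TRUE)
  solf <- solve_network(netf)
  expect_true(solf$converged)
  expect_lt(solf$mass_defect, 1e-10)
  expect_lt(solf$parallel_pressure_defect, 1e-6)
})

test_that("removing one of two identical parallel tubes doubles its drop", {
  base <- default_avm_network(newtonian(20), racemose_diameter = 1e-3)
  base$racemose$n_parallel <- 2L
  two <- solve_network(base)
  base$racemose$n_parallel <- 1L
  one <- solve_network(base)
  dp2 <- two$segments$pressure_drop_Pa[two$segments$label == "racemose"]
  dp1 <- one$segments$pressure_drop_Pa[one$segments$label == "racemose"]
  expect_equal(dp1 / dp2, 2, tolerance = 1e-12)
})

test_that("a Newtonian 2-branch split matches the resistor-network oracle", {
  mu <- 18e-3  # Pa.s
  net <- avm_network(
    catheter = vessel_segment("catheter", 1, 2e-3),
    feeder = vessel_segment("feeder", 20e-3, 3e-3),
    racemose = vessel_segment("branchA", 12e-3, 0.8e-3, n_parallel = 1L),
    fistula = vessel_segment("branchB", 9e-3, 1.7e-3),
    drainer = vessel_segment("drainer", 20e-3, 3e-3),
    viscosity_law = newtonian(mu * 1e3))
  sol <- solve_network(net)
  # independent closed form: conductances G = pi d^4 / (128 mu l),
  # q_i = Q G_i / (G_A + G_B)
  G <- function(d, l) pi * d^4 / (128 * mu * l)
  GA <- G(0.8e-3, 12e-3); GB <- G(1.7e-3, 9e-3)
  qA <- net$inflow * GA / (GA + GB)
  segs <- sol$segments
  expect_equal(segs$flow_m3_s[segs$label == "branchA"], qA,
               tolerance = 1e-10)
  expect_equal(segs$flow_m3_s[segs$label == "branchB"],
               net$inflow - qA, tolerance = 1e-10)
  expect_equal(segs$pressure_drop_Pa[segs$label == "branchA"],
               qA / GA, tolerance = 1e-10)
})

test_that("non-Newtonian solves conserve mass and balance parallel drops", {
  for (pol in c("onyx18", "squid12")) {
    p <- embolic_sisko_params(pol, 37)
    for (fist in c(FALSE, TRUE)) {
      sol <- solve_network(default_avm_network(p, 1e-3, with_fistula = fist))
      expect_true(sol$converged)
      expect_lt(sol$mass_defect, 1e-10)
      expect_lt(sol$parallel_pressure_defect, 1e-6)
      expect_true(all(sol$segments$viscosity_mPas > 0))
      # deep laminar regime throughout
      expect_true(all(sol$segments$reynolds < 2000))
    }
  }
})

test_that("Onyx-18 drives a higher pressure drop than Squid-12", {
  # first confirm viscosity dominance over the operating shear range
  onyx <- embolic_sisko_params("onyx18", 37)
  squid <- embolic_sisko_params("squid12", 37)
  U <- 10^seq(log10(0.2), 2, length.out = 40)
  expect_true(all(eval_sisko(onyx, U) > eval_sisko(squid, U)))
  net_o <- default_avm_network(onyx, 1e-3)
  net_s <- default_avm_network(squid, 1e-3)
  expect_gt(solve_network(net_o)$total_pressure_drop_Pa,
            solve_network(net_s)$total_pressure_drop_Pa)
})

test_that("diameter sweep reproduces the qualitative pressure trends", {
  for (pol in c("onyx18", "squid12")) {
    net <- default_avm_network(embolic_sisko_params(pol, 37), 1e-3)
    sw <- sweep_diameters(net, c(0.5, 0.75, 1, 1.5, 2) * 1e-3)
    expect_true(all(sw$converged))
    nofist <- sw[!sw$fistula, ]; fist <- sw[sw$fistula, ]
    # racemose pressure drop strictly decreasing in diameter
    expect_true(all(diff(nofist$pressure_Pa) < 0), info = pol)
    # fistula strictly lowers the racemose pressure drop at every diameter
    expect_true(all(fist$pressure_Pa < nofist$pressure_Pa), info = pol)
  }
})

test_that("sweep handles empty input and polices the diameter range", {
  net <- default_avm_network(embolic_sisko_params("onyx18", 37), 1e-3)
  empty <- sweep_diameters(net, numeric(0))
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0)
  expect_error(sweep_diameters(net, 6e-3), "within")
})
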