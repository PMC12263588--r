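test_that("mean pressure follows the cuff estimate", {
  # hand evaluation: 82 + (117-82)/3 mmHg
  expect_equal(pa_to_mmhg(mean_pressure(mmHg_to_pa(117), mmHg_to_pa(82))),
               93.667, tolerance = 1e-4)
  expect_equal(pa_to_mmhg(mean_pressure(mmHg_to_pa(124), mmHg_to_pa(87))),
               99.333, tolerance = 1e-4)
  expect_identical(mean_pressure(90, 90), 90)
  expect_error(mean_pressure(80, 90), "systolic")
})

test_that("total resistance is the driving pressure over mean flow", {
  expect_identical(total_resistance(4426, 4426, 2e-4), 0)
  # Pm from the 117/82 cuff estimate, Pout = 4426 Pa
  expect_equal(total_resistance(12487.8, 4426, 1e-4), 8.0618e7,
               tolerance = 1e-4)
  expect_equal(total_resistance(12487.8, 4426, 2e-4),
               total_resistance(12487.8, 4426, 1e-4) / 2)
  expect_error(total_resistance(1e4, 4426, 0), "positive")
})

test_that("parallel area split conserves the total resistance", {
  expect_identical(split_outlet_resistance(5e7, 3e-4), 5e7)
  expect_equal(split_outlet_resistance(5e7, c(2e-4, 2e-4)), c(1e8, 1e8))
  r <- split_outlet_resistance(1e7, c(4, 3, 2, 1) * 1e-4)
  expect_equal(r, c(2.5e7, 10e7 / 3, 5e7, 1e8), tolerance = 1e-9)
  expect_equal(1 / sum(1 / r), 1e7, tolerance = 1e-9)
  expect_error(split_outlet_resistance(1e7, c(1e-4, 0)), "positive")
  # property: conservation and monotonicity for random positive areas
  set.seed(11)
  for (i in 1:25) {
    a <- sort(stats::runif(4, 1e-5, 1e-3), decreasing = TRUE)
    ri <- split_outlet_resistance(7.3e7, a)
    expect_equal(1 / sum(1 / ri), 7.3e7, tolerance = 1e-9)
    expect_true(all(diff(ri) > 0))   # larger area -> smaller resistance
  }
})

test_that("characteristic impedance follows the wave-speed power law", {
  # hand evaluation with rho = 1060, xi = 0.72:
  # c(0.02 m) = 0.72/sqrt(0.02) = 5.0912 m/s; R1 = 1060*5.0912/(pi*1e-4)
  expect_equal(proximal_resistance(0.02, pi * 0.01^2), 1.7178e7,
               tolerance = 1e-4)
  expect_equal(proximal_resistance(0.01, pi * 0.005^2), 9.7173e7,
               tolerance = 1e-4)
  expect_equal(proximal_resistance(0.02) / proximal_resistance(0.01),
               2^(-2.5))
  expect_error(proximal_resistance(-0.01), "positive")
})

test_that("distal resistance is the remainder and names bad outlets", {
  expect_identical(distal_resistance(1e8, 1e7), 9e7)
  # packaged Patient-1 BT row reconstructs its total resistance
  tab <- windkessel_table("Patient-1")
  bt <- tab[tab$outlet == "BT", ]
  expect_equal(bt$R1 + distal_resistance(bt$R1 + bt$R2, bt$R1),
               2.162e8, tolerance = 1e-3)
  expect_error(distal_resistance(5, 5), "characteristic impedance")
  expect_error(distal_resistance(c(1e8, 5), c(1e7, 5), c("BT", "LCC")),
               "LCC")
})

test_that("global compliance scales with pulse, flow swing and interval", {
  wf <- raw_flow_waveform(4.2e-4, 0.2e-4, extrema_interval = 0.1)
  # hand evaluation: 4e-4 / 4666.3 * 0.1
  expect_equal(total_compliance(wf, mmHg_to_pa(117), mmHg_to_pa(82)),
               8.572e-9, tolerance = 1e-4)
  const <- make_waveform("flow", 2e-4, 2e-4)
  expect_identical(total_compliance(const, 2e4, 1e4), 0)
  wf2 <- raw_flow_waveform(4.2e-4, 0.2e-4, extrema_interval = 0.2)
  expect_equal(total_compliance(wf2, mmHg_to_pa(117), mmHg_to_pa(82)),
               2 * total_compliance(wf, mmHg_to_pa(117), mmHg_to_pa(82)))
  expect_error(total_compliance(wf, 1e4, 1e4), "pulse")
})

test_that("compliance distribution conserves the total", {
  expect_identical(distribute_compliance(3e-9, 5e7), 3e-9)
  ci <- distribute_compliance(3e-9, c(1e8, 2e8))
  expect_equal(ci[1] / ci[2], 2)
  expect_equal(sum(ci), 3e-9)
  set.seed(7)
  for (i in 1:100) {
    r <- stats::runif(4, 1e6, 1e9)
    ci <- distribute_compliance(1.3e-8, r)
    expect_equal(sum(ci), 1.3e-8, tolerance = 1e-9)
    expect_true(all(ci > 0))
  }
})

test_that("full calibration composes its parts and reports intermediates", {
  params <- calibrate_windkessel(test_patient(), make_outlet_set())
  expect_identical(nrow(params), 4L)
  expect_true(all(params$R1 > 0 & params$R2 > 0 & params$C > 0))
  rep <- attr(params, "report")
  expect_equal(1 / sum(1 / (params$R1 + params$R2)), rep$R_total,
               tolerance = 1e-9)
  expect_equal(sum(params$C), rep$C_T, tolerance = 1e-9)
  # an outlet too narrow for its share errors by name
  os <- make_outlet_set()
  os$diastolic_diameter[os$name == "LCC"] <- 5e-4
  os$diastolic_area[os$name == "LCC"] <- pi * (2.5e-4)^2
  expect_error(calibrate_windkessel(test_patient(), os), "LCC")
})

test_that("calibrated parameters round-trip through the 0D solver", {
  params <- calibrate_windkessel(test_patient(), make_outlet_set())
  rep <- attr(params, "report")
  inlet <- make_waveform("pressure", mmHg_to_pa(117), mmHg_to_pa(82))
  state <- simulate_network(inlet, params)
  fc <- final_cycle(state)
  q_mean <- mean(rowSums(fc$Q)[-1])
  pm_rec <- rep$Pout + q_mean * rep$R_total
  expect_equal(pm_rec, rep$Pm, tolerance = 0.02)
  pulse_rec <- max(fc$inlet_pressure) - min(fc$inlet_pressure)
  expect_equal(pulse_rec, mmHg_to_pa(117 - 82), tolerance = 0.10)
})

test_that("packaged boundary-condition table matches the printed values", {
  tab <- windkessel_table()
  expect_identical(nrow(tab), 8L)
  p1 <- windkessel_table("Patient-1")
  expect_identical(p1$R1, c(2.82e7, 9.17e7, 7.28e7, 7.72e6))
  expect_identical(p1$R2, c(1.88e8, 3.97e8, 3.45e8, 5.60e7))
  expect_identical(p1$C, c(1.41e-6, 1.72e-6, 1.64e-6, 1.18e-6))
  p2 <- windkessel_table("Patient-2")
  expect_identical(p2$R1, c(7.605e6, 2.800e6, 2.806e6, 1.943e5))
  expect_identical(p2$R2, c(3.814e8, 1.263e9, 8.201e8, 1.560e8))
  expect_identical(p2$C, c(2.278e-7, 5.239e-7, 5.513e-7, 5.019e-7))
})

test_that("parameter CSV round-trips", {
  params <- calibrate_windkessel(test_patient(), make_outlet_set())
  path <- withr::local_tempfile(fileext = ".csv")
  write_params_csv(params, path)
  back <- read_params_csv(path)
  expect_equal(back$R1, params$R1)
  expect_equal(back$C, params$C)
})
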