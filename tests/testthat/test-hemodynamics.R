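test_that("allometric total flow follows the power law", {
  expect_equal(total_coronary_flow(100, coefficient = 0.01, exponent = 1), 1.0)
  expect_equal(total_coronary_flow(120), 2.0)   # calibration point
  expect_equal(total_coronary_flow(240) / total_coronary_flow(120), 2^0.75)
  expect_error(total_coronary_flow(0), class = "ffrct_model_error")
  expect_error(total_coronary_flow(-5), class = "ffrct_model_error")
})

test_that("Murray fractions are diameter-cubed shares summing to one", {
  expect_equal(murray_fractions(3.1), 1)
  expect_equal(murray_fractions(c(4, 2)), c(8 / 9, 1 / 9))
  # d = (3.0, 2.5, 2.0), m = 3: shares of 27 : 15.625 : 8
  fr <- murray_fractions(c(3.0, 2.5, 2.0))
  expect_equal(fr, c(27, 15.625, 8) / 50.625, tolerance = 1e-10)
  expect_equal(sum(fr), 1)
  expect_error(murray_fractions(numeric(0)), class = "ffrct_model_error")
})

test_that("viscous resistance matches the Poiseuille closed form and scaling laws", {
  prof <- centerline_profile(seq(0, 100, 1), rep(1.5, 101))
  expect_equal(segment_viscous_resistance(prof, 0.035),
               128 * 0.035 * 10 / (pi * 0.3^4), tolerance = 1e-12)
  half <- centerline_profile(seq(0, 100, 1), rep(0.75, 101))
  expect_equal(segment_viscous_resistance(half) / segment_viscous_resistance(prof),
               16, tolerance = 1e-12)
  # series additivity of two closed-form tubes
  r3 <- 128 * 0.035 * 5 / (pi * 0.3^4)
  r2 <- 128 * 0.035 * 5 / (pi * 0.2^4)
  two <- centerline_profile(c(seq(0, 49.99, 0.01), seq(50.01, 100, 0.01)),
                            c(rep(1.5, 5000), rep(1.0, 5000)))
  expect_equal(segment_viscous_resistance(two), r3 + r2, tolerance = 1e-3)
})

test_that("stenosis loss has the Young-Tsai form", {
  # degenerate: no narrowing -> no quadratic loss; no flow -> no loss
  expect_equal(stenosis_pressure_loss(3, 3, 3), 0)
  expect_equal(stenosis_pressure_loss(0, 1.5, 3), 0)
  # worked case d0 = 3 mm, ds = 1.5 mm, Q = 3 mL/s
  a_s <- pi * 0.15^2 / 4
  a_0 <- pi * 0.3^2 / 4
  expected <- 1.52 * (1.05 / 2) * (1 / a_s - 1 / a_0)^2 * 9
  expect_equal(stenosis_pressure_loss(3, 1.5, 3), expected, tolerance = 1e-12)
  expect_equal(expected / 1333.22, 9.7, tolerance = 0.01)  # about 9.7 mmHg
  # antisymmetric in flow
  expect_equal(stenosis_pressure_loss(-3, 1.5, 3), -expected)
  expect_error(stenosis_pressure_loss(1, 0, 3), class = "ffrct_model_error")
})

test_that("outlet assignment reproduces the target rest aortic pressure", {
  # single outlet, nearly resistance-free tube: Rp + Rd is the full
  # (Pa - Pv)/Q resistance less the tube's own share
  fat <- tube_tree(d_mm = 4, len_mm = 5, vm = 120)
  inflow <- inflow_model(120, waveform = aortic_waveform(constant = TRUE))
  out <- assign_outlets(fat, inflow, hyperemia_factor = 1)
  r_seg <- segment_viscous_resistance(fat$segments$main$profile)
  expect_equal(out[[1]]$rp + out[[1]]$rd, 93 * 1333.22 / 2 - r_seg,
               tolerance = 1e-9)
  expect_equal(93 * 1333.22 / 2, 61994.73, tolerance = 1e-6)
  expect_equal(out[[1]]$rp / (out[[1]]$rp + out[[1]]$rd), 0.09)

  # identical daughters receive identical outlets
  out2 <- assign_outlets(bifurcation_tree(), inflow, hyperemia_factor = 1)
  expect_equal(out2[[1]]$rp, out2[[2]]$rp)
  expect_equal(out2[[1]]$rd, out2[[2]]$rd)
  expect_equal(out2[[1]]$c, out2[[2]]$c)

  # hyperemia scales both resistances, not the compliance
  out3 <- assign_outlets(fat, inflow, hyperemia_factor = 0.24)
  expect_equal(out3[[1]]$rp + out3[[1]]$rd,
               0.24 * (out[[1]]$rp + out[[1]]$rd), tolerance = 1e-12)
  expect_equal(out3[[1]]$c, out[[1]]$c)
})

test_that("steady network solve matches the series-resistance closed form", {
  tube <- tube_tree(d_mm = 3, len_mm = 100)
  inflow <- inflow_model(120, waveform = aortic_waveform(constant = TRUE))
  out <- assign_outlets(tube, inflow, hyperemia_factor = 1)
  sol <- solve_steady(tube, out, inflow$qbar_ml_s)
  r_seg <- segment_viscous_resistance(tube$segments$main$profile)
  r_out <- out[[1]]$rp + out[[1]]$rd
  # Poiseuille oracle at 1e-10 relative
  expect_equal(sol$inlet_pressure, 2 * (r_seg + r_out),
               tolerance = 1e-10)
  # resistor-divider FFR in the steady limit
  expect_equal(compute_ffr(sol, "main", 100), r_out / (r_seg + r_out),
               tolerance = 1e-10)
  expect_identical(compute_ffr(sol, "main", 0), 1)
  expect_error(compute_ffr(sol, "nowhere", 10), class = "ffrct_solver_error")
})

test_that("symmetric bifurcations split flow equally and conserve mass", {
  tr <- bifurcation_tree()
  inflow <- inflow_model(120, waveform = aortic_waveform(constant = TRUE))
  out <- assign_outlets(tr, inflow, hyperemia_factor = 0.24)
  sol <- solve_steady(tr, out, inflow$qbar_ml_s)
  ed <- sol$network$edges_df
  q_left <- sol$edge_flow[ed$segment == "left"]
  q_right <- sol$edge_flow[ed$segment == "right"]
  expect_equal(q_left, q_right, tolerance = 1e-12)
  expect_lt(junction_residual(sol), 1e-8)
})

test_that("FFR is non-increasing along the flow direction and in severity", {
  tr <- lesion_tree(depth = 0.55)
  inflow <- inflow_model(120, waveform = aortic_waveform(constant = TRUE))
  out <- assign_outlets(tr, inflow, hyperemia_factor = 0.24)
  sol <- solve_steady(tr, out, inflow$qbar_ml_s)
  prof <- ffr_profile(sol)
  prof <- prof[order(prof$s_mm), ]
  expect_true(all(diff(prof$ffr) <= 1e-12))
  expect_true(all(prof$ffr > 0 & prof$ffr <= 1 + 1e-12))

  # severity sweep: deeper narrowing never raises distal FFR
  ffrs <- vapply(c(0, 0.2, 0.4, 0.6, 0.8),
                 function(dep) steady_ffr(lesion_tree(depth = max(dep, 1e-6)),
                                          "main", 90),
                 0)
  expect_true(all(diff(ffrs) < 0))
})

test_that("lowering microvascular resistance (hyperemia) lowers distal FFR", {
  ffr_rest <- steady_ffr(lesion_tree(depth = 0.5), "main", 90,
                         hyperemia_factor = 1)
  ffr_hyper <- steady_ffr(lesion_tree(depth = 0.5), "main", 90,
                          hyperemia_factor = 0.24)
  expect_lt(ffr_hyper, ffr_rest)
})

test_that("constant-waveform pulsatile solve reproduces the steady solution", {
  tr <- lesion_tree(depth = 0.5)
  inflow <- inflow_model(120, waveform = aortic_waveform(constant = TRUE))
  out <- assign_outlets(tr, inflow, hyperemia_factor = 0.24)
  st <- solve_steady(tr, out, inflow$qbar_ml_s)
  un <- solve_unsteady(tr, out, inflow,
                       config = solver_config(dt = 0.005, n_cycles = 4))
  expect_true(un$converged)
  expect_lt(max(abs(un$node_pressure - st$node_pressure)) /
              max(abs(st$node_pressure)), 1e-6)
})

test_that("Windkessel state relaxes with time constant Rd*C", {
  fat <- tube_tree(d_mm = 4, len_mm = 5)
  inflow <- inflow_model(120, waveform = aortic_waveform(constant = TRUE))
  out <- assign_outlets(fat, inflow, hyperemia_factor = 1)
  tau <- out[[1]]$rd * out[[1]]$c
  target <- inflow$qbar_ml_s * out[[1]]$rd   # p_v = 0
  cfg <- solver_config(dt = 0.002, n_cycles = ceiling(5 * tau / 0.8) + 1,
                       periodicity_tol = 0)
  sol <- suppressWarnings(
    solve_unsteady(fat, out, inflow, config = cfg,
                   init = list(pc = stats::setNames(0, names(out)))))
  i5 <- which.min(abs(sol$trace$time - 5 * tau))
  # after 5 time constants the remaining error is under 1% of the step
  expect_lt(abs(sol$trace$pc[i5, 1] - target) / target, 0.01)
  expect_gt(abs(sol$trace$pc[1, 1] - target) / target, 0.9)
})

test_that("BDF2 time stepping shows second-order convergence", {
  fat <- tube_tree(d_mm = 4, len_mm = 5)
  wf <- function(t) 1 + 0.5 * sin(2 * pi * t / 0.8)
  attr(wf, "period") <- 0.8
  inflow <- inflow_model(120, waveform = wf)
  out <- assign_outlets(fat, inflow, hyperemia_factor = 1)
  probe <- function(dt) {
    cfg <- solver_config(dt = dt, n_cycles = 1, periodicity_tol = 0)
    sol <- suppressWarnings(solve_unsteady(fat, out, inflow, config = cfg,
                                           init = list(pc = stats::setNames(0, names(out)))))
    sol$trace$pc[nrow(sol$trace$pc), 1]
  }
  ref <- probe(0.8 / 1600)
  errs <- abs(vapply(c(0.8 / 50, 0.8 / 100, 0.8 / 200), probe, 0) - ref)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_gte(min(orders), 1.9)
})

test_that("junction mass conservation holds in the pulsatile solve", {
  tr <- bifurcation_tree()
  inflow <- inflow_model(120)
  out <- assign_outlets(tr, inflow, hyperemia_factor = 0.24)
  sol <- solve_unsteady(tr, out, inflow,
                        config = solver_config(dt = 0.005, n_cycles = 12))
  expect_true(sol$converged)
  expect_lt(junction_residual(sol), 1e-8)
  expect_true(all(is.finite(sol$node_pressure)))
})
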