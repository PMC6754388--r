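test_that("parameter constructors enforce their invariants", {
  expect_error(kinetic_parameters(par_attenuation_fraction = 1),
               "par_attenuation_fraction")
  expect_error(kinetic_parameters(vmax_prod = -1))
  expect_error(transport_parameters(porosity = 0), "porosity")
  expect_error(transport_parameters(diffusivity = -1), "diffusivity")
  expect_error(grid_1d(n_nodes = 2))
  expect_error(boundary_conditions(top = -5))
  expect_error(boundary_conditions(bottom = "open"), "no_flux")
})

test_that("PAR profile follows the fractional-attenuation law", {
  k <- default_kinetics()
  g <- fine_grid()
  p <- compute_par_profile(k, g)
  expect_equal(p$value[1], 1500)
  # node 100 at the native spacing: 1500 * 0.99^100
  expect_equal(p$value[101], 1500 * 0.99^100, tolerance = 1e-12)
  expect_equal(p$value[101], 549.048, tolerance = 1e-4)
  expect_true(all(diff(p$value) < 0))
  # no attenuation -> constant light field
  k0 <- kinetic_parameters(par_attenuation_fraction = 0)
  expect_true(all(compute_par_profile(k0, g)$value == 1500))
  # non-commensurate spacing uses the continuous exponent
  g2 <- grid_1d(spacing = 0.1, n_nodes = 11)
  p2 <- compute_par_profile(k, g2)
  expect_equal(p2$value[11], 1500 * 0.99^(1 / 0.071), tolerance = 1e-12)
})

test_that("production kinetics saturate in light", {
  k <- default_kinetics()
  expect_equal(production_rate(0, k), 0)
  expect_equal(production_rate(k$km_prod, k), k$vmax_prod / 2)
  expect_equal(production_rate(1500, k), 1500 / 2500 * 2.1)
  par <- seq(0, 5000, by = 50)
  r <- production_rate(par, k)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < k$vmax_prod))
  expect_error(production_rate(-1, k), "non-negative")
})

test_that("respiration kinetics saturate in oxygen", {
  k <- default_kinetics()
  expect_equal(respiration_rate(0, k), 0)
  expect_equal(respiration_rate(250, k), 1.75 / 2)
  expect_equal(respiration_rate(1000, k), 1000 / 1250 * 1.75)
  o2 <- seq(0, 5000, by = 50)
  r <- respiration_rate(o2, k)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < k$vmax_resp))
  expect_error(respiration_rate(-1, k), "non-negative")
})

test_that("the stability guard rejects unstable configurations and accepts the defaults", {
  tr <- transport_parameters()
  g <- fine_grid()
  expect_equal(oxymat:::stability_number(tr, g, 1), 0.1984, tolerance = 1e-3)
  st <- model_state(rep(230, g$n_nodes), step_size = 3)
  expect_error(advance_one_step(st, default_kinetics(), tr, g,
                                boundary_conditions()),
               "0.5")
  expect_error(run_to_steady_state(NULL, default_kinetics(), tr, g,
                                   boundary_conditions(), dt = 3),
               "unstable")
  # error names the offending number (D'dt/dx^2 = 0.595)
  expect_error(run_to_steady_state(NULL, default_kinetics(), tr, g,
                                   boundary_conditions(), dt = 3),
               "0.595")
})

test_that("one FTCS step leaves trivial fields unchanged", {
  k <- kinetic_parameters(vmax_prod = 0, vmax_resp = 0)
  tr <- transport_parameters()
  g <- grid_1d(spacing = 0.142, n_nodes = 20)
  # uniform field with matching boundaries is a fixed point
  bc <- boundary_conditions(top = 230, bottom = 230)
  st <- model_state(rep(230, 20))
  expect_equal(advance_one_step(st, k, tr, g, bc)$o2, rep(230, 20))
  # interior of a linear profile is unchanged (zero second difference)
  lin <- seq(230, 100, length.out = 20)
  bc2 <- boundary_conditions(top = 230, bottom = 100)
  out <- advance_one_step(model_state(lin), k, tr, g, bc2)
  expect_equal(out$o2, lin, tolerance = 1e-12)
  expect_equal(out$time, 1)
})

test_that("the R step and the compiled loop advance identically", {
  k <- default_kinetics()
  tr <- transport_parameters()
  g <- grid_1d(spacing = 0.142, n_nodes = 30)
  bc <- boundary_conditions(top = 230, bottom = "no_flux")
  st <- model_state(seq(230, 50, length.out = 30), step_size = coarse_dt)
  r_state <- st
  for (i in 1:25)
    r_state <- advance_one_step(r_state, k, tr, g, bc)
  cpp_state <- run_fixed_steps(st, k, tr, g, bc, n_steps = 25, dt = coarse_dt)
  expect_equal(r_state$o2, cpp_state$o2, tolerance = 1e-12)
})

test_that("zero kinetics with equal fixed boundaries relax to equilibrium", {
  k <- kinetic_parameters(vmax_prod = 0, vmax_resp = 0)
  tr <- transport_parameters()
  g <- short_grid()
  bc <- boundary_conditions(top = 230, bottom = 230)
  res <- run_to_steady_state(model_state(runif(g$n_nodes, 0, 400),
                                         step_size = coarse_dt),
                             k, tr, g, bc, dt = coarse_dt)
  expect_true(res$converged)
  expect_equal(res$final_state$o2, rep(230, g$n_nodes), tolerance = 1e-2)
  expect_lt(abs(res$efflux_top), 1e-3)
})

test_that("fixed_1200 mode performs exactly 1200 one-second steps", {
  res <- run_to_steady_state(NULL, default_kinetics(),
                             transport_parameters(), fine_grid(),
                             boundary_conditions(), mode = "fixed_1200")
  expect_identical(res$iterations, 1200L)
  expect_equal(res$final_state$time, 1200)
  expect_true(is.na(res$converged))
})

test_that("non-convergence is reported, never silent", {
  expect_warning(
    run_to_steady_state(NULL, default_kinetics(), transport_parameters(),
                        coarse_grid(), boundary_conditions(),
                        dt = coarse_dt, max_steps = 50),
    "not reached")
})

test_that("with no respiration and a closed bottom, efflux equals integrated production", {
  k <- kinetic_parameters(vmax_resp = 0)
  tr <- transport_parameters()
  g <- short_grid()
  res <- run_to_steady_state(NULL, k, tr, g, boundary_conditions(),
                             dt = coarse_dt)
  expect_true(res$converged)
  expect_rel_equal(res$efflux_top, res$areal_net_production, 0.005)
  # independent oracle: trapezoidal integral of the production profile
  skip_if_not_installed("pracma")
  areal_trapz <- tr$porosity *
    pracma::trapz(g$depths * 1e-3, res$prod_profile * 1e-3) * 86400
  expect_rel_equal(res$efflux_top, areal_trapz, 0.02)
})

test_that("steady-state boundary fluxes balance depth-integrated net rates", {
  tr <- transport_parameters()
  g <- short_grid()
  for (k in random_kinetics(5, seed = 7)) {
    res <- run_to_steady_state(NULL, k, tr, g, boundary_conditions(),
                               dt = coarse_dt, tolerance = 1e-5)
    expect_true(res$converged)
    lhs <- res$efflux_top + res$flux_bottom
    expect_lt(abs(lhs - res$areal_net_production) /
                max(abs(res$areal_net_production), 0.05), 0.005)
  }
  # also with a fixed-concentration bottom
  res <- run_to_steady_state(NULL, random_kinetics(1, seed = 9)[[1]], tr, g,
                             boundary_conditions(top = 230, bottom = 0),
                             dt = coarse_dt)
  expect_rel_equal(res$efflux_top + res$flux_bottom,
                   res$areal_net_production, 0.005)
})

test_that("transient FTCS matches the analytic error-function diffusion solution", {
  skip_if_not_installed("pracma")
  # step initial condition: uniform 230 uM, surface suddenly held at 0
  k <- kinetic_parameters(vmax_prod = 0, vmax_resp = 0)
  tr <- transport_parameters()
  g <- fine_grid()
  bc <- boundary_conditions(top = 0, bottom = "no_flux")
  st <- model_state(c(0, rep(230, g$n_nodes - 1)))
  out <- run_fixed_steps(st, k, tr, g, bc, n_steps = 600, dt = 1)
  D <- 1e-9
  analytic <- 230 * pracma::erf(mm_to_m(g$depths) / (2 * sqrt(D * 600)))
  expect_lt(max(abs(out$o2 - analytic)), 0.01 * 230)
})

test_that("the direct Newton solve lands on the FTCS fixed point", {
  tr <- transport_parameters()
  g <- short_grid()
  bc <- boundary_conditions()
  for (k in random_kinetics(3, seed = 5)) {
    direct <- steady_state_direct(k, tr, g, bc)
    ftcs <- run_to_steady_state(NULL, k, tr, g, bc, dt = coarse_dt,
                                tolerance = 1e-5)
    expect_lt(max(abs(direct - ftcs$final_state$o2)), 0.01)
  }
  # fixed-concentration bottom closure agrees too
  k <- default_kinetics()
  bc2 <- boundary_conditions(top = 230, bottom = 50)
  direct <- steady_state_direct(k, tr, g, bc2)
  ftcs <- run_to_steady_state(NULL, k, tr, g, bc2, dt = coarse_dt,
                              tolerance = 1e-5)
  expect_lt(max(abs(direct - ftcs$final_state$o2)), 0.01)
})

test_that("grid refinement changes the steady-state efflux by < 2%", {
  k <- default_kinetics()
  tr <- transport_parameters()
  bc <- boundary_conditions()
  g1 <- grid_1d(spacing = 0.284, n_nodes = 36)   # 9.94 mm
  g2 <- grid_1d(spacing = 0.142, n_nodes = 71)   # same depth, dx halved
  r1 <- run_to_steady_state(NULL, k, tr, g1, bc, dt = 32)
  r2 <- run_to_steady_state(NULL, k, tr, g2, bc, dt = 8)
  expect_rel_equal(r2$efflux_top, r1$efflux_top, 0.02)
})

test_that("interface slope matches closed forms and window invariance on linear data", {
  p <- depth_profile(c(0, 0.071, 0.142, 0.213), c(230, 220, 210, 200),
                     "o2_concentration")
  expect_equal(interface_slope(p, 2), (220 - 230) / 0.071, tolerance = 1e-9)
  expect_equal(interface_slope(p, 2), -140.845, tolerance = 1e-3)
  # exactly linear: same slope for every window
  expect_equal(interface_slope(p, 3), interface_slope(p, 2), tolerance = 1e-9)
  expect_equal(interface_slope(p, 4), interface_slope(p, 2), tolerance = 1e-9)
  flat <- depth_profile(c(0, 1, 2), c(230, 230, 230), "o2_concentration")
  expect_equal(interface_slope(flat, 3), 0)
  expect_error(interface_slope(p, 5), "window")
  expect_error(interface_slope(p, 1), "window")
})

test_that("scenario simulations respect their boundary and light settings", {
  k <- default_kinetics()
  tr <- transport_parameters()
  g <- short_grid()
  # night + anoxic boundary + zero initial oxygen: nothing can appear
  kn <- k; kn$par_surface <- 0
  res0 <- run_to_steady_state(model_state(rep(0, g$n_nodes),
                                          step_size = coarse_dt),
                              kn, tr, g, boundary_conditions(top = 0),
                              dt = coarse_dt)
  expect_true(all(res0$final_state$o2 == 0))
  expect_equal(res0$efflux_top, 0)

  oxic <- simulate_scenario(k, tr, g, "oxic_day", dt = coarse_dt)
  anox <- simulate_scenario(k, tr, g, "anoxic_day", dt = coarse_dt)
  night <- simulate_scenario(k, tr, g, "night", dt = coarse_dt)
  # anoxic top boundary suppresses respiration -> at least as much efflux
  expect_gte(anox$efflux_top, oxic$efflux_top)
  # night mat consumes oxygen: influx from the atmosphere, O2 decreasing
  # into the mat at the interface
  expect_lt(night$efflux_top, 0)
  expect_lt(night$interface_slope, 0)
  expect_error(simulate_scenario(k, tr, g, "noon"))
})

test_that("anoxic boundary yields at least the oxic efflux across random kinetics", {
  tr <- transport_parameters()
  g <- short_grid()
  for (k in random_kinetics(5, seed = 11)) {
    oxic <- simulate_scenario(k, tr, g, "oxic_day", dt = coarse_dt)
    anox <- simulate_scenario(k, tr, g, "anoxic_day", dt = coarse_dt)
    expect_gte(anox$efflux_top, oxic$efflux_top - 1e-6)
  }
})

test_that("noiseless calibration recovers the generating vmax pair", {
  tr <- transport_parameters()
  g <- short_grid()
  bc <- boundary_conditions()
  ktrue <- default_kinetics()
  obs <- gen_o2_profile(ktrue, tr, g, bc, noise_sd = 0, dt = coarse_dt,
                        tolerance = 1e-5)
  fit <- calibrate_vmax(obs, kinetic_parameters(vmax_prod = 1,
                                                vmax_resp = 1),
                        tr, g, bc)
  expect_rel_equal(fit$vmax_prod, ktrue$vmax_prod, 0.01)
  expect_rel_equal(fit$vmax_resp, ktrue$vmax_resp, 0.01)
  expect_lt(fit$residual_norm, 1)
})

test_that("calibration degenerate inputs are flagged", {
  tr <- transport_parameters()
  g <- short_grid()
  bc <- boundary_conditions()
  flat <- depth_profile(g$depths, rep(230, g$n_nodes), "o2_concentration")
  expect_warning(calibrate_vmax(flat, default_kinetics(), tr, g, bc),
                 "flat")
  few <- depth_profile(c(0, 1, 2), c(230, 220, 210), "o2_concentration")
  expect_error(calibrate_vmax(few, default_kinetics(), tr, g, bc),
               "5 observed points")
  # all-zero oxygen under an anoxic boundary: no production signal
  zero <- depth_profile(g$depths, rep(0, g$n_nodes), "o2_concentration")
  fit <- suppressWarnings(
    calibrate_vmax(zero, kinetic_parameters(vmax_prod = 1, vmax_resp = 1),
                   tr, g, boundary_conditions(top = 0)))
  expect_lt(fit$vmax_prod, 0.05)
})

test_that("identity perturbation leaves the sensitivity table at zero", {
  k <- default_kinetics()
  tr <- transport_parameters()
  g <- short_grid()
  tab <- sensitivity_scan(k, tr, g, perturbation = 1e-12,
                          attenuation_levels = k$par_attenuation_fraction,
                          dt = coarse_dt)
  expect_true(all(abs(tab$slope_pct_change) < 0.1))
  expect_false(any(tab$undefined))
})

test_that("with a single boundary sink, efflux responds linearly to vmax_prod", {
  k <- kinetic_parameters(vmax_resp = 0)
  tr <- transport_parameters()
  g <- short_grid()
  base <- run_to_steady_state(NULL, k, tr, g, boundary_conditions(),
                              dt = coarse_dt)
  kup <- k; kup$vmax_prod <- k$vmax_prod * 1.1
  up <- run_to_steady_state(NULL, kup, tr, g, boundary_conditions(),
                            dt = coarse_dt)
  expect_rel_equal(up$efflux_top, 1.1 * base$efflux_top, 0.005)
})

test_that("sensitivity of the interface slope to ±10% is modest", {
  # soft consistency check: reported changes were a few percent at most
  k <- default_kinetics()
  tr <- transport_parameters()
  g <- short_grid()
  tab <- sensitivity_scan(k, tr, g, perturbation = 0.1, dt = coarse_dt)
  expect_true(all(is.finite(tab$slope_pct_change)))
  mult <- tab$parameter != "par_attenuation_fraction"
  expect_true(all(abs(tab$slope_pct_change[mult]) < 50))
  expect_setequal(unique(tab$parameter),
                  c("vmax_prod", "km_prod", "vmax_resp", "km_resp",
                    "par_surface", "par_attenuation_fraction"))
})
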