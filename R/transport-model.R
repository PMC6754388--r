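#' Light field through the mat
#'
#' PAR decays by a fixed fraction per attenuation step, i.e.
#' `PAR(z) = par_surface * (1 - f)^(z / attenuation_step)` with the exponent
#' taken continuously, so any grid spacing is accepted.
#'
#' @param kinetics a [kinetic_parameters()] object.
#' @param grid a [grid_1d()] object.
#' @return a [depth_profile()] of kind `"par"`.
#' @export
#' @examples
#' par <- compute_par_profile(kinetic_parameters(), grid_1d())
#' head(par)
compute_par_profile <- function(kinetics, grid) {
  stopifnot(inherits(kinetics, "kinetic_parameters"),
            inherits(grid, "grid_1d"))
  f <- kinetics$par_attenuation_fraction
  v <- kinetics$par_surface *
    (1 - f)^(grid$depths / kinetics$attenuation_step)
  depth_profile(grid$depths, v, kind = "par")
}

#' Volumetric O2 production from light
#'
#' Michaelis-Menten (saturating) photosynthesis-irradiance response:
#' `rate = PAR * Vmax,Prod / (Km,Prod + PAR)`.
#'
#' @param par PAR (µE m⁻² s⁻¹), scalar or vector; must be non-negative.
#' @param kinetics a [kinetic_parameters()] object.
#' @return volumetric production rate (nmol L⁻¹ s⁻¹).
#' @export
production_rate <- function(par, kinetics) {
  stopifnot(inherits(kinetics, "kinetic_parameters"))
  if (any(par < 0)) stop("PAR must be non-negative", call. = FALSE)
  denom <- kinetics$km_prod + par
  ifelse(denom > 0, par * kinetics$vmax_prod / denom, 0)
}

#' Volumetric O2 respiration
#'
#' Michaelis-Menten oxygen dependence: `rate = O2 * Vmax,Resp / (Km,Resp + O2)`.
#'
#' @param o2 O2 concentration (nmol L⁻¹), scalar or vector; non-negative.
#' @param kinetics a [kinetic_parameters()] object.
#' @return volumetric respiration rate (nmol L⁻¹ s⁻¹).
#' @export
respiration_rate <- function(o2, kinetics) {
  stopifnot(inherits(kinetics, "kinetic_parameters"))
  if (any(o2 < 0)) stop("O2 concentration must be non-negative", call. = FALSE)
  denom <- kinetics$km_resp + o2
  ifelse(denom > 0, o2 * kinetics$vmax_resp / denom, 0)
}

#' Model state of the O2 field
#'
#' @param o2 O2 concentration per node (µmol L⁻¹).
#' @param time elapsed simulated time (s).
#' @param step_size time step Δt (s).
#' @return an object of class `model_state`.
#' @export
model_state <- function(o2, time = 0, step_size = 1) {
  o2 <- as.numeric(o2)
  stopifnot(length(o2) >= 3L, time >= 0, step_size > 0)
  if (any(o2 < 0)) stop("concentrations must be non-negative", call. = FALSE)
  structure(list(o2 = o2, time = time, step_size = step_size),
            class = "model_state")
}

check_stability <- function(transport, grid, dt) {
  s <- stability_number(transport, grid, dt)
  if (s >= 0.5)
    stop(sprintf(
      "unstable configuration: D'*dt/dx^2 = %.4g >= 0.5 (D' = %g cm2/s, dt = %g s, dx = %g mm)",
      s, transport$diffusivity, dt, grid$spacing), call. = FALSE)
  s
}

#' Advance the explicit FTCS scheme by one time step
#'
#' Interior nodes are updated by `(production - respiration + diffusion) * dt`
#' with the diffusion term as the centred second difference
#' `D' (C[x-1] - 2 C[x] + C[x+1]) / dx^2`. The top node is held at the fixed
#' boundary concentration; the bottom node is either fixed or a zero-flux
#' mirror. Respiration at a node is capped at `C/dt` so one step cannot
#' consume more O2 than is present; residual negatives are clipped to 0 with
#' a warning.
#'
#' @param state a [model_state()].
#' @param kinetics,transport,grid,bc model configuration objects.
#' @return the updated `model_state`.
#' @export
advance_one_step <- function(state, kinetics, transport, grid, bc) {
  stopifnot(inherits(state, "model_state"), inherits(grid, "grid_1d"),
            inherits(bc, "boundary_conditions"))
  if (length(state$o2) != grid$n_nodes)
    stop("state length does not match grid", call. = FALSE)
  dt <- state$step_size
  check_stability(transport, grid, dt)
  dx <- mm_to_m(grid$spacing)
  D <- cm2_s_to_m2_s(transport$diffusivity)
  n <- grid$n_nodes
  c0 <- state$o2
  c0[1] <- bc$top
  if (is.numeric(bc$bottom)) c0[n] <- bc$bottom

  par <- compute_par_profile(kinetics, grid)$value
  prod <- nM_s_to_uM_s(production_rate(par, kinetics))          # uM/s
  # concentrations are in uM; respiration kinetics take nM
  resp <- nM_s_to_uM_s(respiration_rate(c0 * 1e3, kinetics))
  resp <- pmin(resp, c0 / dt)

  lap <- numeric(n)
  lap[2:(n - 1)] <- D * (c0[1:(n - 2)] - 2 * c0[2:(n - 1)] + c0[3:n]) / dx^2
  cn <- c0
  cn[2:(n - 1)] <- c0[2:(n - 1)] +
    dt * (prod[2:(n - 1)] - resp[2:(n - 1)] + lap[2:(n - 1)])
  if (is.numeric(bc$bottom)) {
    cn[n] <- bc$bottom
  } else {
    cn[n] <- c0[n] + dt * (prod[n] - resp[n] + D * (c0[n - 1] - c0[n]) / dx^2)
  }
  cn[1] <- bc$top
  if (any(cn < 0)) {
    warning("negative concentrations clipped to 0", call. = FALSE)
    cn[cn < 0] <- 0
  }
  model_state(cn, time = state$time + dt, step_size = dt)
}

#' Run the FTCS model to (approximate) steady state
#'
#' Two modes are provided. `"fixed_1200"` performs exactly 1200
#' iterations of 1 s, the fixed procedure used to parameterize the mat model.
#' `"converge"` (default) iterates until the largest per-node concentration
#' change per second falls below `tolerance`, or `max_steps` is reached, in
#' which case the result is flagged non-converged with a warning.
#'
#' @param initial a [model_state()], or `NULL` for a uniform field at the top
#'   boundary concentration.
#' @param kinetics,transport,grid,bc model configuration objects.
#' @param mode `"converge"` or `"fixed_1200"`.
#' @param tolerance convergence tolerance on the residual
#'   (nmol L⁻¹ s⁻¹; default 1e-4).
#' @param max_steps iteration cap in converge mode.
#' @param dt time step (s); checked against the FTCS stability bound
#'   `D' dt / dx^2 < 0.5`.
#' @param slope_window nodes used for the interface slope (default 2).
#' @return an object of class `steady_state_result`: the final
#'   [model_state()], iteration count, residual (nM s⁻¹), `converged` flag,
#'   `interface_slope` (µmol L⁻¹ mm⁻¹), `efflux_top` and `flux_bottom`
#'   (mmol m⁻² d⁻¹, positive out of the mat), per-node `prod_profile` and
#'   `resp_profile` (nmol L⁻¹ s⁻¹) and `areal_net_production`
#'   (mmol m⁻² d⁻¹).
#' @export
#' @examples
#' res <- run_to_steady_state(
#'   kinetics = kinetic_parameters(), transport = transport_parameters(),
#'   grid = grid_1d(n_nodes = 50), bc = boundary_conditions(),
#'   mode = "fixed_1200")
#' res$efflux_top
run_to_steady_state <- function(initial = NULL, kinetics, transport, grid, bc,
                                mode = c("converge", "fixed_1200"),
                                tolerance = 1e-4, max_steps = 1e6, dt = 1,
                                slope_window = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(kinetics, "kinetic_parameters"),
            inherits(transport, "transport_parameters"),
            inherits(grid, "grid_1d"),
            inherits(bc, "boundary_conditions"))
  check_stability(transport, grid, dt)
  if (is.null(initial))
    initial <- model_state(rep(bc$top, grid$n_nodes), step_size = dt)
  if (length(initial$o2) != grid$n_nodes)
    stop("initial state length does not match grid", call. = FALSE)

  par <- compute_par_profile(kinetics, grid)$value
  bottom_fixed <- is.numeric(bc$bottom)
  if (mode == "fixed_1200") {
    tol_uM <- 0
    max_steps <- 1200L
  } else {
    tol_uM <- nM_s_to_uM_s(tolerance)
  }
  out <- ftcs_run_cpp(
    o2 = initial$o2, par = par,
    vmax_prod = nM_s_to_uM_s(kinetics$vmax_prod), km_prod = kinetics$km_prod,
    vmax_resp = nM_s_to_uM_s(kinetics$vmax_resp),
    km_resp = kinetics$km_resp / 1e3,             # nM -> uM
    D = cm2_s_to_m2_s(transport$diffusivity), dx = mm_to_m(grid$spacing),
    dt = dt, top = bc$top, bottom_fixed = bottom_fixed,
    bottom_value = if (bottom_fixed) bc$bottom else 0,
    max_steps = as.integer(max_steps), tol = tol_uM)

  if (mode == "converge" && !out$converged)
    warning(sprintf(
      "steady state not reached: residual %.3g nM/s after %d steps (tolerance %.3g)",
      uM_s_to_nM_s(out$residual), out$steps, tolerance), call. = FALSE)
  if (out$clipped > 0)
    warning(sprintf("%d negative concentrations clipped to 0", out$clipped),
            call. = FALSE)

  final <- model_state(out$o2, time = initial$time + out$steps * dt,
                       step_size = dt)
  summarize_steady_state(final, kinetics, transport, grid, bc,
                         iterations = out$steps,
                         residual = uM_s_to_nM_s(out$residual),
                         converged = if (mode == "converge") out$converged else NA,
                         mode = mode, slope_window = slope_window)
}

#' Advance the model by a fixed number of steps
#'
#' Thin wrapper over the compiled FTCS core for transient experiments (e.g.
#' comparing against analytic diffusion solutions at a fixed time).
#'
#' @param initial a [model_state()], or `NULL` for a uniform field at the
#'   top boundary value.
#' @param kinetics,transport,grid,bc model configuration objects.
#' @param n_steps number of steps to take.
#' @param dt time step (s).
#' @return the final [model_state()].
#' @export
run_fixed_steps <- function(initial = NULL, kinetics, transport, grid, bc,
                            n_steps, dt = 1) {
  check_stability(transport, grid, dt)
  if (is.null(initial))
    initial <- model_state(rep(bc$top, grid$n_nodes), step_size = dt)
  par <- compute_par_profile(kinetics, grid)$value
  bottom_fixed <- is.numeric(bc$bottom)
  out <- ftcs_run_cpp(
    o2 = initial$o2, par = par,
    vmax_prod = nM_s_to_uM_s(kinetics$vmax_prod), km_prod = kinetics$km_prod,
    vmax_resp = nM_s_to_uM_s(kinetics$vmax_resp),
    km_resp = kinetics$km_resp / 1e3,
    D = cm2_s_to_m2_s(transport$diffusivity), dx = mm_to_m(grid$spacing),
    dt = dt, top = bc$top, bottom_fixed = bottom_fixed,
    bottom_value = if (bottom_fixed) bc$bottom else 0,
    max_steps = as.integer(n_steps), tol = 0)
  model_state(out$o2, time = initial$time + out$steps * dt, step_size = dt)
}

summarize_steady_state <- function(final, kinetics, transport, grid, bc,
                                   iterations, residual, converged, mode,
                                   slope_window = 2L) {
  o2 <- final$o2
  n <- grid$n_nodes
  dx <- mm_to_m(grid$spacing)
  D <- cm2_s_to_m2_s(transport$diffusivity)
  phi <- transport$porosity
  bottom_fixed <- is.numeric(bc$bottom)

  par <- compute_par_profile(kinetics, grid)$value
  prod_nM <- production_rate(par, kinetics)
  resp_nM <- pmin(respiration_rate(o2 * 1e3, kinetics),
                  uM_s_to_nM_s(o2 / final$step_size))

  # discrete fluxes across the boundary faces (uM == mmol m^-3)
  efflux_top <- phi * D * (o2[2] - o2[1]) / dx * 86400
  flux_bottom <- if (bottom_fixed)
    -phi * D * (o2[n] - o2[n - 1]) / dx * 86400 else 0

  # reaction is applied on interior nodes (+ bottom node when no-flux);
  # at steady state this discrete sum balances the boundary fluxes exactly
  active <- if (bottom_fixed) 2:(n - 1) else 2:n
  net_uM_s <- nM_s_to_uM_s(prod_nM - resp_nM)
  areal_net <- phi * sum(net_uM_s[active]) * dx * 86400

  structure(
    list(final_state = final,
         iterations = iterations, residual = residual,
         converged = converged, mode = mode,
         o2_profile = depth_profile(grid$depths, o2, "o2_concentration"),
         interface_slope = slope_from_profile(o2, grid$depths, slope_window),
         efflux_top = efflux_top, flux_bottom = flux_bottom,
         prod_profile = prod_nM, resp_profile = resp_nM,
         areal_net_production = areal_net,
         kinetics = kinetics, transport = transport, grid = grid, bc = bc),
    class = "steady_state_result")
}

slope_from_profile <- function(values, depths, window) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2", call. = FALSE)
  if (window > length(values))
    stop("window exceeds the number of nodes", call. = FALSE)
  i <- seq_len(window)
  if (window == 2L) {
    (values[2] - values[1]) / (depths[2] - depths[1])
  } else {
    unname(stats::coef(stats::lm(values[i] ~ depths[i]))[2])
  }
}

#' O2 slope across the mat-atmosphere interface
#'
#' Least-squares slope of the concentration profile over the top `window`
#' nodes; with the default window of 2 this is the two-point difference.
#'
#' @param result a `steady_state_result` or a [depth_profile()] of O2.
#' @param window number of top nodes to use (>= 2).
#' @return slope (µmol L⁻¹ mm⁻¹); positive when O2 increases downward.
#' @export
interface_slope <- function(result, window = 2L) {
  if (inherits(result, "steady_state_result")) {
    p <- result$o2_profile
  } else if (inherits(result, "depth_profile")) {
    p <- result
  } else stop("need a steady_state_result or depth_profile", call. = FALSE)
  slope_from_profile(p$value, p$depth_mm, window)
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result>\n")
  cat(sprintf("  mode %s: %d iterations, residual %.3g nM/s%s\n",
              x$mode, x$iterations, x$residual,
              if (isTRUE(x$converged)) " (converged)"
              else if (isFALSE(x$converged)) " (NOT converged)" else ""))
  cat(sprintf("  interface slope     %.4g uM/mm\n", x$interface_slope))
  cat(sprintf("  efflux (top)        %.4g mmol/m2/d\n", x$efflux_top))
  cat(sprintf("  flux out (bottom)   %.4g mmol/m2/d\n", x$flux_bottom))
  cat(sprintf("  areal net production %.4g mmol/m2/d\n",
              x$areal_net_production))
  invisible(x)
}

#' Simulate a standard boundary/light scenario
#'
#' * `oxic_day`: air-equilibrated top boundary (default 230 µM), full light.
#' * `anoxic_day`: the oxic steady state is computed first, then the top
#'   boundary is set to 0 µM and the model re-run from that state — the
#'   procedure used to estimate effluxes to an anoxic atmosphere.
#' * `night`: surface PAR set to 0 (respiration only), oxic top boundary.
#'
#' @param kinetics,transport,grid configuration objects.
#' @param scenario one of `"oxic_day"`, `"anoxic_day"`, `"night"`.
#' @param top_oxic top boundary concentration for the oxic cases (µmol L⁻¹).
#' @param bottom bottom closure, as in [boundary_conditions()].
#' @param ... passed to [run_to_steady_state()] (`mode`, `tolerance`, ...).
#' @return a `steady_state_result` with a `scenario` element.
#' @export
simulate_scenario <- function(kinetics, transport, grid,
                              scenario = c("oxic_day", "anoxic_day", "night"),
                              top_oxic = 230, bottom = "no_flux", ...) {
  scenario <- match.arg(scenario)
  res <- switch(scenario,
    oxic_day = run_to_steady_state(
      NULL, kinetics, transport, grid,
      boundary_conditions(top = top_oxic, bottom = bottom), ...),
    night = {
      k <- kinetics
      k$par_surface <- 0
      run_to_steady_state(
        NULL, k, transport, grid,
        boundary_conditions(top = top_oxic, bottom = bottom), ...)
    },
    anoxic_day = {
      oxic <- run_to_steady_state(
        NULL, kinetics, transport, grid,
        boundary_conditions(top = top_oxic, bottom = bottom), ...)
      run_to_steady_state(
        oxic$final_state, kinetics, transport, grid,
        boundary_conditions(top = 0, bottom = bottom), ...)
    })
  res$scenario <- scenario
  res
}

#' Fit the maximal rates to an observed O2 profile
#'
#' Least-squares calibration of `vmax_prod` and `vmax_resp` (non-negative)
#' against a measured or synthetic O2 depth profile, resampled onto the model
#' grid. All other parameters are held fixed. Because the steady-state field
#' is close to linear in the two maximal rates (respiration is light- and
#' O2-saturated over most of the oxic zone), a damped Gauss-Newton iteration
#' with finite-difference sensitivities converges in a handful of forward
#' runs.
#'
#' @param observed a [depth_profile()] of O2 with at least 5 points.
#' @param kinetics starting [kinetic_parameters()]; `vmax_prod`/`vmax_resp`
#'   are the free parameters.
#' @param transport,grid,bc model configuration objects.
#' @param solver forward steady-state solver: `"direct"` (Newton, see
#'   [steady_state_direct()]; default) or `"ftcs"` (explicit relaxation).
#'   Both converge to the same discrete fixed point; the direct path makes
#'   the many forward solves of the fit cheap.
#' @param tolerance forward-run residual tolerance (nmol L⁻¹ s⁻¹). Tighter
#'   than the simulation default because residual drift in the forward
#'   profiles biases the least-squares objective.
#' @param max_iter damped Gauss-Newton iteration cap.
#' @param ... passed to [run_to_steady_state()] when `solver = "ftcs"`.
#' @return a list with the fitted `kinetics`, the fitted
#'   `vmax_prod`/`vmax_resp` (nmol L⁻¹ s⁻¹), `residual_norm` (µM, root sum
#'   of squares), the iteration count and a `convergence` code (0 =
#'   converged).
#' @export
calibrate_vmax <- function(observed, kinetics, transport, grid, bc,
                           solver = c("direct", "ftcs"),
                           tolerance = 1e-5, max_iter = 25L, ...) {
  solver <- match.arg(solver)
  stopifnot(inherits(observed, "depth_profile"))
  if (profile_kind(observed) != "o2_concentration")
    stop("observed profile must be an O2 concentration profile", call. = FALSE)
  if (nrow(observed) < 5L)
    stop("need at least 5 observed points", call. = FALSE)
  target <- resample_profile(observed, grid$depths)
  if (stats::sd(target) == 0)
    warning("degenerate (flat) observed profile: objective is nearly flat",
            call. = FALSE)

  forward <- function(p) {
    k <- kinetics
    k$vmax_prod <- p[1]
    k$vmax_resp <- p[2]
    if (solver == "direct") {
      suppressWarnings(
        steady_state_direct(k, transport, grid, bc, tol = tolerance))
    } else {
      res <- suppressWarnings(
        run_to_steady_state(NULL, k, transport, grid, bc,
                            tolerance = tolerance, ...))
      res$final_state$o2
    }
  }

  p <- pmax(c(kinetics$vmax_prod, kinetics$vmax_resp), 1e-3)
  y0 <- forward(p)
  ssr <- sum((y0 - target)^2)
  code <- 1L
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dp <- pmax(0.01 * p, 0.002)
    J <- cbind((forward(p + c(dp[1], 0)) - y0) / dp[1],
               (forward(p + c(0, dp[2])) - y0) / dp[2])
    step <- tryCatch(qr.solve(J, target - y0),
                     error = function(e) c(0, 0))
    if (all(step == 0)) { code <- 2L; break }
    # damped update with non-negativity clipping
    lambda <- 1
    repeat {
      pn <- pmax(p + lambda * step, 0)
      yn <- forward(pn)
      ssr_n <- sum((yn - target)^2)
      if (ssr_n <= ssr || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    moved <- max(abs(pn - p) / pmax(p, 1e-6))
    p <- pn; y0 <- yn; ssr <- ssr_n
    if (moved < 1e-4) { code <- 0L; break }
  }
  k <- kinetics
  k$vmax_prod <- p[1]
  k$vmax_resp <- p[2]
  list(kinetics = k, vmax_prod = p[1], vmax_resp = p[2],
       residual_norm = sqrt(ssr), iterations = iter, convergence = code)
}

#' Sensitivity of the interface slope to the kinetic parameters
#'
#' Each variable parameter (`vmax_prod`, `km_prod`, `vmax_resp`, `km_resp`,
#' `par_surface`) is perturbed by ±`perturbation` (multiplicative); the PAR
#' attenuation fraction is instead set to the absolute levels 0 and 0.05 per
#' depth step. The model is re-run to steady state for each perturbation and
#' the percent change of the interface slope reported.
#'
#' @param kinetics,transport,grid configuration objects.
#' @param perturbation fractional change (> 0), default 0.1.
#' @param scenario passed to [simulate_scenario()].
#' @param attenuation_levels absolute attenuation fractions to test.
#' @param ... passed to [simulate_scenario()] / [run_to_steady_state()].
#' @return a data.frame with columns `parameter`, `direction`, `value`,
#'   `slope`, `slope_pct_change` (`NA` with a flag column `undefined` when
#'   the baseline slope is 0).
#' @export
sensitivity_scan <- function(kinetics, transport, grid, perturbation = 0.1,
                             scenario = "oxic_day",
                             attenuation_levels = c(0, 0.05), ...) {
  stopifnot(perturbation > 0)
  base <- simulate_scenario(kinetics, transport, grid, scenario, ...)
  s0 <- base$interface_slope
  rows <- list()
  mult_params <- c("vmax_prod", "km_prod", "vmax_resp", "km_resp",
                   "par_surface")
  for (p in mult_params) {
    for (dir in c(-1, 1)) {
      k <- kinetics
      k[[p]] <- k[[p]] * (1 + dir * perturbation)
      r <- simulate_scenario(k, transport, grid, scenario, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p,
        direction = if (dir > 0) sprintf("+%g%%", 100 * perturbation)
                    else sprintf("-%g%%", 100 * perturbation),
        value = k[[p]], slope = r$interface_slope,
        stringsAsFactors = FALSE)
    }
  }
  for (lev in attenuation_levels) {
    k <- kinetics
    k$par_attenuation_fraction <- lev
    r <- simulate_scenario(k, transport, grid, scenario, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "par_attenuation_fraction",
      direction = sprintf("=%g", lev),
      value = lev, slope = r$interface_slope,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$undefined <- s0 == 0
  out$slope_pct_change <- ifelse(out$undefined, NA_real_,
                                 100 * (out$slope - s0) / s0)
  attr(out, "baseline_slope") <- s0
  out
}
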