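# run expr with a local, seeded RNG stream; caller's RNG state is untouched
with_seed_ <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic O2 microprofile
#'
#' Runs the forward reaction-transport model to steady state (converge mode)
#' and adds independent Gaussian sensor noise, clipped at 0. The generating
#' parameters are embedded in the profile metadata so closed-loop
#' parameter-recovery experiments can compare against ground truth.
#'
#' @param kinetics,transport,grid,bc model configuration objects.
#' @param noise_sd Gaussian sensor noise standard deviation (µmol L⁻¹).
#' @param seed integer seed; the same parameters + seed give bitwise-identical
#'   output.
#' @param ... passed to [run_to_steady_state()].
#' @return a [depth_profile()] of O2 with metadata (`vmax_prod`,
#'   `vmax_resp`, `noise_sd`, `seed`, ...).
#' @export
#' @examples
#' p <- gen_o2_profile(kinetic_parameters(), transport_parameters(),
#'                     grid_1d(n_nodes = 60), boundary_conditions(),
#'                     noise_sd = 2, seed = 1)
gen_o2_profile <- function(kinetics, transport, grid, bc,
                           noise_sd = 0, seed = 1L, ...) {
  stopifnot(noise_sd >= 0)
  res <- run_to_steady_state(NULL, kinetics, transport, grid, bc, ...)
  if (isFALSE(res$converged))
    stop("forward model did not converge; cannot generate profile",
         call. = FALSE)
  v <- res$final_state$o2
  if (noise_sd > 0)
    v <- with_seed_(seed, pmax(0, v + stats::rnorm(length(v), 0, noise_sd)))
  depth_profile(grid$depths, v, "o2_concentration",
                metadata = list(
                  generator = "gen_o2_profile", seed = seed,
                  noise_sd = noise_sd,
                  vmax_prod = kinetics$vmax_prod,
                  vmax_resp = kinetics$vmax_resp,
                  km_prod = kinetics$km_prod, km_resp = kinetics$km_resp,
                  par_surface = kinetics$par_surface,
                  top_bc = bc$top))
}

#' Diel schedule of surface PAR
#'
#' @param times character clock times over 24 h.
#' @param par_surface PAR at each time (µE m⁻² s⁻¹, >= 0); night entries 0.
#' @return an object of class `diel_schedule`.
#' @export
diel_schedule <- function(times = c("03:00", "06:00", "09:00", "12:00",
                                    "15:00", "18:00", "21:00", "00:00"),
                          par_surface = c(0, 200, 1000, 1500,
                                          1400, 300, 0, 0)) {
  stopifnot(length(times) == length(par_surface), all(par_surface >= 0))
  structure(list(times = times, par_surface = par_surface),
            class = "diel_schedule")
}

#' Synthetic diel series of O2 profiles
#'
#' One steady-state profile per schedule entry with the surface PAR
#' overridden; night entries (PAR 0) give respiration-only profiles.
#'
#' @param kinetics,transport,grid,bc model configuration objects.
#' @param schedule a [diel_schedule()].
#' @param noise_sd,seed as in [gen_o2_profile()]; each entry uses an offset
#'   of the base seed.
#' @param ... passed to [run_to_steady_state()].
#' @return named list of [depth_profile()]s, one per schedule time.
#' @export
gen_diel_profiles <- function(kinetics, transport, grid, bc, schedule,
                              noise_sd = 0, seed = 1L, ...) {
  stopifnot(inherits(schedule, "diel_schedule"))
  out <- vector("list", length(schedule$times))
  names(out) <- schedule$times
  for (i in seq_along(schedule$times)) {
    k <- kinetics
    k$par_surface <- schedule$par_surface[i]
    out[[i]] <- gen_o2_profile(k, transport, grid, bc,
                               noise_sd = noise_sd, seed = seed + i, ...)
    md <- attr(out[[i]], "metadata")
    md$time_of_day <- schedule$times[i]
    attr(out[[i]], "metadata") <- md
  }
  out
}

#' Synthetic organic-carbon depth profile
#'
#' Exponential decline from a surface value to a deep asymptote:
#' `wt(z) = deep_wt + (surface_wt - deep_wt) * exp(-z / decay_depth)`,
#' plus optional Gaussian noise, clipped at 0. Defaults follow the measured
#' pattern: ~12 wt% at the surface declining to ~1 wt% at depth.
#'
#' @param surface_wt surface organic carbon (wt%), default 12.
#' @param deep_wt deep asymptote (wt%), default 1; must satisfy
#'   `surface_wt >= deep_wt >= 0`.
#' @param decay_depth e-folding depth (mm, > 0), default 5.
#' @param grid a [grid_1d()] giving the sampling depths.
#' @param noise_sd Gaussian noise sd (wt%).
#' @param seed integer seed.
#' @return a [depth_profile()] of kind `"organic_carbon"`.
#' @export
gen_wtc_profile <- function(surface_wt = 12, deep_wt = 1, decay_depth = 5,
                            grid = grid_1d(), noise_sd = 0, seed = 1L) {
  if (!(surface_wt >= deep_wt && deep_wt >= 0))
    stop("need surface_wt >= deep_wt >= 0", call. = FALSE)
  if (decay_depth <= 0) stop("decay_depth must be > 0", call. = FALSE)
  stopifnot(noise_sd >= 0)
  z <- grid$depths
  w <- deep_wt + (surface_wt - deep_wt) * exp(-z / decay_depth)
  if (noise_sd > 0)
    w <- with_seed_(seed, pmax(0, w + stats::rnorm(length(w), 0, noise_sd)))
  depth_profile(z, w, "organic_carbon",
                metadata = list(generator = "gen_wtc_profile", seed = seed,
                                surface_wt = surface_wt, deep_wt = deep_wt,
                                decay_depth = decay_depth,
                                noise_sd = noise_sd))
}

#' Synthetic per-layer cell counts
#'
#' Log-uniform draws within the density range, sorted so counts are
#' non-increasing with depth, as observed in the mat (1e8-1e9 cells cm⁻³,
#' decreasing downward).
#'
#' @param layers list of depth ranges `c(from, to)` in mm, ordered and
#'   non-overlapping.
#' @param density_range `c(min, max)` cells cm⁻³, default `c(1e8, 1e9)`.
#' @param seed integer seed.
#' @return data.frame with `layer_top_mm`, `layer_bottom_mm`,
#'   `cells_per_cm3`.
#' @export
gen_cell_counts <- function(layers, density_range = c(1e8, 1e9), seed = 1L) {
  if (length(layers) == 0L) stop("empty layer list", call. = FALSE)
  stopifnot(length(density_range) == 2L,
            density_range[1] > 0, density_range[1] <= density_range[2])
  tops <- vapply(layers, `[`, numeric(1), 1L)
  bots <- vapply(layers, `[`, numeric(1), 2L)
  if (any(bots <= tops)) stop("each layer needs from < to", call. = FALSE)
  if (any(diff(tops) <= 0) || any(tops[-1] < bots[-length(bots)]))
    stop("layers must be ordered and non-overlapping", call. = FALSE)
  draws <- with_seed_(
    seed,
    10^stats::runif(length(layers), log10(density_range[1]),
                    log10(density_range[2])))
  data.frame(layer_top_mm = tops, layer_bottom_mm = bots,
             cells_per_cm3 = sort(draws, decreasing = TRUE))
}
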