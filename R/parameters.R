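#' Photosynthesis and respiration kinetics
#'
#' Michaelis-Menten kinetic constants for volumetric oxygen production
#' (saturating in photosynthetically active radiation, PAR) and aerobic
#' respiration (saturating in O2), together with the surface PAR and its
#' attenuation rule: PAR drops by a fixed fraction per fixed depth step,
#' i.e. an exponential light field.
#'
#' Defaults are the mat model parameterization: Vmax,Prod 2.1 nM s⁻¹,
#' Km,Prod 1000 µE m⁻² s⁻¹, Vmax,Resp 1.75 nM s⁻¹, Km,Resp 250 nM,
#' surface PAR 1500 µE m⁻² s⁻¹ decreasing by 1% every 0.071 mm.
#'
#' @param vmax_prod maximal volumetric O2 production rate (nmol L⁻¹ s⁻¹).
#' @param km_prod light half-saturation constant (µE m⁻² s⁻¹).
#' @param vmax_resp maximal volumetric respiration rate (nmol L⁻¹ s⁻¹).
#' @param km_resp O2 half-saturation constant (nmol L⁻¹).
#' @param par_surface PAR at the mat surface (µE m⁻² s⁻¹).
#' @param par_attenuation_fraction fractional PAR loss per depth step, in
#'   `[0, 1)`.
#' @param attenuation_step depth step of the attenuation rule (mm).
#' @return an object of class `kinetic_parameters`.
#' @export
#' @examples
#' k <- kinetic_parameters()
#' production_rate(1500, k)
kinetic_parameters <- function(vmax_prod = 2.1,
                               km_prod = 1000,
                               vmax_resp = 1.75,
                               km_resp = 250,
                               par_surface = 1500,
                               par_attenuation_fraction = 0.01,
                               attenuation_step = 0.071) {
  stopifnot(
    is.numeric(vmax_prod), length(vmax_prod) == 1L, vmax_prod >= 0,
    is.numeric(km_prod), km_prod >= 0,
    is.numeric(vmax_resp), vmax_resp >= 0,
    is.numeric(km_resp), km_resp >= 0,
    is.numeric(par_surface), par_surface >= 0,
    attenuation_step > 0
  )
  if (par_attenuation_fraction < 0 || par_attenuation_fraction >= 1)
    stop("par_attenuation_fraction must be in [0, 1)", call. = FALSE)
  structure(
    list(vmax_prod = vmax_prod, km_prod = km_prod,
         vmax_resp = vmax_resp, km_resp = km_resp,
         par_surface = par_surface,
         par_attenuation_fraction = par_attenuation_fraction,
         attenuation_step = attenuation_step),
    class = "kinetic_parameters"
  )
}

#' Porewater transport parameters
#'
#' @param porosity volume fraction of pore water, in `(0, 1]`. Default 0.97.
#' @param diffusivity tortuosity-corrected molecular diffusivity D'
#'   (cm² s⁻¹). Default 1e-5.
#' @return an object of class `transport_parameters`.
#' @export
transport_parameters <- function(porosity = 0.97, diffusivity = 1e-5) {
  stopifnot(is.numeric(porosity), is.numeric(diffusivity))
  if (porosity <= 0 || porosity > 1)
    stop("porosity must be in (0, 1]", call. = FALSE)
  if (diffusivity <= 0)
    stop("diffusivity must be > 0", call. = FALSE)
  structure(list(porosity = porosity, diffusivity = diffusivity),
            class = "transport_parameters")
}

#' Uniform 1D depth grid
#'
#' Node 0 sits at the mat-atmosphere interface, depth positive downward.
#' The default spans 20 mm at the light-attenuation step of 0.071 mm.
#'
#' @param spacing node separation (mm).
#' @param n_nodes node count (>= 3).
#' @return an object of class `grid_1d` with a `depths` vector (mm).
#' @export
grid_1d <- function(spacing = 0.071, n_nodes = 283L) {
  stopifnot(is.numeric(spacing), spacing > 0, n_nodes >= 3)
  n_nodes <- as.integer(n_nodes)
  structure(
    list(spacing = spacing, n_nodes = n_nodes,
         depths = spacing * (seq_len(n_nodes) - 1)),
    class = "grid_1d"
  )
}

#' Boundary conditions for the O2 field
#'
#' The top boundary (mat-atmosphere interface) is always a fixed
#' concentration; the bottom (mat-rock) is either a zero-flux closure or a
#' fixed concentration.
#'
#' @param top fixed concentration at node 0 (µmol L⁻¹).
#' @param bottom `"no_flux"` or a fixed concentration (µmol L⁻¹).
#' @return an object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(top = 230, bottom = "no_flux") {
  stopifnot(is.numeric(top), length(top) == 1L, top >= 0)
  if (is.character(bottom)) {
    if (!identical(bottom, "no_flux"))
      stop("bottom must be \"no_flux\" or a non-negative concentration",
           call. = FALSE)
  } else {
    stopifnot(is.numeric(bottom), length(bottom) == 1L, bottom >= 0)
  }
  structure(list(top = top, bottom = bottom), class = "boundary_conditions")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Michaelis-Menten O2 kinetics\n")
  cat(sprintf("  production : Vmax %.4g nM/s, Km %.4g uE/m2/s\n",
              x$vmax_prod, x$km_prod))
  cat(sprintf("  respiration: Vmax %.4g nM/s, Km %.4g nM\n",
              x$vmax_resp, x$km_resp))
  cat(sprintf("  PAR        : %.4g uE/m2/s surface, -%.3g%% per %.4g mm\n",
              x$par_surface, 100 * x$par_attenuation_fraction,
              x$attenuation_step))
  invisible(x)
}

# stability number of the explicit scheme; must stay < 0.5
stability_number <- function(transport, grid, dt) {
  cm2_s_to_m2_s(transport$diffusivity) * dt / mm_to_m(grid$spacing)^2
}
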