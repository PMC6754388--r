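# constants used by the global scaling calculators
DAYS_PER_YEAR <- 365
MOLAR_MASS_C <- 12.011          # g/mol
EARTH_SURFACE_KM2 <- 5.10e8     # total Earth surface area

#' Land-coverage scenario for global extrapolation
#'
#' @param land_area land surface area (km²).
#' @param coverage_fraction fraction of the land covered by mats, in
#'   `[0, 1]`.
#' @param areal_rate areal rate to scale (mmol m⁻² d⁻¹).
#' @param label free-form scenario label.
#' @return an object of class `coverage_scenario`.
#' @export
coverage_scenario <- function(land_area = 2.5e7, coverage_fraction,
                              areal_rate, label = "") {
  stopifnot(is.numeric(land_area), land_area > 0,
            is.numeric(areal_rate), areal_rate >= 0)
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("coverage_fraction must be in [0, 1]", call. = FALSE)
  structure(list(land_area = land_area,
                 coverage_fraction = coverage_fraction,
                 areal_rate = areal_rate, label = label),
            class = "coverage_scenario")
}

#' Convert a daily areal rate to annual forms
#'
#' @param areal_rate rate in mmol m⁻² d⁻¹ (>= 0).
#' @return list with `mol_m2_yr` (mol m⁻² yr⁻¹) and `Mmol_km2_yr`
#'   (Mmol km⁻² yr⁻¹); e.g. 38 mmol m⁻² d⁻¹ gives 13.87 Mmol km⁻² yr⁻¹.
#' @export
areal_to_annual <- function(areal_rate) {
  stopifnot(is.numeric(areal_rate), all(areal_rate >= 0))
  mol_m2_yr <- areal_rate * 1e-3 * DAYS_PER_YEAR
  list(mol_m2_yr = mol_m2_yr,
       Mmol_km2_yr = mol_m2_yr * 1e6 / 1e6)  # mol/m2/yr * 1e6 m2/km2 / 1e6 mol/Mmol
}

#' Global flux under a coverage scenario
#'
#' `areal rate (annualized) x land area x coverage`, in Tmol yr⁻¹.
#'
#' @param scenario a [coverage_scenario()].
#' @return global flux (Tmol yr⁻¹).
#' @export
#' @examples
#' global_production(coverage_scenario(2.5e7, 0.05, 38))  # ~17 Tmol/yr
global_production <- function(scenario) {
  stopifnot(inherits(scenario, "coverage_scenario"))
  mol_km2_yr <- areal_to_annual(scenario$areal_rate)$mol_m2_yr * 1e6
  mol_km2_yr * scenario$land_area * scenario$coverage_fraction / 1e12
}

#' Cellular carbon budget of the mat
#'
#' @param cell_density_range cells cm⁻³, `c(min, max)`; default 1e8-1e9.
#' @param carbon_per_cell_range fg C per cell, `c(min, max)`; default 1-150.
#' @param toc_wt_range total organic carbon, wt% of dry mass, `c(min, max)`;
#'   default 1-12.
#' @param porosity pore-water fraction, default 0.97.
#' @param particle_density g cm⁻³, default 2.65.
#' @return an object of class `cell_carbon_budget`.
#' @export
cell_carbon_budget <- function(cell_density_range = c(1e8, 1e9),
                               carbon_per_cell_range = c(1, 150),
                               toc_wt_range = c(1, 12),
                               porosity = 0.97, particle_density = 2.65) {
  ordered2 <- function(r) length(r) == 2L && r[1] <= r[2]
  stopifnot(ordered2(cell_density_range), ordered2(carbon_per_cell_range),
            ordered2(toc_wt_range), porosity > 0, porosity < 1,
            particle_density > 0)
  structure(list(cell_density_range = cell_density_range,
                 carbon_per_cell_range = carbon_per_cell_range,
                 toc_wt_range = toc_wt_range,
                 porosity = porosity, particle_density = particle_density),
            class = "cell_carbon_budget")
}

#' Cellular carbon density range in the wet mat
#'
#' @param budget a [cell_carbon_budget()].
#' @return `c(min, max)` in g C cm⁻³ of wet mat (defaults give 1e-7 to
#'   1.5e-4).
#' @export
biomass_carbon_density <- function(budget) {
  stopifnot(inherits(budget, "cell_carbon_budget"))
  fg_to_g <- 1e-15
  c(budget$cell_density_range[1] * budget$carbon_per_cell_range[1] * fg_to_g,
    budget$cell_density_range[2] * budget$carbon_per_cell_range[2] * fg_to_g)
}

#' TOC carbon density in the wet mat from wt%
#'
#' `wt/100 * (1 - porosity) * particle_density`.
#'
#' @param wt_percent organic carbon, wt% of dry mass.
#' @param porosity pore-water fraction.
#' @param particle_density g cm⁻³.
#' @return carbon density (g C cm⁻³ of wet mat).
#' @export
toc_carbon_density <- function(wt_percent, porosity = 0.97,
                               particle_density = 2.65) {
  stopifnot(all(wt_percent >= 0), porosity > 0, porosity < 1,
            particle_density > 0)
  wt_percent / 100 * (1 - porosity) * particle_density
}

#' Cellular biomass as a fraction of total organic carbon
#'
#' The minimum fraction pairs the smallest biomass density with the largest
#' TOC density, the maximum the reverse.
#'
#' @param budget a [cell_carbon_budget()].
#' @return `c(min, max)` in % of TOC.
#' @export
biomass_fraction <- function(budget) {
  stopifnot(inherits(budget, "cell_carbon_budget"))
  bio <- biomass_carbon_density(budget)
  toc <- toc_carbon_density(budget$toc_wt_range, budget$porosity,
                            budget$particle_density)
  if (any(toc == 0)) stop("zero TOC density: fraction undefined", call. = FALSE)
  c(bio[1] / toc[2] * 100, bio[2] / toc[1] * 100)
}

#' Global cell divisions per day
#'
#' Converts an areal carbon fixation rate into a division rate by dividing
#' the carbon fixed over the covered area by the carbon content of one cell.
#'
#' @param areal_c_rate areal carbon fixation (mmol C m⁻² d⁻¹).
#' @param carbon_per_cell fg C per cell (> 0).
#' @param scenario a [coverage_scenario()] (its `areal_rate` is ignored
#'   here; area and coverage are used).
#' @return divisions per day.
#' @export
division_budget <- function(areal_c_rate, carbon_per_cell, scenario) {
  stopifnot(inherits(scenario, "coverage_scenario"),
            areal_c_rate >= 0)
  if (carbon_per_cell <= 0)
    stop("carbon_per_cell must be > 0", call. = FALSE)
  g_m2_d <- areal_c_rate * 1e-3 * MOLAR_MASS_C
  area_m2 <- scenario$land_area * scenario$coverage_fraction * 1e6
  g_m2_d * area_m2 / (carbon_per_cell * 1e-15)
}

#' Cell carbon turnover time in the photosynthetic layer
#'
#' Standing stock of cellular carbon per area divided by the gross carbon
#' fixation rate.
#'
#' @param cell_density cells cm⁻³.
#' @param carbon_per_cell fg C per cell.
#' @param layer_thickness thickness of the active layer (cm).
#' @param gross_c_rate gross carbon fixation (mmol C m⁻² d⁻¹).
#' @return list with `turnover_d` (days; `Inf` with a warning for zero rate)
#'   and `divisions_per_day` (per cell).
#' @export
turnover_time <- function(cell_density, carbon_per_cell, layer_thickness,
                          gross_c_rate) {
  stopifnot(cell_density > 0, carbon_per_cell > 0, layer_thickness > 0,
            gross_c_rate >= 0)
  stock_g_m2 <- cell_density * carbon_per_cell * 1e-15 * layer_thickness * 1e4
  rate_g_m2_d <- gross_c_rate * 1e-3 * MOLAR_MASS_C
  if (rate_g_m2_d == 0) {
    warning("zero gross rate: infinite turnover time", call. = FALSE)
    return(list(turnover_d = Inf, divisions_per_day = 0))
  }
  tt <- stock_g_m2 / rate_g_m2_d
  list(turnover_d = tt, divisions_per_day = 1 / tt)
}

#' Ocean-area bookkeeping for the land/ocean split
#'
#' @param earth_surface_area total Earth surface (km²), default 5.10e8.
#' @param ocean_fraction fraction of the surface that is ocean, in `(0, 1)`.
#' @param ocean_cell_total,ocean_divisions_per_day optional ocean reference
#'   numbers carried along for reporting.
#' @return an object of class `ocean_comparison`.
#' @export
ocean_comparison <- function(earth_surface_area = EARTH_SURFACE_KM2,
                             ocean_fraction = 0.95,
                             ocean_cell_total = NA_real_,
                             ocean_divisions_per_day = NA_real_) {
  stopifnot(earth_surface_area > 0)
  if (ocean_fraction <= 0 || ocean_fraction >= 1)
    stop("ocean_fraction must be in (0, 1)", call. = FALSE)
  structure(list(earth_surface_area = earth_surface_area,
                 ocean_fraction = ocean_fraction,
                 ocean_cell_total = ocean_cell_total,
                 ocean_divisions_per_day = ocean_divisions_per_day),
            class = "ocean_comparison")
}

#' Ocean surface area of a land/ocean split
#'
#' @param comparison an [ocean_comparison()].
#' @return ocean area (km²); defaults give 4.845e8 (i.e. 485e6 km²).
#' @export
ocean_area <- function(comparison) {
  stopifnot(inherits(comparison, "ocean_comparison"))
  comparison$earth_surface_area * comparison$ocean_fraction
}

#' Nitrate export implied by net production and a C:N ratio
#'
#' Net carbon fixation divided by the molar C:N ratio, scaled to the
#' scenario's covered area and a year.
#'
#' @param net_c_rate net carbon fixation (mmol C m⁻² d⁻¹).
#' @param c_to_n molar C:N ratio (> 0), e.g. 15 for the mat biomass.
#' @param scenario a [coverage_scenario()].
#' @return nitrogen export (Tmol N yr⁻¹).
#' @export
nitrate_export <- function(net_c_rate, c_to_n, scenario) {
  stopifnot(inherits(scenario, "coverage_scenario"), net_c_rate >= 0)
  if (c_to_n <= 0) stop("c_to_n must be > 0", call. = FALSE)
  n_rate <- net_c_rate / c_to_n
  global_production(coverage_scenario(scenario$land_area,
                                      scenario$coverage_fraction,
                                      n_rate, scenario$label))
}

#' Compare a scenario against reference global fluxes
#'
#' For each user-supplied reference flux, reports the ratio of the scenario's
#' global flux to the reference and the break-even land-coverage fraction at
#' which the mat flux would match the reference.
#'
#' @param scenario a [coverage_scenario()].
#' @param references named numeric vector of reference fluxes (Tmol yr⁻¹);
#'   literature values supplied by the user, not bundled.
#' @return data.frame with `reference`, `flux_Tmol_yr`, `ratio`,
#'   `breakeven_coverage`; zero references are dropped with a warning.
#' @export
reference_flux_comparison <- function(scenario, references) {
  stopifnot(inherits(scenario, "coverage_scenario"),
            is.numeric(references), length(references) > 0)
  if (any(references == 0)) {
    warning("zero reference fluxes skipped", call. = FALSE)
    references <- references[references != 0]
  }
  gf <- global_production(scenario)
  full_cover <- global_production(coverage_scenario(
    scenario$land_area, 1, scenario$areal_rate))
  data.frame(
    reference = if (is.null(names(references)))
      paste0("ref_", seq_along(references)) else names(references),
    flux_Tmol_yr = as.numeric(references),
    ratio = gf / as.numeric(references),
    breakeven_coverage = as.numeric(references) / full_cover,
    stringsAsFactors = FALSE)
}
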