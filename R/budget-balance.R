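#' Organic-matter accretion inputs
#'
#' Parameters for converting a wt% organic-carbon depth profile into an
#' areal carbon accretion rate: a mat of known thickness accumulated over a
#' known number of years, with solids at `(1 - porosity) * particle_density`.
#'
#' @param wtc_profile a [depth_profile()] of kind `"organic_carbon"`
#'   (wt% of dry mass; depths in mm).
#' @param thickness mat thickness (cm), default 6.
#' @param age accumulation time (yr), default 9.
#' @param porosity pore-water volume fraction, default 0.97.
#' @param particle_density particle bulk density (g cm⁻³), default 2.65.
#' @param molar_mass_c molar mass of carbon (g mol⁻¹), default 12.011.
#' @return an object of class `accretion_inputs`.
#' @export
accretion_inputs <- function(wtc_profile, thickness = 6, age = 9,
                             porosity = 0.97, particle_density = 2.65,
                             molar_mass_c = 12.011) {
  stopifnot(inherits(wtc_profile, "depth_profile"),
            thickness > 0, age > 0, particle_density > 0, molar_mass_c > 0)
  if (profile_kind(wtc_profile) != "organic_carbon")
    stop("wtc_profile must be an organic_carbon profile", call. = FALSE)
  if (porosity <= 0 || porosity >= 1)
    stop("porosity must be in (0, 1)", call. = FALSE)
  structure(list(wtc_profile = wtc_profile, thickness = thickness, age = age,
                 porosity = porosity, particle_density = particle_density,
                 molar_mass_c = molar_mass_c),
            class = "accretion_inputs")
}

#' Areal organic-carbon accretion rate from a wt%C profile
#'
#' Integrates `wt%C(z)/100 * (1 - porosity) * particle_density` over the mat
#' thickness (trapezoids on the profile nodes, constant extension of the
#' deepest value below the profile support) and divides by the accumulation
#' time.
#'
#' @param inputs an [accretion_inputs()] object.
#' @return areal carbon accretion rate (mmol C m⁻² d⁻¹).
#' @export
#' @examples
#' wtc <- depth_profile(c(0, 60), c(1, 1), "organic_carbon")
#' om_accretion_rate(accretion_inputs(wtc))   # ~1.21 for uniform 1 wt%
om_accretion_rate <- function(inputs) {
  stopifnot(inherits(inputs, "accretion_inputs"))
  p <- inputs$wtc_profile
  if (any(p$value < 0)) stop("negative wt%C", call. = FALSE)
  thick_mm <- inputs$thickness * 10
  if (max(p$depth_mm) < thick_mm)
    message(sprintf(
      "wt%%C profile ends at %.3g mm; extending %.3g wt%% down to %.3g mm",
      max(p$depth_mm), p$value[nrow(p)], thick_mm))
  z <- sort(unique(c(pmin(p$depth_mm, thick_mm), thick_mm)))
  z <- z[z <= thick_mm]
  if (z[1] > 0) z <- c(0, z)
  w <- stats::approx(p$depth_mm, p$value, xout = z, rule = 2)$y
  solid <- (1 - inputs$porosity) * inputs$particle_density     # g solids/cm3
  # g C per cm2 column: integral over cm of (wt/100 * solid)
  gC_cm2 <- trapz_(z / 10, w / 100 * solid)
  gC_m2 <- gC_cm2 * 1e4
  gC_m2_d <- gC_m2 / (inputs$age * 365)
  gC_m2_d / inputs$molar_mass_c * 1e3                          # mmol C/m2/d
}

#' Methane efflux used in the flux balance
#'
#' The dark-incubation CH4 production rate is scaled by an inhibition factor
#' (default 0.5) to account for suppression of methanogenesis under the oxic
#' conditions that develop during the day.
#'
#' @param areal_rate_dark CH4 production from the dark incubation, scaled to
#'   area (mmol m⁻² d⁻¹).
#' @param inhibition_factor fraction of the dark rate realized, in `(0, 1]`;
#'   default 0.5.
#' @return CH4 efflux (mmol CH4 m⁻² d⁻¹).
#' @export
ch4_areal_flux <- function(areal_rate_dark, inhibition_factor = 0.5) {
  stopifnot(is.numeric(areal_rate_dark), areal_rate_dark >= 0)
  if (inhibition_factor <= 0 || inhibition_factor > 1)
    stop("inhibition_factor must be in (0, 1]", call. = FALSE)
  areal_rate_dark * inhibition_factor
}

# fixed 4-electron normalization: CH2O -> CO2 is 4 e- (factor 1), CH4 carries
# 8 e- (factor 2), O2 -> 2 H2O is 4 e- (factor 1)
O2_EQUIVALENT_FACTORS <- c(O2 = 1, Corg = 1, CH4 = 2)

#' Ledger of O2-equivalent sources and sinks
#'
#' Each entry is a named areal rate of one species (`O2`, `Corg`, `CH4`)
#' acting as a source or sink of oxidizing power. Conversion to O2
#' equivalents is normalized to 4-electron transfers and immutable: O2 and
#' organic carbon count 1:1, CH4 (8 electrons) counts double.
#'
#' @param entries a data.frame (or list of lists) with columns `name`,
#'   `species`, `rate` (mmol m⁻² d⁻¹), `role` (`"source"`/`"sink"`).
#' @return an object of class `o2_equivalent_ledger`.
#' @export
#' @examples
#' led <- o2_equivalent_ledger(data.frame(
#'   name = c("OM production", "CH4 efflux"),
#'   species = c("Corg", "CH4"), rate = c(20, 2.05),
#'   role = c("source", "source")))
#' to_o2_equivalents(led)$sources   # 24.1
o2_equivalent_ledger <- function(entries) {
  if (is.list(entries) && !is.data.frame(entries))
    entries <- do.call(rbind, lapply(entries, as.data.frame))
  stopifnot(is.data.frame(entries),
            all(c("name", "species", "rate", "role") %in% names(entries)))
  if (!all(entries$species %in% names(O2_EQUIVALENT_FACTORS)))
    stop(sprintf("unknown species: %s",
                 paste(setdiff(entries$species,
                               names(O2_EQUIVALENT_FACTORS)), collapse = ", ")),
         call. = FALSE)
  if (!all(entries$role %in% c("source", "sink")))
    stop("role must be 'source' or 'sink'", call. = FALSE)
  stopifnot(is.numeric(entries$rate), all(entries$rate >= 0))
  entries$factor <- unname(O2_EQUIVALENT_FACTORS[entries$species])
  entries$o2_equivalents <- entries$rate * entries$factor
  structure(list(entries = entries), class = "o2_equivalent_ledger")
}

#' Totals of an O2-equivalent ledger
#'
#' @param ledger an [o2_equivalent_ledger()].
#' @return list with `sources`, `sinks` and `net` (sources - sinks), all in
#'   mmol O2-eq m⁻² d⁻¹.
#' @export
to_o2_equivalents <- function(ledger) {
  stopifnot(inherits(ledger, "o2_equivalent_ledger"))
  e <- ledger$entries
  sources <- sum(e$o2_equivalents[e$role == "source"])
  sinks <- sum(e$o2_equivalents[e$role == "sink"])
  list(sources = sources, sinks = sinks, net = sources - sinks)
}

#' @export
print.o2_equivalent_ledger <- function(x, ...) {
  cat("<o2_equivalent_ledger>\n")
  print.data.frame(x$entries, row.names = FALSE)
  t <- to_o2_equivalents(x)
  cat(sprintf("  sources %.4g, sinks %.4g, net %.4g mmol O2-eq/m2/d\n",
              t$sources, t$sinks, t$net))
  invisible(x)
}

#' Reconcile gross production estimates across methods
#'
#' Each independent net-production estimate (1D model, O2 flux to atmosphere
#' + rock, CH4 efflux + OM accretion) is converted to a gross estimate by
#' adding the same night-time respiration magnitude; the spread across
#' methods is reported.
#'
#' @param net_estimates named numeric vector of net areal production
#'   estimates (mmol O2-eq m⁻² d⁻¹).
#' @param respiration night respiration magnitude (mmol m⁻² d⁻¹, >= 0).
#' @return a data.frame with `method`, `net`, `gross`, plus attributes
#'   `respiration` and `spread` (max - min gross).
#' @export
reconcile_gross <- function(net_estimates, respiration) {
  if (length(net_estimates) == 0L)
    stop("need at least one net estimate", call. = FALSE)
  stopifnot(is.numeric(net_estimates), is.numeric(respiration),
            respiration >= 0)
  out <- data.frame(
    method = if (is.null(names(net_estimates)))
      paste0("method_", seq_along(net_estimates)) else names(net_estimates),
    net = as.numeric(net_estimates),
    gross = as.numeric(net_estimates) + respiration,
    stringsAsFactors = FALSE)
  attr(out, "respiration") <- respiration
  attr(out, "spread") <- diff(range(out$gross))
  out
}
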