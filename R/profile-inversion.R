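#' Diffusive flux from a measured O2 profile (Fick's first law)
#'
#' `J = -phi * D' * dC/dx`, with the gradient taken as the least-squares
#' slope over the `window` points adjacent to the chosen interface (the
#' default window of 2 is the two-point difference). Fluxes are reported
#' positive OUT of the mat through the named interface: at the top that is
#' towards the atmosphere, at the bottom towards the rock.
#'
#' @param profile a [depth_profile()] of kind `"o2_concentration"`.
#' @param transport a [transport_parameters()] object.
#' @param interface `"top_atmosphere"` or `"bottom_rock"`.
#' @param window number of points used for the gradient (>= 2).
#' @return an object of class `flux_estimate` with elements `value`
#'   (mmol m⁻² d⁻¹, positive out of the mat), `interface`, `gradient_used`
#'   (µmol L⁻¹ mm⁻¹) and `window`.
#' @export
#' @examples
#' p <- depth_profile(c(0, 1), c(230, 130), "o2_concentration")
#' fick_flux(p, transport_parameters(), "top_atmosphere")
fick_flux <- function(profile, transport,
                      interface = c("top_atmosphere", "bottom_rock"),
                      window = 2L) {
  interface <- match.arg(interface)
  stopifnot(inherits(profile, "depth_profile"),
            inherits(transport, "transport_parameters"))
  if (profile_kind(profile) != "o2_concentration")
    stop("fick_flux needs an O2 concentration profile", call. = FALSE)
  window <- as.integer(window)
  if (window < 2L || window > nrow(profile))
    stop("window must be between 2 and the number of points", call. = FALSE)

  n <- nrow(profile)
  idx <- if (interface == "top_atmosphere") seq_len(window)
         else seq.int(n - window + 1L, n)
  gradient <- slope_from_profile(profile$value[idx], profile$depth_mm[idx],
                                 window)                       # uM/mm
  # gradient uM/mm == mmol m^-3 per 1e-3 m -> *1e3 mmol m^-4
  J_down <- -transport$porosity * cm2_s_to_m2_s(transport$diffusivity) *
    (gradient * 1e3) * 86400                                    # mmol m^-2 d^-1
  value <- if (interface == "top_atmosphere") -J_down else J_down
  structure(list(value = value, interface = interface,
                 gradient_used = gradient, window = window),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("<flux_estimate> %s: %.4g mmol/m2/d out of the mat (gradient %.4g uM/mm, window %d)\n",
              x$interface, x$value, x$gradient_used, x$window))
  invisible(x)
}

#' Net volumetric rates from the curvature of a steady O2 profile
#'
#' At steady state the reaction-diffusion balance gives
#' `net rate = -phi * D' * d2C/dz2` (bulk-volume basis): net production is
#' positive where the profile is concave-down (a local O2 bulge), net
#' consumption where it is concave-up. Centred second differences are used;
#' an optional moving-average smoothing (window 3) can be applied first,
#' since double differentiation amplifies sensor noise strongly.
#'
#' @param profile a [depth_profile()] of O2 on an approximately uniform grid.
#' @param transport a [transport_parameters()] object.
#' @param smooth if `TRUE`, apply a 3-point moving average before
#'   differencing (default `FALSE`).
#' @return an object of class `net_rate_profile`: a data.frame with
#'   `depth_mm` and `rate_nM_s` (positive = net production) for the interior
#'   points, with attribute/element `areal_integral` (mmol m⁻² d⁻¹,
#'   trapezoidal).
#' @export
invert_net_rates <- function(profile, transport, smooth = FALSE) {
  stopifnot(inherits(profile, "depth_profile"),
            inherits(transport, "transport_parameters"))
  if (profile_kind(profile) != "o2_concentration")
    stop("invert_net_rates needs an O2 concentration profile", call. = FALSE)
  if (nrow(profile) < 3L)
    stop("need at least 3 points", call. = FALSE)
  z <- profile$depth_mm
  v <- profile$value
  if (smooth && length(v) >= 3L) {
    sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    v[!is.na(sm)] <- sm[!is.na(sm)]
  }
  n <- length(z)
  i <- 2:(n - 1)
  h1 <- z[i] - z[i - 1]
  h2 <- z[i + 1] - z[i]
  # second derivative on a possibly non-uniform grid [uM/mm^2]
  d2 <- 2 * (h1 * v[i + 1] - (h1 + h2) * v[i] + h2 * v[i - 1]) /
    (h1 * h2 * (h1 + h2))
  # uM/mm^2 = mmol m^-3 mm^-2 -> * 1e6 mmol m^-5; rate uM/s -> nM/s * 1e3
  rate_nM_s <- -transport$porosity * cm2_s_to_m2_s(transport$diffusivity) *
    d2 * 1e6 * 1e3
  # integrate over the full profile support, extending the first/last
  # interior rate to the boundary nodes (curvature is undefined there)
  zz <- c(z[1], z[i], z[n])
  rr <- c(rate_nM_s[1], rate_nM_s, rate_nM_s[length(rate_nM_s)])
  areal <- trapz_(mm_to_m(zz), nM_s_to_uM_s(rr)) * 86400
  structure(
    list(depths = z[i], rate_nM_s = rate_nM_s, areal_integral = areal),
    class = "net_rate_profile")
}

#' @export
print.net_rate_profile <- function(x, ...) {
  cat(sprintf("<net_rate_profile> %d points, areal integral %.4g mmol/m2/d\n",
              length(x$depths), x$areal_integral))
  invisible(x)
}

#' Integrate a net-rate profile over a depth layer
#'
#' Trapezoidal integral of the volumetric net rate over `layer`, converted to
#' an areal rate.
#'
#' @param rates a `net_rate_profile` from [invert_net_rates()].
#' @param layer depth range `c(from, to)` in mm; default the full support.
#' @return areal rate (mmol m⁻² d⁻¹).
#' @export
integrate_areal_rate <- function(rates, layer = range(rates$depths)) {
  stopifnot(inherits(rates, "net_rate_profile"), length(layer) == 2L)
  layer <- sort(layer)
  z <- rates$depths
  lo <- max(layer[1], min(z))
  hi <- min(layer[2], max(z))
  if (lo >= hi)
    stop("layer does not intersect the rate profile support", call. = FALSE)
  zz <- sort(unique(c(lo, hi, z[z >= lo & z <= hi])))
  vv <- stats::approx(z, rates$rate_nM_s, xout = zz)$y
  trapz_(mm_to_m(zz), nM_s_to_uM_s(vv)) * 86400
}

#' Gross photosynthesis from day and night areal rates
#'
#' Gross production = daytime net production + night-time respiration
#' magnitude. Because respiration can be slower at night (lower O2), this is
#' a lower limit on gross photosynthesis; the result carries a
#' `lower_limit = TRUE` attribute.
#'
#' @param net_day daytime net areal production (mmol m⁻² d⁻¹).
#' @param resp_night night respiration as a positive consumption magnitude
#'   (mmol m⁻² d⁻¹).
#' @return gross areal production (mmol m⁻² d⁻¹) with attribute
#'   `lower_limit`.
#' @export
day_night_gross <- function(net_day, resp_night) {
  stopifnot(is.numeric(net_day), is.numeric(resp_night))
  if (any(resp_night < 0))
    stop("night respiration must be a positive consumption magnitude",
         call. = FALSE)
  structure(net_day + resp_night, lower_limit = TRUE)
}
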