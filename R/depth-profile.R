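#' Depth profiles
#'
#' The common currency of measurement and simulation: an ordered series of
#' (depth, value) pairs with a declared quantity kind. Depth 0 is the
#' mat-atmosphere interface, positive downward (mm). Supported kinds and
#' units:
#'
#' * `o2_concentration` — µmol L⁻¹
#' * `par` — µE m⁻² s⁻¹
#' * `organic_carbon` — wt% of dry mass
#' * `net_rate` — nmol L⁻¹ s⁻¹, positive = net production
#'
#' @param depths strictly increasing depths (mm).
#' @param values measured/simulated quantity, same length as `depths`.
#' @param kind one of the kinds above.
#' @param metadata named character vector or list of free-form metadata
#'   (time of day, site, generator parameters, ...).
#' @return an object of class `depth_profile` (also a data.frame with
#'   columns `depth_mm`, `value`).
#' @export
#' @examples
#' p <- depth_profile(c(0, 0.5, 1), c(230, 250, 240), "o2_concentration")
#' p$value
depth_profile <- function(depths, values,
                          kind = c("o2_concentration", "par",
                                   "organic_carbon", "net_rate"),
                          metadata = list()) {
  kind <- match.arg(kind)
  depths <- as.numeric(depths)
  values <- as.numeric(values)
  if (length(depths) == 0L)
    stop("empty profile", call. = FALSE)
  if (length(depths) != length(values))
    stop("depths and values differ in length", call. = FALSE)
  if (any(!is.finite(depths)) || any(!is.finite(values)))
    stop("depths and values must be finite", call. = FALSE)
  if (any(diff(depths) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  if (kind %in% c("o2_concentration", "par", "organic_carbon") &&
      any(values < 0))
    stop(sprintf("negative values not allowed for kind '%s'", kind),
         call. = FALSE)
  structure(
    data.frame(depth_mm = depths, value = values),
    kind = kind,
    metadata = as.list(metadata),
    class = c("depth_profile", "data.frame")
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> kind=%s, %d points, %.3g-%.3g mm\n",
              attr(x, "kind"), nrow(x), min(x$depth_mm), max(x$depth_mm)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

profile_kind <- function(p) attr(p, "kind")
profile_metadata <- function(p) attr(p, "metadata")

# linear resample of a profile onto target depths (mm); constant extension
# beyond the observed support
resample_profile <- function(p, depths) {
  stats::approx(p$depth_mm, p$value, xout = depths, rule = 2)$y
}
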