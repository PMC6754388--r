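#' Write a depth profile to the canonical TSV dialect
#'
#' Comment lines `# key=value` carry metadata (including the quantity
#' `kind`), followed by a `depth_mm<TAB>value` header and numeric rows.
#' Formatting is deterministic (`%.10g`, LF endings), so writing the same
#' profile twice produces byte-identical files.
#'
#' @param profile a [depth_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  if (nrow(profile) == 0L) stop("empty profile", call. = FALSE)
  md <- profile_metadata(profile)
  md$kind <- profile_kind(profile)
  hdr <- vapply(names(md), function(k)
    sprintf("# %s=%s", k, format(md[[k]], digits = 15, scientific = FALSE,
                                 trim = TRUE)),
    character(1))
  rows <- sprintf("%.10g\t%.10g", profile$depth_mm, profile$value)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, "depth_mm\tvalue", rows), con, sep = "\n")
  invisible(path)
}

#' Read a depth profile from the canonical TSV dialect
#'
#' @param path input file path.
#' @param kind quantity kind override; by default taken from the `kind`
#'   metadata line, falling back to `"o2_concentration"` with a warning.
#' @return a [depth_profile()] with metadata.
#' @export
read_profile <- function(path, kind = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  md <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      md[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[!is_meta]
  if (length(body) < 2L) stop("no data rows", call. = FALSE)
  if (!grepl("^depth_mm\tvalue", body[1]))
    stop("missing 'depth_mm\\tvalue' header row", call. = FALSE)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) < 2L)
  if (length(bad))
    stop(sprintf("malformed row at line %d",
                 which(!is_meta)[1 + bad[1]]), call. = FALSE)
  depths <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 1L)))
  values <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 2L)))
  if (any(is.na(depths)) || any(is.na(values))) {
    bad <- which(is.na(depths) | is.na(values))[1]
    stop(sprintf("non-numeric value at line %d", which(!is_meta)[1 + bad]),
         call. = FALSE)
  }
  if (is.null(kind)) {
    if (!is.null(md$kind)) kind <- md$kind
    else {
      warning("no 'kind' metadata; defaulting to o2_concentration",
              call. = FALSE)
      kind <- "o2_concentration"
    }
  }
  md$kind <- NULL
  depth_profile(depths, values, kind = kind, metadata = md)
}

#' Default pipeline configuration
#'
#' The packaged configuration reproducing the headline analysis:
#' model kinetics/transport/grid defaults, the printed Table-1 style rates
#' (net 23, gross 38, respiration 15, OM 20, dark CH4 4.1 mmol m⁻² d⁻¹) and
#' the global-scaling constants (land area 2.5e7 km², coverages 5% and 55%,
#' Earth surface 5.10e8 km², 95% ocean).
#'
#' @return a nested configuration list, the schema accepted by
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    model = list(
      kinetics = list(), transport = list(),
      grid = list(spacing = 0.071, n_nodes = 283L),
      top_oxic = 230, bottom = "no_flux",
      mode = "converge", tolerance = 1e-4, dt = 2),
    balance = list(
      net_o2_model = 23, respiration = 15,
      om_accretion = 20, ch4_dark = 4.1, ch4_inhibition = 0.5,
      o2_efflux_atmosphere = 6.3, o2_flux_rock = 2.1),
    global_scaling = list(
      gross_rate = 38, land_area = 2.5e7,
      coverages = c(minimal = 0.05, vegetated = 0.55),
      earth_surface = 5.10e8, ocean_fraction = 0.95,
      c_to_n = 15, net_c_rate = 20, nitrate_coverage = 0.10),
    cells = list(
      cell_density_range = c(1e8, 1e9),
      carbon_per_cell_range = c(1, 150),
      toc_wt_range = c(1, 12),
      porosity = 0.97, particle_density = 2.65))
}

#' Read a pipeline configuration file (YAML)
#'
#' Keys missing from the file fall back to [default_pipeline_config()]
#' values; every applied default is reported via `message()`.
#'
#' @param path YAML file path.
#' @return a configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- default_pipeline_config()
  merge_ <- function(d, u, prefix = "") {
    for (k in names(d)) {
      if (is.null(u[[k]])) {
        message(sprintf("config: using default for %s%s", prefix, k))
      } else if (is.list(d[[k]]) && is.list(u[[k]])) {
        d[[k]] <- merge_(d[[k]], u[[k]], paste0(prefix, k, "."))
      } else {
        d[[k]] <- u[[k]]
      }
    }
    d
  }
  merge_(def, user)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: scenario simulations (oxic day, anoxic day, night),
#' interface flux and net-rate inversion of the simulated day profile, the
#' O2-equivalent flux balance, and the global extrapolation calculators, and
#' collects everything into a structured report. Any stage failure aborts
#' the run with a stage-labelled error; partial reports are never returned.
#'
#' @param config a configuration list, e.g. [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @return an object of class `run_report`: nested list with sections
#'   `inputs`, `model`, `fluxes`, `balance`, `global` and a `provenance`
#'   block (config hash, seed, package version).
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(default_pipeline_config())
#' rep$global$production_Tmol_yr
#' }
run_pipeline <- function(config = default_pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  kin <- stage("configure", do.call(kinetic_parameters,
                                    config$model$kinetics))
  tra <- stage("configure", do.call(transport_parameters,
                                    config$model$transport))
  grd <- stage("configure", do.call(grid_1d, config$model$grid))

  scen <- stage("simulate", {
    lapply(c(oxic_day = "oxic_day", anoxic_day = "anoxic_day",
             night = "night"), function(s)
      simulate_scenario(kin, tra, grd, s,
                        top_oxic = config$model$top_oxic,
                        bottom = config$model$bottom,
                        mode = config$model$mode,
                        tolerance = config$model$tolerance,
                        dt = config$model$dt))
  })

  fluxes <- stage("invert", {
    day <- scen$oxic_day$o2_profile
    inv <- invert_net_rates(day, tra)
    list(
      efflux_top_oxic = scen$oxic_day$efflux_top,
      efflux_top_anoxic = scen$anoxic_day$efflux_top,
      fick_top = fick_flux(day, tra, "top_atmosphere")$value,
      inverted_areal_net = inv$areal_integral,
      model_areal_net = scen$oxic_day$areal_net_production)
  })

  bal <- stage("balance", {
    b <- config$balance
    ch4 <- ch4_areal_flux(b$ch4_dark, config$balance$ch4_inhibition)
    led <- o2_equivalent_ledger(data.frame(
      name = c("OM production", "CH4 efflux atmosphere"),
      species = c("Corg", "CH4"), rate = c(b$om_accretion, ch4),
      role = "source"))
    totals <- to_o2_equivalents(led)
    nets <- c("1D model" = b$net_o2_model,
              "O2 flux atmosphere + rock" =
                b$o2_efflux_atmosphere + b$o2_flux_rock,
              "CH4 flux atmosphere + OM production" = totals$sources)
    list(ledger = led, ch4_used = ch4,
         ch4_plus_om_net = totals$sources,
         gross_table = reconcile_gross(nets, b$respiration))
  })

  glob <- stage("global", {
    g <- config$global_scaling
    ann <- areal_to_annual(g$gross_rate)
    prod <- vapply(g$coverages, function(cv)
      global_production(coverage_scenario(g$land_area, cv, g$gross_rate)),
      numeric(1))
    budget <- do.call(cell_carbon_budget, config$cells)
    list(
      annual = ann,
      production_Tmol_yr = as.list(prod),
      ocean_area_km2 = ocean_area(ocean_comparison(g$earth_surface,
                                                   g$ocean_fraction)),
      biomass_density_gC_cm3 = biomass_carbon_density(budget),
      biomass_fraction_pct = biomass_fraction(budget),
      nitrate_export_Tmol_yr = nitrate_export(
        g$net_c_rate, g$c_to_n,
        coverage_scenario(g$land_area, g$nitrate_coverage, g$net_c_rate)))
  })

  structure(
    list(
      inputs = config,
      model = lapply(scen, function(s) list(
        iterations = s$iterations, residual = s$residual,
        converged = s$converged,
        interface_slope = s$interface_slope,
        efflux_top = s$efflux_top, flux_bottom = s$flux_bottom,
        areal_net_production = s$areal_net_production)),
      fluxes = fluxes,
      balance = bal,
      global = glob,
      provenance = list(
        seed = config$seed,
        config_hash = sum(utf8ToInt(paste(
          utils::capture.output(utils::str(config)), collapse = ""))),
        package_version = as.character(utils::packageVersion("oxymat")))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  oxic-day efflux (model)   %.4g mmol/m2/d\n",
              x$fluxes$efflux_top_oxic))
  cat(sprintf("  anoxic-day efflux (model) %.4g mmol/m2/d\n",
              x$fluxes$efflux_top_anoxic))
  cat(sprintf("  CH4 + OM net (O2-eq)      %.4g mmol/m2/d\n",
              x$balance$ch4_plus_om_net))
  cat(sprintf("  global production          %s Tmol/yr\n",
              paste(sprintf("%.4g", x$global$production_Tmol_yr),
                    collapse = " / ")))
  cat(sprintf("  ocean area                 %.4g km2\n",
              x$global$ocean_area_km2))
  invisible(x)
}

#' Write a run report as JSON
#'
#' Full-precision values (no rounding); the printed-precision rendering in
#' the report text mirrors the 2-significant-figure reporting convention.
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- unclass(report)
  out$balance$ledger <- out$balance$ledger$entries
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
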