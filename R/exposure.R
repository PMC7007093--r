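# Exposure modelling: unit conversion of monthly emitted mass to mean flux,
# contraction against precomputed adjoint sensitivity fields under a
# repeating meteorological-year schedule, and seasonal summaries. The
# source-receptor relationship is linear: exposure is a dot product of the
# sensitivity field with the emission flux, so scenarios superpose exactly.

.mass_to_g <- c(g = 1, kg = 1e3, Mg = 1e6, Gg = 1e9, Tg = 1e12)

#' Convert a monthly emissions field to mean flux
#'
#' `flux = mass / (cell area in m2 x seconds in the month)`, in g/m2/s - the
#' denominator units of the adjoint sensitivities. Sub-monthly timing is
#' deliberately collapsed to a monthly mean, matching monthly mean
#' sensitivity maps.
#'
#' @param E An [emissions_field] with units among g, kg, Mg, Gg, Tg.
#' @param cell_area Cell area in km2 (scalar or per-row of E's grid).
#' @return List of class `flux_field`: array `data` (g/m2/s), `time`, `grid`.
#' @export
to_flux <- function(E, cell_area) {
  if (is.null(E$units) || !E$units %in% names(.mass_to_g))
    stop("units metadata missing or unsupported: ", E$units)
  d <- dim(E$data)
  area_m2 <- matrix(cell_area, d[1], d[2]) * 1e6
  out <- array(0, d)
  secs <- days_in_month(E$time$year, E$time$month) * 86400
  for (t in seq_len(d[3]))
    out[, , t] <- E$data[, , t] * .mass_to_g[[E$units]] / (area_m2 * secs[t])
  structure(list(data = out, time = E$time, grid = E$grid,
                 units = "g/m2/s"), class = "flux_field")
}

#' Sum two emissions or flux fields
#'
#' @param a,b Fields on identical grids, time axes and units.
#' @return A field of the same class; for emissions the species is the
#'   summed-smoke label `"OCBC"` when inputs differ.
#' @export
add_fields <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) stop("field dimensions differ")
  if (!identical(a$units, b$units)) stop("field units differ")
  out <- a
  out$data <- a$data + b$data
  if (!is.null(a$species) && !is.null(b$species) && a$species != b$species)
    out$species <- "OCBC"
  out
}

#' Build a repeating meteorological-year schedule
#'
#' Maps every simulation year to one of the available meteorological years
#' by cycling the ordered sequence:
#' `year y -> met_years[(y - start_year) mod length(met_years)]`.
#'
#' @param start_year,end_year Simulation span (inclusive).
#' @param met_years Nonempty ordered vector of met-year labels.
#' @return Named integer vector (names = simulation years).
#' @export
build_schedule <- function(start_year, end_year, met_years) {
  if (!length(met_years)) stop("met_years must be nonempty")
  if (end_year < start_year) stop("end_year before start_year")
  yrs <- start_year:end_year
  stats::setNames(met_years[(yrs - start_year) %% length(met_years) + 1L], yrs)
}

#' Receptor exposure from flux and adjoint sensitivities
#'
#' For receptor r, month m of simulation year y:
#' `X_r(m, y) = sum_cells S_r(cell, m, sched(y)) x flux(cell, m, y)`.
#' Sum species (OC + BC) into one flux before calling.
#'
#' @param flux A coarse-grid `flux_field` (g/m2/s).
#' @param S A [sensitivity_field] on the same coarse grid
#'   ((ug/m3)/(g/m2/s)).
#' @param sched Schedule from [build_schedule] covering every flux year.
#' @return Data frame of class `exposure_series`: `receptor`, `year`,
#'   `month`, `pm25` (ug/m3).
#' @export
apply_sensitivities <- function(flux, S, sched) {
  d <- dim(flux$data)
  dS <- dim(S$fields[[1]])
  if (!identical(d[1:2], dS[1:2]))
    stop("flux and sensitivity grids differ")
  yrs <- unique(flux$time$year)
  if (!all(as.character(yrs) %in% names(sched)))
    stop("schedule does not cover all flux years")
  n <- d[3] * length(S$receptors)
  out <- data.frame(receptor = rep(S$receptors, each = d[3]),
                    year = rep(flux$time$year, length(S$receptors)),
                    month = rep(flux$time$month, length(S$receptors)),
                    pm25 = numeric(n), stringsAsFactors = FALSE)
  for (ri in seq_along(S$receptors)) {
    arr <- S$fields[[ri]]
    for (t in seq_len(d[3])) {
      my <- sched[[as.character(flux$time$year[t])]]
      yi <- match(my, S$met_years)
      if (is.na(yi)) stop("met year ", my, " missing from sensitivity field")
      out$pm25[(ri - 1L) * d[3] + t] <-
        sum(arr[, , flux$time$month[t], yi] * flux$data[, , t])
    }
  }
  class(out) <- c("exposure_series", "data.frame")
  out
}

#' Seasonal / annual exposure means per receptor
#'
#' Arithmetic mean of monthly population-weighted PM2.5 over a chosen
#' month-year set, e.g. the Jul-Oct burning season or the full year (the
#' health module's annual-mean input).
#'
#' @param X An `exposure_series`.
#' @param months Calendar months to average (default Jul-Oct).
#' @param years Years to include (default: all in the series).
#' @return Data frame `receptor`, `mean_pm25`.
#' @export
seasonal_stats <- function(X, months = 7:10, years = NULL) {
  if (is.null(years)) years <- unique(X$year)
  sel <- X$month %in% months & X$year %in% years
  if (!any(sel)) stop("empty month/year selection")
  agg <- stats::aggregate(pm25 ~ receptor, data = X[sel, , drop = FALSE], FUN = mean)
  names(agg)[2] <- "mean_pm25"
  agg[match(unique(X$receptor), agg$receptor), , drop = FALSE]
}

#' Per-year annual-mean exposure per receptor
#'
#' @param X An `exposure_series`.
#' @return Data frame `receptor`, `year`, `annual_pm25`.
#' @export
annual_means <- function(X) {
  agg <- stats::aggregate(pm25 ~ receptor + year, data = X, FUN = mean)
  names(agg)[3] <- "annual_pm25"
  agg[order(match(agg$receptor, unique(X$receptor)), agg$year), , drop = FALSE]
}
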