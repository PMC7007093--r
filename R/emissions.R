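# Fire-emissions modelling: FRP-weighted downscaling of coarse monthly
# emissions to the fine grid, estimation of per-coarse-cell, per-transition
# monthly emission rates (the learned emissions model), projection of those
# rates onto future land use, and speciation of dry matter to OC and BC.

#' Transition / stable-class labels for emissions attribution
#'
#' Each fine cell gets a label combining its cover history and peat status:
#' stable cells are labelled by class (`"plantation.peat"`), transitioning
#' cells by the pair (`"degraded>nonforest.nonpeat"`). These labels are the
#' strata over which emission rates are learned and re-applied; repeated
#' burns at a location enter through the multi-year mean rate of its label.
#'
#' @param map0 A [lulc_map] at the window start.
#' @param map1 Optional [lulc_map] at the window end; when omitted every
#'   cell is labelled stable.
#' @return Character matrix of labels on the fine grid.
#' @export
transition_labels <- function(map0, map1 = NULL) {
  suffix <- ifelse(map0$peat, ".peat", ".nonpeat")
  cls0 <- names(LULC_CLASSES)[map0$classes]
  if (is.null(map1)) {
    lab <- paste0(cls0, suffix)
  } else {
    if (!identical(dim(map0$classes), dim(map1$classes)))
      stop("maps must share one grid")
    cls1 <- names(LULC_CLASSES)[map1$classes]
    lab <- ifelse(cls0 == cls1, paste0(cls0, suffix),
                  paste0(cls0, ">", cls1, suffix))
  }
  matrix(lab, nrow(map0$classes), ncol(map0$classes))
}

#' Downscale coarse monthly emissions with fire radiative power
#'
#' Within each coarse cell and month, coarse mass is shared out to the
#' nested fine cells in proportion to their FRP. Where total FRP is zero but
#' coarse emissions are positive (fires without a satellite detection), the
#' mass is distributed by the ratio of area of each land-cover stratum,
#' uniformly by area within a stratum; with the default unit stratum weights
#' this is area-proportional. Per-coarse-cell monthly totals are conserved
#' exactly.
#'
#' @param coarse A coarse-grid [emissions_field].
#' @param frp A fine-grid [frp_field] on the matching time axis.
#' @param lulc Optional [lulc_map] (or label matrix via `labels`) used by the
#'   zero-FRP fallback; when omitted the fallback is uniform by area.
#' @param factor Coarsening factor linking the two grids.
#' @param class_weights Optional named vector of per-stratum weights for the
#'   fallback (e.g. relative flammability); default 1 for every stratum.
#' @param labels Optional character label matrix overriding `lulc` strata.
#' @param cell_area Fine-cell areas (scalar or per-row) when `lulc` is
#'   omitted.
#' @return A fine-grid [emissions_field] with the same species/units.
#' @export
downscale <- function(coarse, frp, lulc = NULL, factor,
                      class_weights = NULL, labels = NULL, cell_area = 1) {
  dF <- dim(frp$data)
  check_nesting(dF[1], dF[2], factor)
  dC <- dim(coarse$data)
  if (dC[1] != dF[1] %/% factor || dC[2] != dF[2] %/% factor)
    stop("fine grid does not nest into the coarse grid at this factor")
  if (dC[3] != dF[3]) stop("coarse and FRP time axes differ")
  idx <- as.vector(coarse_index(dF[1], dF[2], factor))
  if (!is.null(lulc)) {
    area <- as.vector(cell_area_matrix(lulc))
    if (is.null(labels)) labels <- transition_labels(lulc)
  } else {
    area <- as.vector(matrix(cell_area, dF[1], dF[2]))
  }
  w_fall <- area
  if (!is.null(labels)) {
    lab <- as.vector(labels)
    if (!is.null(class_weights)) {
      cw <- class_weights[lab]
      if (any(is.na(cw))) stop("class_weights missing for some strata")
      w_fall <- area * as.numeric(cw)
    }
  }
  fall_tot <- rowsum(w_fall, idx)[, 1]
  out <- array(0, dF)
  for (t in seq_len(dF[3])) {
    f <- as.vector(frp$data[, , t])
    cv <- as.vector(coarse$data[, , t])
    ftot <- rowsum(f, idx)[, 1]
    use_frp <- ftot > 0
    share <- numeric(length(f))
    share[use_frp[idx]] <- f[use_frp[idx]] / ftot[idx][use_frp[idx]]
    nf <- !use_frp[idx] & cv[idx] > 0
    if (any(nf)) share[nf] <- w_fall[nf] / fall_tot[idx][nf]
    out[, , t] <- share * cv[idx]
  }
  emissions_field(out, coarse$time, coarse$species, coarse$units, grid = "fine")
}

#' Estimate per-transition monthly emission rates
#'
#' The learned emissions model: for each coarse cell `c`, attribution label
#' `T` (see [transition_labels]) and calendar month `m`,
#' `rate(c, T, m)` is the multi-year mean over the observation years of the
#' summed fine emissions of label-`T` cells inside `c` during month `m`,
#' divided by the label's area in `c`. Strata absent from a coarse cell get
#' no entry (not a zero rate). Months with no fire contribute zeros to the
#' mean.
#'
#' @param fine A fine-grid [emissions_field] spanning >= 1 whole years.
#' @param lulc A [lulc_map] (stable labels) or list of two maps (transition
#'   labels over the window); alternatively pass `labels` directly.
#' @param factor Coarsening factor defining the coarse grid.
#' @param labels Optional precomputed label matrix.
#' @return Object of class `fire_rates`: a data frame (`coarse`, `label`,
#'   `month`, `rate`, `area`) with rate in input mass units per km2 per
#'   month, plus grid metadata.
#' @export
estimate_scaling_factors <- function(fine, lulc = NULL, factor, labels = NULL) {
  d <- dim(fine$data)
  check_nesting(d[1], d[2], factor)
  if (is.null(labels)) {
    if (is.null(lulc)) stop("supply `lulc` or `labels`")
    if (inherits(lulc, "lulc_map")) {
      labels <- transition_labels(lulc)
      area_m <- cell_area_matrix(lulc)
    } else {
      labels <- transition_labels(lulc[[1]], lulc[[length(lulc)]])
      area_m <- cell_area_matrix(lulc[[1]])
    }
  } else {
    area_m <- if (inherits(lulc, "lulc_map")) cell_area_matrix(lulc)
              else matrix(1, d[1], d[2])
  }
  idx <- as.vector(coarse_index(d[1], d[2], factor))
  key <- paste(idx, as.vector(labels), sep = "|")
  ukey <- sort(unique(key))
  area <- rowsum(as.vector(area_m), key)[ukey, 1]
  months <- fine$time$month
  years <- unique(fine$time$year)
  n_years_m <- tabulate(months, nbins = 12L)
  sums <- matrix(0, length(ukey), 12L, dimnames = list(ukey, NULL))
  for (t in seq_len(d[3])) {
    s <- rowsum(as.vector(fine$data[, , t]), key)
    sums[rownames(s), months[t]] <- sums[rownames(s), months[t]] + s[, 1]
  }
  rate <- sweep(sums, 2, pmax(n_years_m, 1L), "/") / area
  parts <- strsplit(ukey, "|", fixed = TRUE)
  tab <- data.frame(
    coarse = rep(as.integer(vapply(parts, `[`, "", 1L)), each = 12L),
    label = rep(vapply(parts, `[`, "", 2L), each = 12L),
    month = rep(1:12, times = length(ukey)),
    rate = as.vector(t(rate)),
    area = rep(as.numeric(area), each = 12L))
  structure(list(table = tab, factor = as.integer(factor),
                 coarse_dim = c(d[1] %/% factor, d[2] %/% factor),
                 units = fine$units, n_years = length(years)),
            class = "fire_rates")
}

#' @export
print.fire_rates <- function(x, ...) {
  cat(sprintf("<fire_rates> %d coarse cells x strata, %d-year calibration, units %s/km2/month\n",
              nrow(x$table) / 12L, x$n_years, x$units))
  cat("strata:", paste(sort(unique(x$table$label)), collapse = ", "), "\n")
  invisible(x)
}

#' Project future fire emissions from learned rates
#'
#' Applies the per-coarse-cell, per-stratum monthly rates to the stratum
#' areas of a projected land-use sequence:
#' `E(c, m, y) = sum_T area_future(c, T, period(y)) x rate(c, T, m)`,
#' where `period(y)` is the 5-year land-use map containing year `y`. Strata
#' present in the future with no learned rate contribute zero, with a
#' warning.
#'
#' @param rates A `fire_rates` fit.
#' @param future_labels List of label matrices (one per land-use period), or
#'   list of [lulc_map] from which consecutive-pair transition labels are
#'   derived (the last map contributes stable labels).
#' @param years Calendar years to project.
#' @param period_starts First year covered by each element of
#'   `future_labels`.
#' @param cell_area Fine-cell areas (scalar or per-row) when label matrices
#'   are passed directly.
#' @param output `"coarse"` (default) or `"fine"`: the fine output assigns
#'   `rate x cell area` to every fine cell of a stratum, so fine-grid
#'   scenario masks can be applied before aggregation; its block sums equal
#'   the coarse output exactly.
#' @return A DM [emissions_field] (monthly, `years` x 12) on the requested
#'   grid.
#' @export
project_emissions <- function(rates, future_labels, years, period_starts,
                              cell_area = 1, output = c("coarse", "fine")) {
  output <- match.arg(output)
  stopifnot(inherits(rates, "fire_rates"))
  if (length(future_labels) != length(period_starts))
    stop("one period start per future map")
  if (inherits(future_labels[[1]], "lulc_map")) {
    maps <- future_labels
    area_m <- cell_area_matrix(maps[[1]])
    future_labels <- lapply(seq_along(maps), function(p)
      if (p < length(maps)) transition_labels(maps[[p]], maps[[p + 1L]])
      else transition_labels(maps[[p]]))
  } else {
    area_m <- matrix(cell_area, nrow(future_labels[[1]]),
                     ncol(future_labels[[1]]))
    if (length(cell_area) > 1L)
      area_m <- matrix(rep(cell_area, ncol(future_labels[[1]])),
                       nrow(future_labels[[1]]))
  }
  d <- dim(future_labels[[1]])
  check_nesting(d[1], d[2], rates$factor)
  if (any(years < min(period_starts)))
    stop("years precede the projected land-use coverage")
  idx <- as.vector(coarse_index(d[1], d[2], rates$factor))
  Nr <- rates$coarse_dim[1]; Nc <- rates$coarse_dim[2]
  rate_key <- paste(rates$table$coarse, rates$table$label, rates$table$month,
                    sep = "|")
  rate_lut <- stats::setNames(rates$table$rate, rate_key)
  n_m <- 12L * length(years)
  fine_out <- output == "fine"
  out <- if (fine_out) array(0, c(d[1], d[2], n_m)) else array(0, c(Nr, Nc, n_m))
  time <- data.frame(year = rep(years, each = 12L), month = rep(1:12, length(years)))
  warned <- character(0)
  area_v <- as.vector(area_m)
  for (yi in seq_along(years)) {
    p <- findInterval(years[yi], period_starts)
    lab <- future_labels[[p]]
    key <- paste(idx, as.vector(lab), sep = "|")
    ukey <- unique(key)
    cell_of <- match(key, ukey)
    for (m in 1:12) {
      rk <- paste(ukey, m, sep = "|")
      r <- rate_lut[rk]
      miss <- is.na(r)
      if (any(miss)) {
        warned <- union(warned, ukey[miss])
        r[miss] <- 0
      }
      e_cell <- area_v * r[cell_of]
      if (fine_out) {
        out[, , (yi - 1L) * 12L + m] <- matrix(e_cell, d[1], d[2])
      } else {
        slice <- numeric(Nr * Nc)
        agg <- rowsum(e_cell, idx)
        slice[as.integer(rownames(agg))] <- agg[, 1]
        out[, , (yi - 1L) * 12L + m] <- matrix(slice, Nr, Nc)
      }
    }
  }
  if (length(warned))
    warning("no learned rate for ", length(warned),
            " coarse-cell/stratum combination(s); treated as zero")
  emissions_field(out, time, species = "DM", units = rates$units,
                  grid = if (fine_out) "fine" else "coarse")
}

#' @export
predict.fire_rates <- function(object, future_labels, years, period_starts,
                               cell_area = 1, ...) {
  project_emissions(object, future_labels, years, period_starts, cell_area)
}

#' Default OC / BC emission factors by fire type
#'
#' Representative biomass-burning emission factors (g species per kg dry
#' matter burned) for tropical peat fires, deforestation fires and
#' agricultural / other fires. Configuration data, not hard science: supply
#' your own table for real analyses.
#'
#' @return Data frame with `fire_type`, `ef_oc`, `ef_bc` (g/kg DM).
#' @export
default_emission_factors <- function() {
  data.frame(fire_type = c("peat", "deforestation", "agricultural"),
             ef_oc = c(6.02, 4.71, 2.30),
             ef_bc = c(0.04, 0.52, 0.75),
             stringsAsFactors = FALSE)
}

#' Map attribution labels to fire types
#'
#' Peat cells burn as peat fires; nonpeat conversions of primary forest
#' (intact or degraded sources) are deforestation fires; everything else is
#' agricultural / other burning. Total: every label maps to a type.
#'
#' @param labels Character label matrix (see [transition_labels]).
#' @return Character matrix of fire types.
#' @export
fire_type_from_labels <- function(labels) {
  out <- matrix("agricultural", nrow(labels), ncol(labels))
  defo <- grepl("^(intact|degraded)>", labels)
  out[defo] <- "deforestation"
  out[grepl("\\.peat$", labels)] <- "peat"
  out
}

#' Speciate dry-matter emissions to OC and BC
#'
#' Species mass = DM mass x EF(fire type) / 1000, keeping the input mass
#' unit (EFs are g species per kg DM, applied as kg/kg).
#'
#' @param dm A DM [emissions_field] (fine grid).
#' @param ef Emission-factor table (see [default_emission_factors]).
#' @param fire_types Character matrix of per-cell fire types covering every
#'   cell (see [fire_type_from_labels]).
#' @return List with `OC` and `BC` [emissions_field]s.
#' @export
speciate <- function(dm, ef, fire_types) {
  if (dm$species != "DM") stop("speciate expects a DM field")
  d <- dim(dm$data)
  if (!identical(d[1:2], dim(fire_types)))
    stop("fire-type map must match the emissions grid")
  unmapped <- setdiff(unique(as.vector(fire_types)), ef$fire_type)
  if (length(unmapped))
    stop("fire type(s) without emission factors: ",
         paste(unmapped, collapse = ", "))
  f_oc <- stats::setNames(ef$ef_oc, ef$fire_type)[as.vector(fire_types)] / 1000
  f_bc <- stats::setNames(ef$ef_bc, ef$fire_type)[as.vector(fire_types)] / 1000
  oc <- dm$data; bc <- dm$data
  for (t in seq_len(d[3])) {
    oc[, , t] <- dm$data[, , t] * matrix(f_oc, d[1], d[2])
    bc[, , t] <- dm$data[, , t] * matrix(f_bc, d[1], d[2])
  }
  list(OC = emissions_field(oc, dm$time, "OC", dm$units, dm$grid),
       BC = emissions_field(bc, dm$time, "BC", dm$units, dm$grid))
}
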