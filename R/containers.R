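#' Land-cover class codebook
#'
#' Integer codes for the four base land-cover classes used throughout the
#' package. Peat status is carried as a separate immutable logical layer, so
#' the effective classification is 4 cover classes x peat/nonpeat.
#'
#' @format Named integer vector: intact primary forest (1), degraded primary
#'   forest (2), tree plantation / secondary forest (3), nonforest (4).
#' @export
LULC_CLASSES <- c(intact = 1L, degraded = 2L, plantation = 3L, nonforest = 4L)

#' Construct a land-use / land-cover map
#'
#' A categorical fine-grid map with an immutable peat flag and per-row cell
#' areas. The peat flag is kept separate from the cover class so that cover
#' transitions never touch it.
#'
#' @param classes Integer matrix of class codes (see [LULC_CLASSES]).
#' @param peat Logical matrix, same dimensions; TRUE for peatland cells.
#' @param cell_area Cell area in km2: a scalar or a vector of length
#'   `nrow(classes)` (one area per grid row, allowing latitude-dependent
#'   areas).
#' @param period Integer period index (projection step; 0 = calibration start).
#' @return An object of class `lulc_map`.
#' @export
lulc_map <- function(classes, peat, cell_area = 1, period = 0L) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  peat <- as.matrix(peat)
  if (!identical(dim(classes), dim(peat)))
    stop("`classes` and `peat` must have identical dimensions")
  if (!all(classes %in% LULC_CLASSES))
    stop("unknown class code in `classes`")
  if (length(cell_area) == 1L) cell_area <- rep(cell_area, nrow(classes))
  if (length(cell_area) != nrow(classes))
    stop("`cell_area` must be scalar or one value per grid row")
  if (any(cell_area <= 0)) stop("cell areas must be positive")
  structure(
    list(classes = classes, peat = peat > 0,
         cell_area = as.numeric(cell_area), period = as.integer(period)),
    class = "lulc_map")
}

#' @export
print.lulc_map <- function(x, ...) {
  cat(sprintf("<lulc_map> %d x %d cells, period %d\n",
              nrow(x$classes), ncol(x$classes), x$period))
  tab <- class_areas(x)
  print(tab)
  invisible(x)
}

#' Per-class areas of a map
#'
#' @param map A [lulc_map].
#' @param by_peat Split classes by peat status.
#' @return Named numeric vector of areas (km2) summing to the domain area.
#' @export
class_areas <- function(map, by_peat = FALSE) {
  area <- cell_area_matrix(map)
  key <- names(LULC_CLASSES)[map$classes]
  if (by_peat) key <- paste0(key, ifelse(map$peat, ".peat", ".nonpeat"))
  tapply(area, key, sum)
}

#' Matrix of cell areas for a map
#' @param map A [lulc_map].
#' @return Numeric matrix of per-cell areas (km2).
#' @export
cell_area_matrix <- function(map) {
  matrix(map$cell_area, nrow(map$classes), ncol(map$classes))
}

#' Construct a gridded monthly emissions field
#'
#' A dense array of per-cell, per-month emitted mass with mandatory species
#' and units metadata. The same container holds fine-grid and coarse-grid
#' fields; `grid` records which.
#'
#' @param data Numeric array `[rows, cols, n_months]`, nonnegative.
#' @param time Data frame with columns `year` and `month` (1-12), one row per
#'   slice of the third dimension.
#' @param species One of `"DM"`, `"OC"`, `"BC"`, or `"OCBC"` (summed smoke
#'   aerosol).
#' @param units Mass unit per cell per month, e.g. `"kg"` or `"Tg"`.
#' @param grid `"fine"` or `"coarse"`.
#' @return An object of class `emissions_field`.
#' @export
emissions_field <- function(data, time, species, units, grid = "fine") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3-d array [row, col, month]")
  if (any(data < 0)) stop("emissions must be nonnegative")
  if (missing(species) || missing(units)) stop("species and units metadata are mandatory")
  species <- match.arg(species, c("DM", "OC", "BC", "OCBC"))
  time <- as.data.frame(time)
  if (!all(c("year", "month") %in% names(time)) || nrow(time) != dim(data)[3])
    stop("`time` must have year/month columns, one row per month slice")
  structure(list(data = data, time = time, species = species,
                 units = units, grid = grid),
            class = "emissions_field")
}

#' @export
print.emissions_field <- function(x, ...) {
  cat(sprintf("<emissions_field> %s [%s] %s grid %d x %d, %d months (%d-%02d .. %d-%02d), total %.4g\n",
              x$species, x$units, x$grid, dim(x$data)[1], dim(x$data)[2],
              nrow(x$time), x$time$year[1], x$time$month[1],
              x$time$year[nrow(x$time)], x$time$month[nrow(x$time)],
              sum(x$data)))
  invisible(x)
}

#' Construct a fire radiative power field
#'
#' Fine-grid monthly FRP used as a spatial weight when downscaling coarse
#' emissions. Absolute calibration is irrelevant: only within-coarse-cell
#' relative weights enter the downscaling.
#'
#' @param data Nonnegative numeric array `[rows, cols, n_months]`.
#' @param time Data frame with `year`, `month` columns matching the 3rd dim.
#' @return An object of class `frp_field`.
#' @export
frp_field <- function(data, time) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3-d array")
  if (any(data < 0)) stop("FRP must be nonnegative")
  structure(list(data = data, time = as.data.frame(time)), class = "frp_field")
}

#' Construct an adjoint sensitivity field
#'
#' Per-receptor, per-meteorological-year monthly coarse-grid sensitivities of
#' receptor population-weighted PM2.5 to a unit emission flux in each source
#' cell, in (ug/m3) / (g/m2/s). Population weighting is baked into the fields
#' (it is part of the adjoint cost function), so downstream exposure code
#' never touches population rasters.
#'
#' @param fields Named list (one element per receptor) of numeric arrays
#'   `[rows, cols, 12, n_met_years]`, nonnegative and finite.
#' @param met_years Integer vector of meteorological-year labels, length equal
#'   to the 4th dimension of every array.
#' @return An object of class `sensitivity_field`.
#' @export
sensitivity_field <- function(fields, met_years) {
  if (!length(fields) || is.null(names(fields)))
    stop("`fields` must be a named list with one entry per receptor")
  for (r in names(fields)) {
    a <- fields[[r]]
    if (length(dim(a)) != 4L || dim(a)[3] != 12L)
      stop("each receptor field must be [rows, cols, 12, n_met_years]")
    if (dim(a)[4] != length(met_years))
      stop("4th dimension must match length(met_years)")
    if (any(!is.finite(a)) || any(a < 0))
      stop("sensitivities must be finite and nonnegative")
  }
  structure(list(fields = fields, met_years = as.integer(met_years),
                 receptors = names(fields)),
            class = "sensitivity_field")
}

#' @export
print.sensitivity_field <- function(x, ...) {
  d <- dim(x$fields[[1]])
  cat(sprintf("<sensitivity_field> %d receptor(s): %s; grid %d x %d, met years %s\n",
              length(x$fields), paste(x$receptors, collapse = ", "),
              d[1], d[2], paste(range(x$met_years), collapse = "-")))
  invisible(x)
}
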