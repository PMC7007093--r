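# Grid plumbing: exact nesting of the fine grid into the coarse grid, block
# aggregation, and a chamfer distance transform for dynamic evidence layers.
# Grids are axis-aligned, row-major matrices; the coarse grid is defined by an
# integer coarsening factor that must divide both fine dimensions.

#' Check that a fine grid nests exactly into a coarse grid
#'
#' @param nr,nc Fine grid dimensions.
#' @param factor Integer coarsening factor (>= 1).
#' @return Invisibly TRUE; stops on mismatch.
#' @export
check_nesting <- function(nr, nc, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("coarsening factor must be >= 1")
  if (nr %% factor != 0L || nc %% factor != 0L)
    stop(sprintf("grid %d x %d is not divisible by coarsening factor %d",
                 nr, nc, factor))
  invisible(TRUE)
}

#' Coarse-cell index of every fine cell
#'
#' @param nr,nc Fine grid dimensions.
#' @param factor Coarsening factor.
#' @return Integer matrix `[nr, nc]`; values are 1-based coarse linear indices
#'   in column-major order over the `(nr/factor) x (nc/factor)` coarse grid.
#' @export
coarse_index <- function(nr, nc, factor) {
  check_nesting(nr, nc, factor)
  ci <- (seq_len(nr) - 1L) %/% factor + 1L
  cj <- (seq_len(nc) - 1L) %/% factor + 1L
  outer(ci, cj, function(i, j) i + (j - 1L) * (nr %/% factor))
}

#' Aggregate a fine matrix to the coarse grid by block sum
#'
#' @param x Numeric matrix on the fine grid.
#' @param factor Coarsening factor.
#' @return Matrix on the coarse grid; each entry is the sum over its block of
#'   `factor^2` fine cells.
#' @export
block_sum <- function(x, factor) {
  idx <- coarse_index(nrow(x), ncol(x), factor)
  out <- rowsum(as.vector(x), as.vector(idx))
  matrix(out, nrow(x) %/% factor, ncol(x) %/% factor)
}

#' Aggregate a fine emissions field to the coarse grid
#'
#' Per-month block sums; mass is conserved exactly.
#'
#' @param E A fine-grid [emissions_field].
#' @param factor Coarsening factor.
#' @return A coarse-grid [emissions_field] with the same time axis, species
#'   and units.
#' @export
aggregate_emissions <- function(E, factor) {
  d <- dim(E$data)
  check_nesting(d[1], d[2], factor)
  out <- array(0, c(d[1] %/% factor, d[2] %/% factor, d[3]))
  for (t in seq_len(d[3])) out[, , t] <- block_sum(E$data[, , t], factor)
  emissions_field(out, E$time, E$species, E$units, grid = "coarse")
}

#' Distance to the nearest cell of a target set
#'
#' Two-pass chamfer (3-4) distance transform, scaled so that the horizontal /
#' vertical step is 1 cell. Used to build dynamic distance-to-class evidence
#' layers that are recomputed at every projection step.
#'
#' @param target Logical matrix; TRUE marks the cells distance is measured to.
#' @return Numeric matrix of approximate Euclidean distances in cell units;
#'   `Inf` if `target` has no TRUE cell.
#' @export
distance_to <- function(target) {
  target <- as.matrix(target)
  nr <- nrow(target); nc <- ncol(target)
  big <- 3 * (nr + nc) + 10
  d <- ifelse(target, 0, big)
  # forward pass
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    v <- d[i, j]
    if (i > 1L) v <- min(v, d[i - 1L, j] + 3)
    if (j > 1L) v <- min(v, d[i, j - 1L] + 3)
    if (i > 1L && j > 1L) v <- min(v, d[i - 1L, j - 1L] + 4)
    if (i < nr && j > 1L) v <- min(v, d[i + 1L, j - 1L] + 4)
    d[i, j] <- v
  }
  # backward pass
  for (j in rev(seq_len(nc))) for (i in rev(seq_len(nr))) {
    v <- d[i, j]
    if (i < nr) v <- min(v, d[i + 1L, j] + 3)
    if (j < nc) v <- min(v, d[i, j + 1L] + 3)
    if (i < nr && j < nc) v <- min(v, d[i + 1L, j + 1L] + 4)
    if (i > 1L && j < nc) v <- min(v, d[i - 1L, j + 1L] + 4)
    d[i, j] <- v
  }
  d <- d / 3
  d[d >= big / 3] <- Inf
  d
}

#' Distance-to-class dynamic evidence layer
#'
#' @param map A [lulc_map].
#' @param class_code Integer class code (see [LULC_CLASSES]).
#' @return Numeric matrix: per-cell distance (cell units) to the nearest cell
#'   of the class.
#' @export
distance_to_class <- function(map, class_code) {
  distance_to(map$classes == class_code)
}

#' Days in a calendar month
#' @param year,month Integer vectors (recycled).
#' @return Integer vector of month lengths, Gregorian leap rule applied.
#' @export
days_in_month <- function(year, month) {
  n <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  n + ifelse(month == 2L & leap, 1L, 0L)
}
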