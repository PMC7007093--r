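# Plain-text serialization of the pipeline's tabular artifacts. Gridded
# inputs live in memory as arrays; the learned model objects and result
# tables round-trip through CSV.

#' Write / read a scaling-factor table as CSV
#'
#' Columns: coarse, label, month, rate, area; grid metadata in a `# key=value`
#' header comment.
#'
#' @param x A `fire_rates` object.
#' @param path Output file.
#' @return `write_fire_rates`: the path, invisibly. `read_fire_rates`: the
#'   reconstructed `fire_rates`.
#' @export
write_fire_rates <- function(x, path) {
  hdr <- sprintf("# factor=%d rows=%d cols=%d units=%s n_years=%d",
                 x$factor, x$coarse_dim[1], x$coarse_dim[2], x$units, x$n_years)
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(x$table, path, sep = ",", row.names = FALSE,
                                      col.names = TRUE, append = TRUE))
  invisible(path)
}

#' @rdname write_fire_rates
#' @export
read_fire_rates <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(list(table = tab, factor = as.integer(meta[["factor"]]),
                 coarse_dim = c(as.integer(meta[["rows"]]),
                                as.integer(meta[["cols"]])),
                 units = meta[["units"]], n_years = as.integer(meta[["n_years"]])),
            class = "fire_rates")
}

#' Write weights-of-evidence weights as CSV
#'
#' One row per transition x layer x bin: transition, layer, bin, bin_lo,
#' bin_hi, weight.
#'
#' @param x A `woe_fit`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_woe <- function(x, path) {
  utils::write.csv(x$weights, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an exposure series as CSV (receptor, year, month, pm25)
#'
#' @param x An `exposure_series`.
#' @param path File path.
#' @return `write_exposure`: the path, invisibly; `read_exposure`: the
#'   series.
#' @export
write_exposure <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposure
#' @export
read_exposure <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("exposure_series", "data.frame")
  out
}
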