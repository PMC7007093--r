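# Land-use / land-cover change modelling: layer merging into the analysis
# classification, multicollinearity screening, weights-of-evidence (WoE)
# calibration, and ranked-allocation projection in 5-year steps.
#
# The WoE core follows the standard Bayesian log-odds formulation: for a
# transition T and an evidence bin b, W+(T, b) = ln P(b | T) / P(b | not T),
# with additive smoothing (+0.5 counts) to keep weights finite. Conditional
# independence of evidence layers is assumed after VIF screening; the
# patch-geometry machinery of cellular land-change simulators is deliberately
# omitted because patch shape does not affect coarse-cell emissions totals.

#' Merge forest, tree-cover and peat layers into the analysis classification
#'
#' Nonforested areas (per the forest map) that carry tree cover become the
#' aggregated tree plantation / secondary forest class; nonforested areas
#' without tree cover stay nonforest; intact and degraded primary forest pass
#' through. The peat mask is attached as the immutable peat flag.
#'
#' @param forest_map Integer matrix coded 1 = intact primary, 2 = degraded
#'   primary, 3 = nonforest.
#' @param treecover_map Binary matrix (1 = tree cover present).
#' @param peat_mask Binary matrix (1 = peatland).
#' @param cell_area Cell area in km2 (scalar or per-row).
#' @return A [lulc_map] on the 4-class codebook.
#' @export
merge_layers <- function(forest_map, treecover_map, peat_mask, cell_area = 1) {
  forest_map <- as.matrix(forest_map)
  if (!identical(dim(forest_map), dim(as.matrix(treecover_map))) ||
      !identical(dim(forest_map), dim(as.matrix(peat_mask))))
    stop("forest, tree-cover and peat layers must share one grid")
  if (!all(forest_map %in% 1:3))
    stop("unknown class code in forest_map (expected 1=intact, 2=degraded, 3=nonforest)")
  tc <- as.matrix(treecover_map) > 0
  classes <- forest_map
  classes[forest_map == 3L & tc] <- LULC_CLASSES[["plantation"]]
  classes[forest_map == 3L & !tc] <- LULC_CLASSES[["nonforest"]]
  lulc_map(classes, peat_mask, cell_area = cell_area, period = 0L)
}

#' Variance inflation factors for evidence layers
#'
#' Regresses each layer on all others over all cells and reports
#' VIF = 1 / (1 - R^2), flagging layers at or above the threshold. Used to
#' screen collinear covariates before weights-of-evidence calibration, whose
#' additive log-odds combination assumes conditional independence.
#'
#' @param evidence_layers Named list of >= 2 numeric matrices on one grid.
#' @param threshold Flagging threshold (default 5).
#' @return Data frame with `layer`, `vif`, `pass` (TRUE when VIF < threshold).
#' @export
check_vif <- function(evidence_layers, threshold = 5) {
  if (length(evidence_layers) < 2L) stop("need at least 2 evidence layers")
  X <- sapply(evidence_layers, as.vector)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("layer", seq_len(ncol(X)))
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    stop("constant evidence layer (undefined VIF): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  vif <- vapply(seq_len(ncol(X)), function(i) {
    fit <- stats::lm.fit(cbind(1, X[, -i, drop = FALSE]), X[, i])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, i] - mean(X[, i]))^2)
    if (r2 >= 1) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(layer = colnames(X), vif = vif, pass = vif < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

.transition_name <- function(from, to) {
  paste0(names(LULC_CLASSES)[from], ">", names(LULC_CLASSES)[to])
}

# Materialize evidence layers (matrices, or functions of the current map
# for dynamic layers such as distance-to-class) on a given map.
.eval_layers <- function(evidence_layers, map) {
  lapply(evidence_layers, function(l) if (is.function(l)) l(map) else as.matrix(l))
}

#' Calibrate a weights-of-evidence transition model
#'
#' For every observed cover transition between the two calibration maps,
#' computes binned positive weights of evidence
#' `W+(T, b) = ln[ P(b | T occurred) / P(b | T did not occur) ]`
#' over the cells eligible for the transition (source-class cells at t0),
#' with +0.5 additive count smoothing per bin, plus the transition prior
#' (observed transitioned fraction of eligible cells). Continuous layers are
#' binned by quantiles (deciles by default) over the eligible cells.
#'
#' @param map_t0,map_t1 Calibration [lulc_map]s on one grid.
#' @param evidence_layers Named list of numeric matrices, or functions of a
#'   map (dynamic layers, e.g. [distance_to_class]).
#' @param bins Number of quantile bins per layer (default 10).
#' @param transitions Optional data frame (`from`, `to` class codes)
#'   restricting the modeled transitions; default: every observed pair.
#' @return An object of class `woe_fit` with components `weights` (one row
#'   per transition x layer x bin, with bin edges), `priors`, `demand`
#'   (observed per-5-year transition counts, the business-as-usual default),
#'   and the layer names.
#' @export
calibrate_woe <- function(map_t0, map_t1, evidence_layers, bins = 10,
                          transitions = NULL) {
  if (!identical(dim(map_t0$classes), dim(map_t1$classes)))
    stop("calibration maps must share one grid")
  layers <- .eval_layers(evidence_layers, map_t0)
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("evidence layers must be named")
  c0 <- as.vector(map_t0$classes); c1 <- as.vector(map_t1$classes)
  if (is.null(transitions)) {
    tab <- table(c0, c1)
    idx <- which(tab > 0, arr.ind = TRUE)
    idx <- idx[as.integer(rownames(tab)[idx[, 1]]) !=
               as.integer(colnames(tab)[idx[, 2]]), , drop = FALSE]
    transitions <- data.frame(from = as.integer(rownames(tab)[idx[, 1]]),
                              to = as.integer(colnames(tab)[idx[, 2]]))
  }
  w_rows <- list(); p_rows <- list()
  for (k in seq_len(nrow(transitions))) {
    from <- transitions$from[k]; to <- transitions$to[k]
    tn <- .transition_name(from, to)
    elig <- c0 == from
    if (!any(elig)) stop("no eligible source cells for transition ", tn)
    ev <- elig & c1 == to
    n_elig <- sum(elig); n_ev <- sum(ev)
    p_rows[[tn]] <- data.frame(transition = tn, from = from, to = to,
                               prior = n_ev / n_elig,
                               n_eligible = n_elig, n_events = n_ev)
    for (ln in names(layers)) {
      x <- as.vector(layers[[ln]])[elig]
      edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                      names = FALSE, type = 7))
      if (length(edges) < 2L) edges <- c(min(x) - 0.5, max(x) + 0.5)
      edges[1] <- -Inf; edges[length(edges)] <- Inf
      b <- cut(x, edges, labels = FALSE, include.lowest = TRUE)
      nb <- length(edges) - 1L
      evb <- as.vector(ev)[elig]
      n1 <- tabulate(b[evb], nbins = nb)
      n0 <- tabulate(b[!evb], nbins = nb)
      p1 <- (n1 + 0.5) / (sum(n1) + 0.5 * nb)
      p0 <- (n0 + 0.5) / (sum(n0) + 0.5 * nb)
      w_rows[[paste(tn, ln)]] <- data.frame(
        transition = tn, layer = ln, bin = seq_len(nb),
        bin_lo = edges[-length(edges)], bin_hi = edges[-1],
        weight = log(p1 / p0))
    }
  }
  priors <- do.call(rbind, p_rows); rownames(priors) <- NULL
  weights <- do.call(rbind, w_rows); rownames(weights) <- NULL
  structure(list(weights = weights, priors = priors,
                 layer_names = names(layers), bins = bins,
                 demand = stats::setNames(priors$n_events, priors$transition)),
            class = "woe_fit")
}

#' @export
print.woe_fit <- function(x, ...) {
  cat(sprintf("<woe_fit> %d transition(s), %d evidence layer(s), %d bins\n",
              nrow(x$priors), length(x$layer_names), x$bins))
  print(x$priors[, c("transition", "prior", "n_eligible", "n_events")])
  invisible(x)
}

#' @export
summary.woe_fit <- function(object, ...) {
  agg <- stats::aggregate(weight ~ transition + layer, data = object$weights,
                          FUN = function(w) max(abs(w)))
  names(agg)[3] <- "max_abs_weight"
  out <- list(priors = object$priors, influence = agg)
  class(out) <- "summary.woe_fit"
  out
}

#' @export
print.summary.woe_fit <- function(x, ...) {
  print(x$priors[, c("transition", "prior", "n_events")])
  cat("\nLayer influence (max |W+|):\n")
  print(x$influence)
  invisible(x)
}

#' @export
coef.woe_fit <- function(object, ...) object$weights

#' Transition probability surfaces from a weights-of-evidence fit
#'
#' Per modeled transition, combines the prior log-odds with the summed
#' layer weights: `logit(p) = logit(prior) + sum_layers W+(layer bin)`.
#' Cells not in the source class get `NA`.
#'
#' @param object A `woe_fit`.
#' @param map Current [lulc_map].
#' @param evidence_layers Evidence layers (matrices or functions of the map);
#'   must carry the names used at calibration.
#' @param ... Unused.
#' @return Named list of probability matrices, one per transition.
#' @export
predict.woe_fit <- function(object, map, evidence_layers, ...) {
  layers <- .eval_layers(evidence_layers, map)
  missing_l <- setdiff(object$layer_names, names(layers))
  if (length(missing_l))
    stop("missing evidence layer(s): ", paste(missing_l, collapse = ", "))
  out <- list()
  for (k in seq_len(nrow(object$priors))) {
    tn <- object$priors$transition[k]
    from <- object$priors$from[k]
    prior <- object$priors$prior[k]
    eta <- matrix(stats::qlogis(min(max(prior, 1e-12), 1 - 1e-12)),
                  nrow(map$classes), ncol(map$classes))
    for (ln in object$layer_names) {
      wtab <- object$weights[object$weights$transition == tn &
                             object$weights$layer == ln, ]
      b <- findInterval(as.vector(layers[[ln]]), wtab$bin_lo)
      b[b < 1L] <- 1L; b[b > nrow(wtab)] <- nrow(wtab)
      eta <- eta + matrix(wtab$weight[b], nrow(map$classes), ncol(map$classes))
    }
    p <- stats::plogis(eta)
    p[map$classes != from] <- NA_real_
    out[[tn]] <- p
  }
  out
}

#' Project land use forward with ranked allocation
#'
#' Business-as-usual projection in 5-year steps: at each step, for each
#' modeled transition, the probability surface from the weights-of-evidence
#' fit is evaluated on the current map (dynamic evidence layers are
#' recomputed each step) and exactly `demand` eligible cells are converted -
#' the top-probability cells, with seeded uniform tie-breaking. Transitions
#' are processed in the fit's order; converted cells leave the eligible pool
#' within a step. Total cell count and the peat mask are conserved.
#'
#' @param map Starting [lulc_map].
#' @param woe A `woe_fit`.
#' @param demand Named vector (transition name -> cells per step); defaults
#'   to the calibration-period observed counts stored in the fit.
#' @param n_steps Number of 5-year steps.
#' @param seed Integer seed for tie-breaking.
#' @param evidence_layers Evidence layers (matrices or functions of a map).
#' @return List of [lulc_map]: the input map followed by `n_steps` projected
#'   maps.
#' @export
project_lulc <- function(map, woe, demand = NULL, n_steps = 1L, seed = 1L,
                         evidence_layers) {
  if (is.null(demand)) demand <- woe$demand
  unknown <- setdiff(names(demand), woe$priors$transition)
  if (length(unknown)) stop("demand names unknown to the fit: ",
                            paste(unknown, collapse = ", "))
  set.seed(seed)
  out <- vector("list", n_steps + 1L)
  out[[1]] <- map
  for (s in seq_len(n_steps)) {
    cur <- out[[s]]
    nxt_classes <- cur$classes
    tie <- matrix(stats::runif(length(cur$classes)), nrow(cur$classes))
    probs <- predict(woe, cur, evidence_layers)
    converted <- matrix(FALSE, nrow(cur$classes), ncol(cur$classes))
    for (k in seq_len(nrow(woe$priors))) {
      tn <- woe$priors$transition[k]
      dem <- if (tn %in% names(demand)) demand[[tn]] else 0L
      if (dem <= 0) next
      to <- woe$priors$to[k]
      p <- probs[[tn]]
      p[converted] <- NA_real_
      avail <- which(!is.na(p))
      if (dem > length(avail))
        stop(sprintf("infeasible demand for %s: %d requested, %d eligible",
                     tn, dem, length(avail)))
      if (all(p[avail] == 0))
        stop("probability surface identically zero with positive demand for ", tn)
      ord <- avail[order(-p[avail], tie[avail])]
      sel <- ord[seq_len(dem)]
      nxt_classes[sel] <- to
      converted[sel] <- TRUE
    }
    out[[s + 1L]] <- lulc_map(nxt_classes, cur$peat, cur$cell_area,
                              period = cur$period + 1L)
  }
  out
}
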