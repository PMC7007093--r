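# Health impact modelling: concentration-response functions (CRFs) for adult
# all-cause mortality and child (<5) ALRI mortality, and attributable-death
# accounting with CRF confidence intervals.
#
# Adult: linear 1.03% risk increase per ug/m3 annual-average PM2.5
# (95% CI 0.97-1.11%). Child: linear 1.2% per ug/m3 up to 50 ug/m3
# (95% CI from 3-30% per 10 ug/m3), continuing log-linearly above the
# breakpoint with value- and slope-continuity.

#' Construct a concentration-response function
#'
#' @param slope Central fractional risk increase per ug/m3 (e.g. 0.0103 for
#'   1.03%).
#' @param ci_low,ci_high 95% CI bounds on the slope.
#' @param breakpoint Optional breakpoint in ug/m3 above which risk grows
#'   log-linearly (value- and slope-continuous with the linear segment).
#' @param form `"linear"` or `"linear-loglinear"` (implied by a breakpoint).
#' @return Object of class `crf`.
#' @export
crf <- function(slope, ci_low = slope, ci_high = slope, breakpoint = NULL,
                form = if (is.null(breakpoint)) "linear" else "linear-loglinear") {
  if (!(ci_low > 0 && ci_low <= slope && slope <= ci_high))
    stop("need 0 < ci_low <= slope <= ci_high")
  if (!is.null(breakpoint) && breakpoint <= 0)
    stop("breakpoint must be positive")
  form <- match.arg(form, c("linear", "linear-loglinear"))
  if (form == "linear-loglinear" && is.null(breakpoint))
    stop("piecewise form needs a breakpoint")
  structure(list(slope = slope, ci_low = ci_low, ci_high = ci_high,
                 breakpoint = breakpoint, form = form), class = "crf")
}

#' Default adult all-cause CRF (1.03%/ug/m3, 95% CI 0.97-1.11%)
#' @return A linear [crf].
#' @export
crf_adult <- function() crf(0.0103, 0.0097, 0.0111)

#' Default child ALRI CRF (1.2%/ug/m3 to 50 ug/m3, then log-linear;
#' 95% CI 0.3-3.0%/ug/m3)
#' @return A piecewise [crf] with breakpoint 50.
#' @export
crf_child <- function() crf(0.012, 0.003, 0.030, breakpoint = 50)

.delta_risk_1 <- function(C, s, B) {
  if (is.null(B)) return(s * C)
  k <- s / (1 + s * B)
  ifelse(C <= B, s * C, (1 + s * B) * exp(k * (C - B)) - 1)
}

#' Fractional mortality-risk increase at a concentration
#'
#' Linear form: `slope x C`. Piecewise form: linear up to the breakpoint B,
#' then `(1 + slope B) exp(k (C - B)) - 1` with `k = slope / (1 + slope B)`,
#' which is continuous with continuous first derivative at B.
#'
#' @param C Concentration(s) in ug/m3, >= 0.
#' @param object A [crf].
#' @param which `"central"`, `"low"` or `"high"` slope.
#' @return Fractional risk increase(s), nondecreasing in C.
#' @export
delta_risk <- function(C, object, which = c("central", "low", "high")) {
  if (any(C < 0)) stop("concentration must be nonnegative")
  which <- match.arg(which)
  s <- switch(which, central = object$slope, low = object$ci_low,
              high = object$ci_high)
  .delta_risk_1(C, s, object$breakpoint)
}

#' @export
predict.crf <- function(object, C, which = "central", ...) {
  delta_risk(C, object, which)
}

#' @export
print.crf <- function(x, ...) {
  cat(sprintf("<crf> %s: %.2f%% per ug/m3 (95%% CI %.2f-%.2f%%)%s\n",
              x$form, 100 * x$slope, 100 * x$ci_low, 100 * x$ci_high,
              if (!is.null(x$breakpoint))
                sprintf(", breakpoint %g ug/m3", x$breakpoint) else ""))
  invisible(x)
}

#' Attributable deaths from an exposure difference
#'
#' `D = population x baseline rate x [dR(C_with) - dR(C_without)]`, with low
#' and high bounds from the CRF's CI slopes (each bound evaluated with its
#' own slope, including the breakpoint continuation).
#'
#' @param C_with,C_without Concentrations (ug/m3), `C_with >= C_without >= 0`.
#' @param pop Population at risk.
#' @param rate Baseline mortality rate (deaths/person/yr), in (0, 1).
#' @param object A [crf].
#' @return Named numeric: `central`, `low`, `high` attributable deaths/yr.
#' @export
attributable_deaths <- function(C_with, C_without, pop, rate, object) {
  if (any(C_without < 0) || any(C_with < C_without))
    stop("need C_with >= C_without >= 0")
  if (any(rate <= 0 | rate >= 1)) stop("baseline rate must lie in (0, 1)")
  d <- vapply(c("central", "low", "high"), function(w)
    sum(pop * rate * (delta_risk(C_with, object, w) -
                      delta_risk(C_without, object, w))),
    numeric(1))
  d
}

.burden_one <- function(X, pop, crf_a, crf_c, baseline_pm25, exposure_basis) {
  ann <- annual_means(X)
  if (exposure_basis == "seasonal") {
    seas <- stats::aggregate(pm25 ~ receptor + year,
                             data = X[X$month %in% 7:10, , drop = FALSE],
                             FUN = mean)
    ann <- merge(ann[, c("receptor", "year")], seas, by = c("receptor", "year"))
    names(ann)[3] <- "annual_pm25"
  }
  rows <- lapply(seq_len(nrow(pop)), function(i) {
    a <- ann[ann$receptor == pop$name[i], ]
    ad <- t(vapply(a$annual_pm25, function(cc)
      attributable_deaths(cc + baseline_pm25, baseline_pm25,
                          pop$adult_pop[i], pop$mort_all[i], crf_a),
      numeric(3)))
    cd <- t(vapply(a$annual_pm25, function(cc)
      attributable_deaths(cc + baseline_pm25, baseline_pm25,
                          pop$child_pop[i], pop$mort_alri[i], crf_c),
      numeric(3)))
    data.frame(receptor = pop$name[i],
               adult_deaths = mean(ad[, 1]), adult_low = mean(ad[, 2]),
               adult_high = mean(ad[, 3]),
               child_deaths = mean(cd[, 1]), child_low = mean(cd[, 2]),
               child_high = mean(cd[, 3]))
  })
  do.call(rbind, rows)
}

#' Scenario burden report
#'
#' Per receptor and scenario: mean Jul-Oct smoke exposure, annual-average
#' adult all-cause attributable deaths with CRF CI range, child ALRI deaths,
#' and deaths averted by the scenario. Deaths are computed per simulation
#' year from that year's exposure (so El Nino-type met years show through)
#' and then averaged. By default annual attributable deaths use the
#' annual-mean fire PM2.5 (seasonal exposure diluted over 12 months), since
#' the CRFs are annual; set `exposure_basis = "seasonal"` to treat the
#' Jul-Oct mean as the annual concentration instead.
#'
#' @param X_base,X_scn Baseline and scenario `exposure_series` on matching
#'   receptors and years (`X_scn` may be NULL for a baseline-only report).
#' @param pop Receptor table with `name`, `adult_pop`, `child_pop`,
#'   `mort_all`, `mort_alri` (see [gen_population]).
#' @param crf_a,crf_c Adult and child [crf]s.
#' @param baseline_pm25 Non-fire background concentration added to both arms
#'   of the differencing (default 0).
#' @param exposure_basis `"annual"` (default) or `"seasonal"`.
#' @return Data frame of class `burden_table`, one row per receptor x
#'   scenario, with a `scenario` column.
#' @export
burden_table <- function(X_base, X_scn = NULL, pop, crf_a = crf_adult(),
                         crf_c = crf_child(), baseline_pm25 = 0,
                         exposure_basis = c("annual", "seasonal")) {
  exposure_basis <- match.arg(exposure_basis)
  if (!all(pop$name %in% unique(X_base$receptor)))
    stop("population table receptors missing from the exposure series")
  mk <- function(X, scn) {
    b <- .burden_one(X, pop, crf_a, crf_c, baseline_pm25, exposure_basis)
    s <- seasonal_stats(X)
    b$jul_oct_pm25 <- s$mean_pm25[match(b$receptor, s$receptor)]
    b$scenario <- scn
    b
  }
  out <- mk(X_base, "baseline")
  if (!is.null(X_scn)) {
    if (!setequal(unique(X_scn$receptor), unique(X_base$receptor)))
      stop("scenario and baseline receptors differ")
    out <- rbind(out, mk(X_scn, "scenario"))
  }
  class(out) <- c("burden_table", "data.frame")
  out
}

#' @export
print.burden_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  for (cl in c("adult_deaths", "adult_low", "adult_high",
               "child_deaths", "child_low", "child_high"))
    y[[cl]] <- signif(y[[cl]], digits)
  y$jul_oct_pm25 <- round(y$jul_oct_pm25, 1)
  print(y[, c("scenario", "receptor", "jul_oct_pm25", "adult_deaths",
              "adult_low", "adult_high", "child_deaths")], row.names = FALSE)
  invisible(x)
}
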