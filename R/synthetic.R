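# Seeded generators for every pipeline input: land-cover series, fire
# emissions truth with FRP, plume-shaped adjoint sensitivity kernels, and
# population grids. Each generator draws from its own pseudo-random stream,
# derived from the master seed by a fixed offset, so adding a generator never
# shifts the output of an existing one.

.stream <- c(lulc = 11L, fire = 23L, sens = 37L, pop = 53L)

#' Configuration for the synthetic study domain
#'
#' Defines a small multi-island-like toy domain: a fine grid that nests
#' exactly into a coarse grid, four cover classes split by a peat flag, fire
#' propensities concentrated in peat and non-forest classes, a Jul-Oct
#' burning season, an El Nino-like 5-year multiplier cycle, and receptor
#' population centers with a prevailing wind bearing.
#'
#' @param seed Master integer seed; every generator is a pure function of the
#'   configuration, so identical seeds give bit-identical outputs.
#' @param fine_grid Integer `(rows, cols)` of the fine grid.
#' @param coarsening_factor Integer >= 1; must divide both fine dimensions.
#' @param class_fractions Length-4 vector of initial cover-class fractions
#'   (intact, degraded, plantation, nonforest); must sum to 1.
#' @param transition_rates 4x4 matrix of per-5-year transition probabilities;
#'   rows index the source class, off-diagonal entries are used and each row's
#'   off-diagonal sum must be <= 1.
#' @param fire_propensity Length-4 nonnegative emission intensity per class
#'   (mass per km2 per unit seasonal weight).
#' @param peat_multiplier Nonnegative multiplier applied to propensity on
#'   peat cells (drained peat burns far more intensely per unit area).
#' @param peat_fraction Target fraction of the domain flagged as peat.
#' @param seasonality 12-vector of monthly weights, peaking Jul-Oct.
#' @param elnino_cycle Per-year multipliers over a 5-year cycle (default
#'   `c(1, 4, 1, 0.5, 2)`, a mid-cycle strong event).
#' @param receptor_centers Data frame with columns `name`, `row`, `col`,
#'   `mass` (population mass) on the fine grid.
#' @param wind_bearing Degrees; direction from each receptor toward the
#'   upwind source region whose emissions reach it.
#' @param anisotropy In `[0, 1]`: 0 gives radially symmetric sensitivity
#'   kernels, larger values elongate them upwind.
#' @param plume_scale e-folding length of the sensitivity kernels, in coarse
#'   cells.
#' @param sens_amplitude Peak kernel value in (ug/m3)/(g/m2/s); the default
#'   puts synthetic burning-season exposures in the few-ug/m3 range typical
#'   of regional smoke.
#' @param sens_perturb Lognormal sd of the met-year perturbation of the
#'   sensitivity fields (0 = identical fields across met years).
#' @param frp_dropout Probability that a burning fine cell-month has no FRP
#'   detection (exercises the area-ratio downscaling fallback).
#' @param noise_sd Lognormal sd of multiplicative emission noise (mean 1);
#'   0 gives noise-free fields.
#' @param mort_all,mort_alri Baseline adult all-cause and child ALRI
#'   mortality rates (deaths/person/yr), each in (0, 1).
#' @param start_year First calendar year of the observation record.
#' @param cell_area Fine-cell area in km2 (scalar or per-row vector).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             fine_grid = c(120L, 120L),
                             coarsening_factor = 10L,
                             class_fractions = c(0.35, 0.20, 0.25, 0.20),
                             transition_rates = default_transition_rates(),
                             fire_propensity = c(intact = 2e3, degraded = 4e4,
                                                 plantation = 1.2e5, nonforest = 8e4),
                             peat_multiplier = 8,
                             peat_fraction = 0.25,
                             seasonality = default_seasonality(),
                             elnino_cycle = c(1, 4, 1, 0.5, 2),
                             receptor_centers = default_receptors(fine_grid),
                             wind_bearing = 225,
                             anisotropy = 0.6,
                             plume_scale = 3,
                             sens_amplitude = 2e6,
                             sens_perturb = 0.3,
                             frp_dropout = 0.1,
                             noise_sd = 0.3,
                             mort_all = 0.007,
                             mort_alri = 0.0015,
                             start_year = 2005L,
                             cell_area = 1) {
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  check_nesting(fine_grid[1], fine_grid[2], coarsening_factor)
  if (any(fire_propensity < 0) || peat_multiplier < 0)
    stop("fire propensities and multipliers must be nonnegative")
  if (any(seasonality < 0) || any(elnino_cycle < 0))
    stop("seasonality and El Nino multipliers must be nonnegative")
  if (length(seasonality) != 12L) stop("seasonality must have 12 entries")
  tr <- as.matrix(transition_rates)
  if (!identical(dim(tr), c(4L, 4L)) || any(tr < 0))
    stop("transition_rates must be a nonnegative 4x4 matrix")
  diag(tr) <- 0
  if (any(rowSums(tr) > 1)) stop("off-diagonal transition rates exceed 1 for some class")
  if (mort_all <= 0 || mort_all >= 1 || mort_alri <= 0 || mort_alri >= 1)
    stop("baseline mortality rates must lie in (0, 1)")
  structure(list(
    seed = as.integer(seed), fine_grid = as.integer(fine_grid),
    coarsening_factor = as.integer(coarsening_factor),
    class_fractions = class_fractions, transition_rates = tr,
    fire_propensity = fire_propensity, peat_multiplier = peat_multiplier,
    peat_fraction = peat_fraction, seasonality = seasonality,
    elnino_cycle = elnino_cycle, receptor_centers = receptor_centers,
    wind_bearing = wind_bearing, anisotropy = anisotropy,
    plume_scale = plume_scale, sens_amplitude = sens_amplitude,
    sens_perturb = sens_perturb,
    frp_dropout = frp_dropout, noise_sd = noise_sd,
    mort_all = mort_all, mort_alri = mort_alri,
    start_year = as.integer(start_year), cell_area = cell_area),
    class = "synthetic_config")
}

#' Default per-5-year cover transition probabilities
#'
#' Forest degradation and clearing dominate: intact degrades or is cleared,
#' degraded converts to plantations or nonforest, some nonforest regrows into
#' the plantation/secondary class.
#' @return 4x4 matrix, rows = source class.
#' @export
default_transition_rates <- function() {
  tr <- matrix(0, 4, 4, dimnames = list(names(LULC_CLASSES), names(LULC_CLASSES)))
  tr["intact", "degraded"] <- 0.08
  tr["intact", "nonforest"] <- 0.02
  tr["degraded", "plantation"] <- 0.07
  tr["degraded", "nonforest"] <- 0.06
  tr["plantation", "nonforest"] <- 0.02
  tr["nonforest", "plantation"] <- 0.04
  tr
}

#' Default monthly burning-season weights (Jul-Oct peak)
#' @return Numeric 12-vector summing to 1.
#' @export
default_seasonality <- function() {
  w <- c(0.01, 0.01, 0.02, 0.02, 0.03, 0.05, 0.15, 0.20, 0.25, 0.20, 0.04, 0.02)
  w / sum(w)
}

#' Default receptor population centers for a toy domain
#'
#' One large in-domain receptor and two smaller downwind receptors near the
#' domain edge, echoing the Indonesia / Malaysia / Singapore geometry.
#' @param fine_grid Fine grid dimensions.
#' @return Data frame with `name`, `row`, `col`, `mass`.
#' @export
default_receptors <- function(fine_grid = c(120L, 120L)) {
  nr <- fine_grid[1]; nc <- fine_grid[2]
  data.frame(
    name = c("Indonesia", "Malaysia", "Singapore"),
    row = as.integer(round(c(0.65, 0.20, 0.35) * nr)),
    col = as.integer(round(c(0.40, 0.55, 0.70) * nc)),
    mass = c(1.8e8, 2.2e7, 4e6),
    stringsAsFactors = FALSE)
}

# Peat mask as a union of seeded discs covering roughly the target fraction.
.gen_peat_mask <- function(nr, nc, target_frac) {
  mask <- matrix(FALSE, nr, nc)
  r_mean <- sqrt(target_frac * nr * nc / (6 * pi))
  for (k in 1:6) {
    cr <- runif(1, 1, nr); cc <- runif(1, 1, nc)
    rad <- r_mean * runif(1, 0.7, 1.3)
    d2 <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+")
    mask <- mask | (d2 <= rad^2)
  }
  mask
}

#' Generate a seeded land-cover time series
#'
#' Draws an initial map from the configured class fractions and a disc-union
#' peat mask, then realizes the configured per-5-year transition
#' probabilities by independent per-cell sampling at each step. The peat flag
#' never changes.
#'
#' @param cfg A [synthetic_config].
#' @param n_periods Number of maps (>= 2), 5 years apart.
#' @return List of [lulc_map], periods `0 .. n_periods-1`.
#' @export
gen_lulc_series <- function(cfg, n_periods) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (n_periods < 2) stop("n_periods must be >= 2")
  nr <- cfg$fine_grid[1]; nc <- cfg$fine_grid[2]
  set.seed(cfg$seed + .stream[["lulc"]])
  peat <- .gen_peat_mask(nr, nc, cfg$peat_fraction)
  classes <- matrix(sample.int(4L, nr * nc, replace = TRUE,
                               prob = cfg$class_fractions), nr, nc)
  maps <- vector("list", n_periods)
  maps[[1]] <- lulc_map(classes, peat, cfg$cell_area, period = 0L)
  tr <- cfg$transition_rates
  for (p in seq_len(n_periods - 1L)) {
    cur <- maps[[p]]$classes
    nxt <- cur
    for (i in 1:4) {
      idx <- which(cur == i)
      if (!length(idx)) next
      probs <- tr[i, ]
      stay <- 1 - sum(probs)
      u <- runif(length(idx))
      cum <- cumsum(c(stay, probs))
      dest <- c(i, 1:4)[findInterval(u, cum, rightmost.closed = TRUE) + 1L]
      nxt[idx] <- dest
    }
    maps[[p + 1L]] <- lulc_map(nxt, peat, cfg$cell_area, period = p)
  }
  maps
}

#' Generate fine-grid fire emissions truth and FRP
#'
#' Monthly dry-matter emissions per fine cell:
#' `propensity(class) x peat multiplier x seasonality(month) x El Nino(year)
#' x cell area x lognormal noise`. FRP is proportional to emissions except
#' for seeded dropout cell-months (fires without a detection), which exercise
#' the area-ratio downscaling fallback.
#'
#' @param cfg A [synthetic_config].
#' @param lulc Nonempty list of [lulc_map]; map `p` covers years
#'   `start_year + 5p .. start_year + 5p + 4`.
#' @param years Calendar years to generate (default: the 5 years of the first
#'   map).
#' @return List with `emissions` (fine DM [emissions_field], kg/cell/month)
#'   and `frp` (an [frp_field]).
#' @export
gen_fire_truth <- function(cfg, lulc, years = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!length(lulc)) stop("`lulc` must be nonempty")
  if (is.null(years)) years <- cfg$start_year + 0:4
  nr <- cfg$fine_grid[1]; nc <- cfg$fine_grid[2]
  set.seed(cfg$seed + .stream[["fire"]])
  n_m <- 12L * length(years)
  time <- data.frame(year = rep(years, each = 12L), month = rep(1:12, length(years)))
  em <- array(0, c(nr, nc, n_m))
  frp <- array(0, c(nr, nc, n_m))
  t <- 0L
  for (y in years) {
    p <- min((y - cfg$start_year) %/% 5L + 1L, length(lulc))
    if (p < 1L) stop("year precedes the land-cover record")
    map <- lulc[[p]]
    area <- cell_area_matrix(map)
    base <- cfg$fire_propensity[map$classes] *
      ifelse(map$peat, cfg$peat_multiplier, 1) * area
    dim(base) <- c(nr, nc)
    eln <- cfg$elnino_cycle[(y - cfg$start_year) %% length(cfg$elnino_cycle) + 1L]
    for (m in 1:12) {
      t <- t + 1L
      noise <- if (cfg$noise_sd > 0)
        matrix(stats::rlnorm(nr * nc, -cfg$noise_sd^2 / 2, cfg$noise_sd), nr, nc)
      else 1
      e <- base * cfg$seasonality[m] * eln * noise
      em[, , t] <- e
      keep <- if (cfg$frp_dropout > 0)
        matrix(stats::runif(nr * nc) >= cfg$frp_dropout, nr, nc)
      else TRUE
      frp[, , t] <- e * keep
    }
  }
  list(emissions = emissions_field(em, time, species = "DM", units = "kg"),
       frp = frp_field(frp, time))
}

#' Generate plume-shaped adjoint sensitivity fields
#'
#' For each receptor, a nonnegative coarse-grid kernel peaking at the
#' receptor cell and decaying exponentially with an anisotropic effective
#' distance: the e-folding length is stretched upwind (along the configured
#' bearing) and shortened downwind/crosswind, so sources upwind of a
#' population center matter most. Amplitude scales with receptor population
#' mass; months are modulated by a smooth seasonal transport factor; met
#' years differ by a seeded lognormal perturbation.
#'
#' @param cfg A [synthetic_config].
#' @param met_years Nonempty integer vector of meteorological-year labels.
#' @return A [sensitivity_field].
#' @export
gen_sensitivities <- function(cfg, met_years) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!length(met_years)) stop("`met_years` must be nonempty")
  f <- cfg$coarsening_factor
  Nr <- cfg$fine_grid[1] %/% f; Nc <- cfg$fine_grid[2] %/% f
  set.seed(cfg$seed + .stream[["sens"]])
  th <- cfg$wind_bearing * pi / 180
  ux <- cos(th); uy <- sin(th)
  a <- cfg$anisotropy
  L_up <- cfg$plume_scale * (1 + 3 * a)
  L_dn <- cfg$plume_scale / (1 + a)
  L_cx <- cfg$plume_scale / (1 + a)
  fields <- list()
  for (k in seq_len(nrow(cfg$receptor_centers))) {
    rc <- cfg$receptor_centers[k, ]
    r0 <- (rc$row - 0.5) / f; c0 <- (rc$col - 0.5) / f
    di <- matrix(seq_len(Nr) - 0.5 - r0, Nr, Nc)
    dj <- matrix(rep(seq_len(Nc) - 0.5 - c0, each = Nr), Nr, Nc)
    along <- di * ux + dj * uy
    cross <- -di * uy + dj * ux
    L_al <- ifelse(along >= 0, L_up, L_dn)
    d_eff <- sqrt((along / L_al)^2 + (cross / L_cx)^2)
    # population weighting in the adjoint cost function is a weighted mean,
    # so the kernel amplitude does not scale with total receptor population
    kern <- cfg$sens_amplitude * exp(-d_eff)
    arr <- array(0, c(Nr, Nc, 12L, length(met_years)))
    phase <- stats::runif(1, 0, 2 * pi)
    mon <- 1 + 0.3 * sin(2 * pi * (1:12 - 1) / 12 + phase)
    for (yi in seq_along(met_years)) {
      pert <- if (cfg$sens_perturb > 0)
        stats::rlnorm(1, -cfg$sens_perturb^2 / 2, cfg$sens_perturb)
      else 1
      for (m in 1:12) arr[, , m, yi] <- kern * mon[m] * pert
    }
    fields[[rc$name]] <- arr
  }
  sensitivity_field(fields, met_years)
}

#' Generate population grids and receptor-level health inputs
#'
#' Adult (25+) and child (<5) counts as Gaussian blobs around the receptor
#' centers; per-receptor totals equal fixed fractions (0.55 adult, 0.10
#' child) of the configured masses exactly, by normalizing the blob weights.
#' Baseline mortality rates come from the configuration and must lie in
#' (0, 1).
#'
#' @param cfg A [synthetic_config].
#' @return List with matrices `adult` and `child` (fine grid) and a
#'   `receptors` data frame (`name`, `adult_pop`, `child_pop`, `mort_all`,
#'   `mort_alri`).
#' @export
gen_population <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nr <- cfg$fine_grid[1]; nc <- cfg$fine_grid[2]
  set.seed(cfg$seed + .stream[["pop"]])
  adult <- matrix(0, nr, nc); child <- matrix(0, nr, nc)
  sig <- 0.06 * max(nr, nc)
  recs <- cfg$receptor_centers
  for (k in seq_len(nrow(recs))) {
    w <- exp(-outer((seq_len(nr) - recs$row[k])^2,
                    (seq_len(nc) - recs$col[k])^2, "+") / (2 * sig^2))
    w <- w / sum(w)
    adult <- adult + 0.55 * recs$mass[k] * w
    child <- child + 0.10 * recs$mass[k] * w
  }
  receptors <- data.frame(
    name = recs$name,
    adult_pop = 0.55 * recs$mass,
    child_pop = 0.10 * recs$mass,
    mort_all = cfg$mort_all,
    mort_alri = cfg$mort_alri,
    stringsAsFactors = FALSE)
  list(adult = adult, child = child, receptors = receptors)
}
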