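# Downscaling, scaling-factor estimation, projection and speciation.

test_that("uniform FRP shares coarse mass equally among nested cells", {
  time <- data.frame(year = 2005, month = 1)
  coarse <- emissions_field(array(8, c(1, 1, 1)), time, "DM", "kg", "coarse")
  frp <- frp_field(array(3, c(2, 2, 1)), time)
  fine <- downscale(coarse, frp, factor = 2)
  expect_equal(as.vector(fine$data), rep(2, 4))
})

test_that("zero-FRP fallback distributes by stratum area ratio", {
  time <- data.frame(year = 2005, month = 1)
  coarse <- emissions_field(array(4, c(1, 1, 1)), time, "DM", "kg", "coarse")
  frp <- frp_field(array(0, c(2, 2, 1)), time)
  # 3 cells of one class, 1 of another, equal areas: split 3:1 across classes
  classes <- matrix(c(4L, 4L, 4L, 3L), 2, 2)
  lulc <- lulc_map(classes, matrix(FALSE, 2, 2))
  fine <- downscale(coarse, frp, lulc = lulc, factor = 2)
  expect_equal(sum(fine$data[classes == 4L]), 3)
  expect_equal(sum(fine$data[classes == 3L]), 1)
  # with no strata: uniform by area
  fine_u <- downscale(coarse, frp, factor = 2)
  expect_equal(as.vector(fine_u$data), rep(1, 4))
})

test_that("downscaling conserves per-coarse-cell monthly totals exactly", {
  set.seed(21)
  time <- data.frame(year = rep(2005, 3), month = 1:3)
  coarse <- emissions_field(array(rexp(4 * 4 * 3), c(4, 4, 3)), time,
                            "DM", "kg", "coarse")
  frp_d <- array(rexp(12 * 12 * 3), c(12, 12, 3))
  frp_d[sample(length(frp_d), 100)] <- 0
  frp_d[1:3, 1:3, 1] <- 0                         # force the fallback block
  fine <- downscale(coarse, frp_field(frp_d, time), factor = 3)
  for (t in 1:3)
    expect_equal(block_sum(fine$data[, , t], 3), coarse$data[, , t],
                 tolerance = 1e-13)
  expect_error(downscale(coarse, frp_field(array(0, c(10, 10, 3)), time),
                         factor = 3), "divisible|nest")
})

test_that("round trip: aggregating generated fine emissions and downscaling recovers them", {
  cfg <- tiny_cfg(frp_dropout = 0)
  maps <- gen_lulc_series(cfg, 2)
  ft <- gen_fire_truth(cfg, maps, years = 2005)
  coarse <- aggregate_emissions(ft$emissions, cfg$coarsening_factor)
  fine2 <- downscale(coarse, ft$frp, lulc = maps[[1]],
                     factor = cfg$coarsening_factor)
  expect_equal(fine2$data, ft$emissions$data, tolerance = 1e-12)
})

test_that("scaling factors recover known synthetic rates and invert projection", {
  cfg <- tiny_cfg(noise_sd = 0, frp_dropout = 0, elnino_cycle = rep(1, 5))
  maps <- gen_lulc_series(cfg, 2)
  ft <- gen_fire_truth(cfg, maps, years = 2005)
  labels <- transition_labels(maps[[1]])
  rates <- estimate_scaling_factors(ft$emissions, maps[[1]],
                                    factor = cfg$coarsening_factor)
  # oracle: rate must equal propensity x peat multiplier x seasonality
  base <- cfg$fire_propensity[maps[[1]]$classes] *
    ifelse(maps[[1]]$peat, cfg$peat_multiplier, 1)
  for (i in sample(nrow(rates$table), 50)) {
    row <- rates$table[i, ]
    cells <- which(coarse_index(24, 24, 4) == row$coarse &
                   labels == row$label)
    expected <- mean(base[cells]) * cfg$seasonality[row$month]
    expect_equal(row$rate, expected, tolerance = 1e-10)
  }
  # reprojection reproduces the aggregated input emissions
  proj <- project_emissions(rates, list(labels), years = 2005,
                            period_starts = 2005, cell_area = 1)
  agg <- aggregate_emissions(ft$emissions, cfg$coarsening_factor)
  expect_equal(proj$data, agg$data, tolerance = 1e-12)
})

test_that("a zero-emission year scales mean rates by (n-1)/n", {
  time1 <- data.frame(year = rep(2005, 12), month = 1:12)
  time2 <- data.frame(year = rep(2005:2006, each = 12), month = rep(1:12, 2))
  d1 <- array(rexp(6 * 6 * 12), c(6, 6, 12))
  d2 <- array(0, c(6, 6, 24)); d2[, , 1:12] <- d1
  m <- lulc_map(matrix(4L, 6, 6), matrix(FALSE, 6, 6))
  r1 <- estimate_scaling_factors(emissions_field(d1, time1, "DM", "kg"), m, factor = 3)
  r2 <- estimate_scaling_factors(emissions_field(d2, time2, "DM", "kg"), m, factor = 3)
  expect_equal(r2$table$rate, r1$table$rate / 2, tolerance = 1e-12)
})

test_that("strata absent from a coarse cell get no entry", {
  classes <- matrix(4L, 4, 4); classes[1:2, 1:2] <- 3L
  m <- lulc_map(classes, matrix(FALSE, 4, 4))
  E <- emissions_field(array(1, c(4, 4, 1)),
                       data.frame(year = 2005, month = 1), "DM", "kg")
  r <- estimate_scaling_factors(E, m, factor = 2)
  tab <- r$table
  expect_false(any(tab$coarse == 1 & tab$label == "nonforest.nonpeat"))
  expect_false(any(tab$coarse == 4 & tab$label == "plantation.nonpeat"))
})

test_that("projection is a fixed point on calibration areas and linear in area", {
  cfg <- tiny_cfg(noise_sd = 0, elnino_cycle = rep(1, 5))
  maps <- gen_lulc_series(cfg, 2)
  ft <- gen_fire_truth(cfg, maps, years = 2005:2006)
  labels <- transition_labels(maps[[1]])
  rates <- estimate_scaling_factors(ft$emissions, maps[[1]],
                                    factor = cfg$coarsening_factor)
  proj <- project_emissions(rates, list(labels), years = 2020,
                            period_starts = 2020)
  # monthly climatology equals the observed multi-year mean climatology
  agg <- aggregate_emissions(ft$emissions, cfg$coarsening_factor)
  clim <- (agg$data[, , 1:12] + agg$data[, , 13:24]) / 2
  expect_equal(proj$data[, , 1:12], clim, tolerance = 1e-12)
  # doubling every area doubles emissions
  proj2 <- project_emissions(rates, list(labels), years = 2020,
                             period_starts = 2020, cell_area = 2)
  expect_equal(proj2$data, 2 * proj$data, tolerance = 1e-13)
})

test_that("hand-computed one-coarse-cell projection matches", {
  # 2x2 fine grid in one coarse cell: 3 cells of stratum A (area 1 each),
  # 1 of stratum B; rates: A = 2 kg/km2 in month 1, B = 5
  labels <- matrix(c("A", "A", "A", "B"), 2, 2)
  tab <- data.frame(coarse = 1L, label = rep(c("A", "B"), each = 12),
                    month = rep(1:12, 2), rate = rep(c(2, 5), each = 12),
                    area = rep(c(3, 1), each = 12))
  rates <- structure(list(table = tab, factor = 2L, coarse_dim = c(1L, 1L),
                          units = "kg", n_years = 1L), class = "fire_rates")
  proj <- project_emissions(rates, list(labels), years = 2020,
                            period_starts = 2020)
  expect_equal(proj$data[1, 1, 1], 3 * 2 + 1 * 5)   # spreadsheet arithmetic
  # a stratum with no learned rate contributes zero, with a warning
  labels2 <- matrix(c("A", "A", "C", "B"), 2, 2)
  expect_warning(p2 <- project_emissions(rates, list(labels2), years = 2020,
                                         period_starts = 2020), "no learned rate")
  expect_equal(p2$data[1, 1, 1], 2 * 2 + 1 * 5)
})

test_that("speciation applies emission factors with explicit unit bookkeeping", {
  time <- data.frame(year = 2005, month = 1)
  dm <- emissions_field(array(1, c(2, 2, 1)), time, "DM", "kg")
  types <- matrix(c("peat", "peat", "agricultural", "agricultural"), 2, 2)
  ef <- data.frame(fire_type = c("peat", "agricultural"),
                   ef_oc = c(10, 0), ef_bc = c(1, 2))
  sp <- speciate(dm, ef, types)
  expect_equal(sp$OC$data[1, 1, 1], 0.01)            # 1 kg DM x 10 g/kg
  expect_equal(sp$OC$data[1, 2, 1], 0)               # EF 0 -> identically 0
  expect_equal(sp$BC$data[1, 1, 1] / sp$BC$data[1, 2, 1], 1 / 2)  # EF ratio
  expect_error(speciate(dm, ef, matrix("unknown", 2, 2)), "without emission factors")
  # label -> fire type mapping is total
  labs <- matrix(c("intact>nonforest.nonpeat", "plantation.peat",
                   "nonforest.nonpeat", "degraded>plantation.nonpeat"), 2, 2)
  ft <- fire_type_from_labels(labs)
  expect_equal(as.vector(ft),
               c("deforestation", "peat", "agricultural", "deforestation"))
})
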