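# Fire-blocking masks, scenario comparison arithmetic, site ranking and
# burden shares.

mk_field <- function(d, nr = 6, nc = 6, months = 12) {
  time <- data.frame(year = 2020, month = seq_len(months))
  emissions_field(array(d, c(nr, nc, months)), time, "OC", "kg", "coarse")
}

test_that("mask application zeroes exactly the masked cells", {
  set.seed(41)
  E <- mk_field(rexp(6 * 6 * 12))
  empty <- scenario_mask(matrix(FALSE, 6, 6), "none")
  full <- scenario_mask(matrix(TRUE, 6, 6), "all")
  expect_equal(apply_mask(E, empty)$data, E$data)
  expect_true(all(apply_mask(E, full)$data == 0))
  m1 <- matrix(FALSE, 6, 6); m1[1:3, ] <- TRUE
  m2 <- matrix(FALSE, 6, 6); m2[, 1:2] <- TRUE
  seq2 <- apply_mask(apply_mask(E, scenario_mask(m1)), scenario_mask(m2))
  joint <- apply_mask(E, scenario_mask(m1 | m2))
  expect_equal(seq2$data, joint$data)
  expect_error(apply_mask(E, scenario_mask(matrix(TRUE, 3, 3))), "match")
})

test_that("percent reductions and burden shares reproduce the published table arithmetic", {
  expect_equal(percent_reduction(12.7, 4.4), 65)
  expect_equal(percent_reduction(6.6, 5.5), 17)
  expect_equal(percent_reduction(3, 3), 0)
  expect_true(is.na(percent_reduction(0, 0)))
  shares <- share_of_burden(c(Indonesia = 33000, Malaysia = 2400, Singapore = 360))
  expect_equal(unname(shares), c(92, 7, 1))
  expect_equal(unname(share_of_burden(c(a = 5))), 100)
  expect_equal(unname(share_of_burden(c(a = 1, b = 1, c = 1, d = 1))),
               rep(25, 4))
  expect_error(share_of_burden(numeric(0)), "at least one")
  expect_error(share_of_burden(c(a = 0, b = 0)), "zero total")
})

test_that("scenario metrics never exceed baseline and identical runs give 0%", {
  fx <- study_fixture()
  smoke <- study_smoke(fx)
  sched <- build_schedule(2005, 2009, 2005:2009)
  base <- smoke_run(smoke, fx$S, sched, fx$pop$receptors, factor = 10)
  cmp0 <- compare_runs(base, base)
  expect_equal(cmp0$emissions_reduction_pct, 0)
  expect_true(all(cmp0$receptors$exposure_reduction_pct == 0))
  peat <- scenario_mask(fx$maps[[1]]$peat, "peatlands", "peatlands")
  runp <- smoke_run(smoke, fx$S, sched, fx$pop$receptors, factor = 10,
                    mask = peat)
  cmp <- compare_runs(base, runp)
  expect_lte(cmp$emissions_scen, cmp$emissions_base)
  with(cmp$receptors, {
    expect_true(all(exposure_scen <= exposure_base + 1e-12))
    expect_true(all(deaths_scen <= deaths_base + 1e-9))
    expect_true(all(deaths_averted_low <= deaths_averted + 1e-9))
    expect_true(all(deaths_averted <= deaths_averted_high + 1e-9))
    expect_true(all(exposure_reduction_pct >= 0 & exposure_reduction_pct <= 100))
  })
})

test_that("nested masks give nested benefits", {
  fx <- study_fixture()
  smoke <- study_smoke(fx)
  sched <- build_schedule(2005, 2009, 2005:2009)
  base <- smoke_run(smoke, fx$S, sched, fx$pop$receptors, factor = 10)
  small <- fx$maps[[1]]$peat & (row(fx$maps[[1]]$peat) <= 60)
  runA <- smoke_run(smoke, fx$S, sched, fx$pop$receptors, factor = 10,
                    mask = scenario_mask(small, "A"))
  runB <- smoke_run(smoke, fx$S, sched, fx$pop$receptors, factor = 10,
                    mask = scenario_mask(fx$maps[[1]]$peat, "B"))
  cA <- compare_runs(base, runA)$receptors
  cB <- compare_runs(base, runB)$receptors
  expect_true(all(cA$deaths_averted <= cB$deaths_averted + 1e-9))
})

test_that("site ranking equals exhaustive single-site enumeration and benefits add", {
  fx <- study_fixture()
  smoke <- study_smoke(fx)
  sched <- build_schedule(2005, 2009, 2005:2009)
  # 10 nonoverlapping candidate blocks on the fine grid
  sites <- list()
  for (k in 1:10) {
    m <- matrix(FALSE, 120, 120)
    rows <- ((k - 1) %% 5) * 24 + 1:20
    cols <- ((k - 1) %/% 5) * 55 + 1:20
    m[rows, cols] <- TRUE
    sites[[sprintf("site%02d", k)]] <- scenario_mask(m, sprintf("site%02d", k),
                                                     "restoration_sites")
  }
  rk <- rank_sites(smoke, fx$S, sched, fx$pop$receptors, factor = 10,
                   sites = sites, receptor = "Indonesia", metric = "deaths")
  base <- smoke_run(smoke, fx$S, sched, fx$pop$receptors, factor = 10)
  # exhaustive oracle: recompute every site's benefit independently
  oracle <- sapply(names(sites), function(nm) {
    run <- smoke_run(smoke, fx$S, sched, fx$pop$receptors, factor = 10,
                     mask = sites[[nm]])
    cmp <- compare_runs(base, run)$receptors
    cmp$deaths_averted[cmp$receptor == "Indonesia"]
  })
  oracle_order <- names(sort(-oracle))
  expect_equal(rk$ranking$site, oracle_order)
  expect_equal(rk$ranking$deaths_averted, unname(oracle[rk$ranking$site]),
               tolerance = 1e-12)
  # additivity: summed nonoverlapping single-site exposure benefits equal the
  # joint-blocking benefit (linear operator)
  joint_mask <- Reduce(`|`, lapply(sites, function(s) s$mask))
  run_joint <- smoke_run(smoke, fx$S, sched, fx$pop$receptors, factor = 10,
                         mask = scenario_mask(joint_mask, "joint"))
  cmpj <- compare_runs(base, run_joint)$receptors
  joint_ben <- cmpj$exposure_base[cmpj$receptor == "Indonesia"] -
    cmpj$exposure_scen[cmpj$receptor == "Indonesia"]
  expect_equal(sum(rk$ranking$exposure_benefit), joint_ben,
               tolerance = 1e-9)
  # single candidate: benefit equals compare() against baseline
  rk1 <- rank_sites(smoke, fx$S, sched, fx$pop$receptors, factor = 10,
                    sites = sites[1], receptor = "Indonesia")
  expect_equal(rk1$ranking$deaths_averted, unname(oracle[1]), tolerance = 1e-12)
  expect_error(rank_sites(smoke, fx$S, sched, fx$pop$receptors, factor = 10,
                          sites = list()), "empty")
  # overlapping candidates warn
  expect_warning(rank_sites(smoke, fx$S, sched, fx$pop$receptors, factor = 10,
                            sites = list(a = sites[[1]], b = sites[[1]])),
                 "overlap")
})
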