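# Land-cover merging, VIF screening, weights-of-evidence calibration and
# ranked-allocation projection.

test_that("layer merge splits nonforest by tree cover and attaches peat", {
  forest <- matrix(c(3L, 1L, 3L, 2L), 2, 2)
  tree <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  peat <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  m <- merge_layers(forest, tree, peat)
  expect_equal(m$classes[1, 1], LULC_CLASSES[["plantation"]])  # nonforest + tree cover
  expect_equal(m$classes[1, 2], LULC_CLASSES[["nonforest"]])   # nonforest, no cover
  expect_equal(m$classes[2, 1], LULC_CLASSES[["intact"]])      # forest map wins
  expect_equal(m$classes[2, 2], LULC_CLASSES[["degraded"]])
  expect_identical(m$peat, peat > 0)
  expect_error(merge_layers(forest, tree[1, , drop = FALSE], peat), "share")
  expect_error(merge_layers(matrix(5L, 2, 2), tree, peat), "unknown class")
  # all-nonforest, no tree cover: single-class output
  m2 <- merge_layers(matrix(3L, 3, 3), matrix(0L, 3, 3), matrix(0L, 3, 3))
  expect_true(all(m2$classes == LULC_CLASSES[["nonforest"]]))
})

test_that("VIF matches direct regression and flags collinearity", {
  set.seed(11)
  a <- matrix(rnorm(400), 20)
  b <- matrix(rnorm(400), 20)
  v <- check_vif(list(a = a, b = b))
  expect_true(all(abs(v$vif - 1) < 0.1))
  expect_true(all(v$pass))

  vd <- check_vif(list(a = a, b = b, a2 = a))  # duplicated layer
  expect_false(vd$pass[vd$layer == "a"])
  expect_gt(max(vd$vif), 1e6)

  # three layers, two correlated ~0.6: oracle = 1/(1-R^2) from lm()
  x1 <- rnorm(2000); x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(2000)
  x3 <- rnorm(2000)
  v3 <- check_vif(list(l1 = matrix(x1, 40), l2 = matrix(x2, 40),
                       l3 = matrix(x3, 40)))
  for (i in 1:3) {
    r2 <- summary(lm(cbind(x1, x2, x3)[, i] ~ cbind(x1, x2, x3)[, -i]))$r.squared
    expect_equal(v3$vif[i], 1 / (1 - r2), tolerance = 1e-10)
  }
  expect_error(check_vif(list(a = a, c = matrix(1, 20, 20))), "constant")
  expect_error(check_vif(list(a = a)), "at least 2")
})

test_that("weights are near zero when evidence is independent of transitions", {
  set.seed(5)
  n <- 80
  c0 <- matrix(1L, n, n)
  c1 <- c0; c1[sample(n * n, 800)] <- 4L          # random transitions
  ev <- matrix(rnorm(n * n), n)                   # independent evidence
  m0 <- lulc_map(c0, matrix(FALSE, n, n)); m1 <- lulc_map(c1, matrix(FALSE, n, n))
  fit <- calibrate_woe(m0, m1, list(ev = ev), bins = 5)
  expect_true(all(abs(fit$weights$weight) < 0.35))
  expect_equal(fit$priors$prior, 800 / (n * n))   # prior = transitioned fraction
})

test_that("toy 8-cell weights match the hand-computed smoothed log-ratios", {
  # 8 eligible cells; evidence bin high for 4 of them; transitions in 3 of
  # the high cells and none of the low cells
  c0 <- matrix(1L, 2, 4)
  c1 <- c0; c1[1, 1:3] <- 4L
  ev <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0), 2, 4)   # row 1 = high bin
  fit <- calibrate_woe(lulc_map(c0, matrix(FALSE, 2, 4)),
                       lulc_map(c1, matrix(FALSE, 2, 4)),
                       list(ev = ev), bins = 2)
  w <- fit$weights
  # hand count: events n1 = (low 0, high 3), non-events n0 = (low 4, high 1)
  # smoothed: P(high|T) = 3.5/4, P(high|!T) = 1.5/6 -> W+ = ln(3.5)
  #           P(low |T) = 0.5/4, P(low |!T) = 4.5/6 -> W+ = ln(1/6)
  expect_equal(w$weight[w$bin == 2], log(3.5), tolerance = 1e-12)
  expect_equal(w$weight[w$bin == 1], log(1 / 6), tolerance = 1e-12)
  expect_gt(w$weight[w$bin == 2], 0)
  expect_lt(w$weight[w$bin == 1], 0)
  expect_equal(fit$priors$prior, 3 / 8)
})

test_that("projection respects demand and matches exhaustive top-k ranking", {
  set.seed(9)
  n <- 10
  c0 <- matrix(1L, n, n)
  ev <- matrix(runif(n * n), n)
  c1 <- c0
  c1[ev > quantile(ev, 0.8)] <- 4L               # transitions in high-evidence cells
  m0 <- lulc_map(c0, matrix(FALSE, n, n)); m1 <- lulc_map(c1, matrix(FALSE, n, n))
  fit <- calibrate_woe(m0, m1, list(ev = ev), bins = 5)

  # demand 0: identity
  out0 <- project_lulc(m0, fit, demand = c("intact>nonforest" = 0), n_steps = 2,
                       seed = 1, evidence_layers = list(ev = ev))
  expect_identical(out0[[3]]$classes, m0$classes)

  # exhaustive oracle: every selected cell's probability >= every unselected
  # eligible cell's probability
  k <- 15L
  out <- project_lulc(m0, fit, demand = c("intact>nonforest" = k), n_steps = 1,
                      seed = 1, evidence_layers = list(ev = ev))
  sel <- which(out[[2]]$classes == 4L)
  expect_length(sel, k)
  p <- predict(fit, m0, list(ev = ev))[["intact>nonforest"]]
  expect_gte(min(p[sel]), max(p[-sel]) - 1e-15)

  # demand equal to the full source class exhausts it
  outf <- project_lulc(m0, fit, demand = c("intact>nonforest" = n * n),
                       n_steps = 1, seed = 1, evidence_layers = list(ev = ev))
  expect_true(all(outf[[2]]$classes == 4L))
  expect_error(project_lulc(m0, fit, demand = c("intact>nonforest" = n * n + 1),
                            n_steps = 1, seed = 1,
                            evidence_layers = list(ev = ev)),
               "infeasible")
})

test_that("projection conserves cells and peat, and selections nest with demand", {
  cfg <- tiny_cfg()
  maps <- gen_lulc_series(cfg, 2)
  ev <- list(d_nonforest = function(m) distance_to_class(m, 4L),
             noise = matrix(runif(24 * 24), 24))
  fit <- calibrate_woe(maps[[1]], maps[[2]], ev, bins = 4)
  out <- project_lulc(maps[[1]], fit, n_steps = 3, seed = 2,
                      evidence_layers = ev)
  for (s in 2:4) {
    expect_identical(dim(out[[s]]$classes), dim(maps[[1]]$classes))
    expect_identical(out[[s]]$peat, maps[[1]]$peat)
    expect_equal(length(out[[s]]$classes), 24 * 24)
  }
  # nested selections: larger demand for the first transition keeps all
  # previously converted cells (fixed seed)
  tn <- fit$priors$transition[1]
  to <- fit$priors$to[1]; from <- fit$priors$from[1]
  sel_k <- function(k) {
    o <- project_lulc(maps[[1]], fit, demand = stats::setNames(k, tn),
                      n_steps = 1, seed = 3, evidence_layers = ev)
    which(o[[2]]$classes == to & maps[[1]]$classes == from)
  }
  s5 <- sel_k(5); s12 <- sel_k(12)
  expect_true(all(s5 %in% s12))
})
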