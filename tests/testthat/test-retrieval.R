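optics <- optical_constants(aw665 = 0.40, aw709 = 0.70, bb = 1.5, gamma = 0.68)

stack_from_ratio <- function(ratio, b665 = 0.05) {
  dates <- biweekly_dates(1)
  b <- array(b665, c(1, 1, 1))
  reflectance_stack(b, b * ratio, dates)
}

test_that("band-ratio retrieval matches hand-evaluated algebra", {
  # ratio 1.2: (1.2 * 2.2 - 1.5 - 0.40) / 0.68
  g <- chl_from_bands(stack_from_ratio(1.2), optics)
  expect_equal(g$values[1, 1, 1], 0.74 / 0.68, tolerance = 1e-12)
  # ratio 1: chl = (aw709 - aw665) / gamma
  g1 <- chl_from_bands(stack_from_ratio(1), optics)
  expect_equal(g1$values[1, 1, 1], (0.70 - 0.40) / 0.68, tolerance = 1e-12)
  # ratio at the zero of the numerator
  r0 <- (optics$bb + optics$aw665) / (optics$aw709 + optics$bb)
  g0 <- chl_from_bands(stack_from_ratio(r0), optics)
  expect_equal(g0$values[1, 1, 1], 0, tolerance = 1e-12)
})

test_that("negative retrievals are floored at zero and counted", {
  r_neg <- 0.9 * (optics$bb + optics$aw665) / (optics$aw709 + optics$bb)
  g <- chl_from_bands(stack_from_ratio(r_neg), optics)
  expect_equal(g$values[1, 1, 1], 0)
  expect_equal(attr(g, "n_floored"), 1L)
})

test_that("zero 665 nm reflectance at an observed cell is a named error", {
  dates <- biweekly_dates(1)
  st <- structure(list(b665 = array(0, c(1, 1, 1)), b705 = array(0.05, c(1, 1, 1)),
                       dates = dates), class = "reflectance_stack")
  expect_error(chl_from_bands(st, optics), "t=1, y=1, x=1")
})

test_that("reflectance simulation and retrieval are mutually inverse", {
  cfg <- synthetic_config(ny = 4, nx = 5, gap_fraction = 0, seed = 3)
  truth <- gen_chl_truth(cfg)
  back <- chl_from_bands(gen_reflectance(truth, optics), optics)
  rel <- abs(back$values - truth$values) / pmax(truth$values, 1e-8)
  expect_lt(max(rel), 1e-10)
})

test_that("regrid takes block means of observed cells", {
  dates <- biweekly_dates(1)
  v <- array(NA_real_, c(1, 3, 3))
  v[1, , ] <- matrix(1:9, 3, 3)
  g <- chl_grid(v, dates, pixel_size_m = 100)
  out <- regrid(g, 300)
  expect_equal(dim(out$values), c(1L, 1L, 1L))
  expect_equal(out$values[1, 1, 1], 5)

  # uniform field is preserved under any factor
  vu <- array(2.5, c(1, 6, 6))
  gu <- chl_grid(vu, dates, pixel_size_m = 100)
  expect_true(all(abs(regrid(gu, 250)$values - 2.5) < 1e-12))

  # an all-missing block stays missing, partial blocks use what is there
  vm <- array(NA_real_, c(1, 3, 6))
  vm[1, 1, 4] <- 6
  gm <- chl_grid(vm, dates, pixel_size_m = 100)
  rm2 <- regrid(gm, 300)
  expect_true(is.na(rm2$values[1, 1, 1]))
  expect_equal(rm2$values[1, 1, 2], 6)
})

test_that("biweekly compositing averages available daily values", {
  cal <- biweekly_calendar()
  days <- seq(cal[1], cal[1] + 27, by = 1)   # two full bins
  v <- array(NA_real_, c(28, 1, 1))
  v[3, 1, 1] <- 2; v[9, 1, 1] <- 4           # bin 1: {2, 4}
  g <- chl_grid(v, days, pixel_size_m = 1000)
  out <- composite_biweekly(g, cal)
  expect_equal(out$values[1, 1, 1], 3)
  expect_true(is.na(out$values[2, 1, 1]))    # all 14 days missing
  expect_equal(out$provenance, "composited")

  # constant daily series stays constant, and compositing commutes with
  # positive scaling
  vc <- array(5, c(28, 1, 1))
  gc_ <- chl_grid(vc, days)
  oc <- composite_biweekly(gc_, cal)
  expect_true(all(oc$values[1:2, 1, 1] == 5))
  g3 <- chl_grid(vc * 3, days)
  expect_equal(composite_biweekly(g3, cal)$values[1:2, , ],
               oc$values[1:2, , ] * 3)
})

test_that("daily dates outside the calendar are dropped and counted", {
  cal <- biweekly_calendar()
  days <- c(cal[1] - 5, cal[1], cal[1] + 1)
  v <- array(c(99, 1, 3), c(3, 1, 1))
  g <- chl_grid(v, days)
  out <- composite_biweekly(g, cal)
  expect_equal(attr(out, "n_dropped_dates"), 1L)
  expect_equal(out$values[1, 1, 1], 2)
})

test_that("sparsity filter removes strictly-more-than-half-missing pixels", {
  dates <- biweekly_dates(10)
  s60 <- c(rep(NA, 6), 1, 2, 3, 4)       # 60% missing -> dropped
  s50 <- c(rep(NA, 5), 1, 2, 3, 4, 5)    # exactly 50% -> retained
  full <- 1:10
  g <- grid_from_series(list(s60, s50, full), 1, 3, dates)
  res <- drop_sparse_pixels(g)
  expect_equal(res$dropped$pixel, 1L)
  expect_true(all(is.na(res$grid$values[, 1, 1])))
  expect_equal(res$grid$values[, 1, 2], as.numeric(s50))

  # idempotent; a gap-free grid loses nothing
  res2 <- drop_sparse_pixels(res$grid)
  expect_identical(res2$grid$values, res$grid$values)
  expect_equal(nrow(res2$dropped), 0L)
  gfull <- grid_from_series(list(full, full), 1, 2, dates)
  expect_equal(nrow(drop_sparse_pixels(gfull)$dropped), 0L)
})
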