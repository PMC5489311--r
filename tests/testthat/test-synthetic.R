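test_that("biweekly calendar spans the study period on a 14-day stride", {
  cal <- biweekly_calendar()
  expect_equal(length(cal), 267L)
  expect_equal(cal[1], as.Date("2002-01-05"))
  expect_true(all(diff(as.numeric(cal)) == 14))
  expect_lte(max(cal), as.Date("2012-03-21"))
})

test_that("degenerate generator: zero amplitudes and noise give a constant field", {
  cfg <- synthetic_config(ny = 3, nx = 4, mean_chl = 7, annual_amp = 0,
                          semiannual_amp = 0, hotspots = list(),
                          noise_sd = 0, gap_fraction = 0, seed = 1)
  g <- gen_chl_truth(cfg)
  expect_true(all(g$values == 7))
  expect_false(anyNA(g$values))
})

test_that("noiseless annual cycle has sinusoid structure per pixel", {
  cfg <- synthetic_config(ny = 2, nx = 2, mean_chl = 20, annual_amp = 5,
                          semiannual_amp = 0, hotspots = list(),
                          noise_sd = 0, gap_fraction = 0, seed = 1)
  g <- gen_chl_truth(cfg)
  x <- g$values[, 1, 1]
  # derivative changes sign twice per year
  dsign <- sign(diff(x))
  changes <- sum(diff(dsign) != 0)
  n_years <- as.numeric(diff(range(g$dates))) / 365.25
  expect_equal(changes / n_years, 2, tolerance = 0.06)
  # autocorrelation at a 1-year lag (26 bins ~ 364 days) is near 1
  lag <- 26L
  expect_gt(cor(x[-(1:lag)], x[1:(length(x) - lag)]), 0.95)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(ny = 3, nx = 3, seed = 42)
  s1 <- synth_study(cfg)
  s2 <- synth_study(cfg)
  expect_identical(s1$truth$values, s2$truth$values)
  expect_identical(s1$observed$values, s2$observed$values)
  expect_identical(s1$covariates, s2$covariates)
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(ny = 0), "grid shape")
  expect_error(synthetic_config(start = "2005-01-01", end = "2004-01-01"), "time span")
  expect_error(synthetic_config(ar1 = 1), "AR\\(1\\)")
  expect_error(synthetic_config(gap_fraction = 1), "gap fraction")
  expect_error(synthetic_config(covariate_effects = list(XX = list())), "unknown covariate")
})

test_that("cloud gaps hit the target fraction and only mask observed cells", {
  for (seed in 1:10) {
    cfg <- synthetic_config(ny = 6, nx = 8, gap_fraction = 0.2, seed = seed)
    truth <- gen_chl_truth(cfg)
    gapped <- apply_cloud_gaps(truth, cfg)
    frac <- mean(is.na(gapped$values))
    expect_gt(frac, 0.15); expect_lt(frac, 0.25)
    # masking is monotone: no cell becomes observed
    expect_true(all(is.na(gapped$values[is.na(truth$values)])))
  }
  # f = 0 leaves the grid untouched
  cfg0 <- synthetic_config(ny = 6, nx = 8, gap_fraction = 0, seed = 1)
  truth <- gen_chl_truth(cfg0)
  expect_identical(apply_cloud_gaps(truth, cfg0)$values, truth$values)
})

test_that("gapping pushes some pixels over the sparsity threshold", {
  cfg <- synthetic_config(ny = 6, nx = 8, gap_fraction = 0.2,
                          n_sparse_pixels = 2, seed = 3)
  gapped <- apply_cloud_gaps(gen_chl_truth(cfg), cfg)
  expect_gte(sum(missing_fraction(gapped) > 0.5), 2)
})

test_that("covariate table has the nine variables with plausible seasonality", {
  cfg <- synthetic_config(seed = 8)
  tab <- gen_covariates(cfg)
  expect_true(all(covariate_names() %in% names(tab)))
  expect_equal(nrow(tab), 267L)
  # summer water temperature and radiation exceed winter values
  expect_gt(mean(tab$WTMP[tab$season == "summer"]),
            mean(tab$WTMP[tab$season == "winter"]))
  expect_gt(mean(tab$Rs[tab$season == "summer"]),
            mean(tab$Rs[tab$season == "winter"]))
  # discharge peaks in spring
  expect_gt(mean(tab$Q[tab$season == "spring"]), mean(tab$Q))
})

test_that("injected collinearity drives VIF above the screening threshold", {
  cfg <- synthetic_config(seed = 2, collinearity = list(
    list(target = "WTMP", source = "Rs", r2 = 0.95)))
  tab <- gen_covariates(cfg)
  v <- vif(tab[, covariate_names()])
  expect_gte(v[["WTMP"]], 10)
})

test_that("reflectance simulation propagates the Chl-a mask", {
  cfg <- synthetic_config(ny = 3, nx = 3, gap_fraction = 0.3, seed = 4)
  obs <- apply_cloud_gaps(gen_chl_truth(cfg), cfg)
  st <- gen_reflectance(obs)
  expect_identical(is.na(st$b665), is.na(obs$values))
  expect_identical(is.na(st$b705), is.na(obs$values))
})

test_that("grid CSV round-trips", {
  cfg <- synthetic_config(ny = 3, nx = 4, gap_fraction = 0.2, seed = 6)
  g <- apply_cloud_gaps(gen_chl_truth(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chl_csv(g, path)
  g2 <- read_chl_csv(path)
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_equal(g2$dates, g$dates)
})
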