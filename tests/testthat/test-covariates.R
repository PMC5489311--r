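test_that("aggregation averages hourly to daily to biweekly and across sites", {
  cal <- biweekly_calendar()
  d1 <- cal[1] + 0:13
  # three sites with constant offsets -> cross-site mean
  raw <- do.call(rbind, lapply(1:3, function(s) {
    data.frame(variable = "TP", site = paste0("s", s), time = d1, value = s)
  }))
  tab <- aggregate_biweekly(raw, cal)
  expect_equal(tab$TP[1], 2)

  # hourly constant c collapses to c
  hours <- as.POSIXct(paste(rep(d1, each = 4), c("00:00", "06:00", "12:00", "18:00")),
                      tz = "UTC")
  raw2 <- data.frame(variable = "Wind", time = hours, value = 3.5)
  tab2 <- aggregate_biweekly(raw2, cal)
  expect_equal(tab2$Wind[1], 3.5)
})

test_that("water-temperature gaps are filled from neighbour years", {
  cal <- biweekly_calendar(start = "2002-01-05", end = "2004-12-31")
  # WTMP observed in all bins except one mid-2003 bin; donors 50 and 54
  doy <- as.numeric(format(cal, "%j")); yr <- format(cal, "%Y")
  i <- 40L
  donors <- which(abs(doy - doy[i]) <= 14 & yr != yr[i])
  val <- rep(41, length(cal))
  val[donors] <- rep(c(50, 54), length.out = length(donors))
  days <- cal[-i]
  raw <- data.frame(variable = "WTMP", time = days, value = val[-i])
  tab <- aggregate_biweekly(raw, cal)
  expect_equal(tab$WTMP[i], mean(val[donors]))
})

test_that("bins with no data are reported missing", {
  cal <- biweekly_calendar()
  raw <- data.frame(variable = "Q", time = cal[1] + 0:13, value = 100)
  tab <- aggregate_biweekly(raw, cal)
  expect_true(is.na(tab$Q[2]))
  mb <- attr(tab, "missing_bins")
  expect_true(2L %in% mb$bin[mb$variable == "Q"])
})

test_that("VIF is one for orthogonal predictors", {
  set.seed(31)
  # columns exactly orthogonal to each other and to the intercept
  X <- qr.Q(qr(cbind(1, matrix(rnorm(300), 100, 3))))[, -1]
  colnames(X) <- c("a", "b", "c")
  v <- vif(X)
  expect_true(all(abs(v - 1) < 1e-8))
  expect_true(all(v >= 1 - 1e-10))
})

test_that("VIF agrees with a brute-force least-squares oracle", {
  set.seed(2)
  x1 <- rnorm(120); x2 <- rnorm(120)
  x3 <- x1 + x2 + rnorm(120, 0, 0.5)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  v <- vif(X)
  # oracle: normal equations solved explicitly on standardised data
  oracle_vif <- function(j) {
    Z <- scale(X)
    A <- cbind(1, Z[, -j]); b <- Z[, j]
    beta <- solve(t(A) %*% A, t(A) %*% b)
    r2 <- 1 - sum((b - A %*% beta)^2) / sum((b - mean(b))^2)
    1 / (1 - r2)
  }
  for (j in 1:3) expect_equal(v[[j]], oracle_vif(j), tolerance = 1e-8)
  expect_true(all(v >= 1))
})

test_that("perfect collinearity reports infinite VIF", {
  x1 <- rnorm(50); X <- cbind(a = x1, b = 2 * x1 + 1, c = rnorm(50))
  v <- vif(X)
  expect_true(is.infinite(v[["a"]]) && is.infinite(v[["b"]]))
})

test_that("VIF screening removes exactly one of an injected collinear pair", {
  cfg <- synthetic_config(seed = 2, collinearity = list(
    list(target = "WTMP", source = "Rs", r2 = 0.95)))
  tab <- gen_covariates(cfg)
  rep_ <- vif_screen(tab[, covariate_names()])
  expect_equal(sum(c("WTMP", "Rs") %in% rep_$removed), 1L)
  expect_true(all(rep_$final_vif <= 10))
  # screening terminates in at most p - 1 rounds
  expect_lte(length(rep_$removed), length(covariate_names()) - 1)
})

test_that("orthogonal designs survive screening untouched", {
  set.seed(32)
  X <- as.data.frame(qr.Q(qr(cbind(1, matrix(rnorm(400), 100, 4))))[, -1])
  rep_ <- vif_screen(X)
  expect_equal(length(rep_$removed), 0L)
  expect_equal(rep_$retained, names(X))
})

test_that("season labels partition the calendar", {
  cal <- biweekly_calendar()
  s <- season_of(cal)
  expect_false(anyNA(s))
  expect_equal(length(s), length(cal))
  expect_setequal(levels(s), c("spring", "summer", "fall", "winter"))
  # midpoint rule: a bin starting late February with midpoint in March is spring
  expect_equal(as.character(season_of(as.Date("2002-02-25"))), "spring")
  expect_equal(as.character(season_of(as.Date("2002-02-20"))), "winter")
})

test_that("lag selection recovers the construction lag", {
  cfg <- synthetic_config(seed = 3)
  cov <- gen_covariates(cfg)
  n <- nrow(cov)
  set.seed(1)
  chl0 <- 5 + 0.3 * cov$WTMP + 0.01 * cov$Rs + rnorm(n, 0, 1)
  expect_equal(lag_select(chl0, cov)$lag, 0L)
  chl2 <- c(rnorm(2), 5 + 0.3 * cov$WTMP[1:(n - 2)] + 0.01 * cov$Rs[1:(n - 2)]) +
    rnorm(n, 0, 0.5)
  expect_equal(lag_select(chl2, cov)$lag, 2L)
  # pure noise: no stable winner
  set.seed(9)
  res <- lag_select(rnorm(n), cov)
  expect_true(res$inconclusive)
})
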