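test_that("GCV arithmetic and monotonicity", {
  expect_equal(gcv(50, 100, 1), 50 / (100 * 0.99^2), tolerance = 1e-12)
  expect_equal(gcv(0, 50, 3), 0)
  g <- vapply(1:20, function(m) gcv(10, 100, m), numeric(1))
  expect_true(all(diff(g) > 0))
  expect_error(gcv(1, 10, 10), "saturated")
  expect_error(gcv(1, 10, 0), "positive")
})

test_that("an exactly representable hinge target is recovered perfectly", {
  x <- seq(0, 6, length.out = 41)
  X <- cbind(x = x)
  y <- 2 * pmax(0, x - 3)
  fit <- forward_pass(X, y, minspan = 1, endspan = 0)
  # first pair selects the true knot
  expect_equal(fit$terms[[2]][[1]]$var, 1L)
  expect_equal(fit$terms[[2]][[1]]$knot, 3)
  r2 <- 1 - fit$rss / fit$tss
  expect_equal(r2, 1, tolerance = 1e-10)
})

test_that("a constant response yields the intercept-only model", {
  X <- cbind(x = rnorm(30))
  fit <- mars(X, rep(4.2, 30))
  expect_equal(length(fit$terms), 1L)
  expect_equal(unname(fit$coefficients[1]), 4.2)
  imp <- importance(fit)
  expect_true(attr(imp, "intercept_only"))
  expect_true(is.na(attr(imp, "top")))
  expect_true(all(imp$nsubsets == 0))
})

test_that("the greedy first pair matches an exhaustive-search oracle", {
  set.seed(21)
  n <- 20
  X <- cbind(a = runif(n), b = runif(n))
  y <- sin(3 * X[, 1]) + 0.5 * X[, 2]^2 + rnorm(n, 0, 0.1)
  # oracle: best joint RSS reduction over every (variable, knot) hinge pair
  base_rss <- sum((y - mean(y))^2)
  best <- 0
  for (v in 1:2) for (t in unique(X[, v])) {
    h1 <- pmax(X[, v] - t, 0); h2 <- pmax(t - X[, v], 0)
    fit <- stats::lm.fit(cbind(1, h1, h2), y)
    best <- max(best, base_rss - sum(fit$residuals^2))
  }
  fwd <- forward_pass(X, y, max_terms = 3, minspan = 1, endspan = 0)
  expect_equal(base_rss - fwd$rss, best, tolerance = 1e-8)
})

test_that("pruning removes a truly zero-coefficient term and lowers GCV", {
  x <- seq(-2, 4, length.out = 61)
  X <- cbind(x = x)
  y <- 5 + 2 * pmax(0, x - 1)      # the mirrored hinge has true coefficient 0
  fwd <- forward_pass(X, y, minspan = 1, endspan = 0)
  expect_gte(length(fwd$terms), 3L)
  pruned <- backward_prune(fwd, X, y)
  dirs <- unlist(lapply(pruned$terms, function(tm) vapply(tm, `[[`, numeric(1), "dir")))
  expect_false(any(dirs < 0))       # the (1 - x)+ term is gone
  expect_lt(pruned$gcv, fwd$gcv)
})

test_that("pruned GCV never exceeds the unpruned GCV", {
  set.seed(22)
  for (i in 1:5) {
    X <- matrix(runif(60 * 3), 60, 3)
    y <- X[, 1]^2 - X[, 2] + rnorm(60, 0, 0.3)
    fwd <- forward_pass(X, y)
    expect_lte(backward_prune(fwd, X, y)$gcv, fwd$gcv + 1e-12)
  }
})

test_that("additive two-hinge targets are recovered to knot accuracy 0.1", {
  set.seed(7)
  n <- 200
  X <- cbind(x1 = runif(n, 0, 3), x2 = runif(n, 0, 4))
  y <- pmax(0, X[, 1] - 1) + 3 * pmax(0, 2 - X[, 2]) + rnorm(n, 0, 0.01)
  fit <- mars(X, y)
  expect_gt(fit$r2, 0.99)
  knots1 <- unlist(lapply(fit$terms, function(tm)
    vapply(tm, function(f) if (f$var == 1) f$knot else NA_real_, numeric(1))))
  knots2 <- unlist(lapply(fit$terms, function(tm)
    vapply(tm, function(f) if (f$var == 2) f$knot else NA_real_, numeric(1))))
  expect_lt(min(abs(stats::na.omit(knots1) - 1)), 0.1)
  expect_lt(min(abs(stats::na.omit(knots2) - 2)), 0.1)
})

test_that("a pure-noise response is pruned back to a tiny model", {
  keep_small <- 0; r2s <- numeric(30)
  for (i in 1:30) {
    set.seed(i)
    X <- matrix(rnorm(200 * 9), 200, 9)
    y <- rnorm(200)
    fit <- mars(X, y)
    r2s[i] <- fit$r2
    if (length(fit$terms) <= 3L) keep_small <- keep_small + 1  # <= 2 hinge terms
  }
  expect_gte(keep_small / 30, 0.9)
  expect_lt(mean(r2s), 0.1)
})

test_that("predictions are continuous across every knot", {
  set.seed(23)
  n <- 100
  X <- cbind(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10))
  y <- 2 * sin(X[, 1]) + 0.3 * X[, 1] * X[, 2] + rnorm(n, 0, 0.2)
  fit <- mars(X, y)
  knots <- unlist(lapply(fit$terms, function(tm) vapply(tm, `[[`, numeric(1), "knot")))
  for (k in unique(knots)) {
    lo <- predict(fit, cbind(x1 = k - 1e-9, x2 = 5))
    hi <- predict(fit, cbind(x1 = k + 1e-9, x2 = 5))
    expect_lt(abs(hi - lo), 1e-6)
    lo2 <- predict(fit, cbind(x1 = 5, x2 = k - 1e-9))
    hi2 <- predict(fit, cbind(x1 = 5, x2 = k + 1e-9))
    expect_lt(abs(hi2 - lo2), 1e-6)
  }
})

test_that("duplicating a predictor column leaves fitted values unchanged", {
  set.seed(24)
  n <- 120
  X <- cbind(x1 = runif(n), x2 = runif(n))
  y <- 3 * pmax(0, X[, 1] - 0.4) + rnorm(n, 0, 0.05)
  # identical candidate-knot sets and term budget so the duplicate is a pure tie
  f1 <- mars(X, y, max_terms = 5, minspan = 1, endspan = 0)
  f2 <- mars(cbind(X, x1dup = X[, 1]), y, max_terms = 5, minspan = 1, endspan = 0)
  expect_equal(f2$fitted, f1$fitted, tolerance = 1e-10)
})

test_that("training R-squared stays in the unit interval", {
  set.seed(25)
  for (i in 1:5) {
    X <- matrix(rnorm(80 * 4), 80, 4)
    y <- rnorm(80)
    fit <- mars(X, y)
    expect_gte(fit$r2, 0); expect_lte(fit$r2, 1)
  }
})

test_that("a lone informative predictor tops every importance criterion", {
  set.seed(26)
  n <- 150
  X <- cbind(z = runif(n, -2, 2))
  y <- 4 * pmax(0, X[, 1]) + rnorm(n, 0, 0.1)
  imp <- importance(mars(X, y))
  expect_equal(attr(imp, "top"), "z")
  expect_gt(imp$nsubsets[1], 0)
  expect_equal(imp$rss[1], 100)
  expect_equal(imp$gcv[1], 100)
})

test_that("the informative variable wins nsubsets across seeded replicates", {
  wins <- 0; reps <- 50
  for (i in seq_len(reps)) {
    set.seed(100 + i)
    n <- 100
    X <- matrix(rnorm(n * 9), n, 9,
                dimnames = list(NULL, paste0("v", 1:9)))
    y <- 3 * pmax(0, X[, 1] + 0.5) + rnorm(n, 0, 0.2)
    if (identical(attr(importance(mars(X, y)), "top"), "v1")) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.95)
})

test_that("variables absent from every subset score zero", {
  set.seed(27)
  n <- 150
  X <- cbind(s = runif(n, -1, 1), junk = runif(n))
  y <- 5 * pmax(0, X[, 1]) + rnorm(n, 0, 0.05)
  imp <- importance(mars(X, y))
  if (imp$nsubsets[2] == 0) {
    expect_equal(imp$rss[2], 0)
    expect_equal(imp$gcv[2], 0)
  }
  expect_equal(attr(imp, "top"), "s")
})

test_that("models serialize to JSON with their basis structure", {
  set.seed(28)
  X <- cbind(x = runif(50, 0, 2))
  y <- pmax(0, X[, 1] - 1) + rnorm(50, 0, 0.05)
  fit <- mars(X, y)
  path <- withr::local_tempfile(fileext = ".json")
  mars_to_json(fit, path)
  obj <- jsonlite::read_json(path)
  expect_equal(length(obj$coefficients), length(fit$terms))
  expect_equal(obj$n, 50L)
})
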