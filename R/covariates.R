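#' Aggregate raw environmental series to the biweekly covariate table
#'
#' Accepts long-format observations from heterogeneous sources (hourly or
#' daily; single- or multi-site; gridded series enter as one "site" per cell)
#' and reduces them to one biweekly value per variable: sub-daily values are
#' averaged to daily, daily values to the 14-day bin, and sites (or grid
#' cells) averaged across. Water-temperature gaps are filled with the same
#' +/-14-day neighbour-year climatology used for the Chl-a series.
#'
#' @param raw data.frame with columns `variable`, `time` (Date or POSIXct),
#'   `value`, and optionally `site` (defaults to a single site).
#' @param calendar bin-start dates from [biweekly_calendar()].
#' @param climatology_vars variables whose remaining biweekly gaps are filled
#'   climatologically (default `"WTMP"`).
#' @return data.frame with `bin_start`, `season`, and one column per variable
#'   present; attribute `missing_bins` lists variable/bin pairs with no data.
#' @export
aggregate_biweekly <- function(raw, calendar = biweekly_calendar(),
                               climatology_vars = "WTMP") {
  stopifnot(all(c("variable", "time", "value") %in% names(raw)))
  if (is.null(raw$site)) raw$site <- "site1"
  day <- as.Date(raw$time)
  step <- if (length(calendar) > 1) as.integer(calendar[2] - calendar[1]) else 14L
  # hourly -> daily within (variable, site)
  daily <- stats::aggregate(value ~ variable + site + day,
                            data = data.frame(raw[c("variable", "site", "value")], day = day),
                            FUN = mean, na.rm = TRUE)
  bin <- floor(as.numeric(daily$day - calendar[1]) / step) + 1L
  daily <- daily[bin >= 1 & bin <= length(calendar), ]
  bin <- bin[bin >= 1 & bin <= length(calendar)]
  # daily -> biweekly within (variable, site), then across sites
  bw <- stats::aggregate(value ~ variable + site + bin,
                         data = data.frame(daily[c("variable", "site", "value")], bin = bin),
                         FUN = mean, na.rm = TRUE)
  xv <- stats::aggregate(value ~ variable + bin, data = bw, FUN = mean, na.rm = TRUE)

  out <- data.frame(bin_start = calendar, season = season_of(calendar))
  missing_bins <- NULL
  for (v in unique(xv$variable)) {
    col <- rep(NA_real_, length(calendar))
    sel <- xv$variable == v
    col[xv$bin[sel]] <- xv$value[sel]
    if (v %in% climatology_vars && anyNA(col)) {
      col <- climatology_fill_series(col, calendar)
    }
    if (anyNA(col)) {
      missing_bins <- rbind(missing_bins,
                            data.frame(variable = v, bin = which(is.na(col))))
    }
    out[[v]] <- col
  }
  attr(out, "missing_bins") <- missing_bins
  out
}

#' Variance inflation factors
#'
#' Each predictor is regressed (with intercept) on all the others; its VIF is
#' `1 / (1 - R^2)` of that regression. Predictors are standardised first --
#' VIF is scale-invariant, but standardising keeps the regressions well
#' conditioned. Perfect collinearity yields `Inf`.
#'
#' @param design numeric matrix or data.frame of predictors (>= 2 columns,
#'   more rows than columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2) stop("VIF needs at least two predictors", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("VIF needs more rows than predictors", call. = FALSE)
  X <- scale(X)
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(design)
  out
}

#' Iterative VIF screening
#'
#' Repeatedly removes the predictor with the largest VIF while that VIF
#' exceeds the threshold, recomputing each round. Ties on the largest VIF are
#' broken by removing the variable appearing *later* in the canonical
#' [covariate_names()] order (deterministic). Stops with a warning if only
#' one variable would remain.
#'
#' @param design predictors for one season.
#' @param threshold removal threshold (default 10, the usual severe-
#'   multicollinearity rule of thumb).
#' @return list of class `vif_report`: `initial_vif`, `rounds` (per-round VIF
#'   vectors), `removed` (in order), `retained`, `final_vif`.
#' @export
vif_screen <- function(design, threshold = 10) {
  X <- as.data.frame(design)
  canon <- c(covariate_names(), setdiff(names(X), covariate_names()))
  removed <- character(0)
  rounds <- list()
  initial <- vif(X)
  repeat {
    v <- vif(X)
    rounds[[length(rounds) + 1L]] <- v
    worst <- which(v == max(v))
    if (max(v) <= threshold) break
    if (ncol(X) <= 2) {
      warning("VIF screening stopped: only one variable would remain", call. = FALSE)
      break
    }
    # tie-break: later canonical position goes first
    pick <- names(v)[worst][which.max(match(names(v)[worst], canon))]
    removed <- c(removed, pick)
    X <- X[, setdiff(names(X), pick), drop = FALSE]
  }
  structure(list(initial_vif = initial, rounds = rounds, removed = removed,
                 retained = names(X), final_vif = vif(X), threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("<vif_report> threshold", x$threshold, "\n")
  cat("  removed: ", if (length(x$removed)) paste(x$removed, collapse = " > ") else "(none)", "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Screen predictors season by season
#'
#' @param covariates table from [gen_covariates()] / [aggregate_biweekly()].
#' @param vars predictor columns to consider.
#' @param threshold VIF removal threshold.
#' @return named list of [vif_screen()] reports, one per season.
#' @export
vif_screen_by_season <- function(covariates, vars = covariate_names(),
                                 threshold = 10) {
  vars <- intersect(vars, names(covariates))
  out <- lapply(levels(covariates$season), function(s) {
    vif_screen(covariates[covariates$season == s, vars, drop = FALSE], threshold)
  })
  names(out) <- levels(covariates$season)
  out
}

#' Select the predictor lag by linear regression
#'
#' Fits OLS of the Chl-a series on the covariates shifted back by each
#' candidate lag (in bins) and reports the lag with the highest R-squared.
#' When the R-squared spread across lags is below `min_spread` there is no
#' stable winner and the result is flagged inconclusive.
#'
#' @param chl_series numeric response, aligned with `covariates` rows.
#' @param covariates biweekly covariate table.
#' @param max_lag largest lag tested (bins).
#' @param vars predictor columns.
#' @param min_spread R-squared range below which the choice is inconclusive.
#' @return list: `lag` (selected), `r2` (named by lag), `inconclusive`.
#' @export
lag_select <- function(chl_series, covariates, max_lag = 4L,
                       vars = covariate_names(), min_spread = 0.05) {
  vars <- intersect(vars, names(covariates))
  n <- length(chl_series)
  if (n - max_lag <= length(vars) + 1) {
    stop("insufficient rows after lagging", call. = FALSE)
  }
  X <- as.matrix(covariates[, vars, drop = FALSE])
  r2 <- vapply(0:max_lag, function(L) {
    y <- chl_series[(1 + L):n]
    Z <- X[1:(n - L), , drop = FALSE]
    fit <- stats::lm.fit(cbind(1, Z), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }, numeric(1))
  names(r2) <- 0:max_lag
  list(lag = as.integer(names(r2)[which.max(r2)]), r2 = r2,
       inconclusive = diff(range(r2)) < min_spread)
}
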