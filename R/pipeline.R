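#' Fit seasonal MARS models at every retained pixel
#'
#' For each season and each retained (not fully missing) pixel, fits a MARS
#' model of that pixel's seasonal Chl-a bins on the season's VIF-retained,
#' spatially constant predictors, pooling bins across years within the
#' season. Pixels with fewer seasonal bins than `min_bins` are skipped with a
#' logged reason; a season whose retained predictor set is empty is skipped
#' and reported.
#'
#' @param grid a gap-free biweekly [chl_grid()].
#' @param covariates biweekly covariate table aligned with `grid`.
#' @param vif_reports named list of per-season [vif_screen()] reports (from
#'   [vif_screen_by_season()]); `NULL` uses all of [covariate_names()]
#'   present in `covariates` for every season.
#' @param mars_config list of arguments passed to [mars()] (`max_terms`,
#'   `max_degree`, `thresh`).
#' @param min_bins minimum seasonal sample size per pixel fit.
#' @return object of class `pixel_fit_results`: data.frame `results` (pixel,
#'   y, x, season, n bins, r2, top variable), list `importance` of
#'   per-fit importance tables, data.frame `skipped`, and the grid shape.
#' @export
fit_all_pixels <- function(grid, covariates, vif_reports = NULL,
                           mars_config = list(), min_bins = 20L) {
  stopifnot(inherits(grid, "chl_grid"))
  stopifnot(nrow(covariates) == length(grid$dates))
  m <- as_pixel_matrix(grid)
  d <- dim(grid$values)
  retained <- which(colSums(!is.na(m)) > 0)
  seasons <- levels(covariates$season)

  results <- NULL; skipped <- NULL; imp_list <- list()
  for (s in seasons) {
    vars <- if (is.null(vif_reports)) {
      intersect(covariate_names(), names(covariates))
    } else {
      vif_reports[[s]]$retained
    }
    if (!length(vars)) {
      skipped <- rbind(skipped, data.frame(pixel = NA, season = s,
                                           reason = "empty retained predictor set"))
      next
    }
    in_s <- covariates$season == s
    Xs <- as.matrix(covariates[in_s, vars, drop = FALSE])
    for (px in retained) {
      ys <- m[in_s, px]
      ok <- !is.na(ys)
      if (sum(ok) < min_bins) {
        skipped <- rbind(skipped, data.frame(pixel = px, season = s,
                                             reason = sprintf("only %d seasonal bins", sum(ok))))
        next
      }
      fit <- do.call(mars, c(list(X = Xs[ok, , drop = FALSE], y = ys[ok]), mars_config))
      imp <- importance(fit)
      yx <- pixel_yx(px, d[2L])
      key <- sprintf("%s.%d", s, px)
      imp_list[[key]] <- imp
      results <- rbind(results, data.frame(
        pixel = px, y = yx[1, "y"], x = yx[1, "x"], season = s,
        n_bins = sum(ok), r2 = fit$r2, top = attr(imp, "top")))
    }
  }
  if (!is.null(results)) {
    results$season <- factor(results$season, levels = seasons)
  }
  structure(list(results = results, importance = imp_list, skipped = skipped,
                 ny = d[2L], nx = d[3L]),
            class = "pixel_fit_results")
}

#' @export
print.pixel_fit_results <- function(x, ...) {
  cat(sprintf("<pixel_fit_results> %d fits, %d skipped\n",
              if (is.null(x$results)) 0L else nrow(x$results),
              if (is.null(x$skipped)) 0L else nrow(x$skipped)))
  invisible(x)
}

#' Seasonal shares of the top-importance variable
#'
#' For each season, the percentage of fitted pixels whose highest-importance
#' variable is each predictor. Variables never fitted in a season (e.g.
#' excluded by VIF screening) are `NA`; per season the percentages over
#' participating variables sum to 100 (pixels whose model was intercept-only
#' are excluded from the denominator).
#'
#' @param fits a [fit_all_pixels()] result.
#' @param vars row order of the output; default [covariate_names()].
#' @return data.frame: `variable` plus one percentage column per season.
#' @export
summarize_importance <- function(fits, vars = covariate_names()) {
  stopifnot(inherits(fits, "pixel_fit_results"))
  res <- fits$results
  seasons <- levels(res$season)
  out <- data.frame(variable = vars)
  for (s in seasons) {
    sub <- res[res$season == s & !is.na(res$top), ]
    col <- rep(NA_real_, length(vars))
    if (nrow(sub)) {
      seen <- unique(unlist(lapply(
        fits$importance[sprintf("%s.%d", s, sub$pixel)],
        function(im) im$variable)))
      col[vars %in% seen] <- 0
      tab <- table(sub$top)
      col[match(names(tab), vars)] <- 100 * as.numeric(tab) / nrow(sub)
    }
    out[[s]] <- col
  }
  out
}

#' Seasonal R-squared maps
#'
#' @param fits a [fit_all_pixels()] result.
#' @return list with `maps` (one `ny x nx` matrix per season, `NA` where the
#'   pixel was skipped or dropped) and `means` (seasonal spatial mean R2).
#' @export
r2_map <- function(fits) {
  stopifnot(inherits(fits, "pixel_fit_results"))
  res <- fits$results
  seasons <- levels(res$season)
  maps <- lapply(seasons, function(s) {
    mp <- matrix(NA_real_, fits$ny, fits$nx)
    sub <- res[res$season == s, ]
    mp[cbind(sub$y, sub$x)] <- sub$r2
    mp
  })
  names(maps) <- seasons
  list(maps = maps,
       means = vapply(maps, function(mp) mean(mp, na.rm = TRUE), numeric(1)))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full study end to end
#'
#' Composes every stage on either synthetic inputs (a [synthetic_config()])
#' or files (long-format Chl-a CSV via [read_chl_csv()] plus a covariate
#' CSV): sparsity filter, two-step gap fill, spatial-mean wavelet analysis,
#' per-season VIF screening, per-pixel MARS, and the importance/R-squared
#' summaries. Deterministic given the config seed; the returned manifest
#' records seed, parameters and package version so a rerun reproduces all
#' outputs.
#'
#' @param config a [synthetic_config()], or a list with `chl_csv` and
#'   `covariates_csv` paths for file-based ingest.
#' @param knn a [knn_config()].
#' @param mars_config arguments passed through to [mars()].
#' @param min_bins minimum seasonal bins per pixel fit.
#' @param vif_threshold VIF removal threshold.
#' @return list of class `report_bundle`: `filled` grid, `fill_report`,
#'   `wavelet`, `dominant`, `vif`, `fits`, `importance_summary`, `r2`,
#'   `manifest`.
#' @export
run_study <- function(config, knn = knn_config(), mars_config = list(),
                      min_bins = 20L, vif_threshold = 10) {
  if (inherits(config, "synthetic_config")) {
    study <- run_stage("synthetic", synth_study(config))
    observed <- study$observed
    covariates <- study$covariates
  } else {
    observed <- run_stage("ingest", {
      if (is.null(config$chl_csv) || !file.exists(config$chl_csv)) {
        stop("Chl-a input file not found: ", config$chl_csv %||% "<missing>")
      }
      read_chl_csv(config$chl_csv)
    })
    covariates <- run_stage("ingest", {
      if (is.null(config$covariates_csv) || !file.exists(config$covariates_csv)) {
        stop("covariate input file not found: ", config$covariates_csv %||% "<missing>")
      }
      df <- utils::read.csv(config$covariates_csv)
      df$bin_start <- as.Date(df$bin_start)
      df$season <- season_of(df$bin_start)
      df
    })
  }

  sparse <- run_stage("sparsity_filter", drop_sparse_pixels(observed))
  filled <- run_stage("gapfill", fill_pipeline(sparse$grid, knn))
  dt_yr <- as.numeric(observed$dates[2] - observed$dates[1]) / 365.25
  series <- spatial_mean(filled$grid)
  wav <- run_stage("wavelet", cwt(series, dt = dt_yr))
  dom <- run_stage("wavelet", dominant_periods(wav, n_peaks = 2, x = series))
  vifs <- run_stage("vif", vif_screen_by_season(covariates, threshold = vif_threshold))
  fits <- run_stage("mars", fit_all_pixels(filled$grid, covariates, vifs,
                                           mars_config = mars_config,
                                           min_bins = min_bins))
  imp <- run_stage("summaries", summarize_importance(fits))
  r2 <- run_stage("summaries", r2_map(fits))

  manifest <- list(
    seed = if (inherits(config, "synthetic_config")) config$seed else NA,
    config = if (inherits(config, "synthetic_config")) {
      config[setdiff(names(config), c("covariate_effects", "collinearity"))]
    } else config,
    package_version = as.character(utils::packageVersion("bloomdyn")),
    r_version = R.version.string
  )
  structure(list(filled = filled$grid, fill_report = filled$report,
                 dropped_pixels = sparse$dropped,
                 wavelet = wav, dominant = dom, vif = vifs, fits = fits,
                 importance_summary = imp, r2 = r2, manifest = manifest),
            class = "report_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
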