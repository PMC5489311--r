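#' Canonical environmental covariate names
#'
#' The nine biweekly covariates the importance analysis uses, in their
#' canonical table order: total phosphorus, soluble reactive phosphorus,
#' nitrate+nitrite, total Kjeldahl nitrogen, river discharge, precipitation,
#' wind speed, water temperature, solar radiation.
#'
#' @return character vector of length 9.
#' @export
covariate_names <- function() {
  c("TP", "SRP", "NO23", "TKN", "Q", "PCP", "Wind", "WTMP", "Rs")
}

#' Configuration for the synthetic bloom-grid generator
#'
#' Defines the study conditions the generators emulate: a biweekly Chl-a grid
#' over a shallow eutrophic basin with annual and semiannual cycles, nearshore
#' bloom hotspots decaying away from river outlets, AR(1) red-noise
#' background, cloud-like contiguous gaps, and nine environmental covariates
#' with realistic seasonality.
#'
#' @param ny,nx grid shape (pixels).
#' @param start,end,step time span and stride in days (biweekly default).
#' @param mean_chl basin-mean Chl-a (ug/L).
#' @param annual_amp,semiannual_amp amplitudes of the annual and semiannual
#'   sinusoids (ug/L).
#' @param annual_peak_doy,semiannual_peak_doy day-of-year at which the annual
#'   cycle peaks (default 225, a late-August bloom maximum) and at which the
#'   first of the two semiannual maxima falls (default 120, late spring; the
#'   second follows half a year later).
#' @param hotspots list of `list(y, x, amp, decay)` Gaussian bumps: centre in
#'   grid units, peak amplitude (ug/L), e-folding decay length (pixels).
#' @param ar1 lag-1 autocorrelation of the red-noise background, in `[0, 1)`.
#' @param noise_sd stationary standard deviation of the noise (ug/L).
#' @param spatial_coherence fraction of noise variance shared across all
#'   pixels, in `[0, 1]`; higher values make gaps easier to impute spatially.
#' @param gap_fraction target fraction of cells masked by cloud gaps, `[0, 1)`.
#' @param n_sparse_pixels pixels pushed above 50% missingness (only when
#'   `gap_fraction > 0`) so the sparsity filter has work to do.
#' @param covariate_effects named list (names from [covariate_names()]) of
#'   `list(season =, fn =)`: in bins of that season, `fn(covariate value)` is
#'   added to Chl-a at every pixel, giving known ground truth for
#'   importance-recovery experiments.
#' @param collinearity optional list of `list(target =, source =, r2 =)`
#'   entries: the target covariate is rebuilt as a linear function of the
#'   source plus noise with the stated population R-squared, to exercise VIF
#'   screening.
#' @param seed integer RNG seed; equal seeds give byte-identical output.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(ny = 20, nx = 30,
                             start = "2002-01-05", end = "2012-03-21",
                             step = 14L,
                             mean_chl = 12, annual_amp = 8, semiannual_amp = 4,
                             annual_peak_doy = 225, semiannual_peak_doy = 120,
                             hotspots = list(
                               list(y = 4, x = 4, amp = 18, decay = 4),
                               list(y = 16, x = 25, amp = 10, decay = 5)
                             ),
                             ar1 = 0.6, noise_sd = 2,
                             spatial_coherence = 0.3,
                             gap_fraction = 0.2, n_sparse_pixels = 2,
                             covariate_effects = list(),
                             collinearity = NULL,
                             seed = 1L) {
  if (ny < 1 || nx < 1) stop("invalid config: non-positive grid shape", call. = FALSE)
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("invalid config: empty time span", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("invalid config: AR(1) coefficient must be in [0, 1)", call. = FALSE)
  if (gap_fraction < 0 || gap_fraction >= 1) {
    stop("invalid config: gap fraction must be in [0, 1)", call. = FALSE)
  }
  if (spatial_coherence < 0 || spatial_coherence > 1) {
    stop("invalid config: spatial coherence must be in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(names(covariate_effects), covariate_names())
  if (length(bad)) {
    stop("invalid config: unknown covariate name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (cl in collinearity) {
    if (!all(c(cl$target, cl$source) %in% covariate_names())) {
      stop("invalid config: unknown covariate name in collinearity spec", call. = FALSE)
    }
  }
  structure(
    list(ny = as.integer(ny), nx = as.integer(nx),
         start = start, end = end, step = as.integer(step),
         mean_chl = mean_chl, annual_amp = annual_amp,
         semiannual_amp = semiannual_amp,
         annual_peak_doy = annual_peak_doy,
         semiannual_peak_doy = semiannual_peak_doy,
         hotspots = hotspots,
         ar1 = ar1, noise_sd = noise_sd,
         spatial_coherence = spatial_coherence,
         gap_fraction = gap_fraction,
         n_sparse_pixels = as.integer(n_sparse_pixels),
         covariate_effects = covariate_effects,
         collinearity = collinearity,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Stationary AR(1) columns: innovations scaled so each series has marginal
# standard deviation `sd`; 50-step burn-in from the stationary distribution.
ar1_matrix <- function(n, ncol, alpha, sd) {
  if (sd == 0) return(matrix(0, n, ncol))
  burn <- 50L
  innov <- matrix(stats::rnorm((n + burn) * ncol, 0, sd * sqrt(1 - alpha^2)),
                  n + burn, ncol)
  out <- stats::filter(innov, alpha, method = "recursive")
  matrix(as.numeric(out[(burn + 1):(burn + n), ]), n, ncol)
}

#' Generate the gap-free synthetic Chl-a truth grid
#'
#' Each pixel series is basin mean + annual sinusoid + semiannual sinusoid +
#' a static hotspot field (sum of Gaussian bumps) + AR(1) noise that mixes a
#' basin-wide component with per-pixel components, clipped at zero.
#'
#' @param config a [synthetic_config()].
#' @return a [chl_grid()] with provenance `"truth"` and no missing cells.
#' @export
gen_chl_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dates <- biweekly_calendar(config$start, config$end, config$step)
  nt <- length(dates); ny <- config$ny; nx <- config$nx
  t_yr <- as.numeric(dates - dates[1]) / 365.25

  doy0 <- as.numeric(format(dates[1], "%j"))
  ph1 <- (config$annual_peak_doy - doy0) / 365.25
  ph2 <- (config$semiannual_peak_doy - doy0) / 365.25
  seasonal <- config$annual_amp * cos(2 * pi * (t_yr - ph1)) +
    config$semiannual_amp * cos(4 * pi * (t_yr - ph2))

  hot <- matrix(0, ny, nx)
  for (h in config$hotspots) {
    d2 <- outer((seq_len(ny) - h$y)^2, (seq_len(nx) - h$x)^2, "+")
    hot <- hot + h$amp * exp(-d2 / (2 * h$decay^2))
  }

  set.seed(config$seed)
  w <- config$spatial_coherence
  common <- ar1_matrix(nt, 1L, config$ar1, config$noise_sd)[, 1L]
  indep <- ar1_matrix(nt, ny * nx, config$ar1, config$noise_sd)
  noise <- sqrt(w) * common + sqrt(1 - w) * indep   # recycles common by column

  base <- config$mean_chl + seasonal                 # length nt
  vals <- array(rep(base, ny * nx) + rep(as.vector(hot), each = nt) + noise,
                dim = c(nt, ny, nx))
  vals[vals < 0] <- 0
  chl_grid(vals, dates, provenance = "truth")
}

#' Mask cloud-like gaps into a grid
#'
#' Random contiguous rectangles in (time, y, x) are masked until the target
#' missing fraction is reached, then a few pixels are pushed above 50%
#' missingness so the downstream sparsity filter is exercised. With
#' `gap_fraction = 0` the grid is returned untouched.
#'
#' @param grid a [chl_grid()].
#' @param config a [synthetic_config()]; uses `gap_fraction`,
#'   `n_sparse_pixels` and `seed`.
#' @return the grid with additional `NA` cells, provenance `"raw"`.
#' @export
apply_cloud_gaps <- function(grid, config) {
  stopifnot(inherits(grid, "chl_grid"), inherits(config, "synthetic_config"))
  f <- config$gap_fraction
  if (f == 0) return(grid)
  vals <- grid$values
  d <- dim(vals)
  ncell <- prod(d)
  set.seed(config$seed + 1L)
  guard <- 0L
  while (mean(is.na(vals)) < f && guard < 100000L) {
    t0 <- sample.int(d[1L], 1L); dt <- sample.int(4L, 1L)
    y0 <- sample.int(d[2L], 1L); dy <- sample.int(max(1L, ceiling(d[2L] / 3)), 1L)
    x0 <- sample.int(d[3L], 1L); dx <- sample.int(max(1L, ceiling(d[3L] / 3)), 1L)
    vals[t0:min(d[1L], t0 + dt - 1L),
         y0:min(d[2L], y0 + dy - 1L),
         x0:min(d[3L], x0 + dx - 1L)] <- NA_real_
    guard <- guard + 1L
  }
  if (config$n_sparse_pixels > 0) {
    m <- matrix(vals, d[1L], d[2L] * d[3L])
    px <- sample.int(d[2L] * d[3L], min(config$n_sparse_pixels, d[2L] * d[3L]))
    for (p in px) {
      m[sample.int(d[1L], ceiling(0.6 * d[1L])), p] <- NA_real_
    }
    vals <- array(m, d)
  }
  chl_grid(vals, grid$dates, pixel_size_m = grid$pixel_size_m, provenance = "raw")
}

#' Generate the biweekly environmental covariate table
#'
#' Nine covariates with realistic seasonality: water temperature and solar
#' radiation follow annual cycles peaking in summer, discharge has a spring
#' snowmelt/runoff peak, nutrient concentrations track discharge and season,
#' precipitation is gamma-distributed, wind peaks in winter. Optional
#' collinearity injection rebuilds one covariate as a noisy linear function of
#' another at a stated population R-squared.
#'
#' @param config a [synthetic_config()].
#' @param dates bin-start calendar to generate on; defaults to the config's.
#' @return a `data.frame` with columns `bin_start`, `season`, and the nine
#'   covariates of [covariate_names()].
#' @export
gen_covariates <- function(config, dates = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(dates)) dates <- biweekly_calendar(config$start, config$end, config$step)
  nt <- length(dates)
  doy <- as.numeric(format(dates + 7L, "%j"))
  cyc <- function(peak_doy) cos(2 * pi * (doy - peak_doy) / 365.25)

  set.seed(config$seed + 2L)
  ar <- function(sd) ar1_matrix(nt, 1L, 0.4, sd)[, 1L]
  pos <- function(x) pmax(x, 0)

  Q    <- pos(800 + 2500 * exp(-((doy - 95) / 40)^2) + ar(250))
  tab <- data.frame(
    bin_start = dates,
    season = season_of(dates),
    TP   = pos(60 + 0.02 * Q + ar(10)),
    SRP  = pos(15 + 0.005 * Q + ar(4)),
    NO23 = pos(2000 + 1500 * exp(-((doy - 120) / 50)^2) + ar(300)),
    TKN  = pos(700 + 200 * cyc(200) + ar(80)),
    Q    = Q,
    PCP  = stats::rgamma(nt, shape = 2, scale = 15),
    Wind = pos(5.5 + 1.5 * cyc(15) + ar(0.8)),
    WTMP = 52 + 20 * cyc(215) + ar(2),
    Rs   = pos(180 + 130 * cyc(172) + ar(15))
  )

  for (cl in config$collinearity) {
    src <- tab[[cl$source]]
    tgt <- tab[[cl$target]]
    z <- as.numeric(scale(src))
    eps <- stats::rnorm(nt)
    tab[[cl$target]] <- mean(tgt) +
      stats::sd(tgt) * (sqrt(cl$r2) * z + sqrt(1 - cl$r2) * eps)
  }
  tab
}

#' Add known covariate effects to a truth grid
#'
#' For each entry of `effects` (named by covariate), `fn(covariate)` is added
#' to every pixel's Chl-a in bins belonging to the stated season, then values
#' are re-clipped at zero. This is how the generator plants a known driver for
#' importance-recovery experiments: the effect is spatially constant, like the
#' covariates themselves.
#'
#' @param grid a gap-free truth [chl_grid()].
#' @param covariates table from [gen_covariates()], calendar-aligned with
#'   `grid`.
#' @param effects named list of `list(season =, fn =)`.
#' @return the modified [chl_grid()].
#' @export
apply_covariate_effects <- function(grid, covariates, effects) {
  if (!length(effects)) return(grid)
  bad <- setdiff(names(effects), covariate_names())
  if (length(bad)) stop("unknown covariate name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(nrow(covariates) == length(grid$dates))
  add <- numeric(length(grid$dates))
  for (v in names(effects)) {
    e <- effects[[v]]
    in_season <- covariates$season == e$season
    add[in_season] <- add[in_season] + e$fn(covariates[[v]][in_season])
  }
  vals <- grid$values + add    # recycles along the time dimension
  vals[vals < 0] <- 0
  chl_grid(vals, grid$dates, pixel_size_m = grid$pixel_size_m, provenance = "truth")
}

#' Generate a complete synthetic study
#'
#' Composes the generators into the inputs the analysis chain expects: the
#' gap-free truth grid (with any configured covariate effects applied), the
#' cloud-gapped observed grid, and the covariate table.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `truth`, `observed`, `covariates`, `config`.
#' @export
synth_study <- function(config) {
  truth <- gen_chl_truth(config)
  covariates <- gen_covariates(config)
  truth <- apply_covariate_effects(truth, covariates, config$covariate_effects)
  observed <- apply_cloud_gaps(truth, config)
  list(truth = truth, observed = observed, covariates = covariates,
       config = config)
}
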