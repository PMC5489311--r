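# Small study configurations used across tests. The flat config strips the
# deterministic structure (seasonality, hotspots) so Chl-a is genuinely
# independent of the covariates; the effect config plants a known summer
# water-temperature driver.

flat_config <- function(ny = 4, nx = 5, seed = 11, ...) {
  synthetic_config(ny = ny, nx = nx, annual_amp = 0, semiannual_amp = 0,
                   hotspots = list(), gap_fraction = 0, seed = seed, ...)
}

wtmp_effect_config <- function(ny = 4, nx = 5, seed = 5, strength = 0.8, ...) {
  synthetic_config(
    ny = ny, nx = nx, gap_fraction = 0, seed = seed,
    covariate_effects = list(
      WTMP = list(season = "summer", fn = function(w) strength * (w - 52))),
    ...)
}

# A tiny grid from explicit per-pixel series (list of numeric vectors,
# pixels enumerated column-major in (y, x)).
grid_from_series <- function(series, ny, nx, dates) {
  m <- do.call(cbind, series)
  chl_grid(array(m, c(length(dates), ny, nx)), dates)
}

biweekly_dates <- function(n, start = "2002-01-05") {
  seq(as.Date(start), by = 14, length.out = n)
}
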