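#' Optical constants for the two-band Chl-a retrieval
#'
#' Constants of the semi-analytical red / red-edge band-ratio algorithm for
#' turbid waters: pure-water absorption at the two band centres, a scalar
#' backscattering coefficient, and the Chl-a specific absorption gamma.
#' The water-absorption defaults are configuration, not physics baked into
#' code: the retrieval literature varies in the exact red-edge band centre
#' (705 vs 709 nm), so both absorptions are overridable.
#'
#' @param aw665 pure-water absorption at 665 nm (1/m).
#' @param aw709 pure-water absorption at ~709 nm (1/m).
#' @param bb backscattering coefficient, treated as a known scalar (1/m).
#' @param gamma Chl-a specific absorption (m^2/mg); default 0.68.
#' @return list of class `optical_constants`.
#' @export
optical_constants <- function(aw665 = 0.40, aw709 = 0.70, bb = 1.5, gamma = 0.68) {
  if (any(c(aw665, aw709, bb, gamma) <= 0)) {
    stop("optical constants must be strictly positive", call. = FALSE)
  }
  structure(list(aw665 = aw665, aw709 = aw709, bb = bb, gamma = gamma),
            class = "optical_constants")
}

#' Two-band water-leaving reflectance stack
#'
#' @param b665,b705 numeric `[time, y, x]` arrays of water-leaving reflectance
#'   in the 665 nm and ~705 nm bands; both bands share one missingness mask.
#' @param dates time axis.
#' @return object of class `reflectance_stack`.
#' @export
reflectance_stack <- function(b665, b705, dates) {
  if (!identical(dim(b665), dim(b705))) stop("band arrays must share dimensions", call. = FALSE)
  if (!identical(is.na(b665), is.na(b705))) stop("both bands must share one mask", call. = FALSE)
  if (any(b665 <= 0, na.rm = TRUE) || any(b705 <= 0, na.rm = TRUE)) {
    stop("reflectances must be strictly positive where observed", call. = FALSE)
  }
  structure(list(b665 = b665, b705 = b705, dates = as.Date(dates)),
            class = "reflectance_stack")
}

#' Simulate reflectance that inverts exactly to a given Chl-a grid
#'
#' Constructs the two-band stack by algebraically inverting the band-ratio
#' retrieval: the 665 nm band is held at a constant plausible reflectance and
#' the red-edge band is solved from the Chl-a absorption budget, so
#' [chl_from_bands()] recovers the input to floating-point precision.
#' Missing Chl-a cells propagate to missing reflectance.
#'
#' @param chl a [chl_grid()] with non-negative values.
#' @param optics an [optical_constants()].
#' @param b665 scalar reflectance assigned to the 665 nm band.
#' @return a [reflectance_stack()].
#' @export
gen_reflectance <- function(chl, optics = optical_constants(), b665 = 0.05) {
  stopifnot(inherits(chl, "chl_grid"), inherits(optics, "optical_constants"))
  ratio <- (optics$gamma * chl$values + optics$bb + optics$aw665) /
    (optics$aw709 + optics$bb)
  b665a <- array(b665, dim(chl$values))
  b665a[is.na(chl$values)] <- NA_real_
  reflectance_stack(b665a, b665a * ratio, chl$dates)
}

#' Chl-a concentration from the two-band ratio
#'
#' Per observed cell:
#' `chl = ((B705/B665) * (aw709 + bb) - bb - aw665) / gamma`.
#' Negative retrievals are floored at zero (concentration semantics); the
#' count of floored cells is attached as attribute `n_floored`. Missing cells
#' propagate.
#'
#' @param stack a [reflectance_stack()].
#' @param optics an [optical_constants()].
#' @param pixel_size_m pixel size recorded on the result.
#' @return a [chl_grid()] with provenance `"raw"`.
#' @export
chl_from_bands <- function(stack, optics = optical_constants(), pixel_size_m = 300) {
  stopifnot(inherits(stack, "reflectance_stack"), inherits(optics, "optical_constants"))
  zero <- which(!is.na(stack$b665) & stack$b665 == 0)
  if (length(zero)) {
    ijk <- arrayInd(zero[1L], dim(stack$b665))
    stop(sprintf("B(665) = 0 at observed cell [t=%d, y=%d, x=%d]: band ratio undefined",
                 ijk[1], ijk[2], ijk[3]), call. = FALSE)
  }
  chl <- ((stack$b705 / stack$b665) * (optics$aw709 + optics$bb) -
            optics$bb - optics$aw665) / optics$gamma
  n_floored <- sum(chl < 0, na.rm = TRUE)
  chl[chl < 0] <- 0
  out <- chl_grid(chl, stack$dates, pixel_size_m = pixel_size_m, provenance = "raw")
  attr(out, "n_floored") <- n_floored
  out
}

# Interval-overlap weights mapping n_src source cells onto n_tgt target cells
# of relative size `factor` (>= 1, possibly non-integer).
overlap_weights <- function(n_src, factor) {
  n_tgt <- ceiling(n_src / factor)
  w <- matrix(0, n_src, n_tgt)
  for (j in seq_len(n_tgt)) {
    lo <- (j - 1) * factor; hi <- j * factor
    for (i in seq_len(n_src)) {
      w[i, j] <- max(0, min(i, hi) - max(i - 1, lo))
    }
  }
  w
}

#' Aggregate a grid to a coarser pixel size
#'
#' Block (area-weighted) mean of the observed source cells under each target
#' cell; a target cell is missing only when every contributing source cell is
#' missing. Non-integer aggregation factors are handled by area-weighted
#' overlap fractions.
#'
#' @param grid a [chl_grid()].
#' @param target_pixel_m target pixel edge length (m), at least the source
#'   pixel size.
#' @return a [chl_grid()] at the coarser resolution.
#' @export
regrid <- function(grid, target_pixel_m) {
  stopifnot(inherits(grid, "chl_grid"))
  if (target_pixel_m < grid$pixel_size_m) {
    stop("target pixel size must be >= source pixel size", call. = FALSE)
  }
  f <- target_pixel_m / grid$pixel_size_m
  d <- dim(grid$values)
  wy <- overlap_weights(d[2L], f)
  wx <- overlap_weights(d[3L], f)
  nty <- ncol(wy); ntx <- ncol(wx)
  out <- array(NA_real_, c(d[1L], nty, ntx))
  for (t in seq_len(d[1L])) {
    sl <- grid$values[t, , , drop = TRUE]
    sl <- matrix(sl, d[2L], d[3L])
    obs <- !is.na(sl)
    sl0 <- ifelse(obs, sl, 0)
    num <- t(wy) %*% sl0 %*% wx
    den <- t(wy) %*% (obs * 1) %*% wx
    out[t, , ] <- ifelse(den > 0, num / den, NA_real_)
  }
  chl_grid(out, grid$dates, pixel_size_m = target_pixel_m,
           provenance = grid$provenance)
}

#' Composite a daily grid onto the 14-day calendar
#'
#' Per pixel per bin, the mean of whatever daily values are available within
#' the bin; a bin with no available daily value stays missing. Daily dates
#' falling outside the calendar are dropped; their count is attached as
#' attribute `n_dropped_dates`.
#'
#' @param grid a daily [chl_grid()].
#' @param calendar bin-start dates from [biweekly_calendar()].
#' @return a [chl_grid()] on `calendar`, provenance `"composited"`.
#' @export
composite_biweekly <- function(grid, calendar = biweekly_calendar()) {
  stopifnot(inherits(grid, "chl_grid"))
  step <- if (length(calendar) > 1) as.integer(calendar[2] - calendar[1]) else 14L
  off <- as.numeric(grid$dates - calendar[1])
  bin <- floor(off / step) + 1L
  inside <- bin >= 1L & bin <= length(calendar)
  n_dropped <- sum(!inside)
  d <- dim(grid$values)
  m <- matrix(grid$values, d[1L], d[2L] * d[3L])[inside, , drop = FALSE]
  bin <- bin[inside]
  out <- matrix(NA_real_, length(calendar), d[2L] * d[3L])
  for (b in unique(bin)) {
    sub <- m[bin == b, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    out[b, ] <- mu
  }
  res <- chl_grid(array(out, c(length(calendar), d[2L], d[3L])), calendar,
                  pixel_size_m = grid$pixel_size_m, provenance = "composited")
  attr(res, "n_dropped_dates") <- n_dropped
  res
}

#' Remove pixels with sparse biweekly coverage
#'
#' Pixels whose missing fraction strictly exceeds the threshold are fully
#' masked ("more than 50% missing": exactly 50% is retained). Idempotent.
#'
#' @param grid a biweekly [chl_grid()].
#' @param threshold maximum tolerated missing fraction (default 0.5).
#' @return list with `grid` (sparse pixels fully `NA`) and `dropped`, a
#'   data.frame of the removed pixels' linear index and `(y, x)` coordinates.
#' @export
drop_sparse_pixels <- function(grid, threshold = 0.5) {
  stopifnot(inherits(grid, "chl_grid"))
  frac <- missing_fraction(grid)
  drop <- which(frac > threshold & frac < 1)   # already-empty pixels are not re-reported
  m <- as_pixel_matrix(grid)
  m[, which(frac > threshold)] <- NA_real_
  d <- dim(grid$values)
  out <- chl_grid(array(m, d), grid$dates, pixel_size_m = grid$pixel_size_m,
                  provenance = grid$provenance)
  yx <- pixel_yx(drop, d[2L])
  list(grid = out,
       dropped = data.frame(pixel = drop, y = yx[, 1L], x = yx[, 2L],
                            missing_fraction = frac[drop]))
}
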