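#' KNN imputation configuration
#'
#' @param k neighbour count: a positive integer, or `"auto"` for the
#'   square-root-of-sample-size heuristic `k = round(sqrt(P))` over the `P`
#'   retained (not fully missing) pixels.
#' @return list of class `knn_config`.
#' @export
knn_config <- function(k = "auto") {
  if (!(identical(k, "auto") || (is.numeric(k) && k >= 1))) {
    stop("k must be a positive integer or \"auto\"", call. = FALSE)
  }
  structure(list(k = k), class = "knn_config")
}

#' Resolve the neighbour count for a given pixel population
#' @param cfg a [knn_config()].
#' @param n_pixels number of retained pixels.
#' @return integer `k`, capped at `n_pixels - 1`.
#' @export
resolve_k <- function(cfg, n_pixels) {
  k <- if (identical(cfg$k, "auto")) round(sqrt(n_pixels)) else as.integer(cfg$k)
  max(1L, min(k, n_pixels - 1L))
}

# Pairwise distances between pixel series over jointly observed bins, scaled
# by sqrt(n_bins / overlap) so sparse overlaps are not spuriously close.
# No overlap -> Inf.
series_distances <- function(m, obs = !is.na(m)) {
  nt <- nrow(m); p <- ncol(m)
  m0 <- ifelse(obs, m, 0)
  overlap <- crossprod(obs * 1)
  sq <- crossprod(m0^2, obs) # sq[i,j] = sum over bins observed in both? no:
  # crossprod(m0^2, obs)[i, j] = sum_t m0[t,i]^2 * obs[t,j] = sum over joint of x_i^2
  cross <- crossprod(m0)      # sum over joint of x_i x_j
  ss <- sq + t(sq) - 2 * cross
  ss[ss < 0] <- 0
  d <- sqrt(ss * nt / pmax(overlap, 1))
  d[overlap == 0] <- Inf
  diag(d) <- Inf
  d
}

#' Spatial KNN imputation of a biweekly grid
#'
#' For each retained pixel, its `k` nearest-neighbour pixels are found once,
#' by Euclidean distance between the full time series over jointly observed
#' bins (overlap-scaled). Each missing cell is then filled with the
#' inverse-distance weighted average of the neighbour values observed at that
#' bin. A neighbour at distance zero short-circuits the weights: its value
#' (the mean, if several) is used directly. Cells where no neighbour is
#' observed stay missing; observed cells are never modified. Previously
#' imputed cells are not used as donors, so the operation is idempotent.
#'
#' @param grid a biweekly [chl_grid()] with sparse pixels already dropped.
#' @param cfg a [knn_config()].
#' @return a [chl_grid()] with provenance `"imputed"` and an updated
#'   per-cell `imputed` mask.
#' @export
knn_impute <- function(grid, cfg = knn_config()) {
  stopifnot(inherits(grid, "chl_grid"), inherits(cfg, "knn_config"))
  m <- as_pixel_matrix(grid)
  eligible <- donor_matrix(grid)
  filled <- matrix(FALSE, nrow(m), ncol(m))
  retained <- which(colSums(!is.na(m)) > 0)
  if (length(retained) < 2) return(grid)
  sub <- m[, retained, drop = FALSE]
  el <- eligible[, retained, drop = FALSE]
  k <- resolve_k(cfg, length(retained))
  d <- series_distances(sub, el)

  out <- sub
  for (j in seq_along(retained)) {
    miss_t <- which(is.na(sub[, j]))
    if (!length(miss_t)) next
    nb <- order(d[, j])[seq_len(k)]
    nd <- d[nb, j]
    for (t in miss_t) {
      x <- sub[t, nb]
      ok <- el[t, nb] & is.finite(nd)
      if (!any(ok)) next
      if (any(ok & nd == 0)) {
        out[t, j] <- mean(x[ok & nd == 0])
      } else {
        w <- 1 / nd[ok]
        out[t, j] <- sum(w * x[ok]) / sum(w)
      }
      filled[t, retained[j]] <- TRUE
    }
  }
  m[, retained] <- out
  dims <- dim(grid$values)
  imp0 <- if (is.null(grid$imputed)) array(FALSE, dims) else grid$imputed
  chl_grid(array(m, dims), grid$dates,
           pixel_size_m = grid$pixel_size_m, provenance = "imputed",
           imputed = imp0 | array(filled, dims))
}

# Neighbour-year climatological fill on one series: each missing entry is the
# mean of donor-eligible values at the same pixel whose dates fall within
# +/- `window` calendar days of the target's day-of-year, in a different
# year. Donor sets are frozen up front (no cascading through fresh fills).
climatology_fill_series <- function(x, dates, window = 14L,
                                    eligible = !is.na(x)) {
  miss <- which(is.na(x))
  if (!length(miss)) return(x)
  doy <- as.numeric(format(dates, "%j"))
  yr <- as.numeric(format(dates, "%Y"))
  out <- x
  for (i in miss) {
    dd <- abs(doy - doy[i])
    dd <- pmin(dd, 365.5 - dd)          # circular day-of-year distance
    donors <- which(dd <= window & yr != yr[i] & eligible)
    if (length(donors)) out[i] <- mean(x[donors])
  }
  out
}

#' Neighbour-year climatological fill
#'
#' Remaining missing cells are filled with the mean of the same pixel's
#' observed values whose bin dates fall within +/-14 calendar days of the
#' target date in any other year. Cells with no donor in any year stay
#' missing. Idempotent; observed values untouched.
#'
#' @param grid a biweekly [chl_grid()].
#' @param window half-width of the day-of-year donor window (days).
#' @return a [chl_grid()] with provenance `"imputed"` and an updated
#'   per-cell `imputed` mask.
#' @export
climatology_fill <- function(grid, window = 14L) {
  stopifnot(inherits(grid, "chl_grid"))
  m <- as_pixel_matrix(grid)
  eligible <- donor_matrix(grid)
  was_na <- is.na(m)
  for (j in which(colSums(!is.na(m)) > 0)) {
    m[, j] <- climatology_fill_series(m[, j], grid$dates, window, eligible[, j])
  }
  dims <- dim(grid$values)
  imp0 <- if (is.null(grid$imputed)) array(FALSE, dims) else grid$imputed
  chl_grid(array(m, dims), grid$dates,
           pixel_size_m = grid$pixel_size_m, provenance = "imputed",
           imputed = imp0 | array(was_na & !is.na(m), dims))
}

#' Two-step gap-filling pipeline
#'
#' Spatial KNN imputation first, then the neighbour-year climatological fill
#' for bins where whole neighbourhoods were missing simultaneously. Returns
#' the filled grid and a conservation report: the initial missing fraction
#' equals the fraction filled at step 1 plus step 2 plus the residual.
#'
#' @param grid a biweekly [chl_grid()], sparse pixels dropped.
#' @param cfg a [knn_config()].
#' @return list `grid` (filled) and `report` (fractions per step; also the
#'   count of cells still missing, which triggers a warning when positive on
#'   retained pixels).
#' @export
fill_pipeline <- function(grid, cfg = knn_config()) {
  retained <- missing_fraction(grid) < 1
  frac_missing <- function(g) {
    m <- as_pixel_matrix(g)[, retained, drop = FALSE]
    mean(is.na(m))
  }
  f0 <- frac_missing(grid)
  g1 <- knn_impute(grid, cfg)
  f1 <- frac_missing(g1)
  g2 <- climatology_fill(g1)
  f2 <- frac_missing(g2)
  report <- list(
    initial_missing = f0,
    filled_knn = f0 - f1,
    filled_climatology = f1 - f2,
    residual_missing = f2,
    n_residual_cells = sum(is.na(as_pixel_matrix(g2)[, retained, drop = FALSE]))
  )
  if (report$n_residual_cells > 0) {
    warning(sprintf("%d cells remain missing after both fill steps",
                    report$n_residual_cells), call. = FALSE)
  }
  list(grid = g2, report = report)
}
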