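#' Gridded chlorophyll-a time series
#'
#' The package's central container: a dense `[time, y, x]` array of Chl-a
#' concentrations (ug/L) on a regular pixel grid, with `NA` marking missing
#' observations (cloud, swath gaps, dropped pixels). Carries the bin-start
#' dates of its time axis, the pixel size, and a provenance tag recording how
#' far through the processing chain the values have travelled.
#'
#' @param values numeric 3-d array, dimensions `[time, y, x]`; `NA` = missing.
#' @param dates `Date` vector of length `dim(values)[1]`; daily dates or
#'   14-day bin starts.
#' @param pixel_size_m pixel edge length in metres.
#' @param provenance one of `"raw"`, `"composited"`, `"imputed"`, `"truth"`.
#' @param imputed optional logical array, same shape as `values`, marking
#'   cells whose values were filled rather than observed. Imputed cells are
#'   never used as donors by the gap-filling routines, which keeps both fill
#'   steps idempotent and stops imputation error from propagating.
#' @return an object of class `chl_grid`.
#' @export
chl_grid <- function(values, dates,
                     pixel_size_m = 1000,
                     provenance = c("raw", "composited", "imputed", "truth"),
                     imputed = NULL) {
  provenance <- match.arg(provenance)
  if (!is.numeric(values) || length(dim(values)) != 3L) {
    stop("`values` must be a numeric 3-d array [time, y, x]", call. = FALSE)
  }
  dates <- as.Date(dates)
  if (length(dates) != dim(values)[1L]) {
    stop("length(dates) must equal the time dimension of `values`", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("Chl-a concentrations must be non-negative where observed", call. = FALSE)
  }
  if (!is.null(imputed) && !identical(dim(imputed), dim(values))) {
    stop("`imputed` must match the shape of `values`", call. = FALSE)
  }
  structure(
    list(values = values, dates = dates,
         pixel_size_m = pixel_size_m, provenance = provenance,
         imputed = imputed),
    class = "chl_grid"
  )
}

# Logical time-by-pixel matrix of donor-eligible cells: observed and not
# previously imputed.
donor_matrix <- function(grid) {
  d <- dim(grid$values)
  obs <- !is.na(matrix(grid$values, d[1L], d[2L] * d[3L]))
  if (!is.null(grid$imputed)) {
    obs & !matrix(grid$imputed, d[1L], d[2L] * d[3L])
  } else obs
}

#' @export
print.chl_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<chl_grid> %d bins x %d x %d pixels (%s), %s .. %s\n",
              d[1], d[2], d[3], x$provenance,
              format(min(x$dates)), format(max(x$dates))))
  cat(sprintf("  missing: %.1f%% of cells; pixel size %g m\n",
              100 * mean(is.na(x$values)), x$pixel_size_m))
  invisible(x)
}

#' @export
dim.chl_grid <- function(x) dim(x$values)

#' Flatten a grid to a time-by-pixel matrix
#'
#' Pixels are enumerated column-major in `(y, x)`: linear pixel index
#' `(x - 1) * ny + y`, the same convention [pixel_yx()] inverts.
#'
#' @param grid a [chl_grid()].
#' @return numeric matrix, `n_time` rows by `ny * nx` columns.
#' @export
as_pixel_matrix <- function(grid) {
  d <- dim(grid$values)
  matrix(grid$values, nrow = d[1L], ncol = d[2L] * d[3L])
}

#' Recover (y, x) coordinates from linear pixel indices
#' @param idx integer linear pixel indices.
#' @param ny number of grid rows.
#' @return two-column integer matrix `(y, x)`.
#' @export
pixel_yx <- function(idx, ny) {
  cbind(y = (idx - 1L) %% ny + 1L, x = (idx - 1L) %/% ny + 1L)
}

#' Spatially averaged series over observed pixels
#'
#' Unweighted mean over all pixels observed at each time step; the series the
#' wavelet analysis consumes once the grid is gap filled.
#'
#' @param grid a [chl_grid()].
#' @return numeric vector along the grid's time axis.
#' @export
spatial_mean <- function(grid) {
  rowMeans(as_pixel_matrix(grid), na.rm = TRUE)
}

#' Per-pixel missing fraction
#' @param grid a [chl_grid()].
#' @return numeric vector over linear pixel indices, in `[0, 1]`.
#' @export
missing_fraction <- function(grid) {
  colMeans(is.na(as_pixel_matrix(grid)))
}

#' 14-day analysis calendar
#'
#' Bin-start dates on a fixed 14-day stride. The study default spans
#' 5 Jan 2002 to 21 Mar 2012: 267 biweekly bins, where a bin is kept when its
#' *start* falls on or before the end date.
#'
#' @param start,end first bin start and series end date.
#' @param step bin length in days.
#' @return `Date` vector of bin starts.
#' @export
biweekly_calendar <- function(start = as.Date("2002-01-05"),
                              end = as.Date("2012-03-21"),
                              step = 14L) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("empty time span", call. = FALSE)
  seq(start, end, by = step)
}

#' Season of each biweekly bin
#'
#' Meteorological seasons by the month of the bin midpoint (start + 7 days):
#' MAM spring, JJA summer, SON fall, DJF winter. Bins straddle month
#' boundaries, so the midpoint, not the start, decides.
#'
#' @param dates bin-start `Date`s.
#' @return factor with levels `spring`, `summer`, `fall`, `winter`.
#' @export
season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates) + 7L, "%m"))
  s <- ifelse(m %in% 3:5, "spring",
       ifelse(m %in% 6:8, "summer",
       ifelse(m %in% 9:11, "fall", "winter")))
  factor(s, levels = c("spring", "summer", "fall", "winter"))
}

#' Write / read a grid as long-format CSV
#'
#' Plain-text interchange for gridded series: columns `date, y, x, chl`, one
#' row per cell, empty `chl` for missing. Round-trips through [read_chl_csv()].
#'
#' @param grid a [chl_grid()].
#' @param path file path.
#' @return `path`, invisibly (`write_chl_csv`); a [chl_grid()] (`read_chl_csv`).
#' @export
write_chl_csv <- function(grid, path) {
  d <- dim(grid$values)
  df <- data.frame(
    date = rep(format(grid$dates), times = d[2L] * d[3L]),
    y = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    x = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    chl = as.vector(grid$values)
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_chl_csv
#' @param pixel_size_m,provenance metadata for the reconstructed grid.
#' @export
read_chl_csv <- function(path, pixel_size_m = 1000, provenance = "raw") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dates <- sort(unique(as.Date(df$date)))
  ny <- max(df$y); nx <- max(df$x)
  vals <- array(NA_real_, c(length(dates), ny, nx))
  ti <- match(as.Date(df$date), dates)
  vals[cbind(ti, df$y, df$x)] <- df$chl
  chl_grid(vals, dates, pixel_size_m = pixel_size_m, provenance = provenance)
}
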