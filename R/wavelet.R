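#' Morlet mother wavelet
#'
#' `psi0(eta) = pi^(-1/4) * exp(i * omega0 * eta) * exp(-eta^2 / 2)`.
#'
#' @param eta non-dimensional time.
#' @param omega0 non-dimensional frequency; >= 5 for admissibility
#'   (default 6, the standard choice that makes Fourier period ~ 1.03 scale).
#' @return complex vector.
#' @export
morlet <- function(eta, omega0 = 6) {
  if (omega0 < 5) stop("omega0 must be >= 5 for admissibility", call. = FALSE)
  pi^(-0.25) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
}

#' Fourier period per unit Morlet scale
#' @param omega0 non-dimensional frequency.
#' @return the factor `4 * pi / (omega0 + sqrt(2 + omega0^2))` (~1.033 at 6).
#' @export
fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Continuous wavelet transform of an evenly sampled series
#'
#' Morlet CWT on a dyadic scale set `s_j = s0 * 2^(j * dj)`. The default
#' route convolves in the frequency domain after zero-padding (the series
#' mean is removed first); `method = "direct"` computes the time-domain
#' convolution sum and serves as the independent numerical cross-check. Both
#' use the energy normalisation `sqrt(dt / s)` so power is comparable across
#' scales.
#'
#' @param x numeric series, gap-free, length >= 16.
#' @param dt sampling period (time units of choice; years for the biweekly
#'   Chl-a series: 14/365.25).
#' @param dj scale resolution in octaves (default 0.25).
#' @param s0 smallest scale (default `2 * dt`).
#' @param jtot number of scales minus one; default spans up to `N * dt / 2`.
#' @param omega0 Morlet non-dimensional frequency.
#' @param method `"fft"` or `"direct"`.
#' @return object of class `wavelet_result`: complex `coefs` (scale x time),
#'   `power`, `global` spectrum (time-mean power per scale), `scales`,
#'   `periods`, `coi` (maximum trustworthy period per time step), `dt`,
#'   `omega0`, `n`.
#' @export
cwt <- function(x, dt, dj = 0.25, s0 = 2 * dt, jtot = NULL, omega0 = 6,
                method = c("fft", "direct")) {
  method <- match.arg(method)
  if (anyNA(x)) {
    stop("series contains gaps; run the gap-filling pipeline first", call. = FALSE)
  }
  n <- length(x)
  if (n < 16) stop("series too short for wavelet analysis (need >= 16)", call. = FALSE)
  if (is.null(jtot)) jtot <- floor(log2(n * dt / (2 * s0)) / dj)
  scales <- s0 * 2^(dj * (0:jtot))
  periods <- fourier_factor(omega0) * scales
  xd <- x - mean(x)

  coefs <- matrix(0i, length(scales), n)
  if (method == "fft") {
    # pad well beyond the next power of two: the Morlet tails at the largest
    # scales wrap around a minimally padded circle and would break agreement
    # with the direct convolution
    npad <- 2^(ceiling(log2(n)) + 2L)
    xf <- stats::fft(c(xd, rep(0, npad - n)))
    k <- 0:(npad - 1)
    omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                    -2 * pi * (npad - k) / (npad * dt))
    for (j in seq_along(scales)) {
      s <- scales[j]
      # Poisson summation: the spectrum of the dt-sampled Morlet is the sum
      # of closed-form images shifted by the sampling frequency; the first
      # image carries the aliased mass that matters at the smallest scales
      g <- function(u) exp(-((u - omega0)^2) / 2)
      psihat <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
        (g(s * omega) * (omega > 0) + g(s * (omega + 2 * pi / dt)))
      w <- stats::fft(xf * psihat, inverse = TRUE) / npad
      coefs[j, ] <- w[1:n]
    }
  } else {
    idx <- seq_len(n)
    for (j in seq_along(scales)) {
      s <- scales[j]
      for (i in idx) {
        eta <- (idx - i) * dt / s
        coefs[j, i] <- sum(xd * Conj(morlet(eta, omega0))) * sqrt(dt / s)
      }
    }
  }
  power <- Mod(coefs)^2
  dist_edge <- pmin(0:(n - 1), (n - 1):0)
  coi <- fourier_factor(omega0) / sqrt(2) * dt * pmax(dist_edge, 1e-8)
  structure(
    list(coefs = coefs, power = power, global = rowMeans(power),
         scales = scales, periods = periods, coi = coi,
         dt = dt, dj = dj, omega0 = omega0, n = n),
    class = "wavelet_result"
  )
}

#' @export
print.wavelet_result <- function(x, ...) {
  cat(sprintf("<wavelet_result> N = %d, dt = %g, %d scales (periods %.3g .. %.3g)\n",
              x$n, x$dt, length(x$scales), min(x$periods), max(x$periods)))
  invisible(x)
}

#' Red-noise (AR(1)) significance thresholds
#'
#' The null is that the series is red noise: its lag-1 autocorrelation
#' `alpha` is estimated from the data and the theoretical AR(1) spectrum
#' `P = (1 - alpha^2) / (1 + alpha^2 - 2 * alpha * cos(2 * pi * dt / period))`
#' is evaluated at each wavelet scale's equivalent Fourier period. Local
#' wavelet power is chi-squared with two degrees of freedom about that mean,
#' so the pointwise threshold per scale is
#' `variance * P * qchisq(level, 2) / 2`.
#'
#' @param result a [cwt()] result.
#' @param x the analysed series (for variance and lag-1 autocorrelation).
#' @param level confidence level (default 0.95).
#' @param alpha optional known AR(1) coefficient; estimated from `x` when
#'   `NULL`. Estimates >= 1 are clipped to 0.999 with a warning.
#' @return numeric vector of thresholds, one per scale, with the estimated
#'   `alpha` attached as an attribute.
#' @export
rednoise_significance <- function(result, x, level = 0.95, alpha = NULL) {
  stopifnot(inherits(result, "wavelet_result"))
  if (is.null(alpha)) {
    n <- length(x)
    alpha <- stats::cor(x[-1], x[-n])
  }
  if (alpha >= 1) {
    warning("lag-1 autocorrelation estimate >= 1; clipped to 0.999", call. = FALSE)
    alpha <- 0.999
  }
  if (alpha < 0) alpha <- 0
  pk <- (1 - alpha^2) /
    (1 + alpha^2 - 2 * alpha * cos(2 * pi * result$dt / result$periods))
  thr <- stats::var(x) * pk * stats::qchisq(level, df = 2) / 2
  attr(thr, "alpha") <- alpha
  thr
}

#' Dominant periods of the global wavelet spectrum
#'
#' Fourier periods of the `n_peaks` largest *local* maxima of the global
#' spectrum, strongest first. When the analysed series is supplied, each peak
#' is additionally flagged significant if the global spectrum there exceeds
#' the pointwise red-noise threshold (a conservative reference for the
#' time-averaged spectrum).
#'
#' @param result a [cwt()] result.
#' @param n_peaks how many peaks to report.
#' @param x optional analysed series, enables the significance flag.
#' @param level confidence level for the flag.
#' @param interpolate parabolic peak interpolation on the log-period grid:
#'   the dyadic scale set quantises peak periods to `2^(dj/2)` at worst;
#'   fitting a parabola through the peak and its two neighbours recovers the
#'   sub-grid location (never displacing it by more than one scale step).
#' @return data.frame with `period`, `power`, and (if `x` given)
#'   `significant`; fewer rows than `n_peaks` if the spectrum has fewer
#'   local maxima.
#' @export
dominant_periods <- function(result, n_peaks = 2, x = NULL, level = 0.95,
                             interpolate = TRUE) {
  stopifnot(inherits(result, "wavelet_result"))
  g <- result$global
  m <- length(g)
  peaks <- which(g[2:(m - 1)] > g[1:(m - 2)] & g[2:(m - 1)] > g[3:m]) + 1L
  peaks <- peaks[order(g[peaks], decreasing = TRUE)]
  peaks <- utils::head(peaks, n_peaks)
  period <- result$periods[peaks]
  if (interpolate && length(peaks)) {
    delta <- vapply(peaks, function(i) {
      den <- g[i - 1] - 2 * g[i] + g[i + 1]
      if (den >= 0) return(0)
      max(-1, min(1, 0.5 * (g[i - 1] - g[i + 1]) / den))
    }, numeric(1))
    period <- period * 2^(delta * result$dj)
  }
  out <- data.frame(period = period, power = g[peaks])
  if (!is.null(x) && nrow(out)) {
    thr <- rednoise_significance(result, x, level)
    out$significant <- g[peaks] > thr[peaks]
  }
  out
}
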