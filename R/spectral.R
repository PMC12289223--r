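#' Resample a beat series onto a uniform grid
#'
#' Beat-level values (placed at their R-peak times) are linearly
#' interpolated onto an evenly sampled grid (default 4 Hz) and, when
#' requested, a first-order (linear) trend is removed. Disqualified beats
#' are assumed already dropped by the caller; gaps between the remaining
#' beats up to \code{cfg$max_gap_s} are bridged by the interpolation, longer
#' gaps reject the window.
#'
#' @param t beat times, s (sorted; NA values dropped along with their
#'   times).
#' @param v beat values.
#' @param cfg a [spectralConfig()].
#' @param window numeric(2) analysis window (start, end) s; defaults to the
#'   span of \code{t}.
#' @param detrend apply the configured detrend (TRUE by default).
#' @return On success, list \code{ok = TRUE}, \code{t} (grid), \code{x}
#'   (values). On rejection, list \code{ok = FALSE} and \code{reason}
#'   (\code{"too_short"} or \code{"gap"}).
#' @export
toUniformSeries <- function(t, v, cfg = spectralConfig(), window = NULL,
                            detrend = TRUE) {
  keep <- !is.na(v) & !is.na(t)
  t <- t[keep]; v <- v[keep]
  if (length(t) < 2L) return(list(ok = FALSE, reason = "too_short"))
  if (is.null(window)) window <- range(t)
  inw <- t >= window[1] & t <= window[2]
  tw <- t[inw]
  if (length(tw) < 2L) return(list(ok = FALSE, reason = "too_short"))
  gaps <- c(tw[1] - window[1], diff(tw), window[2] - tw[length(tw)])
  if (max(gaps) > cfg$max_gap_s) return(list(ok = FALSE, reason = "gap"))
  grid <- seq(window[1], window[2], by = 1 / cfg$resample_fs)
  if (length(grid) < cfg$segment_len)
    return(list(ok = FALSE, reason = "too_short"))
  x <- stats::approx(t, v, xout = grid, rule = 2)$y
  if (detrend && cfg$detrend_order >= 1L) {
    x <- stats::residuals(stats::lm.fit(cbind(1, seq_along(x)), x))
  } else if (detrend) {
    x <- x - mean(x)
  }
  list(ok = TRUE, t = grid, x = as.numeric(x))
}

# periodic Hann taper
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Welch transfer-function and coherence estimate
#'
#' Estimates one-sided auto-spectra Pxx, Pyy, the complex cross-spectrum
#' Pxy, the transfer function H(f) = Pxy / Pxx, and the magnitude-squared
#' coherence msc = |Pxy|^2 / (Pxx Pyy) between a uniformly sampled input
#' \code{x} (SBP or a surrogate feature) and output \code{y} (RR). Spectra
#' are Welch averages over \code{segment_len}-sample segments (default 120
#' = 30 s at 4 Hz) with 50% overlap, per-segment mean removal, a periodic
#' Hann taper and density scaling.
#'
#' @param x,y equal-length uniform series sampled at \code{fs}.
#' @param cfg a [spectralConfig()].
#' @param fs sampling rate, Hz (defaults to \code{cfg$resample_fs}).
#' @return a [TransferEstimate-class].
#' @export
estimateTransfer <- function(x, y, cfg = spectralConfig(),
                             fs = cfg$resample_fs) {
  if (length(x) != length(y))
    stop("input and output series must have equal length", call. = FALSE)
  n <- length(x)
  L <- cfg$segment_len
  if (n < L)
    stop("series shorter than one Welch segment (", L, " samples)",
         call. = FALSE)
  step <- max(1L, as.integer(round(L * (1 - cfg$overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- .hann(L)
  scale <- 1 / (fs * sum(w^2))
  nb <- L %/% 2L + 1L
  Sxx <- Syy <- numeric(nb)
  Sxy <- complex(nb)
  for (s in starts) {
    xs <- x[s:(s + L - 1L)]; ys <- y[s:(s + L - 1L)]
    X <- stats::fft((xs - mean(xs)) * w)[seq_len(nb)]
    Y <- stats::fft((ys - mean(ys)) * w)[seq_len(nb)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Conj(X) * Y
  }
  K <- length(starts)
  one_sided <- rep(2, nb)
  one_sided[1] <- 1
  if (L %% 2L == 0L) one_sided[nb] <- 1
  Pxx <- Sxx / K * scale * one_sided
  Pyy <- Syy / K * scale * one_sided
  Pxy <- Sxy / K * scale * one_sided
  H <- ifelse(Pxx > 0, Pxy / Pxx, 0 + 0i)
  denom <- Pxx * Pyy
  msc <- ifelse(denom > 0, pmin(Mod(Pxy)^2 / denom, 1), 0)
  new("TransferEstimate",
      f = (seq_len(nb) - 1L) * fs / L,
      Pxx = Pxx, Pyy = Pyy, Pxy = Pxy, H = H, msc = as.numeric(msc),
      nSegments = K, fs = fs, config = unclass(cfg))
}

#' Band-averaged BRS index from a transfer estimate
#'
#' The BRS value is the mean transfer gain |H(f)| over the bins inside the
#' LF band (0.04-0.15 Hz); the window qualifies when the mean
#' magnitude-squared coherence over the same bins reaches the configured
#' threshold (0.14). The magnitude makes inversely coupled surrogates
#' (PAT, RDRatio) yield positive indices; phase stays available on the
#' estimate.
#'
#' @param est a [TransferEstimate-class] whose grid covers the LF band.
#' @param cfg a [spectralConfig()].
#' @param inputFeature,modality labels carried into the result.
#' @param window analysis window (start, end) s, for bookkeeping.
#' @return a [BRSIndex-class].
#' @export
brsIndex <- function(est, cfg = spectralConfig(), inputFeature = "SBP",
                     modality = "ABP", window = c(NA_real_, NA_real_)) {
  stopifnot(is(est, "TransferEstimate"))
  sel <- est@f >= cfg$lf_band[1] - 1e-9 & est@f <= cfg$lf_band[2] + 1e-9
  sel <- sel & est@f > 0
  if (!any(sel))
    stop("band_unresolved: no frequency bins inside [",
         cfg$lf_band[1], ", ", cfg$lf_band[2], "] Hz", call. = FALSE)
  mlc <- mean(est@msc[sel])
  new("BRSIndex",
      value = mean(Mod(est@H[sel])),
      meanLFCoherence = mlc,
      qualified = mlc >= cfg$coherence_threshold,
      window = as.numeric(window),
      inputFeature = inputFeature, modality = modality)
}

#' HRV band power from a uniform RR series
#'
#' Integrates the Welch auto-spectrum of the (detrended) RR series over a
#' frequency band: LF (0.04-0.15 Hz, baroreflex/Mayer-wave activity around
#' 0.1 Hz) or HF (0.15-0.40 Hz, respiratory activity around 0.25 Hz).
#'
#' @param rr uniform RR series, ms, sampled at \code{fs}.
#' @param band \code{"lf"}, \code{"hf"}, or numeric(2) band edges in Hz.
#' @param cfg a [spectralConfig()].
#' @param fs sampling rate, Hz.
#' @return band power in ms^2.
#' @export
hrvBandPower <- function(rr, band = "lf", cfg = spectralConfig(),
                         fs = cfg$resample_fs) {
  if (is.character(band))
    band <- switch(match.arg(band, c("lf", "hf")),
                   lf = cfg$lf_band, hf = cfg$hf_band)
  est <- estimateTransfer(rr, rr, cfg, fs = fs)
  sel <- est@f >= band[1] - 1e-9 & est@f <= band[2] + 1e-9 & est@f > 0
  df <- fs / cfg$segment_len
  sum(est@Pxx[sel]) * df
}
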