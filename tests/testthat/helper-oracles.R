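# Independent oracles and waveform fixtures used across the suite.

# Brute-force Welch cross-spectra via explicit DFT sums (no fft), same
# estimator definition: Hann taper, per-segment mean removal, density
# scaling, one-sided.
oracleWelch <- function(x, y, L = 120L, overlap = 0.5, fs = 4) {
  step <- as.integer(round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  k <- 0:(L - 1L)
  w <- 0.5 - 0.5 * cos(2 * pi * k / L)
  nb <- L %/% 2L + 1L
  dft <- function(v) {
    vapply(0:(nb - 1L), function(f)
      sum(v * exp(-2i * pi * f * k / L)), complex(1))
  }
  Sxx <- Syy <- numeric(nb); Sxy <- complex(nb)
  for (s in starts) {
    xs <- x[s:(s + L - 1L)]; ys <- y[s:(s + L - 1L)]
    X <- dft((xs - mean(xs)) * w)
    Y <- dft((ys - mean(ys)) * w)
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Conj(X) * Y
  }
  K <- length(starts)
  scale <- 1 / (fs * sum(w^2))
  os <- rep(2, nb); os[1] <- 1
  if (L %% 2L == 0L) os[nb] <- 1
  Pxx <- Sxx / K * scale * os
  Pyy <- Syy / K * scale * os
  Pxy <- Sxy / K * scale * os
  list(f = (0:(nb - 1L)) * fs / L, Pxx = Pxx, Pyy = Pyy, Pxy = Pxy,
       gain = Mod(Pxy / Pxx), msc = Mod(Pxy)^2 / (Pxx * Pyy))
}

# Dense-grid threshold scan for the rise/decay ratio of a continuous pulse
# shape fun(t) on [0, dur]: 10%-70% crossings located on an oversampled
# grid by nearest-sample scanning.
oracleRDRatio <- function(fun, dur, oversample_fs = 24000) {
  tt <- seq(0, dur, by = 1 / oversample_fs)
  v <- fun(tt)
  pk <- which.max(v)
  amp <- v[pk] - v[1]
  lo <- v[1] + 0.1 * amp
  hi <- v[1] + 0.7 * amp
  r10 <- tt[which(v[1:pk] >= lo)[1]]
  r70 <- tt[which(v[1:pk] >= hi)[1]]
  post <- v[pk:length(v)]
  d70 <- tt[pk + which(post <= hi)[1] - 1L]
  d10 <- tt[pk + which(post <= lo)[1] - 1L]
  (r70 - r10) / (d10 - d70)
}

# Two-sided-Gaussian pulse: rise width sr, decay width sd_, peak at mu.
asymGaussPulse <- function(tt, mu, sr, sd_, amp = 1) {
  s <- ifelse(tt <= mu, sr, sd_)
  amp * exp(-(tt - mu)^2 / (2 * s^2))
}

# A train of identical pulses at the given foot times, sampled at fs over
# [0, dur): returns the sample vector.
pulseTrain <- function(foot_times, fs, dur, sr = 0.06, sd_ = 0.09,
                       amp = 1) {
  n <- ceiling(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  sig <- numeric(n)
  for (ft in foot_times) {
    mu <- ft + 2.5 * sr
    sig <- sig + asymGaussPulse(tt, mu, sr, sd_, amp)
  }
  sig
}

# Synthetic ECG: Gaussian QRS at the given times.
syntheticECG <- function(r_times, fs, dur, amp = 1) {
  n <- ceiling(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  sig <- numeric(n)
  for (rt in r_times) sig <- sig + amp * exp(-(tt - rt)^2 / (2 * 0.012^2))
  sig
}

# Beat table holding one hour of regular beats for quality tests.
regularBeats <- function(dur = 3600, rr_ms = 1000, pat_ms = 250,
                         rdr = 0.8) {
  t <- seq(0, dur, by = rr_ms / 1000)
  n <- length(t)
  asBeatTable(t, RR = rep(rr_ms, n), PAT = rep(pat_ms, n),
              RDRatio = rep(rdr, n))
}
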