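#' Simulate beat-to-beat hemodynamics with known baroreflex gain
#'
#' Open-loop (feedforward) generator: SBP is a circadian baseline plus a
#' Mayer-wave LF sinusoid, a respiratory HF sinusoid and broadband
#' beat-to-beat variability; RR follows the full SBP deviation from the
#' local baseline through the reflex gain with a configurable beat delay,
#' so the true LF transfer gain equals \code{gain_ms_per_mmHg} analytically.
#' PAT and the rise/decay ratio are linear in SBP with negative slopes.
#' Beat times accumulate from the observed RR series.
#'
#' The pre-noise (\code{true*}) series satisfy the couplings exactly;
#' observed series add the configured measurement noise. Identical configs
#' (including \code{seed}) give identical output.
#'
#' @param cfg a [simConfig()].
#' @return a [SimGroundTruth-class].
#' @examples
#' gt <- simulateBeats(simConfig(duration_s = 60, rr_noise_sd_ms = 0))
#' nBeats(gt)
#' @export
simulateBeats <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  nmax <- ceiling(cfg$duration_s / 0.3) + 10L
  t <- sbp <- rr <- pat <- rdr <- numeric(nmax)
  tS <- tR <- tP <- tD <- gA <- numeric(nmax)
  dev <- numeric(nmax)
  nzS <- stats::rnorm(nmax, 0, cfg$sbp_noise_sd)
  nzR <- stats::rnorm(nmax, 0, cfg$rr_noise_sd_ms)
  nzP <- stats::rnorm(nmax, 0, cfg$pat_noise_sd_ms)
  nzD <- stats::rnorm(nmax, 0, cfg$rdr_noise_sd)
  circ <- .circadianLookup(cfg$circadian)
  d <- cfg$reflex_delay_beats
  tn <- 0; n <- 0L
  while (tn < cfg$duration_s && n < nmax) {
    n <- n + 1L
    cm <- circ(tn)
    base <- cfg$baseline_sbp * cm[["sbp_mult"]]
    dev[n] <- cfg$lf_amp * sin(2 * pi * cfg$lf_freq * tn) +
      cfg$hf_amp * sin(2 * pi * cfg$hf_freq * tn) + nzS[n]
    tS[n] <- base + dev[n]
    gA[n] <- cfg$gain_ms_per_mmHg * cm[["gain_mult"]]
    lag <- dev[max(1L, n - d)]
    tR[n] <- cfg$rr_baseline_ms * cm[["rr_mult"]] + gA[n] * lag
    tP[n] <- cfg$pat_intercept_ms + cfg$pat_slope_ms_per_mmHg * tS[n]
    tD[n] <- cfg$rdr_intercept + cfg$rdr_slope_per_mmHg * tS[n]
    sbp[n] <- tS[n]
    rr[n] <- tR[n] + nzR[n]
    pat[n] <- tP[n] + nzP[n]
    rdr[n] <- tD[n] + nzD[n]
    if (rr[n] <= 300 || tR[n] <= 300)
      stop("nonphysiologic: configuration yields RR <= 300 ms",
           call. = FALSE)
    t[n] <- tn
    tn <- tn + rr[n] / 1000
  }
  idx <- seq_len(n)
  new("SimGroundTruth", t = t[idx],
      sbp = sbp[idx], rr = rr[idx], pat = pat[idx], rdr = rdr[idx],
      trueSbp = tS[idx], trueRr = tR[idx], truePat = tP[idx],
      trueRdr = tD[idx], trueGain = gA[idx],
      events = .scheduleEvents(cfg), config = unclass(cfg))
}

.circadianLookup <- function(circadian) {
  if (is.null(circadian) || !nrow(circadian)) {
    return(function(t) c(sbp_mult = 1, gain_mult = 1, rr_mult = 1))
  }
  for (col in c("sbp_mult", "gain_mult", "rr_mult"))
    if (is.null(circadian[[col]])) circadian[[col]] <- 1
  function(t) {
    i <- which(circadian$start <= t & t < circadian$end)
    if (!length(i)) return(c(sbp_mult = 1, gain_mult = 1, rr_mult = 1))
    i <- i[1L]
    c(sbp_mult = circadian$sbp_mult[i], gain_mult = circadian$gain_mult[i],
      rr_mult = circadian$rr_mult[i])
  }
}

.scheduleEvents <- function(cfg) {
  ks <- character(); lb <- character(); st <- en <- numeric()
  if (!is.null(cfg$cuff_schedule) && length(cfg$cuff_schedule)) {
    ks <- c(ks, rep("cuff_inflation", length(cfg$cuff_schedule)))
    lb <- c(lb, rep("cuff", length(cfg$cuff_schedule)))
    st <- c(st, cfg$cuff_schedule)
    en <- c(en, cfg$cuff_schedule + 30)
  }
  if (!is.null(cfg$artifact_schedule) && nrow(cfg$artifact_schedule %||% data.frame())) {
    a <- cfg$artifact_schedule
    ks <- c(ks, rep("activity", nrow(a)))
    lb <- c(lb, rep("artifact", nrow(a)))
    st <- c(st, a$start); en <- c(en, a$end)
  }
  if (!is.null(cfg$circadian) && !is.null(cfg$circadian$label)) {
    cc <- cfg$circadian[nzchar(cfg$circadian$label), , drop = FALSE]
    if (nrow(cc)) {
      ks <- c(ks, rep("activity", nrow(cc)))
      lb <- c(lb, cc$label); st <- c(st, cc$start); en <- c(en, cc$end)
    }
  }
  eventList(ks, lb, st, en)
}

# rise/decay geometry of the piecewise-Gaussian pulse lobe: the 10-70%
# crossing separation on either limb is 1.3014 sigma, so sigma_r/sigma_d
# realizes the rise/decay ratio exactly (dicrotic wave placed clear of the
# 10% crossing).
.RD_CONST <- sqrt(2 * log(10)) - sqrt(2 * log(10 / 7))

#' Render waveforms from simulated beats
#'
#' Produces a [MultiChannelRecord-class] whose feature extraction inverts
#' the generator: ECG as Gaussian QRS complexes (plus a small T wave) at
#' the beat times; pulse channels as piecewise-Gaussian pulses whose
#' upstroke (first-derivative maximum) falls at R + PAT, whose foot-to-peak
#' amplitude tracks SBP, and whose rise/decay widths realize the beat's
#' rise/decay ratio (width ratio = RDRatio exactly). A small dicrotic wave
#' is added past the 10% decay crossing. Measurement noise, artifact
#' bursts (pulse channels) and cuff-occlusion attenuation are applied per
#' schedule.
#'
#' @param gt a [SimGroundTruth-class].
#' @param cfg the [simConfig()] used to build \code{gt}.
#' @param channels subset of \code{c("ECG", "PPG", "ABP", "VCP")}.
#' @param noise add measurement noise / artifacts (FALSE gives a noiseless
#'   rendering for recovery checks).
#' @return a [MultiChannelRecord-class].
#' @export
renderSignals <- function(gt, cfg = NULL,
                          channels = c("ECG", "PPG"), noise = TRUE) {
  stopifnot(is(gt, "SimGroundTruth"))
  cfg <- cfg %||% structure(gt@config, class = c("SimConfig", "list"))
  if (cfg$fs < 60)
    stop("fs below 60 Hz cannot resolve pulse morphology", call. = FALSE)
  set.seed(cfg$seed + 1L)
  fs <- cfg$fs
  n <- ceiling(cfg$duration_s * fs) + 1L
  out <- list(); units <- character(); roles <- character()
  sigma_r <- 0.06                      # systolic rise width, s
  addLobe <- function(sig, mu, sd, amp) {
    lo <- max(1L, floor((mu - 4.5 * sd) * fs) + 1L)
    hi <- min(n, ceiling((mu + 4.5 * sd) * fs) + 1L)
    if (hi <= lo) return(sig)
    tt <- (lo:hi - 1L) / fs
    sig[lo:hi] <- sig[lo:hi] + amp * exp(-(tt - mu)^2 / (2 * sd^2))
    sig
  }
  cuffAtten <- function(t) {
    att <- rep(1, length(t))
    if (!is.null(cfg$cuff_schedule))
      for (s in cfg$cuff_schedule) att[t >= s & t <= s + 30] <- 0.15
    att
  }
  for (ch in match.arg(channels, c("ECG", "PPG", "ABP", "VCP"),
                       several.ok = TRUE)) {
    if (ch == "ECG") {
      sig <- numeric(n)
      for (k in seq_along(gt@t)) {
        sig <- addLobe(sig, gt@t[k], 0.012, 1)
        sig <- addLobe(sig, gt@t[k] + 0.25, 0.05, 0.15)
      }
      units[ch] <- "mV"
    } else {
      pressure <- ch %in% c("ABP", "VCP")
      sig <- if (pressure) rep(cfg$dbp_offset_mmHg, n) else numeric(n)
      att <- cuffAtten(gt@t)
      for (k in seq_along(gt@t)) {
        sd_r <- sigma_r
        sd_d <- sd_r / max(gt@rdr[k], 0.05)
        mu <- gt@t[k] + gt@pat[k] / 1000 + sd_r
        amp <- if (pressure) (gt@sbp[k] - cfg$dbp_offset_mmHg)
               else gt@sbp[k] / 100
        amp <- amp * att[k]
        # piecewise-Gaussian main lobe: rise width sd_r, decay width sd_d
        lo <- max(1L, floor((mu - 4.5 * sd_r) * fs) + 1L)
        hi <- min(n, ceiling((mu + 4.5 * sd_d) * fs) + 1L)
        if (hi > lo) {
          tt <- (lo:hi - 1L) / fs
          sd2 <- ifelse(tt <= mu, sd_r, sd_d)
          sig[lo:hi] <- sig[lo:hi] + amp * exp(-(tt - mu)^2 / (2 * sd2^2))
        }
        if (cfg$dicrotic_amp > 0)
          sig <- addLobe(sig, mu + 3.4 * sd_d, 0.25 * sd_d,
                         cfg$dicrotic_amp * amp)
      }
      units[ch] <- if (pressure) "mmHg" else "au"
    }
    roles[ch] <- ch
    if (noise) {
      nz <- cfg$measurement_noise_sd
      sdn <- if (!is.null(names(nz)) && ch %in% names(nz)) nz[[ch]]
             else if (length(nz)) nz[[1]] else 0
      if (sdn > 0) sig <- sig + stats::rnorm(n, 0, sdn)
      if (ch != "ECG" && !is.null(cfg$artifact_schedule) &&
          nrow(cfg$artifact_schedule %||% data.frame())) {
        a <- cfg$artifact_schedule
        tgrid <- (seq_len(n) - 1L) / fs
        for (i in seq_len(nrow(a))) {
          sel <- tgrid >= a$start[i] & tgrid <= a$end[i]
          amp5 <- 5 * stats::sd(sig)
          sig[sel] <- sig[sel] + stats::rnorm(sum(sel), 0, amp5)
        }
      }
    }
    out[[ch]] <- sig
  }
  multiChannelRecord(out, fs = fs, units = units, roles = roles, t0 = 0)
}

#' Simulate a 24-hour free-living scenario
#'
#' A regular office day: 16 daytime hours of sedentary work with two walks
#' (raised heart rate and SBP, depressed reflex gain, motion artifacts on
#' the pulse channel), then 8 hours of sleep with the reflex gain elevated
#' (doubled by default) and slowly oscillating, lower SBP and heart rate.
#' Cuff inflations are scheduled every 15 minutes by day and every 30
#' minutes by night (80 events per 24 h).
#'
#' @param night_gain_mult nocturnal multiplier on the reflex gain.
#' @param walk_gain_mult gain multiplier during walks (the profile's
#'   daytime minimum when < 1).
#' @param render render waveforms (FALSE returns \code{record = NULL} and
#'   is much lighter; the beat-level ground truth is always returned).
#' @param fs waveform rendering rate for the ambulatory prototype, Hz.
#' @param ... overrides passed to [simConfig()] (e.g. \code{seed}).
#' @return list with \code{record} ([MultiChannelRecord-class] or NULL),
#'   \code{events} ([EventList-class]) and \code{gt}
#'   ([SimGroundTruth-class]).
#' @export
scenario24h <- function(night_gain_mult = 2, walk_gain_mult = 0.5,
                        render = FALSE, fs = 80, ...) {
  day_end <- 16 * 3600
  walks <- data.frame(start = c(8 * 3600, 14 * 3600),
                      end = c(9 * 3600, 14.25 * 3600))
  # night split into hourly pieces with alternating gain for a slow
  # nocturnal oscillation around night_gain_mult
  nt <- seq(day_end, 24 * 3600 - 3600, by = 3600)
  night <- data.frame(start = nt, end = nt + 3600,
                      sbp_mult = 0.92,
                      gain_mult = night_gain_mult *
                        (1 + 0.08 * rep_len(c(-1, 1), length(nt))),
                      rr_mult = 1.15,
                      label = c("sleep", rep("", length(nt) - 1L)))
  daywalk <- data.frame(start = walks$start, end = walks$end,
                        sbp_mult = 1.10, gain_mult = walk_gain_mult,
                        rr_mult = 0.72, label = c("walk", "walk"))
  circadian <- rbind(daywalk, night)
  cuffs <- c(seq(600, day_end - 1, by = 900),
             seq(day_end + 600, 24 * 3600 - 1, by = 1800))
  cfg <- simConfig(duration_s = 24 * 3600, fs = fs,
                   circadian = circadian,
                   cuff_schedule = cuffs,
                   artifact_schedule = walks,
                   ...)
  gt <- simulateBeats(cfg)
  rec <- if (render) renderSignals(gt, cfg, channels = c("ECG", "PPG"))
         else NULL
  list(record = rec, events = gt@events, gt = gt)
}

#' Simulate an interventional cohort
#'
#' Virtual participants with individual reflex gains drawn uniformly from
#' \code{gain_range}, each measured in repeated sessions over the standard
#' interventions (rest, paced breathing, handgrip). Per-participant
#' surrogate couplings (PAT and RDRatio slopes on SBP) are jittered by a
#' lognormal factor with log-SD \code{coupling_noise}: at 0 every surrogate
#' index is a fixed multiple of the SBP index, and increasing it decouples
#' the surrogates from the reference.
#'
#' @param n_participants,n_sessions cohort shape (defaults 28 x 3).
#' @param interventions intervention labels; paced breathing boosts the LF
#'   oscillation, handgrip raises SBP and heart rate and lowers the gain.
#' @param gain_range true-gain range, ms/mmHg.
#' @param coupling_noise lognormal log-SD on the per-participant surrogate
#'   coupling slopes.
#' @param trial_s trial length, seconds.
#' @param seed RNG seed.
#' @param ... further [simConfig()] overrides applied to every trial.
#' @return list of trials, each a list with \code{participant},
#'   \code{session}, \code{intervention}, \code{bt} (a
#'   [BeatTable-class] of the observed beat series) and \code{trueGain}.
#' @export
simulateCohort <- function(n_participants = 28, n_sessions = 3,
                           interventions = c("rest", "paced_breathing",
                                             "handgrip"),
                           gain_range = c(4, 12), coupling_noise = 0.1,
                           trial_s = 180, seed = 1L, ...) {
  set.seed(seed)
  gains <- stats::runif(n_participants, gain_range[1], gain_range[2])
  # truncate to a 3-fold range: couplings beyond that are not physiologic
  patMult <- pmin(pmax(exp(stats::rnorm(n_participants, 0, coupling_noise)),
                       1 / 3), 3)
  rdrMult <- pmin(pmax(exp(stats::rnorm(n_participants, 0, coupling_noise)),
                       1 / 3), 3)
  trialSeeds <- sample.int(.Machine$integer.max %/% 2L,
                           n_participants * n_sessions *
                             length(interventions))
  trials <- list(); k <- 0L
  for (p in seq_len(n_participants)) {
    for (s in seq_len(n_sessions)) {
      for (iv in interventions) {
        k <- k + 1L
        ov <- switch(iv,
                     paced_breathing = list(lf_amp = 6),
                     handgrip = list(baseline_sbp = 138,
                                     rr_baseline_ms = 850,
                                     gain_ms_per_mmHg = gains[p] * 0.8),
                     list())
        # jitter the coupling slopes but keep the baseline-working-point
        # PAT/RDRatio fixed, so only the sensitivity varies across people
        base <- list(duration_s = trial_s,
                     gain_ms_per_mmHg = gains[p],
                     pat_slope_ms_per_mmHg = -1 * patMult[p],
                     pat_intercept_ms = 250 + 1 * patMult[p] * 120,
                     rdr_slope_per_mmHg = -0.005 * rdrMult[p],
                     rdr_intercept = 0.8 + 0.005 * rdrMult[p] * 120,
                     seed = trialSeeds[k])
        args <- utils::modifyList(utils::modifyList(base, ov), list(...))
        gt <- simulateBeats(do.call(simConfig, args))
        bt <- asBeatTable(gt@t, RR = gt@rr, PAT = gt@pat, SBP = gt@sbp,
                          RDRatio = gt@rdr, modality = "ABP")
        trials[[k]] <- list(participant = p, session = s,
                            intervention = iv, bt = bt,
                            trueGain = if (iv == "handgrip")
                              gains[p] * 0.8 else gains[p])
      }
    }
  }
  trials
}
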