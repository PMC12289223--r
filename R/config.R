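#' Spectral analysis configuration
#'
#' Parameters of the transfer-function / coherence estimator. Defaults
#' follow common cardiovascular practice: beat series resampled to 4 Hz,
#' linear trend removal, Welch averaging over 120-sample (30 s) Hann-tapered
#' segments with 50% overlap, LF band 0.04-0.15 Hz, HF band 0.15-0.40 Hz,
#' and a window-qualification coherence threshold of 0.14.
#'
#' @param resample_fs uniform resampling rate, Hz.
#' @param detrend_order 0 (mean removal) or 1 (linear trend removal) applied
#'   to the uniform series before Welch estimation.
#' @param segment_len Welch segment length in samples (>= 16).
#' @param overlap fractional segment overlap in [0, 1).
#' @param taper taper family; only \code{"hann"} is implemented.
#' @param lf_band,hf_band numeric(2) band edges in Hz.
#' @param coherence_threshold minimum mean LF magnitude-squared coherence
#'   for a window to qualify.
#' @param max_gap_s beat gaps longer than this (seconds) cannot be bridged
#'   by interpolation; the window is rejected.
#'
#' @return a validated list of class \code{"SpectralConfig"}.
#' @examples
#' cfg <- spectralConfig()
#' cfg$segment_len / cfg$resample_fs  # 30 s segments
#' @export
spectralConfig <- function(resample_fs = 4, detrend_order = 1,
                           segment_len = 120, overlap = 0.5,
                           taper = "hann",
                           lf_band = c(0.04, 0.15),
                           hf_band = c(0.15, 0.40),
                           coherence_threshold = 0.14,
                           max_gap_s = 5) {
  cfg <- list(resample_fs = resample_fs, detrend_order = detrend_order,
              segment_len = as.integer(segment_len), overlap = overlap,
              taper = match.arg(taper), lf_band = lf_band,
              hf_band = hf_band, coherence_threshold = coherence_threshold,
              max_gap_s = max_gap_s)
  stopifnot(resample_fs > 0, detrend_order %in% 0:1,
            cfg$segment_len >= 16L, overlap >= 0, overlap < 1,
            length(lf_band) == 2L, length(hf_band) == 2L,
            all(lf_band > 0), all(hf_band > 0),
            all(c(lf_band, hf_band) < resample_fs / 2),
            lf_band[1] < lf_band[2], hf_band[1] < hf_band[2],
            coherence_threshold >= 0, max_gap_s > 0)
  structure(cfg, class = c("SpectralConfig", "list"))
}

#' Ambulatory signal-qualification configuration
#'
#' Parameters of the five beat/epoch disqualification criteria: cuff
#' blanking, template SNR, physiologic PAT range, beat-to-beat variability
#' screening, and 1-minute epoch qualification.
#'
#' The PAT validity range is derived from an assumed fixed pulse path length
#' and pulse-wave velocities between \code{pwv_min} and \code{pwv_max}: valid
#' PAT lies in \code{[path_length_m / pwv_max, path_length_m / pwv_min]}
#' seconds (80-400 ms at the 0.8 m default).
#'
#' @param cuff_pre_s,cuff_post_s blanking interval around each cuff
#'   inflation start, seconds before / after.
#' @param template_beats consecutive beats forming the morphology template.
#' @param snr_threshold_db minimum template SNR (dB) per beat.
#' @param path_length_m assumed heart-to-sensor pulse path length, metres.
#' @param pwv_min,pwv_max physiologic pulse-wave velocity bounds, m/s.
#' @param max_rel_delta_rr,max_rel_delta_pat maximum allowed relative
#'   beat-to-beat change of RR and PAT.
#' @param epoch_s epoch length for the persistence criterion, seconds.
#' @param min_beat_fraction minimum fraction of ECG-expected beats that must
#'   survive criteria 1-4 in an epoch (inclusive bound).
#'
#' @return a validated list of class \code{"QualityConfig"}.
#' @export
qualityConfig <- function(cuff_pre_s = 15, cuff_post_s = 60,
                          template_beats = 5, snr_threshold_db = 0,
                          path_length_m = 0.8, pwv_min = 2, pwv_max = 10,
                          max_rel_delta_rr = 0.25, max_rel_delta_pat = 0.25,
                          epoch_s = 60, min_beat_fraction = 0.5) {
  cfg <- list(cuff_pre_s = cuff_pre_s, cuff_post_s = cuff_post_s,
              template_beats = as.integer(template_beats),
              snr_threshold_db = snr_threshold_db,
              path_length_m = path_length_m,
              pwv_min = pwv_min, pwv_max = pwv_max,
              max_rel_delta_rr = max_rel_delta_rr,
              max_rel_delta_pat = max_rel_delta_pat,
              epoch_s = epoch_s, min_beat_fraction = min_beat_fraction)
  stopifnot(cuff_pre_s > 0, cuff_post_s > 0, cfg$template_beats >= 3L,
            path_length_m > 0, pwv_min > 0, pwv_min < pwv_max,
            max_rel_delta_rr > 0, max_rel_delta_pat > 0, epoch_s > 0,
            min_beat_fraction > 0, min_beat_fraction <= 1)
  structure(cfg, class = c("QualityConfig", "list"))
}

#' PAT validity bounds implied by a quality configuration
#'
#' @param cfg a [qualityConfig()].
#' @return numeric(2), (min, max) valid PAT in ms.
#' @examples
#' patBounds(qualityConfig())  # 80, 400 ms for 0.8 m and PWV 2-10 m/s
#' @export
patBounds <- function(cfg = qualityConfig()) {
  1000 * c(cfg$path_length_m / cfg$pwv_max, cfg$path_length_m / cfg$pwv_min)
}

#' Simulation configuration
#'
#' Parameters of the open-loop baroreflex simulator. SBP is built from a
#' circadian baseline, a Mayer-wave LF oscillation (default 0.1 Hz), a
#' respiratory HF oscillation (default 0.25 Hz) and broadband beat-to-beat
#' variability; RR follows the full SBP deviation through the reflex gain
#' with a configurable beat delay; PAT and the rise/decay ratio are coupled
#' to SBP with negative slopes (arterial stiffening shortens PAT as pressure
#' rises). Measurement noise is added after the couplings, so the pre-noise
#' series obey them exactly.
#'
#' @param duration_s record length, seconds.
#' @param fs waveform rendering rate, Hz (>= 60 to resolve pulse
#'   morphology).
#' @param baseline_sbp mean SBP, mmHg.
#' @param lf_amp,lf_freq Mayer-wave amplitude (mmHg) and frequency (Hz,
#'   inside 0.04-0.15).
#' @param hf_amp,hf_freq respiratory amplitude (mmHg) and frequency (Hz,
#'   inside 0.15-0.40).
#' @param sbp_noise_sd broadband beat-to-beat SBP variability, mmHg. This
#'   variability passes through the reflex, exciting the transfer function
#'   at all frequencies.
#' @param gain_ms_per_mmHg true baroreflex gain, ms/mmHg.
#' @param reflex_delay_beats beats of delay between an SBP deviation and the
#'   RR response (0-2 keeps the LF gain analytic).
#' @param rr_baseline_ms mean RR, ms.
#' @param rr_noise_sd_ms RR measurement/physiologic noise not explained by
#'   SBP, ms.
#' @param pat_intercept_ms,pat_slope_ms_per_mmHg PAT coupling
#'   \code{PAT = a + b * SBP}; the default slope is negative.
#' @param pat_noise_sd_ms PAT measurement noise, ms.
#' @param rdr_intercept,rdr_slope_per_mmHg,rdr_noise_sd rise/decay-ratio
#'   coupling and noise.
#' @param dbp_offset_mmHg diastolic level of rendered pressure channels
#'   (SBP minus pulse pressure), mmHg.
#' @param measurement_noise_sd named additive waveform noise per channel
#'   role, in channel units.
#' @param dicrotic_amp relative amplitude of the rendered dicrotic wave (0
#'   disables it).
#' @param artifact_schedule data.frame (start, end) of motion-artifact
#'   bursts, seconds; NULL for none.
#' @param cuff_schedule numeric vector of cuff inflation start times,
#'   seconds; NULL for none. Inflations last 30 s.
#' @param circadian data.frame (start, end, sbp_mult, gain_mult, rr_mult,
#'   label) of piecewise multipliers; NULL for a flat profile.
#' @param seed integer RNG seed; identical configs and seeds give identical
#'   output.
#'
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(duration_s = 300, fs = 240,
                      baseline_sbp = 120,
                      lf_amp = 4, lf_freq = 0.1,
                      hf_amp = 2, hf_freq = 0.25,
                      sbp_noise_sd = 2,
                      gain_ms_per_mmHg = 8, reflex_delay_beats = 1,
                      rr_baseline_ms = 1000, rr_noise_sd_ms = 10,
                      pat_intercept_ms = 370, pat_slope_ms_per_mmHg = -1,
                      pat_noise_sd_ms = 2,
                      rdr_intercept = 1.4, rdr_slope_per_mmHg = -0.005,
                      rdr_noise_sd = 0.02,
                      dbp_offset_mmHg = 40,
                      measurement_noise_sd = c(ECG = 0.02, PPG = 0.01,
                                               ABP = 0.5, VCP = 0.5),
                      dicrotic_amp = 0.08,
                      artifact_schedule = NULL, cuff_schedule = NULL,
                      circadian = NULL, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(duration_s > 0, fs > 0, baseline_sbp > 0,
            gain_ms_per_mmHg > 0, rr_baseline_ms > 0,
            lf_freq >= 0.04, lf_freq <= 0.15,
            hf_freq >= 0.15, hf_freq <= 0.40,
            lf_amp >= 0, hf_amp >= 0, sbp_noise_sd >= 0,
            reflex_delay_beats >= 0,
            pat_slope_ms_per_mmHg < 0, rdr_slope_per_mmHg < 0,
            dicrotic_amp >= 0, dicrotic_amp < 0.3)
  cfg$reflex_delay_beats <- as.integer(reflex_delay_beats)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = c("SimConfig", "list"))
}
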