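#' Intra-participant precision of a BRS index
#'
#' The error of each repeated measurement is its difference from the
#' participant's median; precision is the sample SD (n - 1) of the pooled
#' errors, expressed as a percentage of the mean BRS across all
#' measurements. Identical repeats give 0%; the measure is invariant to a
#' common positive scale factor.
#'
#' @param value repeated BRS measurements.
#' @param participant participant id per measurement.
#' @return precision in percent.
#' @examples
#' intraPrecision(c(7, 8, 9, 7, 8, 9), c("A", "A", "A", "B", "B", "B"))
#' @export
intraPrecision <- function(value, participant) {
  stopifnot(length(value) == length(participant))
  keep <- !is.na(value)
  value <- value[keep]; participant <- participant[keep]
  if (!length(value)) stop("no values", call. = FALSE)
  med <- stats::ave(value, participant, FUN = stats::median)
  err <- value - med
  gm <- mean(value)
  if (gm == 0) stop("grand mean is zero: precision undefined", call. = FALSE)
  100 * stats::sd(err) / gm
}

#' Inter-participant variation of a BRS index
#'
#' Sample SD of the per-participant index values (typically the medians of
#' the repeats), expressed as a percentage of their mean. Note this is a
#' ratio measure: an affine shift of all values changes the percentage.
#'
#' @param medians one BRS value per participant.
#' @return variation in percent.
#' @examples
#' interVariation(c(6, 8, 10))  # 25
#' @export
interVariation <- function(medians) {
  medians <- medians[!is.na(medians)]
  if (length(medians) < 2L) stop("need >= 2 participants", call. = FALSE)
  gm <- mean(medians)
  if (gm == 0) stop("grand mean is zero: variation undefined", call. = FALSE)
  100 * stats::sd(medians) / gm
}

#' Correlate two BRS indices
#'
#' Pearson product-moment and Spearman rank correlation with two-sided
#' p-values; incomplete pairs are dropped pairwise.
#'
#' @param a,b paired index values.
#' @return list with \code{pearson}, \code{spearman}, \code{p_pearson},
#'   \code{p_spearman}, \code{n}, and \code{significant} (Pearson p <
#'   0.05). Zero variance in either input yields NA correlations with a
#'   warning.
#' @export
correlateIndices <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance: correlation undefined")
    return(list(pearson = NA_real_, spearman = NA_real_,
                p_pearson = NA_real_, p_spearman = NA_real_,
                n = length(a), significant = NA))
  }
  pe <- stats::cor.test(a, b, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  list(pearson = unname(pe$estimate), spearman = unname(sp$estimate),
       p_pearson = pe$p.value, p_spearman = sp$p.value,
       n = length(a), significant = pe$p.value < 0.05)
}

#' BRS of one trial / window from a beat table
#'
#' Convenience chain: qualified beats of one feature and RR are resampled
#' to the uniform grid, the transfer function is estimated, and the LF
#' band average is returned.
#'
#' @param bt a [BeatTable-class].
#' @param feature input feature column (\code{"SBP"}, \code{"PAT"},
#'   \code{"RDRatio"}, \code{"PeakAmp"}, \code{"Upstroke"}).
#' @param cfg a [spectralConfig()].
#' @param window optional (start, end) s.
#' @return a [BRSIndex-class], or NULL when the window is rejected
#'   (too short or gapped).
#' @export
trialBRS <- function(bt, feature = "SBP", cfg = spectralConfig(),
                     window = NULL) {
  stopifnot(is(bt, "BeatTable"))
  b <- bt@beats[bt@qualified, , drop = FALSE]
  if (!feature %in% names(b))
    stop("beat table has no feature '", feature, "'", call. = FALSE)
  ux <- toUniformSeries(b$t, b[[feature]], cfg, window = window)
  uy <- toUniformSeries(b$t, b$RR, cfg, window = window)
  if (!ux$ok || !uy$ok) return(NULL)
  est <- estimateTransfer(ux$x, uy$x, cfg)
  brsIndex(est, cfg, inputFeature = feature, modality = bt@modality,
           window = window %||% range(b$t))
}

#' Run the interventional comparison
#'
#' For every trial (participant x session x intervention) and input
#' feature the BRS index is estimated; repeats are collapsed to the
#' per-participant median; intra-participant precision and
#' inter-participant variation are computed per index, and all indices are
#' cross-correlated (Pearson and Spearman) across participant x
#' intervention cells.
#'
#' @param trials list of trials as produced by [simulateCohort()]: each a
#'   list with \code{participant}, \code{session}, \code{intervention} and
#'   \code{bt} (a [BeatTable-class]).
#' @param features input features to evaluate (all must be columns of the
#'   trial beat tables).
#' @param cfg a [spectralConfig()].
#' @param collapse \code{"median"} (default) or \code{"mean"} over repeats.
#' @return a [StudyResult-class].
#' @export
runInterventional <- function(trials, features = c("SBP", "PAT", "RDRatio"),
                              cfg = spectralConfig(),
                              collapse = c("median", "mean")) {
  collapse <- match.arg(collapse)
  rows <- list(); k <- 0L
  for (tr in trials) {
    for (f in features) {
      idx <- trialBRS(tr$bt, f, cfg)
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant = tr$participant, session = tr$session,
        intervention = tr$intervention,
        index = paste0("BRS_", f, ",", tr$bt@modality),
        value = if (is.null(idx)) NA_real_ else idx@value,
        coherence = if (is.null(idx)) NA_real_ else idx@meanLFCoherence,
        stringsAsFactors = FALSE)
    }
  }
  raw <- do.call(rbind, rows)
  miss <- stats::aggregate(value ~ participant + intervention + index,
                           raw, FUN = function(v) sum(is.na(v)),
                           na.action = NULL)
  if (any(miss$value > 0))
    warning(sum(miss$value), " trial estimate(s) missing; medians taken ",
            "over the available repeats")
  fun <- if (collapse == "median") {
    function(v) stats::median(v, na.rm = TRUE)
  } else function(v) mean(v, na.rm = TRUE)
  brs <- stats::aggregate(value ~ participant + intervention + index,
                          raw, FUN = fun, na.action = NULL)
  prec <- do.call(rbind, lapply(split(raw, raw$index), function(d) {
    med <- brs[brs$index == d$index[1], ]
    data.frame(index = d$index[1],
               intra_pct = intraPrecision(
                 d$value, paste(d$participant, d$intervention)),
               inter_pct = if (length(unique(med$participant)) >= 2L)
                 interVariation(med$value) else NA_real_)
  }))
  rownames(prec) <- NULL
  idxNames <- sort(unique(raw$index))
  wide <- stats::reshape(brs, idvar = c("participant", "intervention"),
                         timevar = "index", direction = "wide")
  m <- as.matrix(wide[grep("^value\\.", names(wide))])
  colnames(m) <- sub("^value\\.", "", colnames(m))
  m <- m[, idxNames, drop = FALSE]
  nIdx <- length(idxNames)
  corr <- list()
  for (what in c("pearson", "spearman", "p_pearson", "p_spearman")) {
    corr[[what]] <- matrix(NA_real_, nIdx, nIdx,
                           dimnames = list(idxNames, idxNames))
  }
  for (i in seq_len(nIdx)) for (j in seq_len(nIdx)) {
    if (i == j) {
      corr$pearson[i, j] <- corr$spearman[i, j] <- 1
      corr$p_pearson[i, j] <- corr$p_spearman[i, j] <- 0
    } else {
      cc <- tryCatch(correlateIndices(m[, i], m[, j]),
                     error = function(e)
                       list(pearson = NA_real_, spearman = NA_real_,
                            p_pearson = NA_real_, p_spearman = NA_real_))
      corr$pearson[i, j] <- cc$pearson
      corr$spearman[i, j] <- cc$spearman
      corr$p_pearson[i, j] <- cc$p_pearson
      corr$p_spearman[i, j] <- cc$p_spearman
    }
  }
  new("StudyResult", brs = brs, precision = prec, correlations = corr)
}

#' Run the 24-hour ambulatory profile
#'
#' BRS is estimated per input feature over 4-minute sliding windows
#' hopping 60 s (75% overlap), each window qualified by its mean LF
#' coherence (threshold 0.14). On a 15-minute grid, each 1-hour span
#' centered on the grid point is summarized by the median BRS of its
#' qualified windows, their standard error and median coherence, and the
#' percentage of qualified windows; HRV band powers and heart rate are
#' averaged over the same spans, and cuff SBP readings falling in the span
#' are averaged for reference. Spans with no qualified window yield NA.
#'
#' @param bt a (typically [qualifyBeats()]-processed) [BeatTable-class]
#'   covering at least 2 hours.
#' @param features input features to profile.
#' @param cfg a [spectralConfig()].
#' @param window_s,hop_s 4-minute window length and 60 s hop.
#' @param span_s,grid_s 1-hour summary span and 15-minute grid spacing.
#' @param cuff_readings optional data.frame (t, sbp) of cuff reference
#'   readings.
#' @return an [AmbulatoryProfile-class].
#' @export
runAmbulatory <- function(bt, features = c("PAT", "RDRatio"),
                          cfg = spectralConfig(),
                          window_s = 240, hop_s = 60,
                          span_s = 3600, grid_s = 900,
                          cuff_readings = NULL) {
  stopifnot(is(bt, "BeatTable"))
  b <- bt@beats[bt@qualified, , drop = FALSE]
  if (!nrow(b) || diff(range(b$t)) < 2 * 3600)
    stop("need a qualified beat table covering >= 2 h", call. = FALSE)
  tmin <- floor(min(b$t) / 60) * 60
  tmax <- max(b$t)
  starts <- seq(tmin, tmax - window_s, by = hop_s)
  wrows <- list(); hrows <- list(); k <- 0L
  for (s in starts) {
    win <- c(s, s + window_s)
    uy <- toUniformSeries(b$t, b$RR, cfg, window = win)
    hr <- hlf <- hhf <- NA_real_
    if (uy$ok) {
      sel <- b$t >= win[1] & b$t <= win[2]
      hr <- mean(60000 / b$RR[sel], na.rm = TRUE)
      hlf <- hrvBandPower(uy$x, "lf", cfg)
      hhf <- hrvBandPower(uy$x, "hf", cfg)
    }
    hrows[[length(hrows) + 1L]] <-
      data.frame(t_start = s, HR = hr, HRV_LF = hlf, HRV_HF = hhf)
    for (f in features) {
      k <- k + 1L
      if (!uy$ok) {
        wrows[[k]] <- data.frame(t_start = s, t_end = win[2], feature = f,
                                 value = NA_real_, coherence = NA_real_,
                                 qualified = FALSE, reason = uy$reason)
        next
      }
      ux <- toUniformSeries(b$t, b[[f]], cfg, window = win)
      if (!ux$ok) {
        wrows[[k]] <- data.frame(t_start = s, t_end = win[2], feature = f,
                                 value = NA_real_, coherence = NA_real_,
                                 qualified = FALSE, reason = ux$reason)
        next
      }
      est <- estimateTransfer(ux$x, uy$x, cfg)
      idx <- brsIndex(est, cfg, inputFeature = f, modality = bt@modality,
                      window = win)
      wrows[[k]] <- data.frame(t_start = s, t_end = win[2], feature = f,
                               value = idx@value,
                               coherence = idx@meanLFCoherence,
                               qualified = idx@qualified, reason = "")
    }
  }
  wdf <- do.call(rbind, wrows)
  hdf <- do.call(rbind, hrows)
  grid <- seq(tmin + span_s / 2, tmax - span_s / 2 + 1e-9, by = grid_s)
  grows <- lapply(grid, function(g) {
    lo <- g - span_s / 2; hi <- g + span_s / 2
    ctr <- wdf$t_start + window_s / 2
    row <- list(t = g)
    for (f in features) {
      d <- wdf[wdf$feature == f & ctr >= lo & ctr < hi, , drop = FALSE]
      q <- d[d$qualified, , drop = FALSE]
      row[[paste0("BRS_", f)]] <-
        if (nrow(q)) stats::median(q$value) else NA_real_
      row[[paste0("se_", f)]] <-
        if (nrow(q) > 1L) stats::sd(q$value) / sqrt(nrow(q)) else NA_real_
      row[[paste0("coh_", f)]] <-
        if (nrow(q)) stats::median(q$coherence) else NA_real_
      row[[paste0("qualified_pct_", f)]] <-
        if (nrow(d)) 100 * nrow(q) / nrow(d) else NA_real_
    }
    hctr <- hdf$t_start + window_s / 2
    hd <- hdf[hctr >= lo & hctr < hi, , drop = FALSE]
    row$HRV_LF <- mean(hd$HRV_LF, na.rm = TRUE)
    row$HRV_HF <- mean(hd$HRV_HF, na.rm = TRUE)
    row$HR <- mean(hd$HR, na.rm = TRUE)
    row$cuffSBP <- if (!is.null(cuff_readings)) {
      sel <- cuff_readings$t >= lo & cuff_readings$t < hi
      if (any(sel)) mean(cuff_readings$sbp[sel]) else NA_real_
    } else NA_real_
    as.data.frame(row)
  })
  new("AmbulatoryProfile", grid = do.call(rbind, grows), windows = wdf)
}
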